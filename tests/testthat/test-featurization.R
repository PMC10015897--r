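test_that("catalog enumerates canonicalized environments with support pruning", {
  mols <- fixture_mols()
  cat0 <- build_catalog(list(mols$methane), radius = 0, min_support = 1)
  expect_length(cat0$keys, 1)

  catb <- build_catalog(list(mols$benzene), radius = 1, min_support = 1)
  expect_length(catb$keys, 2)  # atom environment + 3-atom aromatic path
  v <- mff_featurize(mols$benzene, catb)
  expect_equal(unname(sort(v)), c(6L, 6L))  # all six atoms equivalent

  # support threshold prunes fragments present in a single molecule
  cat2 <- build_catalog(list(mols$benzene, mols$toluene), radius = 1,
                        min_support = 2)
  counts_tol <- mff_featurize(mols$toluene, cat2)
  expect_true(all(mff_featurize(mols$benzene, cat2) > 0))
  expect_error(build_catalog(list()), "empty")
})

test_that("fragment counts scale with duplicated substructure", {
  mols <- fixture_mols()
  catb <- build_catalog(list(mols$benzene), radius = 0, min_support = 1)
  expect_equal(sum(mff_featurize(mols$benzene, catb)), 6)
  expect_equal(sum(mff_featurize(mols$biphenyl, catb)), 12)
  # disjoint vocabulary gives the zero vector
  f2 <- parse_molecules("FF")[[1]]
  expect_true(all(mff_featurize(mols$ethane,
                                build_catalog(list(f2), 1, 1)) == 0))
})

test_that("catalog build is deterministic and order-invariant", {
  mols <- fixture_mols()
  set1 <- list(mols$benzene, mols$toluene, mols$nitroaniline4)
  c1 <- build_catalog(set1, radius = 2, min_support = 1)
  c2 <- build_catalog(rev(set1), radius = 2, min_support = 1)
  expect_identical(c1$keys, c2$keys)
  path <- tempfile(fileext = ".json")
  write_catalog(c1, path)
  expect_identical(read_catalog(path)$keys, c1$keys)
  expect_identical(read_catalog(path)$index, c1$index)
})

test_that("fragment vectors are invariant to how the input SMILES is written", {
  variants <- list(
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("Nc1ccc(cc1)[N+](=O)[O-]", "[O-][N+](=O)c1ccc(N)cc1"),
    c("Cc1ccccc1", "c1ccccc1C"),
    c("O=C/C=C/c1ccccc1", "c1ccccc1/C=C/C=O")
  )
  for (v in variants) {
    ms <- parse_molecules(v)
    cat1 <- build_catalog(ms[1], radius = 3, min_support = 1)
    expect_identical(mff_featurize(ms[[1]], cat1), mff_featurize(ms[[2]], cat1))
  }
})

test_that("PEOE charges conserve the net molecular charge to 1e-6", {
  mols <- fixture_mols()
  for (nm in names(mols)) {
    q <- peoe_charges(mols[[nm]])
    expect_equal(sum(q), sum(mols[[nm]]$atoms$charge), tolerance = 1e-6,
                 label = paste("charge sum for", nm))
  }
  # a net-charged species conserves its formal charge
  ion <- parse_molecules("C[N+](C)(C)C")[[1]]
  expect_equal(sum(peoe_charges(ion)), 1, tolerance = 1e-6)
})

test_that("PEOE charges agree directionally with the OpenBabel reference", {
  m <- fixture_mols()$nitroaniline4
  q <- peoe_charges(m)
  # heavy-atom correlation with the (4-decimal, unfolded) OpenBabel values
  expect_gt(cor(q, m$ob_gasteiger), 0.9)
  # nitro nitrogen positive, amine nitrogen negative
  expect_gt(q[m$atoms$element == "N" & m$atoms$charge == 1], 0)
  expect_lt(q[m$atoms$element == "N" & m$atoms$charge == 0], 0)
})

test_that("additive logP/MR attributions are self-consistent and match the
           OpenBabel whole-molecule value where typings coincide", {
  mols <- fixture_mols()
  b <- mols$benzene
  expect_equal(sum(atomic_logp(b)), 1.6866, tolerance = 1e-4)
  expect_equal(sum(atomic_mr(b)), 26.442, tolerance = 1e-2)
  # polar groups carry negative logP attributions
  na <- mols$nitroaniline4
  att <- atom_attributions(na, "logp")
  expect_lt(att$values[na$atoms$element == "N" & na$atoms$charge == 0], 0)
  # PEOE has no silicon parameters: explicit unparameterized-atom error
  expect_error(atom_attributions(parse_molecules("CC[SiH3]")[[1]], "peoe_charge"),
               "unparameterized")
})

test_that("fragment-aggregated properties order correctly", {
  mols <- fixture_mols()
  cat2 <- build_catalog(list(mols$benzene, mols$nitrobenzene), radius = 2,
                        min_support = 1)
  for (nm in c("benzene", "nitrobenzene", "stilbene")) {
    m <- mols[[nm]]
    for (p in c("peoe_charge", "logp", "mr")) {
      f <- mff_moe_features(m, cat2, atom_attributions(m, p))
      expect_gte(f[[paste0(p, "_max")]], f[[paste0(p, "_mean")]])
      expect_gte(f[[paste0(p, "_mean")]], f[[paste0(p, "_min")]])
    }
  }
  fb <- mff_moe_features(mols$benzene, cat2,
                         atom_attributions(mols$benzene, "peoe_charge"))
  fn <- mff_moe_features(mols$nitrobenzene, cat2,
                         atom_attributions(mols$nitrobenzene, "peoe_charge"))
  expect_gt(fn[["peoe_charge_max"]], fb[["peoe_charge_max"]])
  # molecule sharing no catalog fragment is degenerate with zero features
  catf <- build_catalog(parse_molecules("FF"), radius = 1, min_support = 1)
  f0 <- mff_moe_features(mols$ethane, catf,
                         atom_attributions(mols$ethane, "logp"))
  expect_true(all(f0 == 0))
  expect_true(attr(f0, "degenerate"))
})

test_that("single-fragment molecule collapses all aggregations to one value", {
  m <- fixture_mols()$methane
  cat0 <- build_catalog(list(m), radius = 0, min_support = 1)
  f <- mff_moe_features(m, cat0, atom_attributions(m, "mr"))
  expect_equal(f[["mr_max"]], f[["mr_min"]])
  expect_equal(f[["mr_max"]], f[["mr_mean"]])
  expect_equal(f[["mr_max"]], f[["mr_sum"]])
})

test_that("general descriptors follow their definitions", {
  mols <- fixture_mols()
  d <- general_descriptors(mols$methane)
  expect_equal(d[["mol_wt"]], 16.043, tolerance = 0.01)
  for (nm in c("benzene", "nitroaniline4", "stilbene", "anisole")) {
    d <- general_descriptors(mols[[nm]])
    expect_gte(d[["max_partial_charge"]], d[["min_partial_charge"]])
    expect_equal(d[["max_abs_partial_charge"]],
                 max(abs(d[["max_partial_charge"]]), abs(d[["min_partial_charge"]])))
  }
  expect_equal(general_descriptors(mols$naphthalene)[["n_aromatic_rings"]], 2)
})

test_that("matrix assembly concatenates blocks, imputes, and tags provenance", {
  mols <- fixture_mols()
  nm <- c("benzene", "toluene", "styrene", "stilbene", "anisole",
          "nitrobenzene", "butadiene", "pyridine", "furan", "phenol")
  samples <- data.frame(molecule_id = nm,
                        smiles = vapply(mols[nm], `[[`, "", "smiles"),
                        wavelength = 800, et30 = 33.9, dielectric = 2.38,
                        dipole = 0.36, stringsAsFactors = FALSE)
  catalog <- build_catalog(mols[nm], radius = 2, min_support = 2)
  fm <- assemble_matrix(samples, mols[nm], catalog)
  n_moe <- 3 * 4
  expect_equal(ncol(fm$x), length(catalog$keys) + 36 + 16 + n_moe + 4)
  expect_false(any(!is.finite(fm$x)))
  expect_identical(unique(fm$features$block),
                   c("mff", "general", "conjugation", "mff_moe", "experimental"))
  expect_false(anyDuplicated(fm$features$name) > 0)
  # single sample: one row whose values equal the per-block outputs
  fm1 <- assemble_matrix(samples[3, ], mols["styrene"], catalog)
  expect_equal(nrow(fm1$x), 1)
  expect_equal(unname(fm1$x[1, paste0("mff|", catalog$keys)]),
               unname(as.numeric(mff_featurize(mols$styrene, catalog))))
  # shuffling sample order permutes rows, not values
  ord <- c(4, 1, 10, 3, 2, 7, 5, 9, 8, 6)
  fm2 <- assemble_matrix(samples[ord, ], mols[nm][ord], catalog)
  expect_equal(fm2$x[samples$molecule_id, ], fm$x)
})
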