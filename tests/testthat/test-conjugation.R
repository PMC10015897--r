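test_that("perception finds the expected systems", {
  mols <- fixture_mols()
  expect_length(perceive_conjugated_systems(mols$ethane), 0)
  sb <- perceive_conjugated_systems(mols$benzene)
  expect_length(sb, 1)
  expect_length(sb[[1]]$atom_indices, 6)
  expect_length(sb[[1]]$bond_indices, 6)
  ss <- perceive_conjugated_systems(mols$stilbene)
  expect_length(ss, 1)
  expect_length(ss[[1]]$atom_indices, 14)
  # an isolated double bond is perceived but flagged minimal
  se <- perceive_conjugated_systems(parse_molecules("C=C")[[1]])
  expect_length(se, 1)
  expect_true(se[[1]]$minimal)
})

test_that("conjugation length equals the all-pairs BFS diameter on the fixture set", {
  mols <- fixture_mols()
  expected <- c(butadiene = 3, benzene = 3, stilbene = 9)
  for (nm in names(expected)) {
    m <- mols[[nm]]
    expect_equal(conju_max_distance(perceive_conjugated_systems(m), m),
                 expected[[nm]], label = nm)
  }
  for (nm in names(mols)) {
    m <- mols[[nm]]
    expect_equal(conju_max_distance(perceive_conjugated_systems(m), m),
                 oracle_L(m), label = paste("BFS oracle for", nm))
  }
})

test_that("polyene homologues gain exactly two bonds of length per unit", {
  Ls <- vapply(2:9, function(k) {
    m <- parse_molecules(strrep("C=C", k))[[1]]
    conju_max_distance(perceive_conjugated_systems(m), m)
  }, 0L)
  expect_equal(diff(Ls), rep(2L, 7))
  expect_equal(Ls[1], 3L)
})

test_that("branch ratio is the degree>=3 fraction of the largest system", {
  mols <- fixture_mols()
  for (nm in c("polyene4", "benzene")) {
    m <- mols[[nm]]
    expect_equal(conju_branch_ratio(perceive_conjugated_systems(m), m), 0)
  }
  m <- mols$triphenylamine
  expect_equal(conju_branch_ratio(perceive_conjugated_systems(m), m), 4 / 19)
})

test_that("conjugated weights and areas behave", {
  mols <- fixture_mols()
  m <- mols$benzene
  w <- conju_weights_and_area(perceive_conjugated_systems(m), m)
  expect_equal(w$conju_wt, 78.11, tolerance = 0.01)
  expect_equal(w$conju_wt, w$full_wt)
  e <- mols$ethane
  we <- conju_weights_and_area(perceive_conjugated_systems(e), e)
  expect_equal(we$conju_wt, 0)
  expect_equal(we$conju_stru_vsa, 0)
  t <- mols$toluene
  wt <- conju_weights_and_area(perceive_conjugated_systems(t), t)
  expect_lt(wt$conju_wt, wt$full_wt)  # methyl carbon excluded
  expect_equal(wt$conju_atom_wt, wt$full_wt / 7)
})

test_that("donor/acceptor assignment and DAratio", {
  mols <- fixture_mols()
  m <- mols$nitroaniline4
  da <- assign_donor_acceptor(m, perceive_conjugated_systems(m))
  expect_true(da$defined)
  expect_gt(da$daratio, 0.75)  # D and A span nearly the whole diameter
  expect_lte(da$daratio, 1)
  # no donor or acceptor: undefined, ratio 0
  b <- mols$benzene
  dab <- assign_donor_acceptor(b, perceive_conjugated_systems(b))
  expect_false(dab$defined)
  expect_equal(dab$daratio, 0)
  # symmetric D-pi-D has no acceptor
  dd <- parse_molecules("CN(C)c1ccc(cc1)N(C)C")[[1]]
  dad <- assign_donor_acceptor(dd, perceive_conjugated_systems(dd))
  expect_false(dad$defined)
  expect_length(dad$acceptor_atoms, 0)
  expect_gt(length(dad$donor_atoms), 0)
})

test_that("daratio lies in [0,1] whenever defined across the fixture set", {
  mols <- fixture_mols()
  for (nm in names(mols)) {
    m <- mols[[nm]]
    da <- assign_donor_acceptor(m, perceive_conjugated_systems(m))
    if (da$defined) {
      expect_gte(da$daratio, 0)
      expect_lte(da$daratio, 1)
    }
  }
})

test_that("conjugation features are invariant to atom reordering", {
  pairs <- list(
    c("c1ccccc1/C=C/c1ccccc1", "C(=C/c1ccccc1)\\c1ccccc1"),
    c("Nc1ccc(cc1)[N+](=O)[O-]", "[O-][N+](=O)c1ccc(N)cc1")
  )
  for (p in pairs) {
    ms <- parse_molecules(p)
    expect_equal(conjugation_features(ms[[1]]), conjugation_features(ms[[2]]))
  }
})

test_that("substructure pattern matcher handles the library syntax", {
  mols <- fixture_mols()
  nb <- mols$nitrobenzene
  hits <- match_pattern(nb, "[N+](=[OX1])[O-]")
  expect_length(hits, 1)
  expect_equal(nb$atoms$element[hits[[1]][1]], "N")
  # ring closure: benzene matches c1ccccc1 (12 automorphisms)
  expect_length(match_pattern(mols$benzene, "c1ccccc1"), 12)
  # H/X counts discriminate primary from tertiary amines
  expect_length(match_pattern(mols$nitroaniline4, "[NX3;H2]"), 1)
  expect_length(match_pattern(mols$triphenylamine, "[NX3;H2]"), 0)
  expect_length(match_pattern(mols$triphenylamine, "[NX3;H0]([#6])([#6])[#6]"), 6)
  expect_length(match_pattern(mols$benzonitrile, "[CX2]#[NX1]"), 1)
})
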