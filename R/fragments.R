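# Molecular fragment fingerprint (MFF) featurization.
#
# Fragments are atom-centred environments of radius 0..R (all atoms within R
# bonds of the centre, with every bond among them), rendered as *standalone*
# canonical SMILES: the context beyond the fragment is discarded and open
# valences are filled with implicit hydrogens, so identical fragments from
# different molecules collide on one key. The count vector records how many
# atom-centred environments of the molecule map to each catalog key.

.tpa_cache <- new.env(parent = emptyenv())

# render induced subgraphs as a V2000 SDF string (kekulized orders, formal
# charges as M CHG lines) for batch canonicalization by OpenBabel
.fragment_sdf <- function(mol, sets, names) {
  blocks <- vapply(seq_along(sets), function(k) {
    atoms <- sets[[k]]
    idx <- match(seq_len(nrow(mol$atoms)), atoms)
    b <- mol$bonds[mol$bonds$i %in% atoms & mol$bonds$j %in% atoms, , drop = FALSE]
    lines <- c(
      names[k], "  tpascreen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", length(atoms), nrow(b)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              0, 0, 0, mol$atoms$element[atoms]),
      if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", idx[b$i], idx[b$j], b$order)
    )
    chg <- which(mol$atoms$charge[atoms] != 0)
    if (length(chg)) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                               paste0(sprintf("%4d%4d", chg, mol$atoms$charge[atoms][chg]),
                                      collapse = "")))
    }
    paste(c(lines, "M  END", "$$$$"), collapse = "\n")
  }, "")
  paste0(paste(blocks, collapse = "\n"), "\n")
}

# all atom-centred environments of one molecule: data.frame(center, radius,
# set_id, key) plus the atom sets themselves
mol_environments <- function(mol, radius) {
  ckey <- paste0(mol$smiles, "|", radius)
  hit <- get0(ckey, envir = .tpa_cache)
  if (!is.null(hit)) return(hit)
  n <- nrow(mol$atoms)
  neigh <- igraph::ego(mol$graph, order = radius, nodes = seq_len(n), mindist = 0)
  dmat <- igraph::distances(mol$graph)
  env <- expand.grid(center = seq_len(n), radius = 0:radius)
  sets <- vector("list", nrow(env))
  sig <- character(nrow(env))
  for (k in seq_len(nrow(env))) {
    a <- env$center[k]; r <- env$radius[k]
    s <- sort(which(dmat[a, ] <= r))
    sets[[k]] <- s
    sig[k] <- paste(s, collapse = ",")
  }
  uniq <- !duplicated(sig)
  uniq_sets <- sets[uniq]
  uniq_sig <- sig[uniq]
  sdftxt <- .fragment_sdf(mol, uniq_sets, paste0("f", seq_along(uniq_sets)))
  res <- ChemmineOB::convertFormat("SDF", "CAN", sdftxt)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, "", 1)
  nm <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
  keymap <- stats::setNames(smi, nm)
  uniq_keys <- unname(keymap[paste0("f", seq_along(uniq_sets))])
  if (anyNA(uniq_keys)) stop("fragment canonicalization failed for molecule ", mol$id)
  env$set_id <- match(sig, uniq_sig)
  env$key <- uniq_keys[env$set_id]
  out <- list(env = env, sets = uniq_sets)
  assign(ckey, out, envir = .tpa_cache)
  out
}

#' Build a fragment catalog
#'
#' Enumerates all atom-centred environments of radius 0..`radius` across the
#' molecule list, keeps keys occurring in at least `min_support` molecules,
#' and assigns deterministic (lexicographic) column indices.
#'
#' @param molecules list of `tpa_mol` objects (NULL entries are skipped).
#' @param radius maximum environment radius in bonds (0..4).
#' @param min_support minimum number of molecules a fragment must occur in.
#' @return a `fragment_catalog`: list with `keys` (ordered character),
#'   `index` (named integer map), `radius`, `min_support`.
#' @export
build_catalog <- function(molecules, radius = 4, min_support = 2) {
  molecules <- Filter(Negate(is.null), molecules)
  if (!length(molecules)) stop("empty molecule list", call. = FALSE)
  stopifnot(radius >= 0)
  support <- new.env(parent = emptyenv())
  for (mol in molecules) {
    keys <- unique(mol_environments(mol, radius)$env$key)
    for (k in keys) assign(k, get0(k, envir = support, ifnotfound = 0L) + 1L, envir = support)
  }
  keys <- ls(support)
  counts <- vapply(keys, function(k) get(k, envir = support), 0L)
  keep <- sort(keys[counts >= min_support], method = "radix")
  structure(list(
    keys = keep,
    index = stats::setNames(seq_along(keep), keep),
    radius = radius,
    min_support = min_support
  ), class = "fragment_catalog")
}

#' @export
print.fragment_catalog <- function(x, ...) {
  cat("<fragment_catalog> ", length(x$keys), " fragments, radius ", x$radius,
      ", min_support ", x$min_support, "\n", sep = "")
  invisible(x)
}

#' Save / load a fragment catalog as JSON
#' @param catalog a `fragment_catalog`.
#' @param path file path.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(
    list(keys = catalog$keys, radius = catalog$radius,
         min_support = catalog$min_support),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(keys = x$keys,
                 index = stats::setNames(seq_along(x$keys), x$keys),
                 radius = x$radius, min_support = x$min_support),
            class = "fragment_catalog")
}

#' Fragment count vector for one molecule
#'
#' @param mol a `tpa_mol`.
#' @param catalog a `fragment_catalog`.
#' @return integer vector of length `length(catalog$keys)`, named by key:
#'   the number of atom-centred environments whose canonical key equals each
#'   catalog entry. Environments not in the catalog are ignored.
#' @export
mff_featurize <- function(mol, catalog) {
  env <- mol_environments(mol, catalog$radius)$env
  counts <- integer(length(catalog$keys))
  names(counts) <- catalog$keys
  tab <- table(env$key)
  hit <- intersect(names(tab), catalog$keys)
  counts[hit] <- as.integer(tab[hit])
  counts
}

#' Fragment-aggregated atomic property (MFF-MOE) features
#'
#' For every catalog fragment instance in the molecule, sums the per-atom
#' property attribution over the fragment's atoms, then aggregates the
#' instance sums per molecule.
#'
#' @param mol a `tpa_mol`.
#' @param catalog a `fragment_catalog`.
#' @param attribution an `atom_attribution` from [atom_attributions()].
#' @param aggregations subset of `c("max", "min", "mean", "sum")`.
#' @return named numeric vector, e.g. `peoe_charge_max`; 0 with a
#'   `degenerate` attribute when the molecule has no catalog fragment.
#' @export
mff_moe_features <- function(mol, catalog, attribution,
                             aggregations = c("max", "min", "mean", "sum")) {
  aggregations <- match.arg(aggregations, several.ok = TRUE)
  me <- mol_environments(mol, catalog$radius)
  in_cat <- me$env$key %in% catalog$keys
  nm <- paste0(attribution$property_name, "_", aggregations)
  if (!any(in_cat)) {
    out <- stats::setNames(rep(0, length(aggregations)), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  set_sums <- vapply(me$sets, function(s) sum(attribution$values[s]), 0)
  inst <- set_sums[me$env$set_id[in_cat]]
  vals <- vapply(aggregations, function(a) {
    switch(a, max = max(inst), min = min(inst), mean = mean(inst), sum = sum(inst))
  }, 0)
  stats::setNames(vals, nm)
}
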