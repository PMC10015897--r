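#' @importFrom igraph graph_from_data_frame distances components degree V ecount vcount
NULL

# Internal molecule representation
#
# A `tpa_mol` bundles everything downstream featurization needs:
#   atoms: data.frame(element, charge, aromatic, nh, degree)
#   bonds: data.frame(i, j, order, aromatic)   (kekulized orders 1/2/3)
#   graph: igraph object over heavy atoms
# Atom order is the OpenBabel order obtained from parsing the *canonical*
# SMILES, so two input SMILES of the same molecule yield identical objects.

.strip_to_largest_fragment <- function(mol) {
  comp <- igraph::components(mol$graph)
  if (comp$no <= 1) return(mol)
  keep <- which(comp$membership == which.max(comp$csize))
  .subset_mol(mol, keep)
}

.subset_mol <- function(mol, keep) {
  idx <- match(seq_len(nrow(mol$atoms)), keep)
  bonds <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  bonds$i <- idx[bonds$i]
  bonds$j <- idx[bonds$j]
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  mol$atoms <- atoms
  mol$bonds <- bonds
  mol$graph <- .mol_graph(nrow(atoms), bonds)
  if (!is.null(mol$atom_type)) mol$atom_type <- mol$atom_type[keep]
  if (!is.null(mol$ob_gasteiger)) mol$ob_gasteiger <- mol$ob_gasteiger[keep]
  mol
}

.mol_graph <- function(n, bonds) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$i, bonds$j))
  g
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Unparsable inputs yield
#' `NA` rather than an error, so rejection reporting can happen upstream.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of the same length; `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  convert <- function(idx) {
    txt <- paste0(smiles[idx], " x", idx, collapse = "\n")
    res <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(txt, "\n")),
      error = function(e) ""
    ))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
    smi <- vapply(parts, `[[`, "", 1)
    ok <- grepl("^x[0-9]+$", got)
    ids <- as.integer(sub("^x", "", got[ok]))
    out[ids] <<- smi[ok]
    # OpenBabel aborts a batch at the first bad molecule; bisect to isolate
    missing <- idx[is.na(out[idx])]
    if (length(missing) == length(idx) && length(idx) > 1) {
      half <- length(idx) %/% 2
      convert(idx[seq_len(half)])
      convert(idx[-seq_len(half)])
    } else if (length(missing) > 0 && length(missing) < length(idx)) {
      if (length(missing) == 1) return(invisible(NULL)) else convert(missing)
    }
    invisible(NULL)
  }
  convert(seq_len(n))
  out
}

# Parse a @<TRIPOS> MOL2 text block (possibly many molecules) into per-molecule
# lists with atom types, formal charges, and aromatic bond flags.
.parse_mol2 <- function(txt) {
  blocks <- strsplit(txt, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    section <- function(tag) {
      s0 <- grep(paste0("@<TRIPOS>", tag), lines, fixed = TRUE)[1]
      if (is.na(s0)) return(character())
      ends <- grep("@<TRIPOS>", lines, fixed = TRUE)
      send <- min(c(ends[ends > s0], length(lines) + 1)) - 1
      if (s0 + 1 > send) return(character())
      out <- lines[(s0 + 1):send]
      out[nzchar(trimws(out))]
    }
    af <- strsplit(trimws(section("ATOM")), "[[:space:]]+")
    types <- vapply(af, `[[`, "", 6)
    charges <- vapply(af, function(x) as.numeric(x[[9]]), 0)
    formal <- rep(0L, length(types))
    attr_lines <- section("UNITY_ATOM_ATTR")
    k <- 1
    while (k < length(attr_lines)) {
      head <- as.integer(strsplit(trimws(attr_lines[k]), "[[:space:]]+")[[1]])
      idx <- head[1]; nattr <- head[2]
      for (a in seq_len(nattr)) {
        kv <- strsplit(trimws(attr_lines[k + a]), "[[:space:]]+")[[1]]
        if (kv[1] == "charge") formal[idx] <- as.integer(kv[2])
      }
      k <- k + nattr + 1
    }
    bonds <- NULL
    bl <- section("BOND")
    if (length(bl)) {
      bf <- strsplit(trimws(bl), "[[:space:]]+")
      bonds <- data.frame(
        i = vapply(bf, function(x) as.integer(x[[2]]), 1L),
        j = vapply(bf, function(x) as.integer(x[[3]]), 1L),
        type = vapply(bf, `[[`, "", 4)
      )
    }
    element <- sub("\\..*$", "", types)
    element <- paste0(toupper(substr(element, 1, 1)),
                      tolower(substr(element, 2, nchar(element))))
    list(element = element, atom_type = types, formal_charge = formal,
         gasteiger = charges, bonds = bonds)
  })
}

#' Parse SMILES into internal molecule objects
#'
#' Canonicalizes, then builds heavy-atom graphs with kekulized bond orders,
#' formal charges, OpenBabel aromaticity flags, and implicit-hydrogen counts.
#' Multi-fragment inputs (salts) are reduced to the largest fragment.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers; defaults to names or `mol<i>`.
#' @return named list of `tpa_mol` objects; unparsable entries are `NULL`.
#' @export
parse_molecules <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  can <- canonical_smiles(smiles)
  out <- stats::setNames(vector("list", length(smiles)), ids)
  ok <- which(!is.na(can))
  if (!length(ok)) return(out)
  key <- paste0("x", ok)
  m2txt <- ChemmineOB::convertFormat(
    "SMI", "MOL2", paste0(paste(can[ok], key), "\n", collapse = "")
  )
  m2 <- .parse_mol2(m2txt)
  stopifnot(length(m2) == length(ok))
  # kekulized bond orders come from the SDF rendering; single-atom molecules
  # have no bond block and are handled from the MOL2 alone
  multi <- which(vapply(m2, function(x) length(x$element) > 1, TRUE))
  sdf <- NULL
  if (length(multi)) {
    sdf <- ChemmineR::smiles2sdf(stats::setNames(can[ok][multi], key[multi]))
  }
  for (k in seq_along(ok)) {
    i <- ok[k]
    s <- if (k %in% multi) sdf[[match(k, multi)]] else NULL
    out[[i]] <- .build_mol(s, m2[[k]], id = ids[i], smiles = can[i])
  }
  out
}

.build_mol <- function(sdf, mol2, id, smiles) {
  n <- length(mol2$element)
  element <- mol2$element
  charge <- mol2$formal_charge
  if (!is.null(sdf)) {
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(dim(bb))) bb <- matrix(bb, ncol = length(bb), dimnames = list(NULL, names(bb)))
    nb <- if (length(bb)) nrow(bb) else 0L
  } else {
    nb <- 0L
  }
  bonds <- data.frame(
    i = if (nb) as.integer(bb[, 1]) else integer(),
    j = if (nb) as.integer(bb[, 2]) else integer(),
    order = if (nb) as.integer(bb[, 3]) else integer()
  )
  # aromatic flags come from the MOL2 rendering of the same canonical SMILES
  arom_bond <- rep(FALSE, nrow(bonds))
  if (!is.null(mol2$bonds) && nrow(bonds)) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    ar <- mol2$bonds$type == "ar"
    arom_bond <- key(bonds$i, bonds$j) %in% key(mol2$bonds$i[ar], mol2$bonds$j[ar])
  }
  aromatic <- rep(FALSE, n)
  if (any(arom_bond)) {
    aromatic[unique(c(bonds$i[arom_bond], bonds$j[arom_bond]))] <- TRUE
  }
  bondsum <- rep(0, n)
  deg <- rep(0L, n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      bondsum[bonds$i[r]] <- bondsum[bonds$i[r]] + bonds$order[r]
      bondsum[bonds$j[r]] <- bondsum[bonds$j[r]] + bonds$order[r]
      deg[bonds$i[r]] <- deg[bonds$i[r]] + 1L
      deg[bonds$j[r]] <- deg[bonds$j[r]] + 1L
    }
  }
  dv <- .element_lookup(.DEFAULT_VALENCE, element, "valence")
  val_eff <- dv + ifelse(element %in% c("N", "O", "S", "P", "C"),
                         ifelse(element == "C", -abs(charge), charge),
                         -abs(charge))
  nh <- pmax(0L, as.integer(round(val_eff - bondsum)))
  mol <- list(
    id = id, smiles = smiles,
    atoms = data.frame(element = element, charge = charge, aromatic = aromatic,
                       nh = nh, degree = deg, stringsAsFactors = FALSE),
    bonds = cbind(bonds, aromatic = arom_bond),
    graph = .mol_graph(n, bonds),
    atom_type = mol2$atom_type,
    ob_gasteiger = mol2$gasteiger
  )
  class(mol) <- "tpa_mol"
  .strip_to_largest_fragment(mol)
}

#' @export
print.tpa_mol <- function(x, ...) {
  cat("<tpa_mol> ", x$id, ": ", x$smiles, "\n",
      "  ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds, ",
      sum(x$atoms$aromatic), " aromatic atoms\n", sep = "")
  invisible(x)
}

#' Molecular weight including implicit hydrogens
#' @param mol a `tpa_mol`.
#' @return molecular weight in g/mol.
#' @export
mol_weight <- function(mol) {
  sum(.element_lookup(.ELEMENT_MASS, mol$atoms$element, "mass")) +
    sum(mol$atoms$nh) * .ELEMENT_MASS[["H"]]
}

#' Elements present in a molecule
#' @param mol a `tpa_mol`.
#' @return character vector of unique element symbols (heavy atoms).
#' @export
mol_elements <- function(mol) unique(mol$atoms$element)
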