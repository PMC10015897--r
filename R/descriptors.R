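# Whole-molecule 2D descriptor block.
#
# A pinned roster of topological, compositional and electronic descriptors
# computed from the heavy-atom graph, PEOE charges, additive logP/MR, E-state
# indices and surface contributions. The roster is versioned in
# inst/extdata/descriptor_manifest.json so feature matrices stay reproducible.

# Ertl-style polar surface contributions by coarse N/O/S typing
.TPSA_CONTRIB <- list(
  N.nh2 = 26.02, N.nh1 = 12.03, N.tert = 3.24, N.ar = 12.89, N.ar.h = 15.79,
  N.pos = 11.68, O.oh = 20.23, O.ether = 9.23, O.carbonyl = 17.07,
  O.ar = 13.14, O.neg = 23.06, S.thio = 25.30, S.h = 38.80
)

.tpsa_like <- function(mol) {
  at <- mol$atoms
  total <- 0
  for (a in seq_len(nrow(at))) {
    e <- at$element[a]
    if (!e %in% c("N", "O", "S")) next
    key <- if (e == "N") {
      if (at$charge[a] > 0 && !at$aromatic[a]) "N.pos"
      else if (at$aromatic[a]) { if (at$nh[a] > 0) "N.ar.h" else "N.ar" }
      else if (at$nh[a] >= 2) "N.nh2"
      else if (at$nh[a] == 1) "N.nh1"
      else "N.tert"
    } else if (e == "O") {
      if (at$charge[a] < 0) "O.neg"
      else if (at$aromatic[a]) "O.ar"
      else if (at$nh[a] > 0) "O.oh"
      else if (any(mol$bonds$order[mol$bonds$i == a | mol$bonds$j == a] == 2)) "O.carbonyl"
      else "O.ether"
    } else {
      if (at$nh[a] > 0) "S.h" else "S.thio"
    }
    total <- total + .TPSA_CONTRIB[[key]]
  }
  total
}

.GENERAL_DESCRIPTORS <- c(
  "mol_wt", "heavy_atom_count", "n_hydrogens", "n_bonds", "n_rings",
  "n_aromatic_atoms", "frac_aromatic_atoms", "n_aromatic_rings",
  "n_rotatable_bonds", "n_hetero", "n_N", "n_O", "n_S", "n_halogen",
  "frac_sp3_carbons", "max_partial_charge", "min_partial_charge",
  "max_abs_partial_charge", "sum_pos_charge", "logp_additive", "mr_additive",
  "tpsa_like", "labute_asa", "max_estate", "min_estate", "mean_estate",
  "chi0", "chi1", "graph_diameter", "mean_graph_distance", "n_hbd", "n_hba",
  "mean_atomic_mass", "max_degree", "n_double_bonds", "n_triple_bonds"
)

#' General 2D descriptor block
#'
#' @param mol a `tpa_mol`.
#' @return named numeric vector following the pinned descriptor manifest;
#'   descriptors that fail to compute are `NA` (imputed at matrix assembly).
#' @export
general_descriptors <- function(mol) {
  at <- mol$atoms
  b <- mol$bonds
  n <- nrow(at)
  out <- stats::setNames(rep(NA_real_, length(.GENERAL_DESCRIPTORS)),
                         .GENERAL_DESCRIPTORS)
  q <- tryCatch(peoe_charges(mol), error = function(e) NULL)
  es <- tryCatch(estate_indices(mol), error = function(e) NULL)
  lp <- tryCatch(atomic_logp(mol), error = function(e) NULL)
  mr <- tryCatch(atomic_mr(mol), error = function(e) NULL)
  vsa <- tryCatch(atom_vsa(mol), error = function(e) NULL)
  hyb <- .hybridization(mol)
  dmat <- igraph::distances(mol$graph)
  arom_sub <- igraph::subgraph_from_edges(mol$graph,
    which(b$aromatic), delete.vertices = TRUE)
  rot <- 0L
  if (nrow(b)) {
    bridge <- igraph::bridges(mol$graph)
    ring_bond <- !(seq_len(nrow(b)) %in% bridge)
    rot <- sum(b$order == 1 & !b$aromatic & !ring_bond &
                 at$degree[b$i] > 1 & at$degree[b$j] > 1)
  }
  out["mol_wt"] <- mol_weight(mol)
  out["heavy_atom_count"] <- n
  out["n_hydrogens"] <- sum(at$nh)
  out["n_bonds"] <- nrow(b)
  out["n_rings"] <- nrow(b) - n + igraph::count_components(mol$graph)
  out["n_aromatic_atoms"] <- sum(at$aromatic)
  out["frac_aromatic_atoms"] <- mean(at$aromatic)
  out["n_aromatic_rings"] <- igraph::ecount(arom_sub) - igraph::vcount(arom_sub) +
    igraph::count_components(arom_sub)
  out["n_rotatable_bonds"] <- rot
  out["n_hetero"] <- sum(!at$element %in% c("C", "H"))
  out["n_N"] <- sum(at$element == "N")
  out["n_O"] <- sum(at$element == "O")
  out["n_S"] <- sum(at$element == "S")
  out["n_halogen"] <- sum(at$element %in% c("F", "Cl", "Br", "I"))
  ncarbon <- sum(at$element == "C")
  out["frac_sp3_carbons"] <- if (ncarbon) sum(at$element == "C" & hyb == "sp3") / ncarbon else 0
  if (!is.null(q)) {
    out["max_partial_charge"] <- max(q)
    out["min_partial_charge"] <- min(q)
    out["max_abs_partial_charge"] <- max(abs(q))
    out["sum_pos_charge"] <- sum(q[q > 0])
  }
  if (!is.null(lp)) out["logp_additive"] <- sum(lp)
  if (!is.null(mr)) out["mr_additive"] <- sum(mr)
  out["tpsa_like"] <- .tpsa_like(mol)
  if (!is.null(vsa)) out["labute_asa"] <- sum(vsa)
  if (!is.null(es)) {
    out["max_estate"] <- max(es)
    out["min_estate"] <- min(es)
    out["mean_estate"] <- mean(es)
  }
  deg <- pmax(at$degree, 1)
  out["chi0"] <- sum(1 / sqrt(deg))
  out["chi1"] <- if (nrow(b)) sum(1 / sqrt(deg[b$i] * deg[b$j])) else 0
  finite_d <- dmat[is.finite(dmat)]
  out["graph_diameter"] <- max(finite_d)
  out["mean_graph_distance"] <- if (n > 1) mean(finite_d[finite_d > 0]) else 0
  out["n_hbd"] <- sum(at$element %in% c("N", "O") & at$nh > 0)
  out["n_hba"] <- sum(at$element %in% c("N", "O"))
  out["mean_atomic_mass"] <- out["mol_wt"] / n
  out["max_degree"] <- max(at$degree)
  out["n_double_bonds"] <- sum(b$order == 2 & !b$aromatic)
  out["n_triple_bonds"] <- sum(b$order == 3)
  out
}
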