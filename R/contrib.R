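# Additive atomic property schemes.
#
# Atomic logP and molar refractivity use a compact atom typing
# (element x aromaticity x heteroatom neighbourhood x protonation) with
# contribution values adapted from published additive schemes
# (Wildman & Crippen 1999 for logP and carbon/nitrogen MR; classical atomic
# refractions for halogens and sulfur). Hydrogens are folded into their heavy
# atom. The typing is deliberately coarser than the original SMARTS-based
# tables: it is self-consistent (molecule value = sum of atom values by
# construction) and directionally faithful (polar groups carry negative logP,
# aromatic/conjugated carbons carry higher refractivity), which is what the
# fragment-aggregated features need.

.LOGP_H <- 0.1230
.MR_H <- 1.057

.atom_contrib_type <- function(mol) {
  el <- mol$atoms$element
  arom <- mol$atoms$aromatic
  n <- nrow(mol$atoms)
  nbr <- vector("list", n)
  b <- mol$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      nbr[[b$i[r]]] <- c(nbr[[b$i[r]]], r)
      nbr[[b$j[r]]] <- c(nbr[[b$j[r]]], r)
    }
  }
  hyb <- .hybridization(mol)
  vapply(seq_len(n), function(a) {
    e <- el[a]
    rows <- nbr[[a]]
    others <- ifelse(b$i[rows] == a, b$j[rows], b$i[rows])
    orders <- b$order[rows]
    het <- any(el[others] %in% c("N", "O", "S", "F", "Cl", "Br", "I", "P"))
    dbl_o <- any(el[others] == "O" & orders == 2)
    switch(e,
      C = if (arom[a]) {
        if (het) "C.ar.het" else "C.ar"
      } else if (hyb[a] != "sp3") {
        if (dbl_o) "C.carbonyl" else "C.unsat"
      } else if (het) "C.al.het" else "C.al",
      N = if (mol$atoms$charge[a] > 0) "N.pos"
          else if (arom[a]) "N.ar"
          else "N.amine",
      O = if (mol$atoms$charge[a] < 0) "O.neg"
          else if (arom[a]) "O.ar"
          else if (any(orders == 2)) "O.carbonyl"
          else if (mol$atoms$nh[a] > 0) "O.hydroxyl"
          else "O.ether",
      S = if (any(orders == 2) && sum(el[others] == "O") >= 1) "S.oxidized"
          else "S.thio",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      P = "P", B = "B", Si = "Si",
      stop("unparameterized atom type for additive contributions: ", e,
           call. = FALSE)
    )
  }, "")
}

.LOGP_CONTRIB <- c(
  C.al = 0.1441, C.al.het = -0.2035, C.ar = 0.1581, C.ar.het = 0.1360,
  C.unsat = 0.1000, C.carbonyl = -0.2783,
  N.amine = -1.0190, N.ar = -0.3239, N.pos = -0.3396,
  O.hydroxyl = -0.2893, O.ether = -0.2057, O.ar = 0.1552,
  O.carbonyl = -0.1526, O.neg = -0.7339,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
  S.thio = 0.6482, S.oxidized = -0.0024,
  P = 0.8612, B = 0.1800, Si = 0.8000
)

.MR_CONTRIB <- c(
  C.al = 2.503, C.al.het = 2.753, C.ar = 3.350, C.ar.het = 3.667,
  C.unsat = 3.000, C.carbonyl = 2.730,
  N.amine = 2.262, N.ar = 2.202, N.pos = 2.700,
  O.hydroxyl = 1.661, O.ether = 1.700, O.ar = 1.550,
  O.carbonyl = 1.600, O.neg = 2.200,
  F = 0.920, Cl = 5.970, Br = 8.870, I = 13.900,
  S.thio = 7.690, S.oxidized = 7.000,
  P = 6.920, B = 3.000, Si = 7.870
)

.atomic_additive <- function(mol, table, h_value, what) {
  type <- .atom_contrib_type(mol)
  v <- table[type]
  if (anyNA(v)) {
    stop("unparameterized atom type(s) for ", what, ": ",
         paste(unique(type[is.na(v)]), collapse = ", "), call. = FALSE)
  }
  unname(v) + mol$atoms$nh * h_value
}

#' Additive atomic logP contributions
#' @param mol a `tpa_mol`.
#' @return per-heavy-atom logP contributions (implicit hydrogens folded in);
#'   their sum is the whole-molecule additive logP of the same scheme.
#' @export
atomic_logp <- function(mol) .atomic_additive(mol, .LOGP_CONTRIB, .LOGP_H, "logP")

#' Additive atomic molar refractivity contributions
#' @param mol a `tpa_mol`.
#' @return per-heavy-atom MR contributions (cm^3/mol), hydrogens folded in.
#' @export
atomic_mr <- function(mol) .atomic_additive(mol, .MR_CONTRIB, .MR_H, "MR")

#' Per-atom van der Waals surface contributions
#'
#' Labute-style approximation: each heavy atom contributes its sphere area
#' minus the spherical caps buried by bonded neighbours (including implicit
#' hydrogens), with idealized bond lengths from covalent radii.
#'
#' @param mol a `tpa_mol`.
#' @return per-heavy-atom exposed surface, in square angstrom (floored at 0).
#' @export
atom_vsa <- function(mol) {
  el <- mol$atoms$element
  Ri <- .element_lookup(.VDW_RADIUS, el, "vdW radius")
  ci <- .element_lookup(.COV_RADIUS, el, "covalent radius")
  area <- 4 * pi * Ri^2
  cap <- function(R1, R2, d) {
    d <- pmax(d, abs(R1 - R2) + 0.05)  # avoid total engulfment
    h <- pmax(0, R1 - (d^2 + R1^2 - R2^2) / (2 * d))
    2 * pi * R1 * pmin(h, 2 * R1)
  }
  order_scale <- c(1, 0.94, 0.87)
  b <- mol$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      sc <- if (b$aromatic[r]) 0.95 else order_scale[b$order[r]]
      d <- (ci[i] + ci[j]) * sc
      area[i] <- area[i] - cap(Ri[i], Ri[j], d)
      area[j] <- area[j] - cap(Ri[j], Ri[i], d)
    }
  }
  nh <- mol$atoms$nh
  hR <- .VDW_RADIUS[["H"]]; hc <- .COV_RADIUS[["H"]]
  hv <- which(nh > 0)
  if (length(hv)) {
    dh <- ci[hv] + hc
    area[hv] <- area[hv] - nh[hv] * cap(Ri[hv], hR, dh)
  }
  pmax(area, 0)
}

#' Electrotopological state (E-state) indices
#'
#' Kier-Hall intrinsic states perturbed by through-graph electronegativity
#' differences: S_i = I_i + sum_j (I_i - I_j) / d_ij^2 with topological
#' distances d (in bonds, plus 1).
#'
#' @param mol a `tpa_mol`.
#' @return numeric vector of per-heavy-atom E-state values.
#' @export
estate_indices <- function(mol) {
  el <- mol$atoms$element
  n <- nrow(mol$atoms)
  zv <- .element_lookup(.VALENCE_ELECTRONS, el, "valence electrons")
  pq <- .element_lookup(.PRINCIPAL_QN, el, "principal quantum number")
  h <- mol$atoms$nh
  delta <- pmax(mol$atoms$degree, 1)
  delta_v <- pmax(zv - h, 1)
  I <- ((2 / pq)^2 * delta_v + 1) / delta
  if (n == 1) return(I)
  d <- igraph::distances(mol$graph) + 1
  S <- I
  for (a in seq_len(n)) {
    S[a] <- I[a] + sum((I[a] - I[-a]) / d[a, -a]^2)
  }
  S
}
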