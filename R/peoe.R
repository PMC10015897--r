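# Partial equalization of orbital electronegativities (PEOE).
#
# Iterative sigma-charge scheme of Gasteiger & Marsili (Tetrahedron 1980):
# electronegativity of an atom is a quadratic function of its charge,
# chi = a + b q + c q^2; at every iteration charge flows across each bond from
# the less to the more electronegative atom, scaled by the cation
# electronegativity of the donor and damped by (1/2)^n. Charge is conserved
# exactly because every transfer is antisymmetric. Hydrogens participate in
# the iteration and are folded into their heavy atom afterwards.

# a, b, c parameters by element and hybridization (sp3/sp2/sp)
.PEOE_PARAMS <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S.sp3  = c(10.14, 9.13, 1.38),
  S.sp2  = c(10.88, 9.49, 1.33),
  P.sp3  = c(8.90, 8.24, 0.96),
  B.sp3  = c(7.38, 6.82, 0.42)
)

# sp3/sp2/sp assignment from kekulized bond orders plus aromatic flags
.hybridization <- function(mol) {
  n <- nrow(mol$atoms)
  ndouble <- rep(0L, n); ntriple <- rep(0L, n); narom <- rep(0L, n)
  b <- mol$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      for (a in c(b$i[r], b$j[r])) {
        if (b$aromatic[r]) narom[a] <- narom[a] + 1L
        else if (b$order[r] == 2) ndouble[a] <- ndouble[a] + 1L
        else if (b$order[r] == 3) ntriple[a] <- ntriple[a] + 1L
      }
    }
  }
  ifelse(ntriple > 0 | ndouble >= 2, "sp",
         ifelse(ndouble > 0 | narom > 0, "sp2", "sp3"))
}

.peoe_type <- function(element, hyb) {
  key <- ifelse(element %in% c("F", "Cl", "Br", "I", "H"),
                element, paste0(element, ".", hyb))
  # collapse unparameterized hybridization variants onto the tabulated ones
  key[key == "S.sp"] <- "S.sp2"
  key[key %in% c("P.sp2", "P.sp")] <- "P.sp3"
  key[key %in% c("B.sp2", "B.sp")] <- "B.sp3"
  key
}

#' PEOE (Gasteiger) partial charges
#'
#' @param mol a `tpa_mol`.
#' @param n_iter number of charge-equalization iterations.
#' @return numeric vector of per-heavy-atom charges (e), implicit hydrogens
#'   folded into their heavy atom. Sums to the net formal charge to machine
#'   precision.
#' @export
peoe_charges <- function(mol, n_iter = 8) {
  nheavy <- nrow(mol$atoms)
  hyb <- .hybridization(mol)
  key <- .peoe_type(mol$atoms$element, hyb)
  bad <- setdiff(unique(key), names(.PEOE_PARAMS))
  if (length(bad)) {
    stop("unparameterized atom type(s) for PEOE: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # expand implicit hydrogens into explicit pseudo-atoms
  nh <- mol$atoms$nh
  nH <- sum(nh)
  ntot <- nheavy + nH
  keys <- c(key, rep("H", nH))
  par <- do.call(rbind, .PEOE_PARAMS[keys])
  a <- par[, 1]; b <- par[, 2]; cc <- par[, 3]
  chi_plus <- a + b + cc
  chi_plus[keys == "H"] <- 20.02  # special cation value for hydrogen
  bi <- mol$bonds$i; bj <- mol$bonds$j
  if (nH > 0) {
    howner <- rep(seq_len(nheavy), nh)
    bi <- c(bi, howner)
    bj <- c(bj, nheavy + seq_len(nH))
  }
  q <- c(as.numeric(mol$atoms$charge), rep(0, nH))
  damp <- 1
  for (it in seq_len(n_iter)) {
    damp <- damp * 0.5
    chi <- a + b * q + cc * q * q
    dchi <- chi[bj] - chi[bi]
    denom <- ifelse(dchi > 0, chi_plus[bi], chi_plus[bj])
    dq <- dchi / denom * damp
    # positive dq moves electron density i -> j, i.e. q_i up, q_j down
    if (length(dq)) {
      acc <- rowsum(c(dq, -dq), group = c(bi, bj))
      q[as.integer(rownames(acc))] <- q[as.integer(rownames(acc))] + acc[, 1]
    }
  }
  out <- q[seq_len(nheavy)]
  if (nH > 0) {
    hsum <- tapply(q[nheavy + seq_len(nH)], rep(seq_len(nheavy), nh), sum)
    idx <- as.integer(names(hsum))
    out[idx] <- out[idx] + hsum
  }
  unname(out)
}

#' Per-atom property attributions
#'
#' Computes per-heavy-atom contributions (hydrogens folded in) for the
#' atom-attributable properties used by the fragment-aggregated features:
#' PEOE partial charge, additive logP, and additive molar refractivity.
#'
#' @param mol a `tpa_mol`.
#' @param property_name one of `"peoe_charge"`, `"logp"`, `"mr"`.
#' @return object of class `atom_attribution`: list with `property_name` and
#'   numeric `values`, one per heavy atom.
#' @export
atom_attributions <- function(mol, property_name = c("peoe_charge", "logp", "mr")) {
  property_name <- match.arg(property_name)
  values <- switch(property_name,
    peoe_charge = peoe_charges(mol),
    logp = atomic_logp(mol),
    mr = atomic_mr(mol)
  )
  if (any(!is.finite(values))) stop("non-finite atom attribution computed")
  structure(list(property_name = property_name, values = values),
            class = "atom_attribution")
}
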