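# Element-level constant tables used across featurization and conjugation.

# Standard atomic weights (IUPAC 2021, abridged).
.ELEMENT_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904
)

# Bondi van der Waals radii (angstrom).
.VDW_RADIUS <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# Covalent radii (angstrom, Cordero 2008) for idealized bond lengths.
.COV_RADIUS <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

# Default valences of the organic subset, used for implicit-hydrogen counts.
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
  Si = 4, P = 3, S = 2, Cl = 1, Br = 1, I = 1
)

# Number of valence electrons (for electrotopological-state intrinsic values).
.VALENCE_ELECTRONS <- c(
  H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
  Si = 4, P = 5, S = 6, Cl = 7, Br = 7, I = 7
)

# Principal quantum number of the valence shell.
.PRINCIPAL_QN <- c(
  H = 1, B = 2, C = 2, N = 2, O = 2, F = 2,
  Si = 3, P = 3, S = 3, Cl = 3, Br = 4, I = 5
)

.element_lookup <- function(table, elements, what) {
  v <- table[elements]
  if (anyNA(v)) {
    bad <- unique(elements[is.na(v)])
    stop("unparameterized atom type(s) for ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(v)
}
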