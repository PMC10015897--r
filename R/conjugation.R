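# Conjugated-system perception and conjugation descriptors.
#
# A bond is flagged conjugated when it is aromatic, has order >= 2, or is a
# single bond whose two ends can share pi density: both ends are pi centres
# (carry a multiple/aromatic bond) or one end is such a centre and the other
# a heteroatom (N, O, S, P) with an available lone pair. Conjugated systems
# are the connected components of the subgraph induced by conjugated bonds.

.conjugated_bond_flags <- function(mol) {
  b <- mol$bonds
  n <- nrow(mol$atoms)
  if (!nrow(b)) return(logical())
  multi <- rep(FALSE, n)
  for (r in seq_len(nrow(b))) {
    if (b$aromatic[r] || b$order[r] >= 2) {
      multi[b$i[r]] <- TRUE
      multi[b$j[r]] <- TRUE
    }
  }
  el <- mol$atoms$element
  # lone-pair donors: neutral/anionic N,O,S,P that are not saturated onium
  lp <- el %in% c("N", "O", "S", "P") &
    !(mol$atoms$charge > 0 & !multi)
  flag <- logical(nrow(b))
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    if (b$aromatic[r] || b$order[r] >= 2) {
      flag[r] <- TRUE
    } else {
      flag[r] <- (multi[i] || multi[j]) &&
        (multi[i] || lp[i]) && (multi[j] || lp[j])
    }
  }
  flag
}

#' Perceive conjugated systems
#'
#' @param mol a `tpa_mol`.
#' @return list of `conjugated_system` objects, ordered by decreasing size
#'   then lowest atom index. Each has `atom_indices`, `bond_indices`,
#'   `is_aromatic` (per atom) and `minimal` (fewer than 3 atoms).
#' @export
perceive_conjugated_systems <- function(mol) {
  flag <- .conjugated_bond_flags(mol)
  if (!any(flag)) return(list())
  b <- mol$bonds[flag, , drop = FALSE]
  bond_rows <- which(flag)
  g <- .mol_graph(nrow(mol$atoms), b)
  comp <- igraph::components(g)
  in_system <- unique(c(b$i, b$j))
  sys_ids <- unique(comp$membership[in_system])
  systems <- lapply(sys_ids, function(s) {
    atoms <- sort(which(comp$membership == s))
    atoms <- intersect(atoms, in_system)
    rows <- bond_rows[b$i %in% atoms & b$j %in% atoms]
    structure(list(
      atom_indices = atoms,
      bond_indices = rows,
      is_aromatic = mol$atoms$aromatic[atoms],
      minimal = length(atoms) < 3
    ), class = "conjugated_system")
  })
  sizes <- vapply(systems, function(s) length(s$atom_indices), 1L)
  first <- vapply(systems, function(s) min(s$atom_indices), 1L)
  systems[order(-sizes, first)]
}

.system_diameter <- function(mol, system) {
  sub <- igraph::induced_subgraph(mol$graph, system$atom_indices)
  max(igraph::distances(sub))
}

#' Conjugation length (maximum conjugated distance)
#'
#' The largest bond-count graph distance between any two atoms of one
#' conjugated system, maximized over systems; 0 for saturated molecules.
#'
#' @param systems list from [perceive_conjugated_systems()].
#' @param mol the molecule the systems were perceived on.
#' @return integer number of bonds.
#' @export
conju_max_distance <- function(systems, mol) {
  if (!length(systems)) return(0L)
  as.integer(max(vapply(systems, function(s) .system_diameter(mol, s), 0)))
}

#' Branching ratio of the largest conjugated system
#'
#' Fraction of atoms in the largest conjugated system whose degree within the
#' system is 3 or more; 0 for linear or ring-only systems and for molecules
#' without conjugation.
#'
#' @inheritParams conju_max_distance
#' @return real in \[0, 1\].
#' @export
conju_branch_ratio <- function(systems, mol) {
  if (!length(systems)) return(0)
  s <- systems[[1]]
  sub <- igraph::induced_subgraph(mol$graph, s$atom_indices)
  mean(igraph::degree(sub) >= 3)
}

#' Conjugated weight, per-atom weight, and conjugated surface area
#'
#' @inheritParams conju_max_distance
#' @return list with `conju_wt` (mass of conjugated atoms + their implicit H,
#'   g/mol), `conju_atom_wt` (molecular weight per heavy atom, g/mol),
#'   `conju_stru_vsa` (summed van der Waals surface of conjugated atoms,
#'   square angstrom) and `full_wt` (molecular weight, g/mol).
#' @export
conju_weights_and_area <- function(systems, mol) {
  atoms <- sort(unique(unlist(lapply(systems, `[[`, "atom_indices"))))
  full_wt <- mol_weight(mol)
  conju_wt <- 0
  conju_vsa <- 0
  if (length(atoms)) {
    conju_wt <- sum(.element_lookup(.ELEMENT_MASS, mol$atoms$element[atoms], "mass")) +
      sum(mol$atoms$nh[atoms]) * .ELEMENT_MASS[["H"]]
    conju_vsa <- sum(atom_vsa(mol)[atoms])
  }
  list(conju_wt = conju_wt,
       conju_atom_wt = full_wt / nrow(mol$atoms),
       conju_stru_vsa = conju_vsa,
       full_wt = full_wt)
}

#' Donor/acceptor assignment and DAratio
#'
#' Matches the shipped donor/acceptor substructure library, takes the donor
#' and acceptor attachment atoms that lie inside conjugated systems, and
#' computes the maximal donor-acceptor bond-path distance restricted to a
#' shared conjugated system, divided by the conjugation length.
#'
#' @param mol a `tpa_mol`.
#' @param systems list from [perceive_conjugated_systems()].
#' @param patterns pattern library from [da_pattern_library()].
#' @return list with `donor_atoms`, `acceptor_atoms`, `da_distance` (bonds),
#'   `daratio`, and `defined` (FALSE when either set is empty; `daratio` is
#'   then 0).
#' @export
assign_donor_acceptor <- function(mol, systems, patterns = da_pattern_library()) {
  hits <- lapply(patterns, function(p) match_pattern(mol, p$pattern))
  roles <- vapply(patterns, `[[`, "", "role")
  att <- function(role) {
    sort(unique(unlist(lapply(which(roles == role), function(k) {
      vapply(hits[[k]], `[[`, 1L, 1)  # first pattern atom = attachment atom
    }))))
  }
  donors <- att("donor")
  acceptors <- att("acceptor")
  # an atom matched as both (e.g. amide N) counts for neither
  both <- intersect(donors, acceptors)
  donors <- setdiff(donors, both)
  acceptors <- setdiff(acceptors, both)
  L <- conju_max_distance(systems, mol)
  da <- 0L
  defined <- FALSE
  if (length(donors) && length(acceptors) && length(systems)) {
    for (s in systems) {
      d_in <- intersect(donors, s$atom_indices)
      a_in <- intersect(acceptors, s$atom_indices)
      if (length(d_in) && length(a_in)) {
        sub <- igraph::induced_subgraph(mol$graph, s$atom_indices)
        dm <- igraph::distances(sub)
        ii <- match(d_in, s$atom_indices)
        jj <- match(a_in, s$atom_indices)
        dist <- max(dm[ii, jj, drop = FALSE])
        if (is.finite(dist)) {
          da <- max(da, as.integer(dist))
          defined <- TRUE
        }
      }
    }
  }
  list(donor_atoms = donors, acceptor_atoms = acceptors,
       da_distance = if (defined) da else 0L,
       daratio = if (defined && L > 0) da / L else 0,
       defined = defined)
}

# registry of conjugation descriptors; each entry maps to one feature column
.CONJUGATION_REGISTRY <- c(
  "conju_max_distance", "conju_branch_ratio", "conju_atom_wt", "conju_wt",
  "conju_stru_vsa", "full_wt", "n_conju_systems", "conju_atom_count",
  "conju_atom_fraction", "conju_largest_system_atoms", "conju_aromatic_fraction",
  "conju_mean_system_size", "conju_ring_count", "conju_hetero_count",
  "conju_max_distance_lg", "daratio"
)

#' Conjugation feature block for one molecule
#'
#' Computes the registry of conjugation descriptors (size, shape, and
#' composition of the conjugated substructure, plus the donor-acceptor
#' ratio).
#'
#' @param mol a `tpa_mol`.
#' @param patterns donor/acceptor pattern library.
#' @return named numeric vector.
#' @export
conjugation_features <- function(mol, patterns = da_pattern_library()) {
  systems <- perceive_conjugated_systems(mol)
  L <- conju_max_distance(systems, mol)
  wts <- conju_weights_and_area(systems, mol)
  da <- assign_donor_acceptor(mol, systems, patterns)
  atoms <- unique(unlist(lapply(systems, `[[`, "atom_indices")))
  n <- nrow(mol$atoms)
  nsys <- length(systems)
  largest <- if (nsys) length(systems[[1]]$atom_indices) else 0L
  arom_frac <- if (length(atoms)) mean(mol$atoms$aromatic[atoms]) else 0
  ring_count <- 0
  if (nsys) {
    ring_count <- sum(vapply(systems, function(s) {
      sub <- igraph::induced_subgraph(mol$graph, s$atom_indices)
      igraph::ecount(sub) - igraph::vcount(sub) + igraph::count_components(sub)
    }, 0))
  }
  hetero <- if (length(atoms)) sum(mol$atoms$element[atoms] != "C") else 0L
  c(
    conju_max_distance = L,
    conju_branch_ratio = conju_branch_ratio(systems, mol),
    conju_atom_wt = wts$conju_atom_wt,
    conju_wt = wts$conju_wt,
    conju_stru_vsa = wts$conju_stru_vsa,
    full_wt = wts$full_wt,
    n_conju_systems = nsys,
    conju_atom_count = length(atoms),
    conju_atom_fraction = length(atoms) / n,
    conju_largest_system_atoms = largest,
    conju_aromatic_fraction = arom_frac,
    conju_mean_system_size = if (nsys) length(atoms) / nsys else 0,
    conju_ring_count = ring_count,
    conju_hetero_count = hetero,
    conju_max_distance_lg = log10(max(L, 1)),
    daratio = da$daratio
  )
}
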