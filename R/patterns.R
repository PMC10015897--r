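# Minimal substructure-pattern matcher.
#
# Supports the SMARTS subset needed by the shipped donor/acceptor library:
#   - bracket atoms [ ... ] with element symbol (aromatic lowercase),
#     #<atomic number> (aromaticity-agnostic), X<d> total connection count
#     (heavy neighbours + hydrogens), H<d> hydrogen count, +/- charge
#     (optionally with a digit); ';' and '&' (and juxtaposition) mean AND
#   - bare atom symbols (C N O S P F Cl Br I and aromatic c n o s)
#   - bonds: default (single or aromatic), - (single), = (double),
#     # (triple), : (aromatic), ~ (any)
#   - branches with parentheses and single-digit ring closures
# Matching is exhaustive backtracking over heavy atoms; matches are
# returned as mappings from pattern atoms to molecule atom indices.

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

.parse_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  atoms <- list()
  bonds <- list()
  stack <- integer()
  prev <- 0L
  pending_bond <- NA_character_
  ring_open <- list()
  i <- 1
  n <- length(chars)
  new_atom <- function(spec) {
    atoms[[length(atoms) + 1]] <<- spec
    cur <- length(atoms)
    if (prev > 0) {
      bonds[[length(bonds) + 1]] <<- list(a = prev, b = cur,
                                          type = if (is.na(pending_bond)) "default" else pending_bond)
    }
    pending_bond <<- NA_character_
    prev <<- cur
  }
  atom_spec <- function(element = NA, aromatic = NA, charge = NA,
                        hcount = NA, xcount = NA, anum = NA) {
    list(element = element, aromatic = aromatic, charge = charge,
         hcount = hcount, xcount = xcount, anum = anum)
  }
  parse_bracket <- function(body) {
    spec <- atom_spec()
    j <- 1
    bc <- strsplit(body, "")[[1]]
    while (j <= length(bc)) {
      ch <- bc[j]
      rest <- paste(bc[j:length(bc)], collapse = "")
      if (ch %in% c(";", "&")) { j <- j + 1; next }
      if (ch == "#") {
        m <- regmatches(rest, regexpr("^#[0-9]+", rest))
        spec$anum <- as.integer(sub("#", "", m))
        j <- j + nchar(m); next
      }
      if (ch == "X") {
        m <- regmatches(rest, regexpr("^X[0-9]+", rest))
        spec$xcount <- as.integer(sub("X", "", m))
        j <- j + nchar(m); next
      }
      if (ch == "H") {
        m <- regmatches(rest, regexpr("^H[0-9]*", rest))
        d <- sub("H", "", m)
        spec$hcount <- if (nzchar(d)) as.integer(d) else 1L
        j <- j + nchar(m); next
      }
      if (ch %in% c("+", "-")) {
        m <- regmatches(rest, regexpr("^[+-][0-9]*", rest))
        d <- substring(m, 2)
        mag <- if (nzchar(d)) as.integer(d) else 1L
        spec$charge <- if (ch == "+") mag else -mag
        j <- j + nchar(m); next
      }
      m <- regmatches(rest, regexpr("^(Cl|Br|Si|[BCNOSPFI]|[cnos])", rest))
      if (length(m) && nzchar(m)) {
        if (m %in% c("c", "n", "o", "s")) {
          spec$element <- toupper(m); spec$aromatic <- TRUE
        } else {
          spec$element <- m; spec$aromatic <- FALSE
        }
        j <- j + nchar(m); next
      }
      stop("unsupported token in pattern bracket: ", rest, call. = FALSE)
    }
    spec
  }
  while (i <= n) {
    ch <- chars[i]
    rest <- paste(chars[i:n], collapse = "")
    if (ch == "[") {
      close <- regexpr("]", rest, fixed = TRUE)
      body <- substr(rest, 2, close - 1)
      new_atom(parse_bracket(body))
      i <- i + close
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- c(`-` = "single", `=` = "double", `#` = "triple",
                        `:` = "aromatic", `~` = "any")[[ch]]
      i <- i + 1
    } else if (grepl("^[0-9]$", ch)) {
      key <- ch
      if (!is.null(ring_open[[key]])) {
        bonds[[length(bonds) + 1]] <- list(a = ring_open[[key]], b = prev,
                                           type = "default")
        ring_open[[key]] <- NULL
      } else ring_open[[key]] <- prev
      i <- i + 1
    } else {
      m <- regmatches(rest, regexpr("^(Cl|Br|Si|[BCNOSPFI]|[cnos])", rest))
      if (!length(m) || !nzchar(m)) stop("unsupported pattern syntax at: ", rest, call. = FALSE)
      if (m %in% c("c", "n", "o", "s")) {
        new_atom(list(element = toupper(m), aromatic = TRUE, charge = NA,
                      hcount = NA, xcount = NA, anum = NA))
      } else {
        new_atom(list(element = m, aromatic = FALSE, charge = NA,
                      hcount = NA, xcount = NA, anum = NA))
      }
      i <- i + nchar(m)
    }
  }
  list(atoms = atoms, bonds = bonds)
}

.atom_matches <- function(mol, a, spec) {
  at <- mol$atoms
  if (!is.na(spec$anum)) {
    if (.ATOMIC_NUMBER[[at$element[a]]] != spec$anum) return(FALSE)
  }
  if (!is.na(spec$element)) {
    if (at$element[a] != spec$element) return(FALSE)
    if (!is.na(spec$aromatic) && at$aromatic[a] != spec$aromatic) return(FALSE)
  }
  if (!is.na(spec$charge) && at$charge[a] != spec$charge) return(FALSE)
  if (!is.na(spec$hcount) && at$nh[a] != spec$hcount) return(FALSE)
  if (!is.na(spec$xcount) && (at$degree[a] + at$nh[a]) != spec$xcount) return(FALSE)
  TRUE
}

.bond_matches <- function(mol, row, type) {
  b <- mol$bonds[row, ]
  switch(type,
    any = TRUE,
    default = (b$order == 1 && !b$aromatic) || b$aromatic,
    single = b$order == 1 && !b$aromatic,
    double = b$order == 2 && !b$aromatic,
    triple = b$order == 3,
    aromatic = isTRUE(b$aromatic)
  )
}

#' Match a substructure pattern against a molecule
#'
#' @param mol a `tpa_mol`.
#' @param pattern pattern string (see file header for the supported subset).
#' @return list of integer vectors; each maps pattern atoms (in written
#'   order) to molecule atom indices. Unique assignments only.
#' @export
match_pattern <- function(mol, pattern) {
  pat <- .parse_pattern(pattern)
  np <- length(pat$atoms)
  if (np == 0) return(list())
  nmol <- nrow(mol$atoms)
  bond_row <- matrix(0L, nmol, nmol)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      bond_row[mol$bonds$i[r], mol$bonds$j[r]] <- r
      bond_row[mol$bonds$j[r], mol$bonds$i[r]] <- r
    }
  }
  # pattern bonds grouped by the later atom so constraints apply ASAP
  results <- list()
  assign <- integer(np)
  bonds_by_atom <- lapply(seq_len(np), function(k) {
    Filter(function(bd) max(bd$a, bd$b) == k, pat$bonds)
  })
  backtrack <- function(k) {
    if (k > np) {
      results[[length(results) + 1]] <<- assign
      return(invisible(NULL))
    }
    for (a in seq_len(nmol)) {
      if (a %in% assign[seq_len(k - 1)]) next
      if (!.atom_matches(mol, a, pat$atoms[[k]])) next
      ok <- TRUE
      for (bd in bonds_by_atom[[k]]) {
        other <- assign[min(bd$a, bd$b)]
        row <- bond_row[a, other]
        if (row == 0L || !.bond_matches(mol, row, bd$type)) { ok <- FALSE; break }
      }
      if (ok) {
        assign[k] <<- a
        backtrack(k + 1)
        assign[k] <<- 0L
      }
    }
  }
  backtrack(1L)
  unique(results)
}

#' Donor/acceptor pattern library
#'
#' Reads the editable pattern file shipped with the package (or a user file
#' of the same layout: `pattern<TAB>role<TAB>label`, `#` comments).
#'
#' @param path optional path to an alternative library file.
#' @return list of entries with `pattern`, `role`, `label`.
#' @export
da_pattern_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "donor_acceptor_patterns.txt",
                        package = "tpascreen")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    list(pattern = f[1], role = f[2], label = f[3])
  })
}
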