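# Measurement-table I/O: reading, validation, filtering, collapsing to one
# modelling sample per molecule, and solvent encoding.
#
# The CSV dialect has one row per experimental TPACS observation with columns
# for SMILES, cross section (GM), measurement wavelength (nm), solvent label,
# and optional method/DOI. Column names are remappable via the dialect.

#' Default measurement-table dialect
#'
#' @param smiles,tpacs,wavelength,solvent,method,doi column names in the CSV.
#' @return named list mapping record fields to column names.
#' @export
tpa_csv_dialect <- function(smiles = "smiles", tpacs = "tpacs_gm",
                            wavelength = "wavelength_nm", solvent = "solvent",
                            method = "method", doi = "doi") {
  list(smiles = smiles, tpacs = tpacs, wavelength = wavelength,
       solvent = solvent, method = method, doi = doi)
}

#' Read a measurement table
#'
#' Reads, validates, and canonicalizes one TPACS observation per row. Rows
#' with unparsable SMILES or non-positive cross sections are dropped and
#' reported in the `rejections` attribute, never silently.
#'
#' @param path CSV file (UTF-8, header row).
#' @param dialect column mapping from [tpa_csv_dialect()].
#' @return data.frame of records (`smiles` canonicalized, plus
#'   `smiles_input`, `tpacs`, `wavelength`, `solvent`, `method`, `doi`) with a
#'   `rejections` attribute (data.frame of row, reason).
#' @export
read_measurements <- function(path, dialect = tpa_csv_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty measurement table: ", path, call. = FALSE)
  required <- c("smiles", "tpacs", "wavelength", "solvent")
  for (f in required) {
    col <- dialect[[f]]
    if (!col %in% names(raw)) {
      stop("missing required column '", col, "' (field ", f, ")", call. = FALSE)
    }
  }
  get_opt <- function(f) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(raw)) as.character(raw[[col]]) else rep(NA_character_, nrow(raw))
  }
  rec <- data.frame(
    smiles_input = as.character(raw[[dialect$smiles]]),
    tpacs = as.numeric(raw[[dialect$tpacs]]),
    wavelength = as.numeric(raw[[dialect$wavelength]]),
    solvent = as.character(raw[[dialect$solvent]]),
    method = get_opt("method"),
    doi = get_opt("doi"),
    stringsAsFactors = FALSE
  )
  can <- canonical_smiles(rec$smiles_input)
  reasons <- rep(NA_character_, nrow(rec))
  reasons[is.na(can)] <- "unparsable SMILES"
  reasons[is.na(reasons) & (!is.finite(rec$tpacs) | rec$tpacs <= 0)] <- "non-positive or missing TPACS"
  reasons[is.na(reasons) & (!is.finite(rec$wavelength) | rec$wavelength <= 0)] <- "non-positive or missing wavelength"
  keep <- is.na(reasons)
  rejections <- data.frame(row = which(!keep), smiles = rec$smiles_input[!keep],
                           reason = reasons[!keep], stringsAsFactors = FALSE)
  out <- rec[keep, , drop = FALSE]
  out$smiles <- can[keep]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()]: emits the same CSV dialect.
#' @param records data.frame of records.
#' @param path output path.
#' @param dialect column mapping.
#' @export
write_measurements <- function(records, path, dialect = tpa_csv_dialect()) {
  df <- data.frame(records$smiles, records$tpacs, records$wavelength,
                   records$solvent, records$method, records$doi,
                   stringsAsFactors = FALSE)
  names(df) <- unlist(dialect[c("smiles", "tpacs", "wavelength", "solvent",
                                "method", "doi")])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter measurements by wavelength window and banned elements
#'
#' Keeps records measured inside `[lambda_min, lambda_max]` whose molecules
#' contain none of the banned elements. Idempotent.
#'
#' @param records data.frame from [read_measurements()].
#' @param lambda_min,lambda_max wavelength window in nm.
#' @param banned_elements character vector of element symbols.
#' @return filtered data.frame.
#' @export
filter_measurements <- function(records, lambda_min = 600, lambda_max = 1100,
                                banned_elements = c("P", "Si", "I")) {
  stopifnot(lambda_min < lambda_max)
  if (!nrow(records)) return(records)
  keep_lambda <- records$wavelength >= lambda_min & records$wavelength <= lambda_max
  mols <- parse_molecules(records$smiles)
  keep_elem <- vapply(mols, function(m) {
    !is.null(m) && !any(mol_elements(m) %in% banned_elements)
  }, TRUE)
  out <- records[keep_lambda & keep_elem, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Solvent constants table
#'
#' Literature ET(30) polarity, static dielectric constant, and gas-phase
#' dipole moment for common TPA measurement solvents, shipped as a versioned
#' CSV with per-row citations.
#'
#' @param path optional alternative CSV of the same layout.
#' @return data.frame with `name`, `et30`, `dielectric`, `dipole`, `aliases`.
#' @export
tpa_solvent_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "solvents.csv", package = "tpascreen")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- c("name", "et30", "dielectric", "dipole", "aliases", "source")
  df
}

.norm_solvent <- function(x) gsub("[ _-]", "", tolower(trimws(x)))

#' Encode a solvent label as its three descriptors
#'
#' @param name solvent label (case/spacing/alias tolerant).
#' @param table solvent table from [tpa_solvent_table()].
#' @return list with `name`, `et30` (kcal/mol), `dielectric`, `dipole`
#'   (Debye).
#' @export
encode_solvent <- function(name, table = tpa_solvent_table()) {
  key <- .norm_solvent(name)
  canon <- .norm_solvent(table$name)
  hit <- match(key, canon)
  if (is.na(hit)) {
    aliases <- strsplit(table$aliases, ";", fixed = TRUE)
    for (i in seq_along(aliases)) {
      if (key %in% .norm_solvent(aliases[[i]])) { hit <- i; break }
    }
  }
  if (is.na(hit)) {
    stop("unknown solvent '", name, "'; known solvents: ",
         paste(table$name, collapse = ", "), call. = FALSE)
  }
  list(name = table$name[hit], et30 = table$et30[hit],
       dielectric = table$dielectric[hit], dipole = table$dipole[hit])
}

#' Collapse measurements to one modelling sample per molecule
#'
#' Groups records by canonical SMILES and keeps one record per molecule:
#' the maximum-cross-section record by default (the screening-relevant peak),
#' or the record nearest a target wavelength. Applies the lg (log10)
#' transform and attaches the solvent descriptors.
#'
#' @param records filtered data.frame of records.
#' @param policy `"max_sigma"` or `"nearest_wavelength"`.
#' @param target_wavelength used by the `nearest_wavelength` policy (nm).
#' @param solvent_table solvent constants table.
#' @return data.frame of modelling samples: `molecule_id`, `smiles`,
#'   `lg_tpacs`, `wavelength`, `solvent`, `et30`, `dielectric`, `dipole`.
#' @export
collapse_to_samples <- function(records, policy = c("max_sigma", "nearest_wavelength"),
                                target_wavelength = 800,
                                solvent_table = tpa_solvent_table()) {
  policy <- match.arg(policy)
  if (!nrow(records)) stop("no records to collapse", call. = FALSE)
  groups <- split(seq_len(nrow(records)), records$smiles)
  picks <- vapply(groups, function(idx) {
    if (policy == "max_sigma") idx[which.max(records$tpacs[idx])]
    else idx[which.min(abs(records$wavelength[idx] - target_wavelength))]
  }, 1L)
  sel <- records[picks, , drop = FALSE]
  enc <- lapply(sel$solvent, encode_solvent, table = solvent_table)
  out <- data.frame(
    molecule_id = paste0("mol", seq_len(nrow(sel))),
    smiles = sel$smiles,
    lg_tpacs = log10(sel$tpacs),
    wavelength = sel$wavelength,
    solvent = vapply(enc, `[[`, "", "name"),
    et30 = vapply(enc, `[[`, 0, "et30"),
    dielectric = vapply(enc, `[[`, 0, "dielectric"),
    dipole = vapply(enc, `[[`, 0, "dipole"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
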