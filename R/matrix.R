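# Feature-matrix assembly: concatenates the feature blocks in a fixed order
# (MFF | general | conjugation | mff-moe | solvent | wavelength), tags every
# column with its block, and applies the median imputation rule.

#' Assemble the molecules-by-features matrix
#'
#' @param samples data.frame of modelling samples with at least
#'   `molecule_id`, `smiles`; `wavelength`, `et30`, `dielectric`, `dipole`
#'   are required when the experimental block is included.
#' @param molecules optional named list of parsed `tpa_mol` (by molecule_id);
#'   parsed from `samples$smiles` when omitted.
#' @param catalog fragment catalog; built from the sample molecules
#'   (radius 4, min_support 2) when omitted and an MFF block is requested.
#' @param blocks feature blocks to include, in assembly order.
#' @param moe_properties atom-attributed properties for the MFF-MOE block.
#' @param moe_aggregations aggregations for the MFF-MOE block.
#' @param patterns donor/acceptor pattern library for conjugation features.
#' @return a `feature_matrix`: list with `x` (numeric matrix), `sample_ids`,
#'   `features` (data.frame name/block), `catalog`, and an `imputed` attribute
#'   marking imputed cells.
#' @export
assemble_matrix <- function(samples, molecules = NULL, catalog = NULL,
                            blocks = c("mff", "general", "conjugation",
                                       "mff_moe", "experimental"),
                            moe_properties = c("peoe_charge", "logp", "mr"),
                            moe_aggregations = c("max", "min", "mean", "sum"),
                            patterns = da_pattern_library()) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (is.null(molecules)) {
    molecules <- parse_molecules(samples$smiles, ids = samples$molecule_id)
  }
  if (any(vapply(molecules, is.null, TRUE))) {
    stop("unparsable SMILES in samples: ",
         paste(samples$molecule_id[vapply(molecules, is.null, TRUE)], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(catalog) && any(c("mff", "mff_moe") %in% blocks)) {
    catalog <- build_catalog(molecules)
  }
  # per-molecule feature computation memoized by canonical SMILES
  memo <- new.env(parent = emptyenv())
  per_mol <- lapply(molecules, function(mol) {
    hit <- get0(mol$smiles, envir = memo)
    if (!is.null(hit)) return(hit)
    parts <- list()
    if ("mff" %in% blocks) parts$mff <- mff_featurize(mol, catalog)
    if ("general" %in% blocks) parts$general <- general_descriptors(mol)
    if ("conjugation" %in% blocks) parts$conjugation <- conjugation_features(mol, patterns)
    if ("mff_moe" %in% blocks) {
      parts$mff_moe <- unlist(lapply(moe_properties, function(p) {
        mff_moe_features(mol, catalog, atom_attributions(mol, p), moe_aggregations)
      }))
    }
    assign(mol$smiles, parts, envir = memo)
    parts
  })
  cols <- list()
  feat <- list()
  grab <- function(block) {
    m <- do.call(rbind, lapply(per_mol, `[[`, block))
    nm <- colnames(m)
    if (block == "mff") nm <- paste0("mff|", nm)
    colnames(m) <- nm
    cols[[block]] <<- m
    feat[[block]] <<- data.frame(name = nm, block = block, stringsAsFactors = FALSE)
  }
  for (blk in setdiff(blocks, "experimental")) grab(blk)
  if ("experimental" %in% blocks) {
    need <- c("et30", "dielectric", "dipole", "wavelength")
    miss <- setdiff(need, names(samples))
    if (length(miss)) stop("samples lack experimental columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    m <- as.matrix(samples[, need])
    colnames(m) <- c("et30", "dielectric", "dipole", "wavelength_nm")
    cols$experimental <- m
    feat$experimental <- data.frame(name = colnames(m), block = "experimental",
                                    stringsAsFactors = FALSE)
  }
  x <- do.call(cbind, cols[blocks])
  features <- do.call(rbind, feat[blocks])
  rownames(features) <- NULL
  if (anyDuplicated(features$name)) {
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(x) <- samples$molecule_id
  imputed <- !is.finite(x)
  if (any(imputed)) {
    for (jcol in which(colSums(imputed) > 0)) {
      v <- x[, jcol]
      med <- stats::median(v[is.finite(v)])
      if (!is.finite(med)) med <- 0
      x[!is.finite(v), jcol] <- med
    }
  }
  structure(list(x = x, sample_ids = samples$molecule_id, features = features,
                 catalog = catalog),
            class = "feature_matrix", imputed = imputed)
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$features$block)
  cat("<feature_matrix> ", nrow(x$x), " samples x ", ncol(x$x), " features (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a feature matrix (dense CSV + column manifest JSON)
#' @param fm a `feature_matrix`.
#' @param path output CSV path; the manifest is written next to it.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(molecule_id = fm$sample_ids, fm$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(fm$features, sub("\\.csv$", "_manifest.json", path))
  invisible(path)
}

#' Select columns of a feature matrix by name
#' @param fm a `feature_matrix`.
#' @param names feature names to keep, in the requested order.
#' @return a `feature_matrix` restricted to those columns.
#' @export
select_features <- function(fm, names) {
  miss <- setdiff(names, colnames(fm$x))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  fm$x <- fm$x[, names, drop = FALSE]
  fm$features <- fm$features[match(names, fm$features$name), , drop = FALSE]
  rownames(fm$features) <- NULL
  fm
}
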