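# Synthetic chromophore generator.
#
# Builds homologous families of conjugated molecules by template
# concatenation, with optional donor/acceptor termini, and plants a
# power-law-plus-effects model on the targets:
#   lg_tpacs = alpha + beta * lg(L) + gamma_da * 1[D and A present] + eps,
#   eps ~ N(0, sigma_noise^2),
# where L is the conjugation length the conjugation module measures on the
# same SMILES. Every stage of the pipeline can therefore be tested offline
# against known ground truth.

.SYNTH_FAMILIES <- c("polyene", "opv", "da_polyene")

.synth_smiles <- function(family, k) {
  switch(family,
    polyene = strrep("C=C", k),
    opv = paste0("c1ccc(cc1)", strrep("C=Cc1ccc(cc1)", k - 1), "C=Cc1ccccc1"),
    da_polyene = paste0("CN(C)", strrep("C=C", k), "[N+](=O)[O-]"),
    stop("unknown family '", family, "'", call. = FALSE)
  )
}

# template arithmetic for the true conjugation length
.synth_true_L <- function(family, k) {
  switch(family,
    polyene = 2L * k - 1L,
    opv = 9L + 6L * (k - 1L),
    da_polyene = 2L * k + 2L
  )
}

.synth_has_da <- function(family) family == "da_polyene"

#' Generator configuration
#'
#' @param family one or more of `"polyene"`, `"opv"` (oligophenylene
#'   vinylene), `"da_polyene"` (dimethylamino/nitro-capped polyene).
#' @param n_min,n_max repeat-unit range per family.
#' @param beta planted exponent on lg(conjugation length).
#' @param gamma_da planted donor-acceptor effect, lg units.
#' @param alpha intercept, lg units.
#' @param sigma_noise Gaussian noise sd, lg units.
#' @param n_samples number of rows (repeat counts resampled uniformly).
#' @param wavelength,solvent experimental columns (fixed plausible values).
#' @param seed RNG seed.
#' @return a `generator_config` list.
#' @export
synth_config <- function(family = c("polyene", "opv", "da_polyene"),
                         n_min = 1, n_max = 8, beta = 1.8, gamma_da = 0.3,
                         alpha = 0, sigma_noise = 0.3, n_samples = 400,
                         wavelength = 800, solvent = "toluene", seed = 1L) {
  family <- match.arg(family, .SYNTH_FAMILIES, several.ok = TRUE)
  stopifnot(n_min >= 1, n_min <= n_max, sigma_noise >= 0, n_samples >= 1)
  structure(list(family = family, n_min = n_min, n_max = n_max, beta = beta,
                 gamma_da = gamma_da, alpha = alpha, sigma_noise = sigma_noise,
                 n_samples = n_samples, wavelength = wavelength,
                 solvent = solvent, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic chromophore series
#'
#' @param config a `generator_config` from [synth_config()].
#' @return data.frame (class `synthetic_dataset`) with `molecule_id`,
#'   `smiles`, `family`, `repeat_units`, `true_L`, `has_da`, `lg_tpacs`,
#'   `tpacs`, `wavelength`, `solvent`; the generating config is attached as
#'   attribute `config`.
#' @export
make_series <- function(config = synth_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  fam <- sample(config$family, config$n_samples, replace = TRUE)
  k <- sample(seq(config$n_min, config$n_max), config$n_samples, replace = TRUE)
  smiles <- mapply(.synth_smiles, fam, k)
  L <- mapply(.synth_true_L, fam, k)
  has_da <- .synth_has_da(fam)
  eps <- stats::rnorm(config$n_samples, 0, config$sigma_noise)
  lg <- config$alpha + config$beta * log10(L) + config$gamma_da * has_da + eps
  out <- data.frame(
    molecule_id = sprintf("syn%04d", seq_len(config$n_samples)),
    smiles = unname(smiles),
    family = fam,
    repeat_units = k,
    true_L = as.integer(L),
    has_da = has_da,
    lg_tpacs = lg,
    tpacs = 10^lg,
    wavelength = config$wavelength,
    solvent = config$solvent,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("synthetic_dataset", "data.frame")
  out
}

#' Write a synthetic dataset in the measurement-table dialect
#'
#' The emitted CSV is indistinguishable to the pipeline from a real
#' measurement table.
#'
#' @param dataset a `synthetic_dataset`.
#' @param path output CSV path.
#' @param dialect column mapping.
#' @export
write_synthetic_measurements <- function(dataset, path,
                                         dialect = tpa_csv_dialect()) {
  rec <- data.frame(smiles = dataset$smiles, tpacs = dataset$tpacs,
                    wavelength = dataset$wavelength, solvent = dataset$solvent,
                    method = "synthetic", doi = NA_character_,
                    stringsAsFactors = FALSE)
  write_measurements(rec, path, dialect)
}

#' Linear regression fixture
#'
#' Standard-normal features with linear targets plus Gaussian noise, for
#' testing the selection and evaluation machinery with known ground truth.
#'
#' @param n_samples rows.
#' @param n_informative number of features with nonzero coefficients.
#' @param n_noise number of pure-noise features.
#' @param coefficients coefficients of the informative features.
#' @param sigma noise sd.
#' @param seed RNG seed.
#' @return list with `x` (columns `x1`, `x2`, ...), `y`, `coefficients`
#'   (full-length vector, zeros for noise features).
#' @export
make_regression_fixture <- function(n_samples, n_informative, n_noise,
                                    coefficients = rep(1, n_informative),
                                    sigma = 0.3, seed = 1L) {
  stopifnot(length(coefficients) == n_informative)
  set.seed(seed)
  p <- n_informative + n_noise
  x <- matrix(stats::rnorm(n_samples * p), n_samples, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- c(coefficients, rep(0, n_noise))
  y <- as.numeric(x %*% beta) + stats::rnorm(n_samples, 0, sigma)
  list(x = x, y = y, coefficients = beta)
}
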