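# Pipeline orchestration: a single configuration object drives reproducible
# runs of the stages (simulate, featurize, select, train, evaluate, explain,
# predict); every artifact records the configuration hash and all randomness
# flows from one base seed.

#' Default run configuration
#'
#' @param overrides named list merged over the defaults (nested lists merged
#'   recursively).
#' @return a `run_config` list.
#' @export
tpa_default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    out_dir = "tpa_artifacts",
    featurize = list(radius = 4, min_support = 2,
                     blocks = c("mff", "general", "conjugation", "mff_moe",
                                "experimental"),
                     lambda_min = 600, lambda_max = 1100,
                     banned_elements = c("P", "Si", "I"),
                     collapse_policy = "max_sigma"),
    model = list(regressor = "xgb", n_runs = 24, test_fraction = 0.15,
                 hyper = list()),
    selection = list(methods = c("lasso", "gbrt", "xgb"), refresh_every = 10,
                     stop_size = 6, importance_runs = 24, eval_runs = 8,
                     seed_feature = "conju_max_distance", tolerance = 0.005),
    explain = list(feature = "conju_max_distance", features = NULL),
    simulate = list()
  )
  cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

# order-independent configuration hash
.sort_rec <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, .sort_rec)
  } else x
}

#' Configuration hash
#' @param config a `run_config` (or any list); key order does not affect the
#'   hash.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(.sort_rec(unclass(config)), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.write_json_artifact <- function(x, path, config) {
  x$config_hash <- config_hash(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' @param command one of `simulate`, `featurize`, `select`, `train`,
#'   `evaluate`, `explain`, `predict`.
#' @param config a `run_config` (see [tpa_default_config()]).
#' @param input input file (measurement CSV for featurize onwards; SMILES CSV
#'   with `smiles`, `wavelength`, `solvent` columns for predict).
#' @return invisible list of artifact paths; artifacts are written under
#'   `config$out_dir`.
#' @export
tpa_run <- function(command = c("simulate", "featurize", "select", "train",
                                "evaluate", "explain", "predict"),
                    config = tpa_default_config(), input = NULL) {
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  artifacts <- list()
  log_msg <- function(...) message("[tpascreen] ", ...)

  load_samples <- function() {
    path <- input %||% out("measurements.csv")
    rec <- read_measurements(path)
    rej <- attr(rec, "rejections")
    fcfg <- config$featurize
    rec <- filter_measurements(rec, fcfg$lambda_min, fcfg$lambda_max,
                               fcfg$banned_elements)
    samples <- collapse_to_samples(rec, policy = fcfg$collapse_policy)
    .write_json_artifact(list(n_rejected = nrow(rej), rejections = rej,
                              n_records = nrow(rec), n_samples = nrow(samples)),
                         out("rejection_report.json"), config)
    log_msg(nrow(samples), " samples after filtering/collapse (",
            nrow(rej), " rows rejected)")
    samples
  }

  build_matrix <- function(samples) {
    fcfg <- config$featurize
    mols <- parse_molecules(samples$smiles, samples$molecule_id)
    catalog <- build_catalog(mols, radius = fcfg$radius,
                             min_support = fcfg$min_support)
    fm <- assemble_matrix(samples, mols, catalog, blocks = fcfg$blocks)
    write_catalog(catalog, out("catalog.json"))
    write_feature_matrix(fm, out("features.csv"))
    log_msg("feature matrix ", nrow(fm$x), " x ", ncol(fm$x))
    fm
  }

  if (command == "simulate") {
    sim <- do.call(synth_config, utils::modifyList(list(seed = config$seed),
                                                   config$simulate))
    ds <- make_series(sim)
    write_synthetic_measurements(ds, out("measurements.csv"))
    utils::write.csv(ds, out("simulated_truth.csv"), row.names = FALSE)
    artifacts$measurements <- out("measurements.csv")
    log_msg("simulated ", nrow(ds), " measurements")
  } else if (command == "featurize") {
    samples <- load_samples()
    build_matrix(samples)
    utils::write.csv(samples, out("samples.csv"), row.names = FALSE)
    artifacts$features <- out("features.csv")
  } else if (command %in% c("select", "train", "evaluate", "explain")) {
    samples <- load_samples()
    fm <- build_matrix(samples)
    y <- samples$lg_tpacs
    mcfg <- config$model
    scfg <- config$selection
    if (command == "select") {
      bk <- backward_eliminate(fm$x, y, refresh_every = scfg$refresh_every,
                               stop_size = scfg$stop_size,
                               regressor = mcfg$regressor,
                               eval_runs = scfg$eval_runs,
                               importance_runs = scfg$importance_runs,
                               base_seed = config$seed, methods = scfg$methods,
                               hyper = mcfg$hyper)
      utils::write.csv(bk, out("backward_trace.csv"), row.names = FALSE)
      fw <- forward_stepwise(fm$x, y, seed_features = scfg$seed_feature,
                             candidate_pool = setdiff(attr(bk, "selected"),
                                                      scfg$seed_feature),
                             tolerance = scfg$tolerance,
                             regressor = mcfg$regressor,
                             eval_runs = scfg$eval_runs,
                             base_seed = config$seed, hyper = mcfg$hyper)
      utils::write.csv(fw, out("forward_trace.csv"), row.names = FALSE)
      .write_json_artifact(list(selected = attr(fw, "selected")),
                           out("selected_features.json"), config)
      artifacts$selected <- out("selected_features.json")
    } else if (command == "train") {
      ens <- train_ensemble(fm$x, y, mcfg$regressor,
                            cv_protocol(mcfg$n_runs, mcfg$test_fraction,
                                        config$seed), mcfg$hyper)
      saveRDS(ens, out("ensemble.rds"))
      .write_json_artifact(list(regressor = mcfg$regressor,
                                n_models = length(ens$models),
                                features = ens$feature_names),
                           out("model_manifest.json"), config)
      artifacts$ensemble <- out("ensemble.rds")
    } else if (command == "evaluate") {
      ev <- evaluate(fm$x, y, mcfg$regressor,
                     cv_protocol(mcfg$n_runs, mcfg$test_fraction, config$seed),
                     mcfg$hyper)
      .write_json_artifact(list(regressor = mcfg$regressor, mse = ev$mse,
                                mae = ev$mae, r2 = ev$r2,
                                n_runs = mcfg$n_runs),
                           out("metrics.json"), config)
      utils::write.csv(ev$runs, out("metrics_runs.csv"), row.names = FALSE)
      artifacts$metrics <- out("metrics.json")
      log_msg("MSE ", signif(ev$mse, 3), ", MAE ", signif(ev$mae, 3),
              ", R2 ", signif(ev$r2, 3))
    } else {
      feats <- config$explain$features %||% colnames(fm$x)
      xsel <- fm$x[, feats, drop = FALSE]
      spec <- .resolve_regressor(mcfg$regressor, mcfg$hyper)
      model <- spec$fit(xsel, y, seed = config$seed, h = spec$hyperparameters)
      ex <- shap_values(model, xsel)
      utils::write.csv(shap_table(ex), out("shap_values.csv"),
                       row.names = FALSE)
      pl <- fit_power_law(ex, config$explain$feature)
      .write_json_artifact(list(feature = pl$feature, exponent = pl$exponent,
                                intercept = pl$intercept, stderr = pl$stderr,
                                r_squared = pl$r_squared, n = pl$n),
                           out("power_law.json"), config)
      artifacts$power_law <- out("power_law.json")
      log_msg("power-law exponent ", signif(pl$exponent, 3), " +/- ",
              signif(pl$stderr, 2))
    }
  } else if (command == "predict") {
    if (is.null(input)) stop("predict requires an input CSV", call. = FALSE)
    ens <- readRDS(out("ensemble.rds"))
    catalog <- read_catalog(out("catalog.json"))
    newdf <- utils::read.csv(input, stringsAsFactors = FALSE)
    enc <- lapply(newdf$solvent, encode_solvent)
    samples <- data.frame(
      molecule_id = newdf$smiles, smiles = newdf$smiles,
      wavelength = newdf$wavelength,
      et30 = vapply(enc, `[[`, 0, "et30"),
      dielectric = vapply(enc, `[[`, 0, "dielectric"),
      dipole = vapply(enc, `[[`, 0, "dipole"), stringsAsFactors = FALSE)
    fm <- assemble_matrix(samples, catalog = catalog,
                          blocks = config$featurize$blocks)
    pred <- stats::predict(ens, fm$x)
    res <- cbind(newdf, pred)
    utils::write.csv(res, out("predictions.csv"), row.names = FALSE)
    artifacts$predictions <- out("predictions.csv")
  }
  invisible(artifacts)
}
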