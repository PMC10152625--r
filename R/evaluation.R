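# The simulation driver: scenarios x estimators x techniques x measures,
# with the large independent validation set as gold standard.

#' Evaluate a fitted model on an independent validation set
#'
#' The simulation's gold standard: the model's predicted probabilities are
#' computed on a large fresh draw from the same data-generating mechanism
#' and all three measures are evaluated there.
#'
#' @param model An `ov_fit`.
#' @param valset An [ov_dataset()] drawn from the same scenario.
#' @return Named list with elements `cstat`, `dslope`, `brier`.
#' @export
independent_validation <- function(model, valset) {
  p <- predict(model, valset)
  list(cstat = c_statistic(p, valset$y),
       dslope = discrimination_slope(p, valset$y),
       brier = brier_score(p, valset$y))
}

#' Run one simulation replicate
#'
#' Draws one development dataset from the scenario, fits every requested
#' estimator, computes all applicable technique x measure estimates and
#' the independent-validation values, and records the separation status of
#' the development data.
#'
#' @param scenario An [make_scenario()] object.
#' @param replicate_seed Integer seed; the replicate is bit-reproducible
#'   from it.
#' @param valset The scenario's validation set (generated once per
#'   scenario, see [gen_validation_set()]).
#' @param estimators Subset of `c("ml", "fl", "rr")`.
#' @param techniques Subset of [ov_techniques()].
#' @param measures Subset of [ov_measures()].
#' @param f,r,B Technique parameters, see [kfold_cv()] and
#'   [enhanced_bootstrap()].
#' @param control A [fit_control()] object.
#' @return A long data.frame with one row per estimator x technique x
#'   measure: columns `scenario`, `replicate_seed`, `estimator`,
#'   `technique`, `measure`, `estimate`, `iv`, `separation`, `n_fits`,
#'   `n_failed`.
#' @export
run_replicate <- function(scenario, replicate_seed, valset,
                          estimators = c("ml", "fl", "rr"),
                          techniques = ov_techniques(),
                          measures = ov_measures(),
                          f = 5L, r = 40L, B = 200L,
                          control = fit_control()) {
  dev <- gen_dataset(scenario, seed = replicate_seed)
  sep <- detect_separation(dev)
  rows <- list()
  for (est in estimators) {
    Xd <- design_matrix(dev$X)
    full <- tryCatch(fit_core(dev$y, Xd, est, control), error = function(e) NULL)
    if (is.null(full)) {
      rows[[est]] <- data.frame(estimator = est, technique = NA_character_,
                                measure = NA_character_, estimate = NA_real_,
                                iv = NA_real_, n_fits = 0L, n_failed = 1L,
                                stringsAsFactors = FALSE)
      next
    }
    p_val <- plogis(full$beta[1L] + drop(valset$X %*% full$beta[-1L]))
    iv <- vapply(measures, measure_value, 0, p = p_val, y = valset$y)
    tab <- internal_validation(dev, est, techniques, measures, f, r, B,
                               seed = derive_seed(replicate_seed, match(est, c("ml", "fl", "rr"))),
                               control = control)
    tab$estimator <- est
    tab$iv <- iv[tab$measure]
    rows[[est]] <- tab[, c("estimator", "technique", "measure", "estimate",
                           "iv", "n_fits", "n_failed")]
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- cbind(data.frame(scenario = scenario$id,
                          replicate_seed = replicate_seed,
                          stringsAsFactors = FALSE), out)
  out$separation <- sep
  out
}

#' Summarize replicate records against the gold standard
#'
#' For each scenario x estimator x technique x measure cell, computes the
#' per-replicate differences `d = estimate - IV`, their mean (`mean_diff`,
#' the bias), the root mean squared difference (`rmsd`), and Monte-Carlo
#' standard errors: `mcse_msd = sd(d^2)/sqrt(m)` for the mean squared
#' difference and, by the delta method, `mcse_rmsd = mcse_msd / (2 rmsd)`.
#'
#' @param records Row-bound output of [run_replicate()] calls.
#' @return A data.frame with one row per cell: `scenario`, `estimator`,
#'   `technique`, `measure`, `n_replicates`, `mean_diff`, `rmsd`,
#'   `mcse_msd`, `mcse_rmsd`, `pct_separated`.
#' @export
summarize_replicates <- function(records) {
  records <- records[!is.na(records$technique) & !is.na(records$estimate) &
                       !is.na(records$iv), , drop = FALSE]
  if (!nrow(records)) stop_("no usable replicate records")
  key <- interaction(records$scenario, records$estimator, records$technique,
                     records$measure, drop = TRUE)
  parts <- lapply(split(records, key), function(g) {
    d <- g$estimate - g$iv
    m <- length(d)
    rmsd <- sqrt(mean(d^2))
    mcse_msd <- if (m > 1) sd(d^2) / sqrt(m) else NA_real_
    data.frame(scenario = g$scenario[1], estimator = g$estimator[1],
               technique = g$technique[1], measure = g$measure[1],
               n_replicates = m, mean_diff = mean(d), rmsd = rmsd,
               mcse_msd = mcse_msd,
               mcse_rmsd = if (rmsd > 0) mcse_msd / (2 * rmsd) else NA_real_,
               pct_separated = 100 * mean(g$separation[!duplicated(g$replicate_seed)] != "none"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[order(out$scenario, out$estimator, out$technique, out$measure), ,
      drop = FALSE]
}

#' Study configuration
#'
#' Default settings of the full simulation study: 5-fold cross-validation
#' with 40 repetitions, 200 bootstrap resamples, 1000 replicates per
#' scenario, and a 100,000-observation validation set.
#'
#' @param n_replicates Replicates per scenario.
#' @param iv_size Validation-set size.
#' @param f,r,B Technique parameters.
#' @param estimators,techniques,measures What to run.
#' @param dgm Data-generating parameters, see [dgm_params()].
#' @param grid Ridge tuning grid.
#' @param calib_n Monte-Carlo size for intercept calibration.
#' @return A validated list of class `ov_config`.
#' @export
study_config <- function(n_replicates = 1000L, iv_size = 1e5,
                         f = 5L, r = 40L, B = 200L,
                         estimators = c("ml", "fl", "rr"),
                         techniques = ov_techniques(),
                         measures = ov_measures(),
                         dgm = dgm_params(), grid = ridge_grid(),
                         calib_n = 1e6) {
  cfg <- list(n_replicates = as.integer(n_replicates), iv_size = iv_size,
              f = as.integer(f), r = as.integer(r), B = as.integer(B),
              estimators = estimators, techniques = techniques,
              measures = measures, dgm = dgm, grid = grid, calib_n = calib_n)
  validate_config(cfg)
  structure(cfg, class = "ov_config")
}

#' Read a study configuration from a YAML file
#'
#' Accepts a nested key-value file overriding any subset of the
#' [study_config()] fields; the `dgm` block may override `binary_prev`,
#' `ordinal_shift`, `beta_weak`, `beta_strong` and `corr` (given as a full
#' 5x5 matrix, row-wise), and `grid` may give `n_pos`, `lambda_min`,
#' `lambda_max`.  Unknown keys are rejected with a field-level message.
#'
#' @param path Path to a YAML file.
#' @return A validated [study_config()] object.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_("the 'yaml' package is required to read configuration files")
  raw <- yaml::read_yaml(path)
  known <- c("n_replicates", "iv_size", "f", "r", "B", "estimators",
             "techniques", "measures", "dgm", "grid", "calib_n")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_("invalid config: unknown field(s) %s", paste(bad, collapse = ", "))
  args <- raw[setdiff(names(raw), c("dgm", "grid"))]
  if (!is.null(raw$dgm)) {
    dbad <- setdiff(names(raw$dgm),
                    c("binary_prev", "ordinal_shift", "beta_weak",
                      "beta_strong", "corr"))
    if (length(dbad))
      stop_("invalid config: unknown dgm field(s) %s",
            paste(dbad, collapse = ", "))
    if (!is.null(raw$dgm$corr))
      raw$dgm$corr <- matrix(unlist(raw$dgm$corr), 5, 5, byrow = TRUE)
    args$dgm <- do.call(dgm_params, raw$dgm)
  }
  if (!is.null(raw$grid)) {
    gbad <- setdiff(names(raw$grid), c("n_pos", "lambda_min", "lambda_max",
                                       "include_zero"))
    if (length(gbad))
      stop_("invalid config: unknown grid field(s) %s",
            paste(gbad, collapse = ", "))
    args$grid <- do.call(ridge_grid, raw$grid)
  }
  do.call(study_config, args)
}

validate_config <- function(cfg) {
  req <- c("n_replicates", "iv_size", "f", "r", "B", "estimators",
           "techniques", "measures", "dgm", "grid", "calib_n")
  missing_f <- setdiff(req, names(cfg))
  if (length(missing_f))
    stop_("invalid config: missing field(s) %s", paste(missing_f, collapse = ", "))
  if (cfg$n_replicates < 1L) stop_("invalid config: n_replicates must be >= 1")
  if (cfg$iv_size < 1) stop_("invalid config: iv_size must be >= 1")
  if (!all(cfg$estimators %in% c("ml", "fl", "rr")))
    stop_("invalid config: estimators must be among ml, fl, rr")
  if (!all(cfg$techniques %in% ov_techniques()))
    stop_("invalid config: unknown technique")
  if (!all(cfg$measures %in% ov_measures()))
    stop_("invalid config: unknown measure")
  invisible(TRUE)
}

#' Run the simulation study
#'
#' Executes the requested scenarios at the configured replicate count: per
#' scenario one validation set is drawn and reused across replicates, each
#' replicate draws a development dataset and computes every estimator x
#' technique x measure estimate plus its independent-validation
#' counterpart, and the records are summarized with [summarize_replicates()].
#' Replicate failures are logged and the run continues.
#'
#' @param scenarios List of [make_scenario()] objects (defaults to the
#'   12-scenario grid).
#' @param config An [study_config()] object.
#' @param master_seed Single integer seed; every replicate and resample
#'   substream is derived from it deterministically.
#' @param out_dir Optional directory: tidy summary, replicate archive and
#'   a run manifest are written there as CSV/text.
#' @param verbose Print per-scenario progress.
#' @return List of class `ov_study` with elements `summary`, `replicates`
#'   (the archive), `errors` and `manifest`.
#' @export
run_study <- function(scenarios = NULL, config = study_config(),
                      master_seed = 1L, out_dir = NULL, verbose = FALSE) {
  validate_config(config)
  if (is.null(scenarios))
    scenarios <- make_scenario_grid(config$dgm, config$calib_n,
                                    seed = derive_seed(master_seed, 999L))
  control <- fit_control(grid = config$grid)
  all_recs <- list()
  errors <- character()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    if (verbose) message("scenario ", sc$id)
    valset <- gen_validation_set(sc, config$iv_size,
                                 seed = derive_seed(master_seed, si, 0L))
    for (ri in seq_len(config$n_replicates)) {
      rec <- tryCatch(
        run_replicate(sc, derive_seed(master_seed, si, ri), valset,
                      config$estimators, config$techniques, config$measures,
                      config$f, config$r, config$B, control),
        error = function(e) {
          errors <<- c(errors, sprintf("%s replicate %d: %s", sc$id, ri,
                                       conditionMessage(e)))
          NULL
        })
      if (!is.null(rec)) all_recs[[length(all_recs) + 1L]] <- rec
    }
  }
  replicates <- do.call(rbind, c(all_recs, list(make.row.names = FALSE)))
  summary <- summarize_replicates(replicates)
  manifest <- list(master_seed = master_seed,
                   n_replicates = config$n_replicates,
                   iv_size = config$iv_size,
                   f = config$f, r = config$r, B = config$B,
                   scenarios = vapply(scenarios, `[[`, "", "id"),
                   package_version = as.character(utils::packageVersion("optivalid")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- structure(list(summary = summary, replicates = replicates,
                        errors = errors, manifest = manifest),
                   class = "ov_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write.csv(replicates, file.path(out_dir, "replicates.csv"), row.names = FALSE)
    writeLines(c(sprintf("%s: %s", names(manifest),
                         vapply(manifest, function(x) paste(x, collapse = " "), "")),
                 if (length(errors)) c("errors:", errors)),
               file.path(out_dir, "manifest.txt"))
  }
  out
}

#' @export
print.ov_study <- function(x, ...) {
  cat(sprintf("<ov_study> %d summary cells, %d replicate rows, %d errors\n",
              nrow(x$summary), nrow(x$replicates), length(x$errors)))
  invisible(x)
}
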