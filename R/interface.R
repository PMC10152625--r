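# User-facing entry points for external data and the leave-one-out
# illustration.  The package's functions (and the scripts/ directory of the
# source repository) are the interface; no separate executable is shipped.

#' Optimism-corrected validation of a user-supplied dataset
#'
#' Runs the full internal-validation table (apparent plus the requested
#' correction techniques, all applicable measures) for each estimator on a
#' dataset supplied as a CSV file or data.frame.  The outcome column must
#' be coded 0/1; covariates must be numeric, complete and non-constant.
#'
#' @param data Path to a CSV file with a header row, or a data.frame.
#' @param outcome Name of the outcome column.
#' @param estimators Subset of `c("ml", "fl", "rr")`.
#' @param techniques Subset of [ov_techniques()].
#' @param f,r,B Technique parameters.
#' @param seed Integer seed for the resampling techniques.
#' @param control A [fit_control()] object.
#' @param out_csv Optional path: the table is also written there.
#' @return A data.frame with columns `estimator`, `technique`, `measure`,
#'   `estimate`, `n_fits`, `n_failed`.
#' @export
validate_data <- function(data, outcome = "y",
                          estimators = c("ml", "fl", "rr"),
                          techniques = ov_techniques(),
                          f = 5L, r = 40L, B = 200L, seed = 1L,
                          control = fit_control(), out_csv = NULL) {
  df <- if (is.character(data)) read.csv(data, check.names = FALSE) else
    as.data.frame(data)
  if (!outcome %in% names(df))
    stop_("outcome column '%s' not found", outcome)
  y <- df[[outcome]]
  if (anyNA(df)) stop_("data contain missing values")
  if (!all(y %in% c(0, 1)))
    stop_("outcome column '%s' is not binary 0/1", outcome)
  X <- df[setdiff(names(df), outcome)]
  if (!all(vapply(X, is.numeric, TRUE)))
    stop_("all covariate columns must be numeric")
  X <- as.matrix(X)
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(const))
    stop_("constant covariate column(s): %s",
          paste(colnames(X)[const], collapse = ", "))
  ds <- ov_dataset(y, X)
  parts <- lapply(estimators, function(est) {
    tab <- internal_validation(ds, est, techniques, ov_measures(), f, r, B,
                               seed = derive_seed(seed, match(est, c("ml", "fl", "rr"))),
                               control = control)
    cbind(data.frame(estimator = est, stringsAsFactors = FALSE),
          tab[, c("technique", "measure", "estimate", "n_fits", "n_failed")])
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Leave-one-out trace on a toy dataset
#'
#' Generates the illustrative setting in which the downward bias of pooled
#' leave-one-out cross-validation is easiest to see: `n` observations of a
#' single standard-normal covariate with `k` randomly chosen observations
#' labelled as events (so the covariate carries no true signal).  For each
#' requested estimator, every observation is left out in turn, the model
#' is refitted, and the left-out prediction is recorded.  Leaving out an
#' event lowers the training event fraction, so the left-out event's
#' predicted probability tends to be too low (and a non-event's too high),
#' which biases the pooled c-statistic downwards -- the more so the more
#' the estimator shrinks predictions towards the event fraction.
#'
#' @param seed Integer seed.
#' @param n,k Number of observations and events.
#' @param estimators Subset of `c("ml", "fl", "rr")`.
#' @param control A [fit_control()] object.
#' @return A data.frame with one row per estimator x iteration: columns
#'   `estimator`, `iteration`, `left_out_event`, `x`, `p_left_out`; the
#'   pooled leave-one-out c-statistic per estimator is in attribute
#'   `"pooled_cstat"`.
#' @export
loo_trace <- function(seed = 1L, n = 20L, k = 5L,
                      estimators = c("ml", "rr"), control = fit_control()) {
  ds <- with_seed(seed, {
    x <- rnorm(n)
    y <- rep(0, n)
    y[sample.int(n, k)] <- 1
    ov_dataset(y, cbind(x = x))
  })
  Xd <- design_matrix(ds$X)
  rows <- list()
  pooled <- numeric(0)
  for (est in estimators) {
    preds <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      core <- fit_try(ds$y[-i], Xd[-i, , drop = FALSE], est, control)
      if (!is.null(core)) preds[i] <- pred_core(core, Xd[i, , drop = FALSE])
    }
    ord <- order(-ds$y)              # events first, as iterations 1..k
    rows[[est]] <- data.frame(estimator = est, iteration = seq_len(n),
                              left_out_event = ds$y[ord] == 1,
                              x = ds$X[ord, 1], p_left_out = preds[ord],
                              stringsAsFactors = FALSE)
    ok <- !is.na(preds)
    pooled[est] <- c_statistic(preds[ok], ds$y[ok])
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "pooled_cstat") <- pooled
  out
}
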