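#' Parameters of the synthetic data-generating mechanism
#'
#' The covariates mimic the mixed variable types met in clinical data sets:
#' a latent 5-dimensional multivariate normal draw with a fixed correlation
#' matrix is transformed into one binary column (dichotomized at a threshold
#' giving prevalence `binary_prev`), one ordinal column (truncation towards
#' zero of a shifted normal, giving integer levels mostly in 0..4), and
#' three continuous columns, one of which is exponentiated to induce
#' skewness.  All thresholds, correlations and effect-size vectors live in
#' this one configuration block so they can be swapped wholesale.
#'
#' The default slope vectors were calibrated once, by simulation on a large
#' draw, so that the true-model c-statistic (the discrimination achievable
#' with the data-generating coefficients themselves) is about 0.60 under
#' `weak` effects and about 0.68 under `strong` effects.
#'
#' @param binary_prev Prevalence of the binary covariate.
#' @param ordinal_shift Shift applied before truncating the ordinal column.
#' @param corr 5x5 latent correlation matrix (positive definite).
#' @param beta_weak,beta_strong Slope vectors (length 5) for the weak and
#'   strong effect settings; the null setting always uses the zero vector.
#'
#' @return A list of class `ov_dgm` with the fields above plus the Cholesky
#'   factor of `corr`.
#' @export
dgm_params <- function(binary_prev = 0.3,
                       ordinal_shift = 2,
                       corr = default_corr(),
                       beta_weak = c(0.286, 0.131, 0.131, 0.061, 0.131),
                       beta_strong = c(0.561, 0.258, 0.258, 0.119, 0.258)) {
  stopifnot(is.matrix(corr), nrow(corr) == 5L, ncol(corr) == 5L,
            length(beta_weak) == 5L, length(beta_strong) == 5L,
            binary_prev > 0, binary_prev < 1)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_("corr must be positive definite")
  structure(list(binary_prev = binary_prev,
                 ordinal_shift = ordinal_shift,
                 corr = corr,
                 chol = chol(corr),
                 beta_weak = beta_weak,
                 beta_strong = beta_strong),
            class = "ov_dgm")
}

default_corr <- function() {
  R <- diag(5)
  set_ <- rbind(c(1, 2, .1), c(1, 3, .3), c(1, 4, .2), c(1, 5, 0),
                c(2, 3, .2), c(2, 4, .1), c(2, 5, .1),
                c(3, 4, .3), c(3, 5, .2), c(4, 5, .1))
  for (k in seq_len(nrow(set_))) {
    R[set_[k, 1], set_[k, 2]] <- R[set_[k, 2], set_[k, 1]] <- set_[k, 3]
  }
  R
}

#' Construct a dataset object
#'
#' Bundles a 0/1 outcome vector with a numeric covariate matrix and
#' per-column type tags.  This is the unit that every estimator and every
#' resampling technique consumes.
#'
#' @param y 0/1 outcome vector.
#' @param X Numeric covariate matrix with `length(y)` rows (may have zero
#'   columns for intercept-only models).
#' @param var_types Optional character vector of per-column tags among
#'   `"binary"`, `"ordinal"`, `"continuous"`.
#' @param seed_info Optional record of the random state used to generate
#'   the data.
#' @return An object of class `ov_dataset`.
#' @export
ov_dataset <- function(y, X, var_types = NULL, seed_info = NULL) {
  y <- as.numeric(y)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = length(y))
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop_("nrow(X) must equal length(y)")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_("y must contain only 0 and 1 with no missing values")
  if (anyNA(X)) stop_("X contains missing values")
  if (!is.null(var_types)) {
    stopifnot(length(var_types) == ncol(X),
              all(var_types %in% c("binary", "ordinal", "continuous")))
  }
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(y = y, X = X, var_types = var_types, seed_info = seed_info),
            class = "ov_dataset")
}

#' @export
print.ov_dataset <- function(x, ...) {
  cat(sprintf("<ov_dataset> n = %d, %d covariates, %d events (%.1f%%)\n",
              length(x$y), ncol(x$X), sum(x$y), 100 * mean(x$y)))
  invisible(x)
}

#' Draw the covariate matrix of the data-generating mechanism
#'
#' @param n Number of rows (at least 2).
#' @param dgm Parameter block from [dgm_params()].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A list with the `n x 5` matrix `X` (columns `x1`..`x5`) and the
#'   `var_types` tags.
#' @export
gen_covariates <- function(n, dgm = dgm_params(), seed = NULL) {
  if (!is.numeric(n) || n < 2) stop_("invalid size: n must be at least 2")
  n <- as.integer(n)
  with_seed(seed, {
    Z <- matrix(rnorm(n * 5L), n, 5L) %*% dgm$chol
    X <- cbind(x1 = as.numeric(Z[, 1] > qnorm(1 - dgm$binary_prev)),
               x2 = trunc(dgm$ordinal_shift + Z[, 2]),
               x3 = Z[, 3],
               x4 = exp(Z[, 4]),
               x5 = Z[, 5])
    list(X = X,
         var_types = c("binary", "ordinal", "continuous", "continuous",
                       "continuous"))
  })
}

#' Calibrate the intercept of a scenario to a target marginal event fraction
#'
#' Solves, by Monte-Carlo root finding on a large covariate draw, for the
#' intercept `a` with `mean(plogis(a + X beta)) = event_fraction`.  With a
#' zero slope vector the solution is `qlogis(event_fraction)` exactly and no
#' simulation is performed.
#'
#' @param beta Slope vector (length 5).
#' @param event_fraction Target marginal event fraction in (0, 1).
#' @param dgm Parameter block from [dgm_params()].
#' @param calib_n Number of Monte-Carlo rows used for calibration.
#' @param seed Optional integer seed for the calibration draw.
#' @param tol Tolerance on the achieved event fraction at the root.
#' @return The calibrated intercept (a single real number).
#' @export
calibrate_intercept <- function(beta, event_fraction, dgm = dgm_params(),
                                calib_n = 1e6, seed = NULL, tol = 1e-4) {
  if (event_fraction <= 0 || event_fraction >= 1)
    stop_("event_fraction must lie in (0, 1)")
  if (all(beta == 0)) return(qlogis(event_fraction))
  X <- gen_covariates(calib_n, dgm, seed = seed)$X
  xb <- drop(X %*% beta)
  g <- function(a) mean(plogis(a + xb)) - event_fraction
  lo <- -40; hi <- 40
  if (g(lo) > 0 || g(hi) < 0)
    stop_("calibration failure: search interval does not bracket the root")
  root <- uniroot(g, c(lo, hi), tol = 1e-8)$root
  if (abs(g(root)) > tol)
    stop_("calibration failure: residual event-fraction error above tolerance")
  root
}

#' Define a simulation scenario
#'
#' A scenario couples a sample size, a target marginal event fraction, and
#' an effect-size setting (`"null"`, `"weak"`, `"strong"`) with the slope
#' vector and calibrated intercept they imply under the data-generating
#' mechanism.
#'
#' @inheritParams calibrate_intercept
#' @param n Development sample size.
#' @param effect One of `"null"`, `"weak"`, `"strong"`.
#' @return An object of class `ov_scenario`.
#' @export
make_scenario <- function(n, event_fraction, effect = c("null", "weak", "strong"),
                          dgm = dgm_params(), calib_n = 1e6, seed = NULL) {
  effect <- match.arg(effect)
  beta <- switch(effect, null = rep(0, 5), weak = dgm$beta_weak,
                 strong = dgm$beta_strong)
  intercept <- calibrate_intercept(beta, event_fraction, dgm, calib_n, seed)
  structure(list(n = as.integer(n), event_fraction = event_fraction,
                 effect = effect, beta = beta, intercept = intercept,
                 dgm = dgm,
                 id = sprintf("n%d_ef%g_%s", n, event_fraction, effect)),
            class = "ov_scenario")
}

#' @export
print.ov_scenario <- function(x, ...) {
  cat(sprintf("<ov_scenario> %s: n = %d, E(y) = %g, effect = %s, a = %.4f\n",
              x$id, x$n, x$event_fraction, x$effect, x$intercept))
  invisible(x)
}

#' The 12-scenario factorial grid
#'
#' Crosses sample size (50, 100), marginal event fraction (0.25, 0.5) and
#' effect size (null, weak, strong) into twelve scenarios with calibrated
#' intercepts.
#'
#' @inheritParams calibrate_intercept
#' @param seed Seed for the calibration draws (one derived substream per
#'   effect x event-fraction combination).
#' @return A list of 12 [make_scenario()] objects.
#' @export
make_scenario_grid <- function(dgm = dgm_params(), calib_n = 1e6, seed = 1L) {
  grid <- expand.grid(n = c(50L, 100L), ef = c(0.25, 0.5),
                      effect = c("null", "weak", "strong"),
                      stringsAsFactors = FALSE)
  # the intercept depends only on (effect, ef): calibrate each pair once
  key <- paste(grid$effect, grid$ef)
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (is.null(cache[[key[i]]])) {
      cache[[key[i]]] <- make_scenario(
        grid$n[i], grid$ef[i], grid$effect[i], dgm, calib_n,
        seed = derive_seed(seed, match(grid$effect[i], c("null", "weak", "strong")),
                           round(grid$ef[i] * 100)))
    }
    sc <- cache[[key[i]]]
    sc$n <- grid$n[i]
    sc$id <- sprintf("n%d_ef%g_%s", sc$n, sc$event_fraction, sc$effect)
    out[[i]] <- sc
  }
  out
}

#' Draw Bernoulli outcomes under a scenario's logistic model
#'
#' @param X Covariate matrix matching the 5-column layout.
#' @param scenario An [make_scenario()] object.
#' @param seed Optional integer seed.
#' @return A 0/1 vector of length `nrow(X)`.
#' @export
gen_outcomes <- function(X, scenario, seed = NULL) {
  if (ncol(X) != length(scenario$beta))
    stop_("X does not match the scenario's covariate layout")
  p <- plogis(scenario$intercept + drop(X %*% scenario$beta))
  with_seed(seed, rbinom(nrow(X), 1L, p))
}

#' Draw a development dataset from a scenario
#'
#' @param scenario An [make_scenario()] object.
#' @param seed Optional integer seed (covariates and outcomes are drawn
#'   from derived substreams so development and validation draws never
#'   share randomness).
#' @return An [ov_dataset()].
#' @export
gen_dataset <- function(scenario, seed = NULL) {
  s1 <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  s2 <- if (is.null(seed)) NULL else derive_seed(seed, 2L)
  cv <- gen_covariates(scenario$n, scenario$dgm, seed = s1)
  y <- gen_outcomes(cv$X, scenario, seed = s2)
  ov_dataset(y, cv$X, cv$var_types,
             seed_info = list(seed = seed, scenario = scenario$id))
}

#' Draw the large independent validation set of a scenario
#'
#' @inheritParams gen_dataset
#' @param N Validation-set size (defaults to 100,000).
#' @return An [ov_dataset()] of `N` rows from the same mechanism.
#' @export
gen_validation_set <- function(scenario, N = 1e5, seed = NULL) {
  if (N < 1) stop_("N must be at least 1")
  sc <- scenario
  sc$n <- as.integer(N)
  gen_dataset(sc, seed = seed)
}

#' Write or read a dataset as CSV
#'
#' The interchange format has a header row, the outcome in a column named
#' `y`, and covariates `x1`, `x2`, ...
#'
#' @param dataset An [ov_dataset()].
#' @param path File path.
#' @return `read_dataset_csv()` returns an [ov_dataset()];
#'   `write_dataset_csv()` returns `path` invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(y = dataset$y, dataset$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"y" %in% names(df)) stop_("CSV must contain an outcome column named 'y'")
  ov_dataset(df$y, as.matrix(df[setdiff(names(df), "y")]))
}
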