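#' Fitting control parameters
#'
#' @param maxit Maximum number of Newton iterations (step-halving within)
#'   for the ML and ridge fits, whose Newton steps use the exact Hessian
#'   and converge quadratically.
#' @param tol Convergence tolerance on the maximal coefficient change.
#' @param grid Ridge tuning grid, see [ridge_grid()].
#' @param maxit_firth Iteration cap for Firth's modified-score fit, whose
#'   Fisher-scoring steps converge only linearly near the optimum and need
#'   more iterations at tight tolerances.
#' @return A list of class `ov_control`.
#' @export
fit_control <- function(maxit = 25L, tol = 1e-8, grid = ridge_grid(),
                        maxit_firth = 500L) {
  structure(list(maxit = as.integer(maxit), tol = tol, grid = grid,
                 maxit_firth = as.integer(maxit_firth)),
            class = "ov_control")
}

#' Log-equidistant ridge tuning grid
#'
#' 96 log-equidistant positive tuning values spanning `1e-4` to `1e4`,
#' preceded by 0 (so that unpenalized maximum likelihood is a candidate,
#' which matters under separation where the penalized AIC may still select
#' no shrinkage).
#'
#' @param n_pos Number of positive grid points.
#' @param lambda_min,lambda_max Range of the positive part.
#' @param include_zero Whether to prepend 0.
#' @return Increasing numeric vector of tuning values.
#' @export
ridge_grid <- function(n_pos = 96L, lambda_min = 1e-4, lambda_max = 1e4,
                       include_zero = TRUE) {
  stopifnot(n_pos >= 2L, lambda_min > 0, lambda_max > lambda_min)
  pos <- exp(seq(log(lambda_min), log(lambda_max), length.out = n_pos))
  if (include_zero) c(0, pos) else pos
}

# ---- internal fitting cores -------------------------------------------------

design_matrix <- function(X) cbind("(Intercept)" = 1, X)

# squared standardization scales for the ridge penalty (0 for the intercept);
# constant columns get scale 0 and are left unpenalized
ridge_s2 <- function(X) {
  if (ncol(X) == 0L) return(numeric(0))
  v <- apply(X, 2, stats::var)
  v[!is.finite(v)] <- 0
  v
}

# Fast path used by the resampling loops: operates on a prebuilt design
# matrix, returns a bare list.  estimator is "ml", "fl" or "rr".
fit_core <- function(y, Xd, estimator, control) {
  p <- ncol(Xd)
  if (estimator == "ml") {
    f <- .irls_fit(Xd, y, rep(0, p), rep(0, p), control$maxit, control$tol)
    list(beta = drop(f$beta), converged = f$converged, loglik = f$loglik,
         max_abs_eta = f$max_abs_eta, lambda = NULL, df_e = NULL)
  } else if (estimator == "fl") {
    f <- .firth_fit(Xd, y, rep(0, p),
                    control$maxit_firth %||% 500L, control$tol)
    list(beta = drop(f$beta), converged = f$converged, loglik = f$loglik,
         lambda = NULL, df_e = NULL)
  } else if (estimator == "rr") {
    s2 <- c(0, ridge_s2(Xd[, -1, drop = FALSE]))
    pth <- .ridge_path(Xd, y, s2, control$grid, control$maxit, control$tol)
    aic <- -2 * pth$loglik + 2 * pth$df_e
    best <- which(aic <= min(aic) + 1e-9)
    j <- best[which.max(control$grid[best])]   # ties broken to more shrinkage
    list(beta = drop(pth$beta[, j]), converged = pth$converged[j] == 1L,
         loglik = pth$loglik[j], lambda = control$grid[j],
         df_e = pth$df_e[j],
         path = data.frame(lambda = control$grid, loglik = pth$loglik,
                           df_e = pth$df_e, aic = aic,
                           converged = pth$converged == 1L))
  } else stop_("unknown estimator '%s'", estimator)
}

new_fit <- function(estimator, core, dataset, separation) {
  beta <- core$beta
  names(beta) <- c("(Intercept)", colnames(dataset$X))
  structure(list(estimator = estimator, coef = beta,
                 converged = core$converged, separation = separation,
                 lambda = core$lambda, df_e = core$df_e,
                 loglik = core$loglik, n = length(dataset$y),
                 event_fraction = mean(dataset$y)),
            class = "ov_fit")
}

#' @export
print.ov_fit <- function(x, ...) {
  cat(sprintf("<ov_fit> %s, n = %d, loglik = %.4f, converged = %s",
              toupper(x$estimator), x$n, x$loglik, x$converged))
  if (!is.null(x$lambda))
    cat(sprintf(", lambda = %.4g, df_e = %.3f", x$lambda, x$df_e))
  if (!is.na(x$separation) && x$separation != "none")
    cat(sprintf(" [%s separation]", x$separation))
  cat("\n")
  print(round(x$coef, 4))
  invisible(x)
}

# decide whether to run the (comparatively costly) LP separation check:
# an interior converged ML fit certifies overlap, so the LP is only needed
# when the fit diverged or probabilities hit the boundary
maybe_separation <- function(dataset, converged, max_abs_eta, check) {
  if (!check) return(NA_character_)
  if (converged && max_abs_eta < 18) return("none")
  detect_separation(dataset)
}

# ---- public estimators ------------------------------------------------------

#' Maximum-likelihood logistic regression
#'
#' Newton/IRLS maximizer of the binomial log-likelihood.  Under quasi- or
#' complete separation the maximum-likelihood estimate does not exist; the
#' fit is then reported at the iteration cap with `converged = FALSE` and
#' the separation status recorded.
#'
#' @param dataset An [ov_dataset()] (both outcome classes must be present).
#' @param maxit,tol Convergence control, see [fit_control()].
#' @param check_separation Run [detect_separation()] when the fit looks
#'   divergent (set to `FALSE` in tight resampling loops).
#' @return An object of class `ov_fit` with elements `estimator`, `coef`
#'   (intercept first), `converged`, `separation`, `loglik`.
#' @export
fit_ml <- function(dataset, maxit = 25L, tol = 1e-8, check_separation = TRUE) {
  check_binary_outcome(dataset$y)
  ctl <- fit_control(maxit, tol)
  core <- fit_core(dataset$y, design_matrix(dataset$X), "ml", ctl)
  sep <- maybe_separation(dataset, core$converged, core$max_abs_eta,
                          check_separation)
  if (!is.na(sep) && sep != "none") core$converged <- FALSE
  new_fit("ml", core, dataset, sep)
}

#' Firth's penalized-likelihood logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l(beta) + 0.5 log det I(beta)` by modified score equations with
#' hat-diagonal adjustments.  Coefficients remain finite even under
#' complete separation.
#'
#' @inheritParams fit_ml
#' @param maxit Iteration cap (the modified-score iteration converges
#'   linearly, so the cap is higher than for ML).
#' @return An `ov_fit` object.
#' @export
fit_firth <- function(dataset, maxit = 500L, tol = 1e-8,
                      check_separation = TRUE) {
  check_binary_outcome(dataset$y)
  ctl <- fit_control(maxit = maxit, tol = tol, maxit_firth = maxit)
  core <- fit_core(dataset$y, design_matrix(dataset$X), "fl", ctl)
  if (!core$converged)
    stop_("fit failure: Firth iterations did not converge in %d steps", maxit)
  sep <- if (check_separation) detect_separation(dataset) else NA_character_
  new_fit("fl", core, dataset, sep)
}

#' Ridge logistic regression at a fixed tuning value
#'
#' Maximizes `l(beta) - lambda * ||beta_slopes||^2` with the intercept
#' unpenalized and the slopes penalized on the standardized scale (each
#' slope multiplied by its covariate's standard deviation before entering
#' the penalty); coefficients are returned on the original scale.
#'
#' @inheritParams fit_ml
#' @param lambda Nonnegative tuning parameter.
#' @return An `ov_fit` object with `lambda` and `df_e` recorded.
#' @export
fit_ridge <- function(dataset, lambda, maxit = 25L, tol = 1e-8,
                      check_separation = TRUE) {
  check_binary_outcome(dataset$y)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop_("invalid tuning: lambda must be a single nonnegative number")
  ctl <- fit_control(maxit, tol, grid = lambda)
  core <- fit_core(dataset$y, design_matrix(dataset$X), "rr", ctl)
  sep <- if (check_separation) detect_separation(dataset) else NA_character_
  fit <- new_fit("rr", core, dataset, sep)
  attr(fit, "path") <- core$path
  fit
}

#' Effective degrees of freedom of a ridge fit
#'
#' Computes `trace(I(beta) (I(beta) + penalty Hessian)^(-1))`, the trace of
#' the unpenalized information times the inverse penalized information at
#' the fitted coefficients.  Equals the number of parameters at
#' `lambda = 0` and decreases towards 1 (the unpenalized intercept) as
#' `lambda` grows.
#'
#' @param dataset The training [ov_dataset()].
#' @param model A ridge `ov_fit`.
#' @return The effective degrees of freedom (a single real number).
#' @export
effective_df <- function(dataset, model) {
  if (!inherits(model, "ov_fit") || model$estimator != "rr")
    stop_("effective_df is defined for ridge fits only")
  Xd <- design_matrix(dataset$X)
  p <- plogis(drop(Xd %*% model$coef))
  w <- p * (1 - p)
  I <- crossprod(Xd, Xd * w)
  pen <- c(0, 2 * model$lambda * ridge_s2(dataset$X))
  Ipen <- I + diag(pen, nrow(I))
  tr <- tryCatch(sum(diag(solve(Ipen, I))), error = function(e) NULL)
  if (is.null(tr)) stop_("numerical failure: penalized information is singular")
  tr
}

#' Ridge regression with penalized-AIC tuning
#'
#' Fits a ridge model at every value of the tuning grid (warm-started from
#' the strongest penalty down) and selects the value minimizing the
#' penalized Akaike criterion `-2 l(beta) + 2 df_e`, with `df_e` the
#' effective degrees of freedom.  Ties are broken towards the larger
#' tuning value (more shrinkage).
#'
#' @inheritParams fit_ml
#' @param grid Increasing vector of nonnegative tuning values, see
#'   [ridge_grid()].
#' @return An `ov_fit` with `lambda`, `df_e` and, as attribute `"path"`,
#'   the per-grid-point log-likelihoods, effective degrees of freedom and
#'   criterion values.
#' @export
tune_ridge <- function(dataset, grid = ridge_grid(), maxit = 25L, tol = 1e-8,
                       check_separation = TRUE) {
  check_binary_outcome(dataset$y)
  if (any(grid < 0) || is.unsorted(grid, strictly = TRUE) || length(grid) < 1L)
    stop_("grid must be a strictly increasing vector of nonnegative values")
  ctl <- fit_control(maxit, tol, grid = grid)
  core <- fit_core(dataset$y, design_matrix(dataset$X), "rr", ctl)
  if (all(!core$path$converged))
    stop_("tuning failure: no grid point produced a converged fit")
  sep <- if (check_separation) detect_separation(dataset) else NA_character_
  fit <- new_fit("rr", core, dataset, sep)
  attr(fit, "path") <- core$path
  fit
}

#' Predicted event probabilities
#'
#' @param object An `ov_fit`.
#' @param newdata An [ov_dataset()] or a covariate matrix with the training
#'   column layout.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ov_fit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "ov_dataset")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$coef) - 1L)
    stop_("schema error: newdata has %d columns, the model expects %d",
          ncol(X), length(object$coef) - 1L)
  eta <- object$coef[1L] + drop(X %*% object$coef[-1L])
  if (type == "link") eta else plogis(eta)
}
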