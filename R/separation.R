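# Separation diagnostics for binary-outcome regression data.
#
# Complete separation: some linear combination of the covariates (plus
# intercept) is strictly positive for every event and strictly negative for
# every non-event; the maximum-likelihood estimate then diverges.  Quasi
# separation: a combination achieves this with ties (zero margin) on the
# boundary.  Both are decided exactly by two small linear programs in the
# Albert-Anderson taxonomy; no LP solver among the package's dependencies
# covers this, so a dense primal simplex (Bland's rule, single phase: the
# origin is always feasible) is implemented here.

# max c'x  s.t.  A x <= b (all b >= 0),  x >= 0
simplex_max <- function(cvec, A, b, tol = 1e-9, maxit = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  Tm <- cbind(A, diag(m))
  cost <- c(cvec, rep(0, m))
  basis <- n + seq_len(m)
  bb <- b
  for (it in seq_len(maxit)) {
    red <- cost - drop(cost[basis] %*% Tm)
    enter <- which(red > tol)
    if (!length(enter))
      return(list(status = "optimal", value = sum(cost[basis] * bb)))
    j <- min(enter)                       # Bland's rule on entering
    col <- Tm[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", value = Inf))
    ratio <- bb[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])]     # Bland's rule on leaving
    piv <- Tm[i, j]
    Tm[i, ] <- Tm[i, ] / piv
    bb[i] <- bb[i] / piv
    adj <- setdiff(which(abs(Tm[, j]) > 0), i)
    for (r in adj) {
      f <- Tm[r, j]
      Tm[r, ] <- Tm[r, ] - f * Tm[i, ]
      bb[r] <- bb[r] - f * bb[i]
    }
    bb[bb < 0] <- 0                        # guard tiny negative round-off
    basis[i] <- j
  }
  list(status = "maxit", value = NA_real_)
}

#' Classify a dataset as unseparated, quasi-separated, or completely separated
#'
#' Decides, by linear programming over the coefficient box `[-1, 1]`,
#' whether some linear combination of the covariates separates events from
#' non-events: strictly (`"complete"`), with ties on the separating
#' hyperplane (`"quasi"`), or not at all (`"none"`).
#'
#' @param dataset An [ov_dataset()], or a 0/1 vector `y` (then `X` must be
#'   given).
#' @param X Covariate matrix when `dataset` is an outcome vector.
#' @param tol Strict-positivity tolerance of the LP margins.
#' @return One of `"none"`, `"quasi"`, `"complete"`.
#' @examples
#' detect_separation(c(0, 0, 1, 1), X = cbind(1:4))   # "complete"
#' detect_separation(c(0, 1, 0, 1), X = cbind(1:4))   # "none"
#' @export
detect_separation <- function(dataset, X = NULL, tol = 1e-7) {
  if (inherits(dataset, "ov_dataset")) {
    y <- dataset$y
    X <- dataset$X
  } else {
    y <- as.numeric(dataset)
    if (is.null(X)) stop_("X must be supplied when dataset is a vector")
    X <- as.matrix(X)
  }
  check_binary_outcome(y)
  # rescale columns so LP tolerances are unit-scale
  Xs <- scale(X, center = FALSE, scale = apply(abs(X), 2, max) + 1e-300)
  D <- (2 * y - 1) * cbind(1, Xs)
  n <- nrow(D)
  p1 <- ncol(D)
  zero <- matrix(0, p1, p1)
  # variables: beta = bp - bm with bp, bm in [0, 1], plus the margin t.
  # complete separation <=> max t s.t. D beta >= t has optimum > 0.
  A1 <- rbind(cbind(-D, D, 1), cbind(diag(p1), zero, 0),
              cbind(zero, diag(p1), 0))
  b1 <- c(rep(0, n), rep(1, 2 * p1))
  r1 <- simplex_max(c(rep(0, 2 * p1), 1), A1, b1)
  if (r1$status == "optimal" && r1$value > tol) return("complete")
  # any separation <=> max sum(D beta) s.t. D beta >= 0 has optimum > 0.
  A2 <- rbind(cbind(-D, D), cbind(diag(p1), zero), cbind(zero, diag(p1)))
  b2 <- c(rep(0, n), rep(1, 2 * p1))
  r2 <- simplex_max(c(colSums(D), -colSums(D)), A2, b2)
  if (r2$status == "optimal" && r2$value > tol) return("quasi")
  "none"
}
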