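# Independent oracles used across the suite.  Each is a deliberately
# simple brute-force or external implementation, kept separate from the
# code paths it checks.

# c-statistic by explicit enumeration of all contrary-outcome pairs
cstat_brute <- function(p, y, tie = 0.5) {
  ev <- p[y == 1]
  ne <- p[y == 0]
  tot <- 0
  for (a in ev) for (b in ne)
    tot <- tot + (a > b) + tie * (a == b)
  tot / (length(ev) * length(ne))
}

# discrimination slope as the average pairwise difference
dslope_pairs <- function(p, y) {
  ev <- p[y == 1]
  ne <- p[y == 0]
  mean(outer(ev, ne, "-"))
}

# Firth's penalized log-likelihood, maximized by general-purpose
# optimization (independent of the package's modified-score iterations)
firth_optim <- function(y, X) {
  Xd <- cbind(1, X)
  negpl <- function(b) {
    eta <- drop(Xd %*% b)
    p <- plogis(eta)
    I <- crossprod(Xd, Xd * (p * (1 - p)))
    -(sum(y * eta - log1p(exp(eta))) +
        0.5 * determinant(I, logarithm = TRUE)$modulus)
  }
  optim(rep(0, ncol(Xd)), negpl, method = "BFGS",
        control = list(reltol = 1e-14, maxit = 500))$par
}

# separation classification via scipy's LP solver (HiGHS), batched:
# takes a list of list(y=, X=) cases, returns a character vector
sep_oracle_py <- function(cases) {
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog

def classify(y, X, tol=1e-7):
    y = np.asarray(y, float); X = np.asarray(X, float)
    s = 2*y - 1
    D = s[:, None] * np.column_stack([np.ones(len(y)), X])
    n, p1 = D.shape
    A = np.column_stack([-D, np.ones(n)])
    c = np.zeros(p1+1); c[-1] = -1
    bounds = [(-1, 1)]*p1 + [(0, None)]
    r = linprog(c, A_ub=A, b_ub=np.zeros(n), bounds=bounds, method="highs")
    if r.status == 0 and -r.fun > tol:
        return "complete"
    r2 = linprog(-D.sum(axis=0), A_ub=-D, b_ub=np.zeros(n),
                 bounds=[(-1, 1)]*p1, method="highs")
    if r2.status == 0 and -r2.fun > tol:
        return "quasi"
    return "none"

cases = json.load(sys.stdin)
out = [classify(c["y"], np.array(c["X"]).reshape(len(c["y"]), -1))
       for c in cases]
print(json.dumps(out))
'
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  payload <- jsonlite::toJSON(
    lapply(cases, function(cs) list(y = cs$y, X = as.vector(t(cs$X)))),
    auto_unbox = FALSE)
  res <- system2("python", f, input = as.character(payload), stdout = TRUE)
  unlist(jsonlite::fromJSON(paste(res, collapse = "")))
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# quick deterministic toy datasets
toy_scenario <- function(n = 50, ef = 0.25, effect = "null", calib_n = 2e5,
                         seed = 10) {
  make_scenario(n, ef, effect, calib_n = calib_n, seed = seed)
}
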