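# Performance measures for predicted probabilities of a binary outcome.
# All three are pure functions of (p, y).

#' Concordance statistic (c-statistic, area under the ROC curve)
#'
#' The proportion of event/non-event pairs in which the event carries the
#' higher predicted probability.  Tied probabilities count 1/2 by default
#' (the midrank convention, under which the value equals the area under the
#' ROC curve); `ties = "strict"` counts ties as discordant, for sensitivity
#' checks.
#'
#' @param p Vector of predicted probabilities.
#' @param y 0/1 outcome vector (both classes must be present).
#' @param ties `"half"` (default) or `"strict"`.
#' @return The c-statistic in `[0, 1]`.
#' @export
c_statistic <- function(p, y, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  stopifnot(length(p) == length(y))
  check_binary_outcome(y)
  k <- as.numeric(sum(y))
  n <- as.numeric(length(y))
  r <- rank(p)                       # midranks
  cval <- (sum(r[y == 1]) - k * (k + 1) / 2) / (k * (n - k))
  if (ties == "strict") {
    tt <- table(p[y == 1])
    t0 <- table(p[y == 0])
    common <- intersect(names(tt), names(t0))
    n_tied <- sum(as.numeric(tt[common]) * as.numeric(t0[common]))
    cval <- cval - 0.5 * n_tied / (k * (n - k))
  }
  cval
}

#' Discrimination slope
#'
#' Mean predicted probability among events minus the mean among non-events;
#' equivalently the average pairwise difference in predicted probabilities
#' over all event/non-event pairs (a parametric analogue of the
#' c-statistic, and Tjur's R-squared for logistic regression).
#'
#' @inheritParams c_statistic
#' @return The discrimination slope in `[-1, 1]`.
#' @export
discrimination_slope <- function(p, y) {
  stopifnot(length(p) == length(y))
  check_binary_outcome(y)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Brier score
#'
#' Mean squared difference between the 0/1 outcome and the predicted
#' probability.  Defined per observation and averaged; 0 for a perfect
#' model, and `ef * (1 - ef)` for the non-informative model predicting the
#' event fraction `ef` everywhere.
#'
#' @inheritParams c_statistic
#' @return The Brier score in `[0, 1]`.
#' @export
brier_score <- function(p, y) {
  if (length(p) != length(y))
    stop_("schema error: p and y have different lengths")
  mean((y - p)^2)
}

#' Winsorize a c-statistic at a floor
#'
#' Replaces c-statistic values below `floor` (default 0.5, the value of an
#' uninformative model) by `floor`.  Cross-validated c-statistics can fall
#' below 0.5 through resampling artefacts; winsorizing trades this
#' information away for reduced mean squared error.
#'
#' @param c A c-statistic in `[0, 1]` (vectorized).
#' @param floor The winsorization floor.
#' @return `pmax(c, floor)`.
#' @export
winsorize_c <- function(c, floor = 0.5) {
  stopifnot(all(c >= 0 & c <= 1))
  pmax(c, floor)
}

# internal dispatcher used by the resampling techniques
measure_value <- function(measure, p, y, ...) {
  switch(measure,
         cstat = c_statistic(p, y, ...),
         dslope = discrimination_slope(p, y),
         brier = brier_score(p, y),
         stop_("unknown measure '%s'", measure))
}

# is the measure defined on this outcome vector?
measure_defined <- function(measure, y) {
  if (measure == "brier") length(y) > 0 else length(unique(y)) == 2L
}
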