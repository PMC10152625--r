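# Optimism-corrected estimation of performance measures.
#
# Every technique refits the full model-development process (including the
# ridge tuning search) on each resample, and reports one row per requested
# measure with bookkeeping of how many resample fits were performed and how
# many resamples had to be skipped.  Resamples whose training data contain a
# single outcome class or linearly dependent covariate columns are redrawn
# (bootstrap resamples and fold partitions; up to 50 attempts) and then
# skipped; separated resamples are NOT redrawn -- each estimator's own
# behaviour under separation is part of what is being studied.

#' Technique and measure names
#'
#' @return Character vectors of the supported optimism-correction
#'   techniques and performance measures.
#' @export
ov_techniques <- function() c("apparent", "loo", "lpo", "kfold",
                              "enhanced_boot", "boot632plus")

#' @rdname ov_techniques
#' @export
ov_measures <- function() c("cstat", "dslope", "brier")

res_rows <- function(technique, measures, estimates, n_fits, n_failed,
                     notes = character()) {
  out <- data.frame(technique = technique, measure = measures,
                    estimate = as.numeric(estimates),
                    n_fits = n_fits, n_failed = n_failed,
                    stringsAsFactors = FALSE)
  attr(out, "notes") <- notes
  out
}

check_estimator <- function(estimator) {
  if (!estimator %in% c("ml", "fl", "rr"))
    stop_("estimator must be one of 'ml', 'fl', 'rr'")
  estimator
}

# is (y, X) usable as a training set: both classes and full column rank
train_ok <- function(y, Xd) {
  if (length(unique(y)) < 2L) return(FALSE)
  qr(Xd)$rank == ncol(Xd)
}

# random partition into f folds of sizes differing by at most one
fold_assign <- function(n, f) sample(rep_len(seq_len(f), n))

fit_try <- function(y, Xd, estimator, control) {
  tryCatch(fit_core(y, Xd, estimator, control), error = function(e) NULL)
}

pred_core <- function(core, Xd) plogis(drop(Xd %*% core$beta))

#' Apparent (uncorrected) performance
#'
#' The measure of the model's fitted probabilities on its own training
#' data.
#'
#' @param dataset An [ov_dataset()].
#' @param estimator `"ml"`, `"fl"` or `"rr"` (ridge retuned by penalized
#'   AIC).
#' @param measures Subset of `c("cstat", "dslope", "brier")`.
#' @param control A [fit_control()] object.
#' @return A data.frame with columns `technique`, `measure`, `estimate`,
#'   `n_fits`, `n_failed`; resample logs in attribute `"notes"`.
#' @export
apparent <- function(dataset, estimator, measures = ov_measures(),
                     control = fit_control()) {
  check_estimator(estimator)
  check_binary_outcome(dataset$y)
  Xd <- design_matrix(dataset$X)
  core <- fit_core(dataset$y, Xd, estimator, control)
  p <- pred_core(core, Xd)
  res_rows("apparent", measures,
           vapply(measures, measure_value, 0, p = p, y = dataset$y),
           n_fits = 1L, n_failed = 0L)
}

#' Pooled leave-one-out cross-validation
#'
#' Each observation is left out in turn, the model is refitted on the
#' remaining `n - 1` observations, and the left-out observation's
#' probability is predicted.  The c-statistic and discrimination slope are
#' computed once from the pooled vector of `n` held-out predictions (they
#' are pairwise measures and cannot be averaged over single observations);
#' the Brier score is computed per left-out observation and averaged, which
#' is identical to pooling.
#'
#' @inheritParams apparent
#' @return A data.frame as in [apparent()].
#' @export
loo_cv <- function(dataset, estimator, measures = ov_measures(),
                   control = fit_control()) {
  check_estimator(estimator)
  check_binary_outcome(dataset$y)
  n <- length(dataset$y)
  if (n < 3L) stop_("leave-one-out requires at least 3 observations")
  Xd <- design_matrix(dataset$X)
  preds <- rep(NA_real_, n)
  n_fits <- 0L
  notes <- character()
  for (i in seq_len(n)) {
    yi <- dataset$y[-i]
    Xi <- Xd[-i, , drop = FALSE]
    if (!train_ok(yi, Xi)) {
      notes <- c(notes, sprintf("loo: subset without observation %d unusable", i))
      next
    }
    core <- fit_try(yi, Xi, estimator, control)
    if (is.null(core)) {
      notes <- c(notes, sprintf("loo: fit failed without observation %d", i))
      next
    }
    n_fits <- n_fits + 1L
    preds[i] <- pred_core(core, Xd[i, , drop = FALSE])
  }
  ok <- !is.na(preds)
  n_failed <- n - n_fits
  est <- vapply(measures, function(m) {
    if (!measure_defined(m, dataset$y[ok])) return(NA_real_)
    measure_value(m, preds[ok], dataset$y[ok])
  }, 0)
  res_rows("loo", measures, est, n_fits, n_failed, notes)
}

#' Leave-pair-out cross-validation
#'
#' Every pair of one event and one non-event is excluded in turn, the
#' model is refitted on the remaining `n - 2` observations, and the two
#' held-out probabilities are predicted.  The LPO c-statistic is the
#' proportion of pairs in which the event's probability exceeds the
#' non-event's (ties counting 1/2); the LPO discrimination slope is the
#' average of the within-pair differences.  The Brier score is not
#' supported: averaging it over pairs would weight events and non-events
#' equally regardless of the event fraction, biasing the estimate.
#'
#' @inheritParams apparent
#' @param measures Subset of `c("cstat", "dslope")`.
#' @return A data.frame as in [apparent()]; `n_fits` is `k * (n - k)` when
#'   no pair is skipped.
#' @export
lpo_cv <- function(dataset, estimator, measures = c("cstat", "dslope"),
                   control = fit_control()) {
  check_estimator(estimator)
  check_binary_outcome(dataset$y)
  if ("brier" %in% measures)
    stop_("unsupported measure: the Brier score is not defined for leave-pair-out")
  n <- length(dataset$y)
  if (n < 4L) stop_("leave-pair-out requires at least 4 observations")
  Xd <- design_matrix(dataset$X)
  ev <- which(dataset$y == 1)
  ne <- which(dataset$y == 0)
  n_pairs <- length(ev) * length(ne)
  pe <- pn <- rep(NA_real_, n_pairs)
  n_fits <- 0L
  notes <- character()
  idx <- 0L
  for (i in ev) for (j in ne) {
    idx <- idx + 1L
    keep <- setdiff(seq_len(n), c(i, j))
    if (!train_ok(dataset$y[keep], Xd[keep, , drop = FALSE])) {
      notes <- c(notes, sprintf("lpo: pair (%d,%d) leaves unusable training data", i, j))
      next
    }
    core <- fit_try(dataset$y[keep], Xd[keep, , drop = FALSE], estimator, control)
    if (is.null(core)) {
      notes <- c(notes, sprintf("lpo: fit failed for pair (%d,%d)", i, j))
      next
    }
    n_fits <- n_fits + 1L
    pr <- pred_core(core, Xd[c(i, j), , drop = FALSE])
    pe[idx] <- pr[1]
    pn[idx] <- pr[2]
  }
  ok <- !is.na(pe)
  est <- vapply(measures, function(m) {
    if (!any(ok)) return(NA_real_)
    switch(m,
           cstat = mean((pe[ok] > pn[ok]) + 0.5 * (pe[ok] == pn[ok])),
           dslope = mean(pe[ok] - pn[ok]))
  }, 0)
  res_rows("lpo", measures, est, n_fits, n_pairs - n_fits, notes)
}

#' Repeated f-fold cross-validation
#'
#' The data are partitioned at random into `f` folds of sizes differing by
#' at most one (unstratified).  Each fold is held out in turn, the model is
#' refitted on the rest, and the measure is computed on the held-out fold;
#' the `f` fold values are averaged.  The whole procedure is repeated `r`
#' times with fresh partitions and the repetition averages are averaged
#' again.  Folds on which a pairwise measure is undefined (single-class
#' fold) are dropped from that repetition's average; partitions with an
#' unusable training set are redrawn up to 50 times, then the repetition is
#' skipped.
#'
#' @inheritParams apparent
#' @param f Number of folds.
#' @param r Number of repetitions.
#' @param seed Optional integer seed making the partitions reproducible.
#' @return A data.frame as in [apparent()]; `n_fits` is `f * r` when no
#'   repetition is skipped.
#' @export
kfold_cv <- function(dataset, estimator, measures = ov_measures(),
                     f = 5L, r = 40L, seed = NULL, control = fit_control()) {
  check_estimator(estimator)
  check_binary_outcome(dataset$y)
  n <- length(dataset$y)
  if (n < f) stop_("need at least f observations")
  Xd <- design_matrix(dataset$X)
  notes <- character()
  n_fits <- 0L
  n_failed <- 0L
  rep_vals <- matrix(NA_real_, r, length(measures))
  with_seed(seed, {
    for (rep_i in seq_len(r)) {
      folds <- NULL
      for (att in seq_len(50L)) {
        cand <- fold_assign(n, f)
        ok_all <- all(vapply(seq_len(f), function(fd) {
          tr <- which(cand != fd)
          train_ok(dataset$y[tr], Xd[tr, , drop = FALSE])
        }, TRUE))
        if (ok_all) { folds <- cand; break }
      }
      if (is.null(folds)) {
        n_failed <- n_failed + 1L
        notes <- c(notes, sprintf("kfold: repetition %d skipped (no usable partition in 50 draws)", rep_i))
        next
      }
      fold_vals <- matrix(NA_real_, f, length(measures))
      for (fd in seq_len(f)) {
        tr <- which(folds != fd)
        te <- which(folds == fd)
        core <- fit_try(dataset$y[tr], Xd[tr, , drop = FALSE], estimator, control)
        if (is.null(core)) {
          notes <- c(notes, sprintf("kfold: fit failed in repetition %d fold %d", rep_i, fd))
          next
        }
        n_fits <- n_fits + 1L
        pte <- pred_core(core, Xd[te, , drop = FALSE])
        for (mi in seq_along(measures)) {
          if (measure_defined(measures[mi], dataset$y[te]))
            fold_vals[fd, mi] <- measure_value(measures[mi], pte, dataset$y[te])
          else
            notes <- c(notes, sprintf("kfold: %s undefined in repetition %d fold %d (single-class fold)",
                                      measures[mi], rep_i, fd))
        }
      }
      rep_vals[rep_i, ] <- colMeans(fold_vals, na.rm = TRUE)
    }
  })
  est <- colMeans(rep_vals, na.rm = TRUE)
  if (all(is.nan(est)))
    stop_("estimation failure: measure undefined in every fold of every repetition")
  est[is.nan(est)] <- NA_real_
  res_rows("kfold", measures, est, n_fits, n_failed, notes)
}

draw_boot_idx <- function(y, Xd, attempts = 50L) {
  n <- length(y)
  for (att in seq_len(attempts)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (train_ok(y[idx], Xd[idx, , drop = FALSE])) return(idx)
  }
  NULL
}

#' Enhanced bootstrap optimism correction
#'
#' `B` bootstrap resamples of size `n` are drawn with replacement.  On each
#' resample the model is refitted and the measure is computed both on the
#' resample itself and on the original data; the average of those
#' differences estimates the optimism, which is subtracted from the
#' apparent measure.
#'
#' @inheritParams kfold_cv
#' @param B Number of bootstrap resamples.
#' @return A data.frame as in [apparent()]; `n_fits` is `B` when no
#'   resample is skipped (the apparent fit is not counted).
#' @export
enhanced_bootstrap <- function(dataset, estimator, measures = ov_measures(),
                               B = 200L, seed = NULL,
                               control = fit_control()) {
  check_estimator(estimator)
  check_binary_outcome(dataset$y)
  n <- length(dataset$y)
  if (n < 3L) stop_("need at least 3 observations")
  Xd <- design_matrix(dataset$X)
  app_core <- fit_core(dataset$y, Xd, estimator, control)
  p_app <- pred_core(app_core, Xd)
  app <- vapply(measures, measure_value, 0, p = p_app, y = dataset$y)
  opt <- matrix(NA_real_, B, length(measures))
  n_fits <- 0L
  n_failed <- 0L
  notes <- character()
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- draw_boot_idx(dataset$y, Xd)
      if (is.null(idx)) {
        n_failed <- n_failed + 1L
        notes <- c(notes, sprintf("enhanced_boot: resample %d skipped", b))
        next
      }
      core <- fit_try(dataset$y[idx], Xd[idx, , drop = FALSE], estimator, control)
      if (is.null(core)) {
        n_failed <- n_failed + 1L
        notes <- c(notes, sprintf("enhanced_boot: fit failed in resample %d", b))
        next
      }
      n_fits <- n_fits + 1L
      p_boot <- pred_core(core, Xd[idx, , drop = FALSE])
      p_orig <- pred_core(core, Xd)
      opt[b, ] <- vapply(seq_along(measures), function(mi) {
        measure_value(measures[mi], p_boot, dataset$y[idx]) -
          measure_value(measures[mi], p_orig, dataset$y)
      }, 0)
    }
  })
  est <- app - colMeans(opt, na.rm = TRUE)
  res_rows("enhanced_boot", measures, est, n_fits, n_failed, notes)
}

# ---- .632+ machinery --------------------------------------------------------

# orient a measure to the "error" scale (smaller is better)
to_err <- function(measure, val) switch(measure, cstat = 1 - val,
                                        dslope = -val, brier = val)
from_err <- function(measure, err) switch(measure, cstat = 1 - err,
                                          dslope = -err, brier = err)

# no-information error rate: the expected error when predictions and
# outcomes are paired at random (permutation form)
noinfo_err <- function(measure, p_app, y) {
  switch(measure,
         cstat = 0.5,
         dslope = 0,
         brier = mean(y) - 2 * mean(y) * mean(p_app) + mean(p_app^2))
}

# the .632+ combination of an apparent and an out-of-bag value, on the
# error scale, with relative overfitting rate R and weight .632/(1-.368R)
combine_632plus <- function(measure, app, oob, p_app, y) {
  err_app <- to_err(measure, app)
  err_oob <- to_err(measure, oob)
  gamma <- noinfo_err(measure, p_app, y)
  err_oob_tr <- min(err_oob, gamma)
  R <- if (err_oob_tr > err_app && gamma > err_app)
    (err_oob_tr - err_app) / (gamma - err_app) else 0
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  from_err(measure, (1 - w) * err_app + w * err_oob_tr)
}

#' .632+ bootstrap
#'
#' Combines the apparent measure with the average "out-of-bag" measure
#' (the model fitted on a bootstrap resample, evaluated on the
#' observations absent from that resample) as a weighted average.  The
#' weight on the out-of-bag value is `0.632 / (1 - 0.368 R)` with `R` the
#' relative overfitting rate: the excess of the out-of-bag error over the
#' apparent error, relative to the excess of the no-information error (0.5
#' for the c-statistic; the permutation expectation for the discrimination
#' slope and Brier score).  The out-of-bag error is truncated at the
#' no-information error, which guarantees that the .632+ c-statistic never
#' falls below the minimum of the apparent c-statistic and 0.5.
#'
#' @inheritParams enhanced_bootstrap
#' @return A data.frame as in [apparent()].
#' @export
boot632plus <- function(dataset, estimator, measures = ov_measures(),
                        B = 200L, seed = NULL, control = fit_control()) {
  check_estimator(estimator)
  check_binary_outcome(dataset$y)
  n <- length(dataset$y)
  if (n < 3L) stop_("need at least 3 observations")
  Xd <- design_matrix(dataset$X)
  app_core <- fit_core(dataset$y, Xd, estimator, control)
  p_app <- pred_core(app_core, Xd)
  app <- vapply(measures, measure_value, 0, p = p_app, y = dataset$y)
  oob_vals <- matrix(NA_real_, B, length(measures))
  n_fits <- 0L
  n_failed <- 0L
  notes <- character()
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- draw_boot_idx(dataset$y, Xd)
      if (is.null(idx)) {
        n_failed <- n_failed + 1L
        notes <- c(notes, sprintf("boot632plus: resample %d skipped", b))
        next
      }
      oob <- setdiff(seq_len(n), idx)
      if (!length(oob)) {
        n_failed <- n_failed + 1L
        notes <- c(notes, sprintf("boot632plus: resample %d has empty out-of-bag set", b))
        next
      }
      core <- fit_try(dataset$y[idx], Xd[idx, , drop = FALSE], estimator, control)
      if (is.null(core)) {
        n_failed <- n_failed + 1L
        notes <- c(notes, sprintf("boot632plus: fit failed in resample %d", b))
        next
      }
      n_fits <- n_fits + 1L
      p_oob <- pred_core(core, Xd[oob, , drop = FALSE])
      for (mi in seq_along(measures)) {
        if (measure_defined(measures[mi], dataset$y[oob]))
          oob_vals[b, mi] <- measure_value(measures[mi], p_oob, dataset$y[oob])
        else
          notes <- c(notes, sprintf("boot632plus: %s undefined out-of-bag in resample %d",
                                    measures[mi], b))
      }
    }
  })
  est <- vapply(seq_along(measures), function(mi) {
    oob_m <- mean(oob_vals[, mi], na.rm = TRUE)
    if (is.nan(oob_m)) return(NA_real_)
    combine_632plus(measures[mi], app[mi], oob_m, p_app, dataset$y)
  }, 0)
  res_rows("boot632plus", measures, est, n_fits, n_failed, notes)
}

#' All optimism-correction techniques for one dataset and estimator
#'
#' Convenience wrapper running [apparent()] and any subset of the five
#' correction techniques, with derived random substreams per technique so
#' the whole table is reproducible from one seed.  The Brier score is
#' automatically excluded from leave-pair-out.
#'
#' @inheritParams kfold_cv
#' @param techniques Subset of
#'   `c("apparent", "loo", "lpo", "kfold", "enhanced_boot", "boot632plus")`.
#' @param B Number of bootstrap resamples.
#' @return A data.frame with one row per technique x measure; notes
#'   concatenated in attribute `"notes"`.
#' @export
internal_validation <- function(dataset, estimator,
                                techniques = ov_techniques(),
                                measures = ov_measures(),
                                f = 5L, r = 40L, B = 200L, seed = NULL,
                                control = fit_control()) {
  stopifnot(all(techniques %in% ov_techniques()))
  parts <- list()
  for (tech in techniques) {
    parts[[tech]] <- switch(tech,
      apparent = apparent(dataset, estimator, measures, control),
      loo = loo_cv(dataset, estimator, measures, control),
      lpo = lpo_cv(dataset, estimator, intersect(measures, c("cstat", "dslope")),
                   control),
      kfold = kfold_cv(dataset, estimator, measures, f, r,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, 11L),
                       control = control),
      enhanced_boot = enhanced_bootstrap(dataset, estimator, measures, B,
                                         seed = if (is.null(seed)) NULL else derive_seed(seed, 12L),
                                         control = control),
      boot632plus = boot632plus(dataset, estimator, measures, B,
                                seed = if (is.null(seed)) NULL else derive_seed(seed, 13L),
                                control = control))
  }
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  attr(out, "notes") <- unlist(lapply(parts, attr, "notes"), use.names = FALSE)
  out
}
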