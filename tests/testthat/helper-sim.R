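# Shared Monte-Carlo runs, computed once per session and reused by several
# test files.  Sizes are chosen to keep the whole suite at desk scale while
# leaving Monte-Carlo errors small enough for the properties under test.

.sim_cache <- new.env(parent = emptyenv())

# 200 replicates of the small-sample null scenario (n = 50, event fraction
# 0.25): per replicate the pooled-LOO and apparent estimates for all three
# estimators, leave-pair-out and enhanced-bootstrap estimates for ML, and
# the independent-validation values of every fitted model.
headline_sim <- function() {
  if (!is.null(.sim_cache$headline)) return(.sim_cache$headline)
  n_rep <- 200L
  sc <- make_scenario(50, 0.25, "null")
  valset <- gen_validation_set(sc, 1e5, seed = 777001L)
  ests <- c("ml", "fl", "rr")
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    ds <- gen_dataset(sc, seed = 100000L + i)
    part <- list()
    for (est in ests) {
      fit <- switch(est,
                    ml = fit_ml(ds, check_separation = FALSE),
                    fl = fit_firth(ds, check_separation = FALSE),
                    rr = tune_ridge(ds, check_separation = FALSE))
      iv <- independent_validation(fit, valset)
      app <- apparent(ds, est)
      loo <- loo_cv(ds, est)
      part[[est]] <- data.frame(
        rep = i, estimator = est,
        technique = c(app$technique, loo$technique),
        measure = c(app$measure, loo$measure),
        estimate = c(app$estimate, loo$estimate),
        iv = unlist(iv)[c(app$measure, loo$measure)],
        stringsAsFactors = FALSE)
    }
    lpo <- lpo_cv(ds, "ml")
    enh <- enhanced_bootstrap(ds, "ml", measures = "cstat", B = 200L,
                              seed = 200000L + i)
    iv_ml <- part$ml$iv[match(c(lpo$measure, "cstat"),
                              part$ml$measure)]
    part$extra <- data.frame(
      rep = i, estimator = "ml",
      technique = c(lpo$technique, enh$technique),
      measure = c(lpo$measure, enh$measure),
      estimate = c(lpo$estimate, enh$estimate),
      iv = iv_ml, stringsAsFactors = FALSE)
    rows[[i]] <- do.call(rbind, c(part, list(make.row.names = FALSE)))
  }
  .sim_cache$headline <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  .sim_cache$headline
}

# helper to pull a replicate-level column out of the headline run
hs_vals <- function(hs, estimator, technique, measure, col = "estimate") {
  sel <- hs$estimator == estimator & hs$technique == technique &
    hs$measure == measure
  hs[[col]][sel][order(hs$rep[sel])]
}

# 200 ML-only replicates at n = 50 and n = 100 (null, event fraction 0.25)
# for the sample-size behaviour of the RMSD.
rmsd_n_sim <- function() {
  if (!is.null(.sim_cache$rmsd_n)) return(.sim_cache$rmsd_n)
  out <- list()
  for (n in c(50L, 100L)) {
    sc <- make_scenario(n, 0.25, "null")
    valset <- gen_validation_set(sc, 5e4, seed = 888000L + n)
    recs <- vector("list", 200L)
    for (i in seq_len(200L)) {
      ds <- gen_dataset(sc, seed = 300000L + 1000L * (n == 100L) + i)
      fit <- fit_ml(ds, check_separation = FALSE)
      iv_c <- c_statistic(predict(fit, valset), valset$y)
      loo <- loo_cv(ds, "ml", measures = "cstat")
      kf <- kfold_cv(ds, "ml", measures = "cstat", f = 5L, r = 40L,
                     seed = 400000L + i)
      enh <- enhanced_bootstrap(ds, "ml", measures = "cstat", B = 200L,
                                seed = 500000L + i)
      recs[[i]] <- data.frame(n = n, rep = i,
                              technique = c("loo", "kfold", "enhanced_boot"),
                              estimate = c(loo$estimate, kf$estimate,
                                           enh$estimate),
                              iv = iv_c, stringsAsFactors = FALSE)
    }
    out[[as.character(n)]] <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  }
  .sim_cache$rmsd_n <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  .sim_cache$rmsd_n
}
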