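test_that("apparent performance is the model on its own training data", {
  sep <- ov_dataset(c(0, 0, 1, 1, 0, 1), cbind(x = c(1, 2, 3, 4, 1.5, 3.5)))
  expect_equal(apparent(sep, "ml", "cstat")$estimate, 1)  # perfect fit
  ds0 <- ov_dataset(c(rep(1, 5), rep(0, 15)), matrix(numeric(0), 20, 0))
  expect_equal(apparent(ds0, "ml", "dslope")$estimate, 0)
})

test_that("fit-count bookkeeping is exact for every technique", {
  ds <- gen_dataset(toy_scenario(30, 0.5, "null"), seed = 200)
  k <- sum(ds$y)
  expect_equal(loo_cv(ds, "ml")$n_fits[1], 30L)
  lpo <- lpo_cv(ds, "ml")
  expect_equal(lpo$n_fits[1], as.integer(k * (30 - k)))
  expect_equal(kfold_cv(ds, "ml", f = 5, r = 7, seed = 1)$n_fits[1], 35L)
  expect_equal(enhanced_bootstrap(ds, "ml", B = 25, seed = 1)$n_fits[1], 25L)
  expect_equal(boot632plus(ds, "ml", B = 25, seed = 1)$n_fits[1], 25L)
})

test_that("pooled leave-one-out predictions equal independent hold-one-out refits", {
  # interleaved classes: no leave-one-out subset is separated, so the ML
  # refits are well defined and comparable with glm
  ds <- ov_dataset(c(1, 1, 0, 1, 0, 0),
                   cbind(x = c(-0.84, 1.38, -1.26, 0.07, 1.71, -0.6)))
  res <- loo_cv(ds, "ml")
  # brute-force oracle: six glm refits
  preds <- sapply(1:6, function(i) {
    g <- suppressWarnings(glm(y ~ x, family = binomial,
             data = data.frame(y = ds$y[-i], x = ds$X[-i, 1])))
    plogis(coef(g)[1] + coef(g)[2] * ds$X[i, 1])
  })
  expect_equal(res$estimate[res$measure == "cstat"],
               cstat_brute(preds, ds$y))
  expect_equal(res$estimate[res$measure == "dslope"],
               dslope_pairs(preds, ds$y))
  expect_equal(res$estimate[res$measure == "brier"],
               mean((ds$y - preds)^2))
})

test_that("LOO Brier by averaging equals LOO Brier by pooling", {
  for (s in 1:20) {
    ds <- gen_dataset(toy_scenario(25, 0.5, "null"), seed = 210 + s)
    pooled <- loo_cv(ds, "ml", measures = "brier")$estimate
    # averaging strategy via independent glm refits
    per_obs <- sapply(seq_along(ds$y), function(i) {
      g <- suppressWarnings(glm(y ~ ., family = binomial,
               data = data.frame(y = ds$y[-i], ds$X[-i, ])))
      p <- plogis(sum(coef(g) * c(1, ds$X[i, ])))
      (ds$y[i] - p)^2
    })
    expect_equal(pooled, mean(per_obs), tolerance = 1e-8)
  }
})

test_that("leave-pair-out equals exhaustive enumeration on a tiny dataset", {
  # chosen so that no pair-removed subset is separated
  ds <- ov_dataset(c(1, 1, 0, 0, 0, 0),
                   cbind(x = c(1, 0.58, -0.75, -0.05, 1.82, 1.7)))
  res <- lpo_cv(ds, "ml")
  ev <- which(ds$y == 1)
  ne <- which(ds$y == 0)
  conc <- diff_ <- c()
  for (i in ev) for (j in ne) {
    keep <- setdiff(1:6, c(i, j))
    g <- suppressWarnings(glm(y ~ x, family = binomial,
             data = data.frame(y = ds$y[keep], x = ds$X[keep, 1])))
    pi_ <- plogis(coef(g)[1] + coef(g)[2] * ds$X[i, 1])
    pj_ <- plogis(coef(g)[1] + coef(g)[2] * ds$X[j, 1])
    conc <- c(conc, (pi_ > pj_) + 0.5 * (pi_ == pj_))
    diff_ <- c(diff_, pi_ - pj_)
  }
  expect_equal(res$estimate[res$measure == "cstat"], mean(conc),
               tolerance = 1e-8)
  expect_equal(res$estimate[res$measure == "dslope"], mean(diff_),
               tolerance = 1e-8)
  expect_equal(res$n_fits[1], 8L)
  # strongly separated signal: every left-out pair is ordered correctly
  sig <- ov_dataset(c(rep(0, 6), rep(1, 6)), cbind(x = c(1:6, 101:106)))
  expect_equal(lpo_cv(sig, "fl", "cstat")$estimate, 1)
  expect_error(lpo_cv(ds, "ml", measures = c("cstat", "brier")),
               "unsupported measure")
})

test_that("fold partitions are balanced and repetitions reduce variance", {
  sizes <- sort(tabulate(optivalid:::fold_assign(52, 5)))
  expect_equal(sizes, c(10, 10, 10, 11, 11))
  ds <- gen_dataset(toy_scenario(40, 0.5, "null"), seed = 220)
  a <- kfold_cv(ds, "ml", "cstat", r = 5, seed = 9)
  b <- kfold_cv(ds, "ml", "cstat", r = 5, seed = 9)
  expect_identical(a, b)
  # r = 40 averages away partition noise relative to r = 1
  est <- sapply(1:40, function(s) c(
    r1 = kfold_cv(ds, "ml", "cstat", r = 1, seed = 1000 + s)$estimate,
    r40 = kfold_cv(ds, "ml", "cstat", r = 40, seed = 1000 + s)$estimate))
  expect_lt(sd(est["r40", ]), sd(est["r1", ]))
})

test_that("enhanced bootstrap equals a hand-computed average at tiny B", {
  # fixed balanced fixture on which the first bootstrap resamples are known
  # to be unseparated, keeping the glm oracle well defined
  y20 <- c(1, 1, 0, 1, 1, 0, 0, 1, 1, 1, 1, 0, 1, 0, 1, 0, 0, 0, 0, 0)
  x20 <- c(-1.56, -1.864, -0.032, 0.248, -0.262, -0.722, 0.084, 0.125,
           -1.487, 0.339, 0.167, 1.975, -0.302, -0.651, -1.097, -0.939,
           2.302, 1.237, -1.005, 0.942)
  ds <- ov_dataset(y20, cbind(x = x20))
  res <- enhanced_bootstrap(ds, "ml", B = 3, seed = 42)
  expect_equal(res$n_failed[1], 0L)
  # reconstruct the three resamples and the optimism by hand with glm
  g_app <- suppressWarnings(glm(y ~ x, family = binomial,
               data = data.frame(y = ds$y, x = ds$X[, 1])))
  p_app <- fitted(g_app)
  opt <- matrix(NA, 3, 3)
  with_seed_test(42, {
    for (b in 1:3) {
      idx <- sample.int(20, 20, replace = TRUE)
      g <- suppressWarnings(glm(y ~ x, family = binomial,
               data = data.frame(y = ds$y[idx], x = ds$X[idx, 1])))
      pb <- fitted(g)
      po <- plogis(coef(g)[1] + coef(g)[2] * ds$X[, 1])
      opt[b, ] <- c(
        cstat_brute(pb, ds$y[idx]) - cstat_brute(po, ds$y),
        dslope_pairs(pb, ds$y[idx]) - dslope_pairs(po, ds$y),
        mean((ds$y[idx] - pb)^2) - mean((ds$y - po)^2))
    }
  })
  expected <- c(cstat_brute(p_app, ds$y), dslope_pairs(p_app, ds$y),
                mean((ds$y - p_app)^2)) - colMeans(opt)
  expect_equal(res$estimate, expected, tolerance = 1e-6)
})

test_that(".632+ weighting follows the relative-overfitting-rate formula", {
  comb <- optivalid:::combine_632plus
  # out-of-bag equal to apparent: estimate equals apparent regardless
  expect_equal(comb("cstat", 0.7, 0.7, runif(10), rbinom(10, 1, .5)), 0.7)
  # oob better than apparent (R = 0): plain .632 weighting
  expect_equal(comb("cstat", 0.7, 0.8, NULL, NULL),
               1 - (0.368 * 0.3 + 0.632 * 0.2))
  # maximal overfitting (oob at the no-information value): R = 1,
  # weight = .632/(1-.368) and oob truncated at 0.5
  expect_equal(comb("cstat", 0.9, 0.4, NULL, NULL),
               1 - ((1 - 1) * 0.1 + 1 * 0.5))
  # brier no-information value is the permutation product form
  y <- c(1, 1, 0, 0)
  p <- c(0.9, 0.6, 0.4, 0.1)
  expect_equal(optivalid:::noinfo_err("brier", p, y),
               mean(outer(y, p, function(a, b) (a - b)^2)))
})

test_that("every technique is reproducible from its seed", {
  ds <- gen_dataset(toy_scenario(30, 0.5, "null"), seed = 240)
  expect_identical(enhanced_bootstrap(ds, "ml", B = 15, seed = 7),
                   enhanced_bootstrap(ds, "ml", B = 15, seed = 7))
  expect_identical(boot632plus(ds, "ml", B = 15, seed = 7),
                   boot632plus(ds, "ml", B = 15, seed = 7))
  expect_identical(loo_cv(ds, "rr", "cstat"), loo_cv(ds, "rr", "cstat"))
  iv1 <- internal_validation(ds, "ml", f = 3, r = 2, B = 10, seed = 5)
  iv2 <- internal_validation(ds, "ml", f = 3, r = 2, B = 10, seed = 5)
  expect_identical(iv1, iv2)
  expect_equal(nrow(iv1), 3 + 3 + 2 + 3 + 3 + 3)
})

test_that("leave-one-out is biased low, and more so for shrinkage estimators", {
  # the one-covariate toy mechanism: 20 observations, 5 randomly labelled
  # events, no true signal
  n_seeds <- 200
  pooled <- sapply(1:n_seeds, function(s) {
    attr(loo_trace(seed = s), "pooled_cstat")
  })
  traces <- loo_trace(seed = 1)
  expect_equal(nrow(traces), 40)  # 20 iterations x 2 estimators
  # left-out events receive lower predictions than left-out non-events
  gap <- sapply(1:100, function(s) {
    tr <- loo_trace(seed = s, estimators = "ml")
    mean(tr$p_left_out[tr$left_out_event], na.rm = TRUE) -
      mean(tr$p_left_out[!tr$left_out_event], na.rm = TRUE)
  })
  expect_lt(mean(gap), 0)
  # ridge at least as biased as ML in most draws, and clearly on average
  expect_gte(mean(pooled["rr", ] <= pooled["ml", ]), 0.7)
  expect_lt(mean(pooled["rr", ]), mean(pooled["ml", ]))
  expect_lt(mean(pooled["ml", ]), 0.5)
})

test_that("null-scenario ranking: apparent > LPO > pooled LOO; RR bias exceeds ML", {
  hs <- headline_sim()
  app_ml <- hs_vals(hs, "ml", "apparent", "cstat")
  loo_ml <- hs_vals(hs, "ml", "loo", "cstat")
  loo_rr <- hs_vals(hs, "rr", "loo", "cstat")
  lpo_ml <- hs_vals(hs, "ml", "lpo", "cstat")
  iv_ml <- hs_vals(hs, "ml", "loo", "cstat", col = "iv")
  iv_rr <- hs_vals(hs, "rr", "loo", "cstat", col = "iv")
  expect_gt(mean(app_ml - loo_ml), 0)
  expect_gte(mean(app_ml >= loo_ml), 0.9)
  # pooled LOO below LPO on average, and below 0.5 for ridge
  expect_lt(mean(loo_ml), mean(lpo_ml))
  expect_lt(mean(loo_rr), 0.5)
  # downward LOO bias larger in magnitude for ridge than for ML
  expect_gt(abs(mean(loo_rr - iv_rr)), abs(mean(loo_ml - iv_ml)))
  # the enhanced bootstrap pulls the apparent value back towards 0.5
  enh_ml <- hs_vals(hs, "ml", "enhanced_boot", "cstat")
  expect_lt(mean(abs(enh_ml - 0.5)), mean(abs(app_ml - 0.5)))
})
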