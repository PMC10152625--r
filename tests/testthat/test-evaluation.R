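const_model <- function(p0, ncov = 5L) {
  # a model predicting the same probability for every observation
  structure(list(estimator = "ml", coef = c(qlogis(p0), rep(0, ncov)),
                 converged = TRUE, separation = "none", lambda = NULL,
                 df_e = NULL, loglik = NA_real_, n = NA_integer_,
                 event_fraction = p0),
            class = "ov_fit")
}

test_that("independent validation recovers the analytic gold-standard values", {
  sc <- toy_scenario(50, 0.25, "null")
  val <- gen_validation_set(sc, 5e4, seed = 320)
  cm <- const_model(0.25)
  iv <- independent_validation(cm, val)
  expect_equal(iv$dslope, 0)
  expect_equal(iv$brier, 0.1875, tolerance = 0.005)
  # a model fitted to a null-scenario draw has no real discrimination
  dev <- gen_dataset(sc, seed = 321)
  iv2 <- independent_validation(fit_ml(dev), val)
  expect_lt(abs(iv2$cstat - 0.5), 0.01)
})

test_that("summaries compute bias, RMSD and Monte-Carlo errors correctly", {
  base <- data.frame(scenario = "s", replicate_seed = 1:2, estimator = "ml",
                     technique = "loo", measure = "cstat",
                     separation = "none", stringsAsFactors = FALSE)
  # d = (+0.1, -0.1): zero bias, RMSD 0.1
  r1 <- cbind(base, estimate = c(0.6, 0.4), iv = c(0.5, 0.5))
  s1 <- summarize_replicates(r1)
  expect_equal(s1$mean_diff, 0)
  expect_equal(s1$rmsd, 0.1)
  # estimates identical to IV: everything zero
  r2 <- cbind(base, estimate = c(0.6, 0.4), iv = c(0.6, 0.4))
  s2 <- summarize_replicates(r2)
  expect_equal(s2$mean_diff, 0)
  expect_equal(s2$rmsd, 0)

  # rmsd^2 = bias^2 + variance, rmsd >= |bias|, on simulated differences
  set.seed(33)
  m <- 400
  d <- rnorm(m, 0.05, 0.1)
  r3 <- data.frame(scenario = "s", replicate_seed = 1:m, estimator = "ml",
                   technique = "loo", measure = "cstat", separation = "none",
                   estimate = 0.5 + d, iv = 0.5, stringsAsFactors = FALSE)
  s3 <- summarize_replicates(r3)
  expect_gte(s3$rmsd, abs(s3$mean_diff))
  expect_equal(s3$rmsd^2, s3$mean_diff^2 + mean((d - mean(d))^2),
               tolerance = 1e-12)
  # delta-method MCSE of the RMSD agrees with a bootstrap-over-replicates
  # oracle within 20%
  set.seed(34)
  boot_rmsd <- replicate(200, sqrt(mean(sample(d, m, replace = TRUE)^2)))
  expect_lt(abs(s3$mcse_rmsd - sd(boot_rmsd)) / sd(boot_rmsd), 0.2)
  expect_equal(s3$mcse_msd, sd(d^2) / sqrt(m), tolerance = 1e-12)
})

test_that("replicates are bit-reproducible and structurally complete", {
  sc <- toy_scenario(30, 0.5, "null")
  val <- gen_validation_set(sc, 5e3, seed = 330)
  r1 <- run_replicate(sc, 12345L, val, f = 3L, r = 2L, B = 10L)
  r2 <- run_replicate(sc, 12345L, val, f = 3L, r = 2L, B = 10L)
  expect_identical(r1, r2)
  # per estimator: 5 techniques x cstat, 5 x dslope, 4 x brier (no LPO),
  # plus the apparent row of each measure
  for (est in c("ml", "fl", "rr")) {
    sub <- r1[r1$estimator == est, ]
    expect_equal(sum(sub$measure == "cstat"), 6L)
    expect_equal(sum(sub$measure == "dslope"), 6L)
    expect_equal(sum(sub$measure == "brier"), 5L)
    expect_false(any(sub$technique == "lpo" & sub$measure == "brier"))
    expect_true(all(is.finite(sub$iv)))
  }
})

test_that("the study driver runs scenarios end to end with a manifest", {
  cfg <- study_config(n_replicates = 3L, iv_size = 4e3, f = 3L, r = 2L,
                      B = 10L, calib_n = 1e5)
  scens <- list(make_scenario(30, 0.5, "null", calib_n = 1e5),
                make_scenario(30, 0.5, "weak", calib_n = 1e5, seed = 5))
  out_dir <- tempfile("study")
  st <- run_study(scens, cfg, master_seed = 99L, out_dir = out_dir)
  expect_s3_class(st, "ov_study")
  expect_length(st$errors, 0)
  # all expected summary cells: 2 scenarios x 3 estimators x (6 technique
  # x measure combinations x 3 measures - LPO brier) = 2 x 3 x 17
  expect_equal(nrow(st$summary), 2 * 3 * 17)
  expect_true(all(st$summary$n_replicates == 3L))
  expect_true(all(st$summary$rmsd >= abs(st$summary$mean_diff) - 1e-12))
  expect_true(file.exists(file.path(out_dir, "summary.csv")))
  expect_true(file.exists(file.path(out_dir, "replicates.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.txt")))
  expect_match(readLines(file.path(out_dir, "manifest.txt"))[1], "master_seed")
  unlink(out_dir, recursive = TRUE)
})

test_that("configuration validation names the offending field", {
  expect_error(study_config(n_replicates = 0), "n_replicates")
  expect_error(study_config(estimators = "svm"), "estimators")
  cfg <- study_config(n_replicates = 2, calib_n = 1e5)
  cfg$iv_size <- NULL
  expect_error(optivalid:::validate_config(cfg), "iv_size")
})

test_that("study configurations round-trip through YAML files", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_replicates: 7", "B: 50",
               "estimators: [ml, rr]",
               "dgm:",
               "  binary_prev: 0.4",
               "  beta_weak: [0.2, 0.1, 0.1, 0.05, 0.1]",
               "grid:",
               "  n_pos: 10",
               "  lambda_min: 0.001",
               "  lambda_max: 100"), f)
  cfg <- read_study_config(f)
  expect_equal(cfg$n_replicates, 7L)
  expect_equal(cfg$B, 50L)
  expect_equal(cfg$estimators, c("ml", "rr"))
  expect_equal(cfg$dgm$binary_prev, 0.4)
  expect_length(cfg$grid, 11L)  # 10 positive points plus zero
  # unknown keys are named in the error
  writeLines("bootstraps: 10", f)
  expect_error(read_study_config(f), "bootstraps")
  unlink(f)
})

test_that("winsorizing at 0.5 reduces the RMSD of null-scenario c-statistics", {
  hs <- headline_sim()
  loo_ml <- hs_vals(hs, "ml", "loo", "cstat")
  iv_ml <- hs_vals(hs, "ml", "loo", "cstat", col = "iv")
  raw <- sqrt(mean((loo_ml - iv_ml)^2))
  win <- sqrt(mean((winsorize_c(loo_ml) - iv_ml)^2))
  expect_lt(win, raw)
})

test_that("the RMSD of every technique decreases with sample size", {
  rs <- rmsd_n_sim()
  for (tech in unique(rs$technique)) {
    r50 <- with(rs[rs$technique == tech & rs$n == 50, ],
                sqrt(mean((estimate - iv)^2)))
    r100 <- with(rs[rs$technique == tech & rs$n == 100, ],
                 sqrt(mean((estimate - iv)^2)))
    expect_lt(r100, r50)
  }
})
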