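test_that("config validates its fields and carries the standard C grid", {
  cfg <- brainage_config()
  expect_length(cfg$C_grid, 9)
  expect_equal(min(cfg$C_grid), 2^-7)
  expect_equal(max(cfg$C_grid), 2^7)
  expect_error(brainage_config(C_grid = c(1, -1)), "positive")
  expect_error(brainage_config(n_folds = 1), "n_folds")
  expect_error(brainage_config(split_sd_factor = 0), "positive")
})

test_that("linear SVR recovers a noiseless linear signal and constants", {
  set.seed(1)
  X <- matrix(runif(60 * 3, -2, 2), 60, 3)
  y <- 2 * X[, 1] + 10
  m <- fit_svr_linear(X[1:40, ], y[1:40])
  expect_lt(mean(abs(predict(m, X[41:60, ]) - y[41:60])), 0.05)
  const <- fit_svr_linear(X[1:40, ], rep(7, 40), C_grid = 1)
  expect_lt(max(abs(predict(const, X[41:60, ]) - 7)), const$epsilon + 1e-6)
  expect_error(fit_svr_linear(X[1:3, ], y[1:3]), "folds")
})

test_that("RVR matches the least-squares solution on noiseless data and prunes noise", {
  set.seed(2)
  X <- matrix(runif(70 * 2, -3, 3), 70, 2)
  y <- 2 * X[, 1]
  m <- fit_rvr(X[1:50, ], y[1:50])
  expect_lt(max(abs(predict(m, X[51:70, ]) - y[51:70])), 1e-3)
  # pure noise with irrelevant features: nearly all kernel bases pruned
  set.seed(3)
  Xn <- matrix(rnorm(60 * 20), 60, 20)
  yn <- rnorm(60)
  mn <- fit_rvr(Xn, yn)
  expect_lt(length(mn$relevance) / mn$n_basis_total, 0.2)
  Xbad <- Xn; Xbad[1, 1] <- Inf
  expect_error(fit_rvr(Xbad, yn), "missing or non-finite")
})

test_that("linear-kernel GPR behaves like Bayesian linear regression", {
  set.seed(4)
  X <- matrix(runif(80 * 2, -3, 3), 80, 2)
  y <- 1.5 * X[, 1] - 0.5 * X[, 2] + 12
  m <- fit_gpr_linear(X[1:60, ], y[1:60])
  expect_lt(mean(abs(predict(m, X[61:80, ]) - y[61:80])), 0.05)
  # pure noise: predictive mean collapses to the training mean
  yn <- rnorm(60)
  mn <- fit_gpr_linear(X[1:60, ], yn)
  expect_lt(max(abs(predict(mn, X[61:80, ]) - mean(yn))), 0.2 * sd(yn))
  # duplicate rows must not break the Cholesky
  Xd <- rbind(X[1:30, ], X[1:30, ])
  yd <- c(y[1:30], y[1:30])
  expect_silent(md <- fit_gpr_linear(Xd, yd))
  expect_lt(mean(abs(predict(md, X[61:80, ]) - y[61:80])), 0.5)
})

test_that("stratified folds partition subjects and balance age", {
  set.seed(5)
  age <- runif(137, 5, 20)
  f <- stratified_folds(age, n_folds = 10, n_strata = 10, seed = 3)
  expect_length(f, 137)
  expect_setequal(unique(f), 1:10)
  expect_true(all(table(f) >= 13 & table(f) <= 14))
  # fold age means stay close to the sample mean (stratification at work)
  expect_lt(max(abs(tapply(age, f, mean) - mean(age))), 1.5)
  expect_identical(f, stratified_folds(age, 10, 10, seed = 3))
  expect_error(stratified_folds(runif(5), n_folds = 10), "fewer subjects")
})

test_that("cross-validated brain age is leak-free, deterministic, and accurate", {
  sim <- simulate_age_features(120, 8, r2 = 0.9, seed = 6)
  asd <- simulate_age_features(40, 8, r2 = 0.9, seed = 7)
  cfg <- brainage_config(model = "gpr", n_folds = 5, n_shuffles = 2,
                         n_strata = 5, seed = 11)
  res <- cross_validated_brainage(sim$X, sim$age, asd$X, asd$age, cfg)
  # partition property: every NC appears in exactly one fold per shuffle
  expect_true(all(!is.na(res$folds)))
  for (s in 1:2) expect_setequal(unique(res$folds[, s]), 1:5)
  # MAE <= RMSE per shuffle
  expect_true(all(res$performance$mae <= res$performance$rmse + 1e-12))
  expect_true(all(abs(res$performance$rho) <= 1))
  # gap identity
  expect_equal(res$nc$gap, res$nc$brain_age - res$nc$age)
  expect_equal(res$asd$gap, res$asd$brain_age - res$asd$age)
  # determinism
  res2 <- cross_validated_brainage(sim$X, sim$age, asd$X, asd$age, cfg)
  expect_identical(res$nc, res2$nc)
  expect_identical(res$asd, res2$asd)
  # no leakage: held-out predictions equal an independently refit fold model
  f1 <- res$folds[, 1]
  hold <- f1 == 1
  model <- fit_gpr_linear(sim$X[!hold, , drop = FALSE], sim$age[!hold])
  expect_equal(res$predictions_nc[hold, 1],
               predict(model, sim$X[hold, , drop = FALSE]))
})

test_that("model MAE comparison handles ties, offsets, and stays calibrated", {
  mae <- c(1.1, 1.3, 0.9, 1.2, 1.0)
  same <- compare_models_mae(a = mae, b = mae)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  off <- compare_models_mae(a = mae, b = mae + 1)
  expect_lt(off$p, 1e-6)
  expect_error(compare_models_mae(a = mae, b = mae[1:3]), "matched")
  expect_equal(attr(compare_models_mae(a = mae, b = mae, c = mae), "threshold"),
               0.05 / 3)
  # null calibration of the paired t at the Bonferroni threshold
  set.seed(8)
  rej <- mean(replicate(1000, {
    compare_models_mae(a = rnorm(10, 2), b = rnorm(10, 2))$p < 0.05 / 3
  }))
  expect_lt(abs(rej - 0.05 / 3), 0.011)
})

test_that("DED/PRD rule applies the 0.5-SD band exactly", {
  # SD of brain_age fixed by construction below
  ba <- c(10, 15, 12.5, 11)
  s <- sd(ba)
  split <- split_ded_prd(ba, age = c(10 + 0.5 * s + 0.01, 15 - 0.5 * s - 0.01,
                                     12.5, 11))
  expect_identical(as.character(split$dev_label),
                   c("DED", "PRD", "neither", "neither"))
  expect_equal(split$gap, split$brain_age - split$age)
  expect_equal(attr(split, "sd_brain_age"), s)
  expect_warning(z <- split_ded_prd(rep(3, 5), 1:5), "zero SD")
  expect_true(all(z$dev_label == "neither"))
  expect_error(split_ded_prd(1:3, 1:2), "length mismatch")
})

test_that("DED/PRD cognition comparison uses covariate-adjusted group tests", {
  set.seed(9)
  n <- 60
  split <- data.frame(age = runif(2 * n, 5, 20), brain_age = 0, gap = 0,
                      dev_label = factor(rep(c("DED", "PRD"), each = n),
                                         levels = c("DED", "PRD", "neither")))
  ph <- data.frame(age = split$age, sex = rbinom(2 * n, 1, 0.8),
                   fiq = rnorm(2 * n, 105, 15),
                   adi_rrb = rnorm(2 * n, 6, 2.5),
                   adi_soc = rnorm(2 * n, 20, 5),
                   adi_ver = rnorm(2 * n, 16, 4) + rep(c(0, 4), each = n))
  res <- compare_ded_prd_cognition(split, ph)
  expect_identical(res$score, c("fiq", "adi_rrb", "adi_soc", "adi_ver"))
  expect_lt(res$p[res$score == "adi_ver"], 0.01)
  expect_gt(min(res$p[res$score != "adi_ver"]), 0.01)
  # identical score vectors -> p = 1
  ph2 <- ph; ph2$fiq <- 100
  expect_equal(compare_ded_prd_cognition(split, ph2)$p[1], 1)
  bad <- split; bad$dev_label[] <- "DED"
  expect_error(compare_ded_prd_cognition(bad, ph), "non-empty")
})

test_that("site residualization removes site age offsets only", {
  set.seed(10)
  age <- c(runif(100, 5, 15), runif(100, 5, 15) + 3)
  site <- rep(1:2, each = 100)
  adj <- site_residualized_age(age, site)
  expect_equal(mean(adj[site == 2]) - mean(adj[site == 1]), 0, tolerance = 1e-10)
  expect_equal(mean(adj), mean(age))
  # balanced identical sites: adjustment within sampling noise of site means
  age2 <- runif(200, 5, 20)
  adj2 <- site_residualized_age(age2, rep(1:2, 100))
  expect_lt(max(abs(adj2 - age2)), 1)
  expect_warning(same <- site_residualized_age(age2, rep(1, 200)), "single site")
  expect_identical(same, age2)
})
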