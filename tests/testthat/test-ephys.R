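test_that("PPR bins and period averages follow the binning rules", {
  # identical pulses: every bin PPR is 1
  s <- sweep_series(1:20, rep(80, 20), rep(80, 20))
  pp <- compute_ppr(s)
  expect_true(all(pp$bins$ppr == 1))
  expect_equal(pp$baseline_ppr, 1)
  # 20 sweeps make exactly 4 bins
  expect_equal(nrow(pp$bins), 4)

  # hand-built 10-sweep table against spreadsheet-style ratios
  e1 <- c(100, 110, 90, 105, 95, 100, 100, 100, 120, 80)
  e2 <- c(150, 160, 170, 140, 150, 180, 200, 160, 170, 190)
  pp2 <- compute_ppr(sweep_series(1:10, e1, e2), bin_size = 5)
  expect_equal(pp2$bins$ppr,
               c(mean(e2[1:5]) / mean(e1[1:5]),
                 mean(e2[6:10]) / mean(e1[6:10])))

  # baseline/drug averages and their difference
  s3 <- rbind(sweep_series(1:20, rep(100, 20), rep(150, 20)),
              sweep_series(1:20, rep(100, 20), rep(120, 20),
                           period = "drug"))
  pp3 <- compute_ppr(s3)
  expect_equal(pp3$baseline_ppr, 1.5)
  expect_equal(pp3$post_ppr, 1.2)
  expect_equal(pp3$delta_ppr, -0.3)

  # incomplete final bin dropped with a warning
  expect_warning(compute_ppr(sweep_series(1:23, rep(1, 23), rep(1, 23))),
                 "incomplete")
})

test_that("Gaussian fit recovers mean and spread and rejects degenerate input", {
  set.seed(51)
  x <- rnorm(1e4, mean = 2, sd = 0.3)
  f <- fit_gaussian_to_ppr(x)
  expect_gt(f$mu, 1.99); expect_lt(f$mu, 2.01)
  expect_gt(f$sigma, 0.29); expect_lt(f$sigma, 0.31)
  expect_equal(f$mu, mean(x))
  expect_error(fit_gaussian_to_ppr(rep(2, 10)), "variance")
  expect_error(fit_gaussian_to_ppr(c(1, 2)), "at least 5")
  # binned variant lands near the MLE on a large sample
  fb <- fit_gaussian_to_ppr(x, method = "binned", breaks = 40)
  expect_equal(fb$mu, f$mu, tolerance = 0.02)
  expect_equal(fb$sigma, f$sigma, tolerance = 0.05)
})

test_that("variance F test matches the F-distribution oracle and its direction", {
  x <- rnorm(30)
  a <- 2 + (x - mean(x)) / sd(x) * 0.4   # sample variance exactly 0.16
  y <- rnorm(30)
  b <- 2 + (y - mean(y)) / sd(y) * 0.2   # sample variance exactly 0.04
  ft <- variance_f_test(a, b)
  expect_equal(ft$F, 4, tolerance = 1e-12)
  expect_equal(ft$p, oracle_f_tail(4, 29, 29), tolerance = 1e-12)
  expect_lt(ft$p, 0.05)  # a variance reduction is detected
  # identical samples: F = 1, one-tailed p = 0.5
  ft0 <- variance_f_test(a, a)
  expect_equal(ft0$F, 1)
  expect_equal(ft0$p, 0.5)
  expect_error(variance_f_test(rep(1, 5), a), "variance")
})

test_that("delta-PPR regression matches the normal-equations oracle", {
  set.seed(52)
  base <- runif(20, 1.2, 2.6)
  post <- 0.6 * base + rnorm(20, 0, 0.1)
  reg <- delta_ppr_regression(base, post)
  d <- post - base
  X <- cbind(1, base)
  beta <- solve(t(X) %*% X, t(X) %*% d)
  expect_equal(reg$intercept, beta[1], tolerance = 1e-10)
  expect_equal(reg$slope, beta[2], tolerance = 1e-10)
  expect_equal(reg$x_intercept, -beta[1] / beta[2], tolerance = 1e-10)
  expect_equal(reg$pearson_r, cor(base, d), tolerance = 1e-12)

  # full regression to the mean: slope -1, x-intercept at the mean
  post_m <- rep(mean(base), 20)
  reg_m <- delta_ppr_regression(base, post_m)
  expect_equal(reg_m$slope, -1, tolerance = 1e-12)
  expect_equal(reg_m$x_intercept, mean(base), tolerance = 1e-9)

  # no change: flagged undefined correlation, never silently zero
  reg_0 <- delta_ppr_regression(base, base)
  expect_equal(reg_0$slope, 0)
  expect_true(is.na(reg_0$pearson_r))
  expect_error(delta_ppr_regression(rep(2, 5), runif(5)), "spread")
})

test_that("inverse CV^2 follows its definition and the quantal closed form", {
  s <- rbind(sweep_series(1:20, rnorm(20, 100, 10), rep(100, 20)),
             sweep_series(1:20, rnorm(20, 100, 10), rep(100, 20),
                          period = "drug"))
  cv <- inverse_cv_squared(s)
  b <- s$epsc1[s$period == "baseline"]
  p <- s$epsc1[s$period == "drug"]
  expect_equal(cv$cv2_inv_baseline, (mean(b) / sd(b))^2)
  expect_equal(cv$ratio, cv$cv2_inv_post / cv$cv2_inv_baseline)

  # binomial release with N = 10, p = 0.5: CV^-2 = Np/(1-p) = 10
  set.seed(53)
  cc <- replicate(300, {
    amps <- 10 * rbinom(20, 10, 0.5)
    (mean(amps) / sd(amps))^2
  })
  expect_equal(median(cc), 10, tolerance = 0.15)

  # scaling amplitudes leaves CV^-2 unchanged
  s2 <- s
  s2$epsc1 <- s2$epsc1 * 7
  expect_equal(inverse_cv_squared(s2)$cv2_inv_baseline,
               cv$cv2_inv_baseline, tolerance = 1e-12)
})

test_that("PPR disparity is a symmetric absolute difference", {
  expect_equal(ppr_disparity(1.8, 2.2), 0.4)
  expect_equal(ppr_disparity(2.2, 1.8), 0.4)
  expect_equal(ppr_disparity(2, 2), 0)
  expect_error(ppr_disparity(-1, 2))
})

test_that("the Brown-Forsythe alternative detects spread reduction", {
  set.seed(55)
  a <- rnorm(30, 2, 0.4)
  b <- rnorm(30, 2, 0.15)
  lv <- variance_levene_test(a, b)
  expect_lt(lv$p, 0.05)
  # symmetric null: p well away from the rejection region on average
  ps <- replicate(200, variance_levene_test(rnorm(30), rnorm(30))$p)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # pipeline flag switches the variance test
  ex <- gen_epsc_experiment(experiment_design(n_inputs = 12, seed = 56))
  st <- ppr_stats(ex$sweeps, var_test = "levene")
  expect_true(is.null(st$f_test$F))
  expect_true(st$f_test$p >= 0 && st$f_test$p <= 1)
})

test_that("the pipeline is invariant under input relabelling", {
  ex <- gen_epsc_experiment(experiment_design(n_inputs = 8, seed = 54))
  st1 <- ppr_stats(ex$sweeps)
  # permute the input blocks
  ids <- unique(ex$sweeps$input_id)
  perm <- sample(ids)
  reord <- do.call(rbind, lapply(perm, function(id)
    ex$sweeps[ex$sweeps$input_id == id, ]))
  st2 <- ppr_stats(reord)
  expect_equal(st1$f_test$F, st2$f_test$F, tolerance = 1e-12)
  expect_equal(st1$gaussian_baseline$mu, st2$gaussian_baseline$mu,
               tolerance = 1e-12)
  expect_equal(sort(st1$per_input$baseline_ppr),
               sort(st2$per_input$baseline_ppr), tolerance = 1e-12)
})
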