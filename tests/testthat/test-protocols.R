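# tiny grids keep these unit tests fast; the full protocol properties are
# exercised in test-acceptance.R

test_that("no postsynaptic drive means no pairings and zero weight change", {
  cfg <- pairing_config(A2_grid = 0, dt_grid = c(-10, 10), n_draws = 5,
                        seed = 2)
  r <- run_pairing_protocol(cfg)
  expect_true(all(r$mean_dw == 0))
})

test_that("degenerate sampling reproduces a deterministic single run", {
  fit <- fm_gamma_fits()$control
  U_mean <- fit$k * fit$theta / 140
  cfg <- pairing_config(A2_grid = 400, dt_grid = 20, n_draws = 1, seed = 3)
  r <- run_pairing_protocol(cfg, U_values = U_mean)
  pre <- regular_train(10, 20, 500, pulse_width = 10, t_start = 20)
  post <- regular_train(10, 20, 400, pulse_width = 10, t_start = 40)
  sim <- simulate_pair(pre, post, tpm_params(U_SE = U_mean), lif_params(),
                       coupling_params(), stdp = stdp_params(),
                       t_end = 20 + 450 + 20 + 10 + 120)
  expect_equal(unname(r$mean_dw[1, 1]), sim$dw_rel, tolerance = 1e-12)
})

test_that("timing sign maps onto potentiation and depression", {
  fit <- fm_gamma_fits()$control
  U_mean <- fit$k * fit$theta / 140
  cfg <- pairing_config(A2_grid = 400, dt_grid = c(-20, 20), n_draws = 1,
                        seed = 4)
  r <- run_pairing_protocol(cfg, U_values = U_mean)
  expect_lt(r$mean_dw["-20", "400"], 0)
  expect_gt(r$mean_dw["20", "400"], 0)
})

test_that("pairing runs are reproducible and reuse one draw set per condition", {
  cfg <- pairing_config(A2_grid = c(200, 400), dt_grid = 0, n_draws = 4,
                        seed = 5)
  r1 <- run_pairing_protocol(cfg)
  r2 <- run_pairing_protocol(cfg)
  expect_identical(r1$mean_dw, r2$mean_dw)
  expect_identical(r1$U_draws, r2$U_draws)
  expect_length(r1$U_draws, 4)
})

fake_pairing_result <- function(mean_dw, dt_grid, A2_grid) {
  structure(list(mean_dw = mean_dw,
                 cfg = list(dt_grid = dt_grid, A2_grid = A2_grid)),
            class = "pairing_result")
}

test_that("LTP threshold equals a linear-scan oracle and flags empty grids", {
  A2 <- seq(0, 100, by = 20)
  dts <- c(-10, 0, 10)
  set.seed(6)
  grid <- matrix(runif(18, -0.05, 0.08), 3, 6,
                 dimnames = list(dts, A2))
  r <- fake_pairing_result(grid, dts, A2)
  thr <- ltp_threshold_A2(r, eps = 0.01)
  for (i in 1:3) {
    scan <- NA_real_
    for (j in seq_along(A2)) {
      if (grid[i, j] > 0.01) { scan <- A2[j]; break }
    }
    expect_identical(unname(thr$per_dt[i]), scan)
  }
  none <- fake_pairing_result(matrix(0, 3, 6, dimnames = list(dts, A2)),
                              dts, A2)
  expect_true(all(is.na(ltp_threshold_A2(none)$per_dt)))
  expect_true(is.na(ltp_threshold_A2(none)$overall))
})

test_that("window-averaged maximum matches a brute-force reduction", {
  A2 <- seq(100, 300, by = 20)
  dts <- seq(-20, 20, by = 10)
  set.seed(7)
  grid <- matrix(rnorm(length(dts) * length(A2)), length(dts), length(A2),
                 dimnames = list(dts, A2))
  r <- fake_pairing_result(grid, dts, A2)
  # explicit double loop
  acc <- 0
  for (i in seq_along(dts)) {
    best <- -Inf
    for (j in seq_along(A2))
      if (A2[j] >= 180 && A2[j] <= 200) best <- max(best, grid[i, j])
    acc <- acc + best
  }
  expect_equal(window_avg_max_dw(r), acc / length(dts), tolerance = 1e-12)
  # constant field returns the constant; single column reduces to itself
  const <- fake_pairing_result(matrix(0.3, 5, 11, dimnames = list(dts, A2)),
                               dts, A2)
  expect_equal(window_avg_max_dw(const), 0.3)
  expect_equal(window_avg_max_dw(r, A2_window = c(200, 200)),
               mean(grid[, "200"]))
  expect_error(window_avg_max_dw(r, A2_window = c(500, 600)), "intersect")
})

test_that("plasticity reduction follows its definition", {
  r <- structure(list(final_dw = cbind(control = c(0.2, -0.2),
                                       AP5 = c(0.1, -0.1))),
                 class = "poisson_result")
  expect_equal(plasticity_reduction(r, "AP5"), 0.1)
  expect_equal(plasticity_reduction(r, "AP5", trials = "ltp"), 0.1)
  expect_equal(plasticity_reduction(r, "AP5", trials = "ltd"), 0.1)
  # identical conditions give zero
  r2 <- structure(list(final_dw = cbind(control = c(0.3, -0.4),
                                        same = c(0.3, -0.4))),
                  class = "poisson_result")
  expect_equal(plasticity_reduction(r2, "same"), 0)
  expect_error(plasticity_reduction(r, "missing"), "not present")
})

test_that("poisson protocol is seed-reproducible and null under zero rate", {
  cfg <- poisson_config(rate = 10, duration = 1, n_trials = 5, seed = 8)
  r1 <- run_poisson_protocol(cfg)
  r2 <- run_poisson_protocol(cfg)
  expect_identical(r1$final_dw, r2$final_dw)

  z <- run_poisson_protocol(poisson_config(rate = 0, duration = 1,
                                           n_trials = 3, seed = 9))
  expect_true(all(z$final_dw == 0))
})

test_that("a condition entered twice yields identical final weights", {
  fits <- fm_gamma_fits()
  cfg <- poisson_config(duration = 2, n_trials = 6, seed = 10,
                        conditions = list(control = fits$control,
                                          AP5 = fits$AP5,
                                          AP5_again = fits$AP5))
  r <- run_poisson_protocol(cfg)
  expect_identical(r$final_dw[, "AP5"], r$final_dw[, "AP5_again"])
})

test_that("binned relative differences cover all trials once", {
  set.seed(11)
  r <- structure(list(final_dw = cbind(control = rnorm(100),
                                       AP5 = rnorm(100))),
                 class = "poisson_result")
  b <- binned_relative_diff(r, "AP5")
  expect_equal(sum(b$n), 100)
  expect_equal(nrow(b), 20)
})
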