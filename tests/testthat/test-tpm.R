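test_that("first spike from rest releases U_SE and conserves resources", {
  up <- tpm_spike_update(tpm_state(), tpm_params(U_SE = 0.3))
  expect_equal(up$state$u0, 0.3)
  expect_equal(up$released, 0.3)
  expect_equal(up$state$x0, 0.7)
  expect_equal(up$state$x1, 0.3)
  expect_equal(with(up$state, x0 + x1 + x2), 1)
})

test_that("spike update conserves resources from arbitrary states", {
  set.seed(11)
  for (i in 1:25) {
    x <- runif(3)
    x <- x / sum(x)
    st <- tpm_state(x[1], x[2], x[3], u0 = runif(1))
    p <- tpm_params(U_SE = runif(1))
    up <- tpm_spike_update(st, p)
    expect_equal(with(up$state, x0 + x1 + x2), 1, tolerance = 1e-12)
    expect_true(all(unlist(up$state[c("x0", "x1", "x2")]) >= 0))
  }
})

test_that("inter-spike decay follows the exact exponentials", {
  p <- tpm_params(tau_in = 3, tau_rec = 300, tau_f = 200)
  s <- tpm_decay_step(tpm_state(x0 = 0.7, x1 = 0.3), p, dt = 3)
  expect_equal(s$x1, 0.3 * exp(-1), tolerance = 1e-12)
  expect_equal(s$x0 + s$x1 + s$x2, 1, tolerance = 1e-12)

  # dt -> 0 leaves the state unchanged
  s0 <- tpm_state(0.5, 0.3, 0.2, u0 = 0.4)
  s1 <- tpm_decay_step(s0, p, dt = 1e-9)
  expect_equal(unlist(s1[c("x0", "x1", "x2", "u0")]),
               unlist(s0[c("x0", "x1", "x2", "u0")]), tolerance = 1e-9)

  # long decay returns to rest
  s2 <- tpm_decay_step(tpm_state(0.2, 0.5, 0.3, u0 = 0.9), p, dt = 1e5)
  expect_equal(s2$x0, 1, tolerance = 1e-9)
  expect_equal(s2$u0, 0, tolerance = 1e-9)

  # equal tau_in and tau_rec (degenerate chain) still conserves
  pd <- tpm_params(tau_in = 5, tau_rec = 5)
  sd <- tpm_decay_step(tpm_state(0.4, 0.4, 0.2), pd, dt = 7)
  expect_equal(sd$x0 + sd$x1 + sd$x2, 1, tolerance = 1e-12)
})

test_that("within a spike-free interval x0 is non-decreasing and u0 non-increasing", {
  p <- tpm_params()
  s <- tpm_state(0.3, 0.4, 0.3, u0 = 0.6)
  for (i in 1:50) {
    s2 <- tpm_decay_step(s, p, dt = 2)
    expect_gte(s2$x0, s$x0)
    expect_lte(s2$u0, s$u0)
    s <- s2
  }
})

test_that("two-spike response matches the hand recursion oracle", {
  # reference case: second spike 50 ms after the first
  o <- oracle_two_spike(0.2, tau_in = 3, tau_rec = 300, tau_f = 200,
                        isi = 50)
  p <- tpm_params(U_SE = 0.2, tau_in = 3, tau_rec = 300, tau_f = 200)
  up1 <- tpm_spike_update(tpm_state(), p)
  st <- tpm_decay_step(up1$state, p, 50)
  up2 <- tpm_spike_update(st, p)
  expect_equal(up2$released / up1$released, o$ppr_release,
               tolerance = 1e-12)

  # and across 20 random parameter sets via the voltage-clamp readout
  set.seed(21)
  for (i in 1:20) {
    U <- runif(1, 0.05, 0.95)
    tin <- runif(1, 1, 6)
    trec <- runif(1, 30, 600)
    tf <- runif(1, 30, 600)
    o <- oracle_two_spike(U, tin, trec, tf, isi = 50)
    r <- epsc_train_response(tpm_params(U, tin, trec, tf),
                             coupling_params(), n_pulses = 2, rate = 20)
    expect_equal(r$ppr, o$ppr_clamp, tolerance = 1e-6)
  }
})

test_that("EPSC trains facilitate or depress in the expected regimes", {
  # strong facilitation, slow recovery irrelevant at tiny U
  fac <- epsc_train_response(tpm_params(U_SE = 0.05, tau_f = 1000,
                                        tau_rec = 50),
                             coupling_params(), 2, 20)
  expect_gt(fac$ppr, 1)
  # negligible facilitation: PPR is governed by depletion, below 1
  dep <- epsc_train_response(tpm_params(U_SE = 0.5, tau_f = 1e-3,
                                        tau_rec = 500),
                             coupling_params(), 2, 20)
  expect_lt(dep$ppr, 1)
})

test_that("calibration recovers known constants and matches a grid oracle", {
  fit <- fm_gamma_fits()$control
  truth <- list(tau_f = 100, tau_rec = 150, w0 = 8)
  p <- (seq_len(101) - 0.5) / 101
  U_q <- pmin(stats::qgamma(p, fit$k, scale = fit$theta) / 140, 1)
  target <- epsc_train_response(
    tpm_params(U_SE = mean(U_q), tau_f = truth$tau_f,
               tau_rec = truth$tau_rec),
    coupling_params(w = truth$w0), n_pulses = 5, rate = 20)
  pprs <- vapply(U_q, function(u)
    epsc_train_response(tpm_params(U_SE = u, tau_f = truth$tau_f,
                                   tau_rec = truth$tau_rec),
                        coupling_params(w = 1), 2, 20)$ppr, numeric(1))
  tf_grid <- seq(50, 200, 25)
  tr_grid <- seq(50, 300, 25)
  cal <- calibrate_tpm(target$ratios, var(pprs), fit,
                       target_peak1 = target$peaks[1],
                       tau_f_grid = tf_grid, tau_rec_grid = tr_grid)
  expect_equal(cal$tau_f, truth$tau_f)
  expect_equal(cal$tau_rec, truth$tau_rec)
  expect_equal(cal$w0, truth$w0, tolerance = 1e-6)

  # independent exhaustive argmin over the same grid
  obj <- outer(tf_grid, tr_grid, Vectorize(function(tf, tr) {
    r <- epsc_train_response(tpm_params(U_SE = mean(U_q), tau_f = tf,
                                        tau_rec = tr),
                             coupling_params(w = 1), 5, 20)
    pp <- vapply(U_q, function(u)
      epsc_train_response(tpm_params(U_SE = u, tau_f = tf, tau_rec = tr),
                          coupling_params(w = 1), 2, 20)$ppr, numeric(1))
    sum((r$ratios - target$ratios)^2) + (var(pp) - var(pprs))^2
  }))
  idx <- which(obj == min(obj), arr.ind = TRUE)
  expect_equal(cal$tau_f, tf_grid[idx[1]])
  expect_equal(cal$tau_rec, tr_grid[idx[2]])
})

test_that("degenerate calibration inputs are rejected", {
  fit <- fm_gamma_fits()$control
  expect_error(calibrate_tpm(c(1, 0.8), 0.01, fit,
                             tau_f_grid = numeric(0)),
               "empty")
  expect_error(calibrate_tpm(c(1, NA), 0.01, fit))
})
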