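#' Apply a presynaptic spike to the TPM synapse state
#'
#' Event update at a presynaptic spike: the utilization first jumps by
#' facilitation, `u0+ = u0- + U_SE * (1 - u0-)`, and the released
#' fraction is `u0+ * x0-`, which moves from the available pool `x0`
#' into the active pool `x1`.  Resource conservation
#' (`x0 + x1 + x2 = 1`) is preserved exactly.
#'
#' @param state a [tpm_state()].
#' @param params a [tpm_params()].
#' @return A list with elements `state` (the updated [tpm_state()]) and
#'   `released` (the released resource fraction).
#' @export
#' @examples
#' up <- tpm_spike_update(tpm_state(), tpm_params(U_SE = 0.3))
#' up$released                       # 0.3 on the first spike from rest
tpm_spike_update <- function(state, params) {
  stopifnot(inherits(state, "tpm_state"), inherits(params, "tpm_params"))
  u_after <- state$u0 + params$U_SE * (1 - state$u0)
  released <- u_after * state$x0
  new <- tpm_state(x0 = state$x0 - released, x1 = state$x1 + released,
                   x2 = state$x2, u0 = u_after, t = state$t)
  list(state = new, released = released)
}

# closed-form inter-spike decay of (x1, x2, u0); x0 absorbs the balance
decay_x <- function(x1, x2, dt, tau_in, tau_rec) {
  e_in <- exp(-dt / tau_in)
  if (abs(tau_in - tau_rec) < 1e-12) {
    nx2 <- (x2 + x1 * dt / tau_in) * exp(-dt / tau_rec)
  } else {
    A <- x1 * tau_rec / (tau_in - tau_rec)
    nx2 <- (x2 - A) * exp(-dt / tau_rec) + A * e_in
  }
  c(x1 = x1 * e_in, x2 = nx2)
}

#' Advance the TPM synapse state between spikes
#'
#' Exact solution of the inter-spike kinetics over a step `dt`: the
#' active fraction `x1` decays into the recovering fraction `x2` with
#' `tau_in`, `x2` recovers into `x0` with `tau_rec`, and the utilization
#' `u0` decays with `tau_f`.  The update uses the closed-form solution of
#' the linear kinetics, so it is exact for any `dt`.
#'
#' @inheritParams tpm_spike_update
#' @param dt time step, ms (`> 0`).
#' @return The advanced [tpm_state()].
#' @export
#' @examples
#' s <- tpm_state(x0 = 0.7, x1 = 0.3)
#' tpm_decay_step(s, tpm_params(), dt = 3)$x1  # = 0.3 * exp(-1)
tpm_decay_step <- function(state, params, dt) {
  stopifnot(inherits(state, "tpm_state"), inherits(params, "tpm_params"),
            dt > 0)
  nx <- decay_x(state$x1, state$x2, dt, params$tau_in, params$tau_rec)
  x0 <- state$x0 + (state$x1 + state$x2) - sum(nx)
  tpm_state(x0 = x0, x1 = nx[["x1"]], x2 = nx[["x2"]],
            u0 = state$u0 * exp(-dt / params$tau_f), t = state$t + dt)
}

#' EPSC train response of the TPM synapse under voltage clamp
#'
#' Peak EPSC amplitudes for a regular presynaptic spike train with the
#' postsynaptic membrane held at `V_hold` (a voltage-clamp-like readout,
#' so the synaptic state is exercised without postsynaptic spiking).
#' At each spike the conductance jumps by `w * u0+ * x0-` on top of the
#' residual conductance; the peak current is the conductance at the jump
#' times the driving force `E_E - V_hold`.  Computed from the exact
#' inter-spike solution (no grid integration).
#'
#' @param tpm a [tpm_params()].
#' @param coupling a [coupling_params()].
#' @param n_pulses number of presynaptic spikes (`>= 2`).
#' @param rate spike rate, Hz.
#' @param V_hold holding potential, mV.
#' @return A list with `peaks` (pA), `ratios` (`peaks/peaks[1]`) and
#'   `ppr` (`peaks[2]/peaks[1]`).
#' @export
#' @examples
#' r <- epsc_train_response(tpm_params(U_SE = 0.2), coupling_params(),
#'                          n_pulses = 10, rate = 20)
#' r$ppr   # paired-pulse ratio at 50 ms
epsc_train_response <- function(tpm, coupling, n_pulses = 10, rate = 20,
                                V_hold = -70) {
  stopifnot(inherits(tpm, "tpm_params"), inherits(coupling, "coupling_params"),
            n_pulses >= 2, rate > 0)
  isi <- 1000 / rate
  drive <- coupling$E_E - V_hold
  st <- tpm_state()
  gE <- 0
  peaks <- numeric(n_pulses)
  for (i in seq_len(n_pulses)) {
    up <- tpm_spike_update(st, tpm)
    st <- up$state
    gE <- gE + coupling$w * up$released
    peaks[i] <- gE * drive
    if (i < n_pulses) {
      st <- tpm_decay_step(st, tpm, isi)
      gE <- gE * exp(-isi / coupling$tau_syn_E)
    }
  }
  list(peaks = peaks, ratios = peaks / peaks[1], ppr = peaks[2] / peaks[1])
}

#' Calibrate the free TPM constants against EPSC train targets
#'
#' Grid search over `(tau_f, tau_rec)` minimising the squared error
#' between the simulated 20 Hz EPSC peak ratios (at the mean release
#' probability of `use_distribution`) and `target_peak_ratios`, plus the
#' squared error between the paired-pulse-ratio variance under release
#' probabilities sampled from `use_distribution` and
#' `target_ppr_variance`.  Peak ratios and PPR variance are invariant to
#' the weight, so `w0` is solved afterwards from the absolute
#' first-peak target `target_peak1` (pA under voltage clamp at
#' `V_hold`), to which every peak is proportional.
#'
#' @param target_peak_ratios target `peak_i/peak_1` sequence (length
#'   `>= 2`, finite and positive; element 1 is 1).
#' @param target_ppr_variance target variance of the PPR across the
#'   release-probability population.
#' @param use_distribution a [gamma_fit] describing the release
#'   probability distribution (see [fm_gamma_fits()]).
#' @param target_peak1 target first-peak amplitude, pA.
#' @param tau_f_grid,tau_rec_grid search grids, ms.
#' @param rate train rate, Hz.
#' @param tau_in release time constant, ms (held fixed).
#' @param n_quantiles number of gamma quantiles used to evaluate the PPR
#'   variance (deterministic quadrature over the distribution).
#' @param V_hold holding potential for the readout, mV.
#' @return A list with `tau_f`, `tau_rec`, `w0`, the achieved `ratios`
#'   and `ppr_variance`, and the objective value `residual`.
#' @export
calibrate_tpm <- function(target_peak_ratios, target_ppr_variance,
                          use_distribution, target_peak1 = 60,
                          tau_f_grid = seq(50, 500, by = 25),
                          tau_rec_grid = seq(50, 800, by = 25),
                          rate = 20, tau_in = 3, n_quantiles = 101,
                          V_hold = -70) {
  stopifnot(length(target_peak_ratios) >= 2,
            all(is.finite(target_peak_ratios)), all(target_peak_ratios > 0),
            is.finite(target_ppr_variance), target_ppr_variance >= 0,
            target_peak1 > 0)
  if (length(tau_f_grid) < 1 || length(tau_rec_grid) < 1)
    stop("empty calibration grid")
  fit <- use_distribution
  stopifnot(inherits(fit, "gamma_fit"))
  # deterministic quadrature over the release-probability distribution
  p <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  U_q <- pmin(stats::qgamma(p, shape = fit$k, scale = fit$theta) / 140, 1)
  U_mean <- mean(U_q)
  n_pulses <- length(target_peak_ratios)

  best <- list(residual = Inf)
  for (tf in tau_f_grid) {
    for (tr in tau_rec_grid) {
      tpm_mean <- tpm_params(U_SE = U_mean, tau_in = tau_in, tau_rec = tr,
                             tau_f = tf)
      cp <- coupling_params(w = 1)
      resp <- epsc_train_response(tpm_mean, cp, n_pulses = n_pulses,
                                  rate = rate, V_hold = V_hold)
      pprs <- vapply(U_q, function(u) {
        epsc_train_response(tpm_params(U_SE = u, tau_in = tau_in,
                                       tau_rec = tr, tau_f = tf),
                            cp, n_pulses = 2, rate = rate,
                            V_hold = V_hold)$ppr
      }, numeric(1))
      obj <- sum((resp$ratios - target_peak_ratios)^2) +
        (stats::var(pprs) - target_ppr_variance)^2
      if (obj < best$residual) {
        best <- list(tau_f = tf, tau_rec = tr, residual = obj,
                     ratios = resp$ratios, ppr_variance = stats::var(pprs),
                     peak1_unit_w = resp$peaks[1])
      }
    }
  }
  best$w0 <- target_peak1 / best$peak1_unit_w
  best$peak1_unit_w <- NULL
  best
}
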