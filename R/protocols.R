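#' Configuration of the spike-pairing plasticity protocol
#'
#' The pairing experiment: neuron 1 receives `n_spikes` suprathreshold
#' current pulses of amplitude `A1` at `rate` Hz; neuron 2 receives the
#' same train shifted rigidly by `dt` and scaled to amplitude `A2`.
#' For every `(dt, A2)` grid cell the release probability of the
#' synapse is drawn `n_draws` times from the condition's gamma
#' distribution and the relative weight change after the pairing is
#' averaged over draws.  The same release-probability sample set is
#' reused across all grid cells of a condition.
#'
#' Pulses are 10 ms wide: at 500 pA the presynaptic neuron fires exactly
#' once per pulse, while for the postsynaptic neuron the probed
#' 180-200 pA range stays a few millivolts short of threshold on its
#' own, so that spiking there requires synaptic assistance and the
#' protocol is sensitive to the release-probability draw (see the
#' methods vignette).
#'
#' @param A1 presynaptic pulse amplitude, pA.
#' @param A2_grid postsynaptic amplitudes, pA.
#' @param dt_grid train shifts, ms (positive: postsynaptic train later).
#' @param n_spikes pulses per train.
#' @param rate train rate, Hz.
#' @param n_draws release-probability draws per grid cell (`>= 1`).
#' @param seed integer seed for the draws.
#' @param condition label of the release-probability condition; one of
#'   `names(fm_gamma_fits())`.
#' @param pre_width,post_width pulse widths, ms.
#' @return An object of class `"pairing_config"`.
#' @export
pairing_config <- function(A1 = 500, A2_grid = seq(0, 400, by = 10),
                           dt_grid = seq(-50, 50, by = 5), n_spikes = 10,
                           rate = 20, n_draws = 200, seed = 1,
                           condition = "control", pre_width = 10,
                           post_width = 10) {
  stopifnot(length(A2_grid) >= 1, length(dt_grid) >= 1, n_draws >= 1,
            n_spikes >= 1, rate > 0)
  structure(list(A1 = A1, A2_grid = sort(A2_grid), dt_grid = sort(dt_grid),
                 n_spikes = n_spikes, rate = rate, n_draws = n_draws,
                 seed = as.integer(seed), condition = condition,
                 pre_width = pre_width, post_width = post_width),
            class = "pairing_config")
}

#' Run the spike-pairing plasticity protocol
#'
#' Simulates the two-neuron circuit with online STDP for every
#' `(dt, A2)` cell of the configuration grid and every release
#' probability draw, and fills the grid of mean relative weight changes
#' `(w_final - w0)/w0`.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [pairing_config()].
#' @param tpm a [tpm_params()]; its `U_SE` is replaced per draw.
#' @param lif a [lif_params()].
#' @param coupling a [coupling_params()].
#' @param stdp an [stdp_params()].
#' @param fit the release-probability [gamma_fit]; defaults to
#'   `fm_gamma_fits()[[cfg$condition]]`.
#' @param U_values optional fixed release-probability draws (overrides
#'   sampling; must have length `cfg$n_draws`).
#' @param dt_int integration step, ms.
#' @return An object of class `"pairing_result"`: a list with
#'   `mean_dw` (a `dt x A2` matrix of mean relative weight changes),
#'   `draws` (array `dt x A2 x n_draws`), `U_draws`, `cfg` and
#'   `condition`.
#' @seealso [ltp_threshold_A2()], [window_avg_max_dw()]
#' @export
run_pairing_protocol <- function(cfg, tpm = tpm_params(),
                                 lif = lif_params(),
                                 coupling = coupling_params(),
                                 stdp = stdp_params(), fit = NULL,
                                 U_values = NULL, dt_int = 0.05) {
  stopifnot(inherits(cfg, "pairing_config"))
  if (is.null(fit)) {
    fits <- fm_gamma_fits()
    if (!cfg$condition %in% names(fits))
      stop("unknown condition: ", cfg$condition)
    fit <- fits[[cfg$condition]]
  }
  if (is.null(U_values)) {
    U <- sample_release_prob(fit, cfg$n_draws, seed = cfg$seed)
  } else {
    stopifnot(length(U_values) == cfg$n_draws)
    U <- U_values
  }
  isi <- 1000 / cfg$rate
  offset <- max(0, -min(cfg$dt_grid)) + 10
  pre_on <- offset + (seq_len(cfg$n_spikes) - 1) * isi
  t_end <- offset + (cfg$n_spikes - 1) * isi + max(cfg$dt_grid, 0) +
    cfg$post_width + 120

  nd <- length(cfg$dt_grid)
  na <- length(cfg$A2_grid)
  draws <- array(NA_real_, dim = c(nd, na, cfg$n_draws),
                 dimnames = list(cfg$dt_grid, cfg$A2_grid, NULL))
  for (i in seq_len(nd)) {
    post_on <- pre_on + cfg$dt_grid[i]
    for (j in seq_len(na)) {
      draws[i, j, ] <- cpp_dw_batch(
        U, pre_on, post_on, cfg$pre_width, cfg$post_width,
        cfg$A1, cfg$A2_grid[j],
        tpm$tau_in, tpm$tau_rec, tpm$tau_f,
        lif$Cm, lif$Rm, lif$EL, lif$Vthre, lif$Vreset, lif$tau_ref,
        coupling$tau_syn_E, coupling$E_E,
        stdp$w0, stdp$lam, stdp$tau_plus, stdp$tau_minus, stdp$w_max,
        dt_int, t_end)
    }
  }
  mean_dw <- apply(draws, c(1, 2), mean)
  structure(list(mean_dw = mean_dw, draws = draws, U_draws = U,
                 cfg = cfg, condition = cfg$condition),
            class = "pairing_result")
}

#' Minimum postsynaptic current that evokes LTP
#'
#' For each train shift `dt`, the smallest `A2` on the grid whose mean
#' relative weight change exceeds the LTP criterion `eps`, and the
#' overall minimum across shifts.  Shifts (or grids) where no cell
#' exceeds the criterion yield `NA` rather than an error.
#'
#' @param result a [run_pairing_protocol()] result.
#' @param eps LTP criterion on the mean relative weight change.
#' @return A list with `per_dt` (named vector of thresholds, pA, `NA`
#'   where LTP is never evoked) and `overall` (the minimum across
#'   shifts, `NA` if LTP occurs nowhere).
#' @export
ltp_threshold_A2 <- function(result, eps = 0.01) {
  stopifnot(inherits(result, "pairing_result"))
  A2 <- result$cfg$A2_grid
  per_dt <- apply(result$mean_dw, 1, function(row) {
    hit <- which(row > eps)
    if (length(hit)) A2[min(hit)] else NA_real_
  })
  overall <- if (all(is.na(per_dt))) NA_real_ else min(per_dt, na.rm = TRUE)
  list(per_dt = per_dt, overall = overall)
}

#' Window-averaged maximum weight change
#'
#' For each train shift `dt`, the maximum mean relative weight change
#' over the postsynaptic amplitudes inside `A2_window`; those maxima
#' are then averaged across shifts.  This is the protocol's scalar
#' summary of how readily potentiation is expressed for near-threshold
#' postsynaptic drive.
#'
#' @param result a [run_pairing_protocol()] result.
#' @param A2_window inclusive amplitude window, pA.
#' @return The scalar average of per-shift maxima.
#' @export
window_avg_max_dw <- function(result, A2_window = c(180, 200)) {
  stopifnot(inherits(result, "pairing_result"), length(A2_window) == 2)
  A2 <- result$cfg$A2_grid
  in_win <- A2 >= min(A2_window) & A2 <= max(A2_window)
  if (!any(in_win))
    stop("A2_window does not intersect the A2 grid")
  mean(apply(result$mean_dw[, in_win, drop = FALSE], 1, max))
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("Pairing protocol result (%s)\n", x$condition))
  cat(sprintf("  grid: %d shifts x %d amplitudes, %d draws/cell\n",
              nrow(x$mean_dw), ncol(x$mean_dw), x$cfg$n_draws))
  thr <- ltp_threshold_A2(x)
  cat(sprintf("  min A2 for LTP: %s pA; window-avg max dw [180,200] pA: %.4f\n",
              format(thr$overall),
              tryCatch(window_avg_max_dw(x), error = function(e) NA)))
  invisible(x)
}

#' @export
plot.pairing_result <- function(x, ...) {
  graphics::image(x$cfg$dt_grid, x$cfg$A2_grid, x$mean_dw,
                  xlab = "train shift dt (ms)", ylab = "A2 (pA)",
                  main = sprintf("mean relative weight change (%s)",
                                 x$condition),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}

#' Configuration of the Poisson-train plasticity protocol
#'
#' Both neurons receive independent homogeneous Poisson trains of brief
#' near-threshold current pulses, a coincidence-driven spiking regime:
#' a single pulse does not reach threshold, spikes arise when pulses
#' cluster in time, and the postsynaptic neuron is additionally
#' recruited when a presynaptic release event lands on a charging pulse
#' — the channel through which the synapse's release probability
#' shapes the plasticity outcome.  Presynaptic spikes themselves are
#' chance coincidences, so the depression pathway (postsynaptic
#' cluster spikes pairing with earlier presynaptic spikes) is largely
#' insensitive to the release probability while the potentiation
#' pathway (release-assisted postsynaptic spikes) is gated by it.
#'
#' Across conditions within a trial the trains are identical, and the
#' per-trial release probabilities of the conditions are coupled
#' through a shared uniform variate mapped through each condition's
#' gamma quantile function, so differences between conditions reflect
#' the distributions and not sampling noise.
#'
#' @param rate Poisson event rate, Hz.
#' @param duration train duration, s.
#' @param pre_amplitude presynaptic pulse amplitude, pA.
#' @param post_amplitude postsynaptic pulse amplitude, pA.
#' @param pulse_width pulse width, ms (both trains).
#' @param n_trials number of independent trials.
#' @param seed integer seed.
#' @param conditions named list of [gamma_fit] release-probability
#'   distributions; defaults to [fm_gamma_fits()].
#' @return An object of class `"poisson_config"`.
#' @export
poisson_config <- function(rate = 10, duration = 10, pre_amplitude = 700,
                           post_amplitude = 450, pulse_width = 3,
                           n_trials = 500, seed = 1,
                           conditions = fm_gamma_fits()) {
  stopifnot(rate >= 0, duration > 0, n_trials >= 1,
            length(conditions) >= 1, !is.null(names(conditions)))
  structure(list(rate = rate, duration = duration,
                 pre_amplitude = pre_amplitude,
                 post_amplitude = post_amplitude,
                 pulse_width = pulse_width, n_trials = n_trials,
                 seed = as.integer(seed), conditions = conditions),
            class = "poisson_config")
}

#' Run the Poisson-train plasticity protocol
#'
#' For each trial, one Poisson pulse train per neuron (independent of
#' each other, shared across conditions); for each condition, a release
#' probability drawn from that condition's distribution; the circuit is
#' simulated with online STDP and the final relative weight change
#' recorded.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [poisson_config()].
#' @inheritParams run_pairing_protocol
#' @return An object of class `"poisson_result"`: a list with
#'   `final_dw` (matrix `n_trials x conditions` of relative weight
#'   changes), `U` (matching matrix of release probabilities) and
#'   `cfg`.
#' @seealso [plasticity_reduction()], [binned_relative_diff()]
#' @export
run_poisson_protocol <- function(cfg, tpm = tpm_params(),
                                 lif = lif_params(),
                                 coupling = coupling_params(),
                                 stdp = stdp_params(), dt_int = 0.05) {
  stopifnot(inherits(cfg, "poisson_config"))
  conds <- cfg$conditions
  nc <- length(conds)
  dur_ms <- cfg$duration * 1000
  t_end <- dur_ms + cfg$pulse_width + 120
  set.seed(cfg$seed)
  final_dw <- matrix(NA_real_, cfg$n_trials, nc,
                     dimnames = list(NULL, names(conds)))
  U_mat <- final_dw
  for (tr in seq_len(cfg$n_trials)) {
    pre <- poisson_train(cfg$rate, dur_ms, cfg$pre_amplitude,
                         cfg$pulse_width)
    post <- poisson_train(cfg$rate, dur_ms, cfg$post_amplitude,
                          cfg$pulse_width)
    v <- stats::runif(1)
    U <- vapply(conds, function(f)
      min(stats::qgamma(v, shape = f$k, scale = f$theta) / 140, 1),
      numeric(1))
    U_mat[tr, ] <- U
    final_dw[tr, ] <- cpp_dw_batch(
      U, pre$pulse_onsets, post$pulse_onsets,
      cfg$pulse_width, cfg$pulse_width,
      cfg$pre_amplitude, cfg$post_amplitude,
      tpm$tau_in, tpm$tau_rec, tpm$tau_f,
      lif$Cm, lif$Rm, lif$EL, lif$Vthre, lif$Vreset, lif$tau_ref,
      coupling$tau_syn_E, coupling$E_E,
      stdp$w0, stdp$lam, stdp$tau_plus, stdp$tau_minus, stdp$w_max,
      dt_int, t_end)
  }
  structure(list(final_dw = final_dw, U = U_mat, cfg = cfg),
            class = "poisson_result")
}

#' Sign-corrected reduction of plasticity relative to control
#'
#' The mean over trials of
#' `sign(dw_control) * (dw_control - dw_condition)`: positive when the
#' condition expresses less plasticity (weaker potentiation on trials
#' that potentiated under control, weaker depression on trials that
#' depressed).  `trials` restricts the average to potentiating
#' (`"ltp"`, `dw_control > 0`) or depressing (`"ltd"`) trials.
#'
#' @param result a [run_poisson_protocol()] result.
#' @param condition condition name (column of `result$final_dw`).
#' @param control name of the control column.
#' @param trials `"all"`, `"ltp"` or `"ltd"`.
#' @return The scalar reduction.
#' @export
#' @examples
#' # hand check of the definition:
#' r <- structure(list(final_dw = cbind(control = c(0.2, -0.2),
#'                                      AP5 = c(0.1, -0.1))),
#'                class = "poisson_result")
#' plasticity_reduction(r, "AP5")  # 0.1
plasticity_reduction <- function(result, condition, control = "control",
                                 trials = c("all", "ltp", "ltd")) {
  stopifnot(inherits(result, "poisson_result"))
  trials <- match.arg(trials)
  dw <- result$final_dw
  if (!condition %in% colnames(dw))
    stop("condition not present: ", condition)
  if (!control %in% colnames(dw))
    stop("control condition not present: ", control)
  dc <- dw[, control]
  keep <- switch(trials, all = rep(TRUE, length(dc)), ltp = dc > 0,
                 ltd = dc < 0)
  mean(sign(dc[keep]) * (dc[keep] - dw[keep, condition]))
}

#' Binned relative weight-change differences
#'
#' Bins the control-condition weight changes into `n_bins` equal-width
#' bins over their observed range and averages the per-trial difference
#' `dw_condition - dw_control` within each bin (the summary used to
#' display how plasticity expression shifts across the control
#' outcome range).
#'
#' @inheritParams plasticity_reduction
#' @param n_bins number of equal-width bins.
#' @return A data frame with `bin_mid`, `mean_diff` and `n`.
#' @export
binned_relative_diff <- function(result, condition, control = "control",
                                 n_bins = 20) {
  stopifnot(inherits(result, "poisson_result"), n_bins >= 1)
  dw <- result$final_dw
  if (!condition %in% colnames(dw))
    stop("condition not present: ", condition)
  dc <- dw[, control]
  diff <- dw[, condition] - dc
  br <- range(dc)
  if (diff(br) == 0) br <- br + c(-0.5, 0.5)
  breaks <- seq(br[1], br[2], length.out = n_bins + 1)
  idx <- findInterval(dc, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mid <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  data.frame(bin_mid = mid,
             mean_diff = vapply(seq_len(n_bins), function(b)
               if (any(idx == b)) mean(diff[idx == b]) else NA_real_,
               numeric(1)),
             n = tabulate(idx, n_bins))
}

#' @export
print.poisson_result <- function(x, ...) {
  cat("Poisson-train protocol result\n")
  cat(sprintf("  %d trials, %g Hz x %g s, conditions: %s\n",
              x$cfg$n_trials, x$cfg$rate, x$cfg$duration,
              paste(colnames(x$final_dw), collapse = ", ")))
  for (cn in setdiff(colnames(x$final_dw), "control"))
    cat(sprintf("  plasticity reduction (%s): %.4f\n", cn,
                plasticity_reduction(x, cn)))
  invisible(x)
}
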