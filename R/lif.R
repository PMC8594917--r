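#' Advance a LIF neuron by one time step
#'
#' One forward-Euler step of the leaky integrate-and-fire membrane with
#' leak, injected current and excitatory synaptic current
#' `I_E = gE * (E_E - Vm)`.  The synaptic conductance then decays by its
#' exact exponential factor.  If the membrane reaches threshold at the
#' end of the step, a spike is recorded at `t + dt`, the membrane is
#' reset and held at `Vreset` for the refractory period.
#'
#' Units: `Vm` mV, currents pA, conductances nS (the leak conductance is
#' `1000 / Rm[MOhm]` nS).
#'
#' @param state a [neuron_state()].
#' @param params a [lif_params()].
#' @param coupling a [coupling_params()] (conductance kinetics).
#' @param I_stim injected current over the step, pA.
#' @param dt time step, ms (`> 0`).
#' @param t time at the start of the step, ms.
#' @return A list with `state` (the updated [neuron_state()]) and
#'   `spiked` (logical).
#' @export
#' @examples
#' s <- neuron_state(Vm = -65)
#' lif_step(s, lif_params(), coupling_params(), I_stim = 0, dt = 0.05)$spiked
lif_step <- function(state, params, coupling, I_stim, dt, t = 0) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "lif_params"),
            dt > 0)
  gL <- 1000 / params$Rm
  Vm <- state$Vm
  if (t >= state$refractory_until) {
    Vm <- Vm + dt * (-(Vm - params$EL) * gL + I_stim +
                       state$gE * (coupling$E_E - Vm)) / params$Cm
  } else {
    Vm <- params$Vreset
  }
  gE <- state$gE * exp(-dt / coupling$tau_syn_E)
  t_next <- t + dt
  spiked <- (t >= state$refractory_until) && (Vm >= params$Vthre)
  ref <- state$refractory_until
  spikes <- state$spike_times
  if (spiked) {
    Vm <- params$Vreset
    ref <- t_next + params$tau_ref
    spikes <- c(spikes, t_next)
  }
  list(state = neuron_state(Vm = Vm, gE = gE, refractory_until = ref,
                            spike_times = spikes),
       spiked = spiked)
}

#' Simulate the two-neuron TPM/STDP circuit
#'
#' Integrates the full model: neuron 1 (presynaptic) and neuron 2
#' (postsynaptic) are leaky integrate-and-fire neurons driven by
#' rectangular current-pulse trains; a TPM synapse connects neuron 1 to
#' neuron 2, its conductance jumping by `w * u0+ * x0-` at each
#' presynaptic spike; an optional soft-bounded STDP rule updates the
#' weight online from the spike pairings.  Membrane potentials advance
#' by forward Euler; all synaptic decays use their exact exponential
#' solutions (implemented in C++).
#'
#' @param pre_stim,post_stim [stimulus_train()]s for neurons 1 and 2.
#' @param tpm a [tpm_params()].
#' @param lif a [lif_params()] (shared by both neurons).
#' @param coupling a [coupling_params()]; `coupling$w` is the initial
#'   weight (overridden by `stdp$w0` when `stdp` is supplied).
#' @param stdp a [stdp_params()], or `NULL` for a fixed weight.
#' @param dt integration step, ms.  Rejected if larger than one tenth of
#'   the smallest model time constant.
#' @param t_end simulation end time, ms (defaults to cover both trains).
#' @param record_every record the state trace every this many steps
#'   (`0` to skip trace recording).
#' @return An object of class `"pair_sim"`: a list with `pre_spikes`,
#'   `post_spikes` (ms), `w0`, `w_final`, `dw_rel`
#'   (`(w_final - w0)/w0`) and, if recorded, `traces` (a data frame with
#'   columns `t, Vm1, Vm2, gE, x0, x1, x2, u0, w`).
#' @export
#' @examples
#' pre <- regular_train(10, 20, amplitude = 500)
#' sim <- simulate_pair(pre, stimulus_train(numeric(0), 0),
#'                      tpm_params(), lif_params(), coupling_params())
#' length(sim$pre_spikes)  # one spike per pulse
simulate_pair <- function(pre_stim, post_stim, tpm, lif, coupling,
                          stdp = NULL, dt = 0.05, t_end = NULL,
                          record_every = 0) {
  stopifnot(inherits(pre_stim, "stimulus_train"),
            inherits(post_stim, "stimulus_train"),
            inherits(tpm, "tpm_params"), inherits(lif, "lif_params"),
            inherits(coupling, "coupling_params"))
  tau_min <- min(tpm$tau_in, tpm$tau_rec, tpm$tau_f,
                 lif$Cm * lif$Rm / 1000, coupling$tau_syn_E)
  if (dt > tau_min / 10)
    stop(sprintf(paste0("dt = %g ms is unstable: it exceeds one tenth of ",
                        "the smallest time constant (%g ms)"), dt, tau_min))
  if (is.null(t_end)) {
    last <- max(c(pre_stim$pulse_onsets + pre_stim$pulse_width,
                  post_stim$pulse_onsets + post_stim$pulse_width, 0))
    t_end <- last + 100
  }
  if (length(pre_stim$pulse_onsets) && min(pre_stim$pulse_onsets) < 0 ||
      length(post_stim$pulse_onsets) && min(post_stim$pulse_onsets) < 0)
    stop("pulse onsets must lie in [0, t_end]")
  stdp_on <- !is.null(stdp)
  if (stdp_on) stopifnot(inherits(stdp, "stdp_params"))
  w0 <- if (stdp_on) stdp$w0 else coupling$w
  out <- cpp_simulate_pair(
    pre_stim$pulse_onsets, post_stim$pulse_onsets,
    pre_stim$pulse_width, post_stim$pulse_width,
    pre_stim$amplitude, post_stim$amplitude,
    tpm$U_SE, tpm$tau_in, tpm$tau_rec, tpm$tau_f,
    lif$Cm, lif$Rm, lif$EL, lif$Vthre, lif$Vreset, lif$tau_ref,
    coupling$tau_syn_E, coupling$E_E, w0,
    stdp_on,
    if (stdp_on) stdp$lam else 0,
    if (stdp_on) stdp$tau_plus else 1,
    if (stdp_on) stdp$tau_minus else 1,
    if (stdp_on) stdp$w_max else w0,
    dt, t_end, as.integer(record_every))
  res <- list(pre_spikes = out$pre_spikes, post_spikes = out$post_spikes,
              w0 = w0, w_final = out$w_final,
              dw_rel = (out$w_final - w0) / w0,
              dt = dt, t_end = t_end)
  if (record_every > 0) {
    tr <- as.data.frame(out$traces)
    names(tr) <- c("t", "Vm1", "Vm2", "gE", "x0", "x1", "x2", "u0", "w")
    res$traces <- tr
  }
  class(res) <- "pair_sim"
  res
}

#' @export
print.pair_sim <- function(x, ...) {
  cat("Two-neuron TPM/STDP simulation\n")
  cat(sprintf("  %d presynaptic, %d postsynaptic spikes over %g ms\n",
              length(x$pre_spikes), length(x$post_spikes), x$t_end))
  cat(sprintf("  w: %.4g -> %.4g nS (relative change %+.3f)\n",
              x$w0, x$w_final, x$dw_rel))
  invisible(x)
}
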