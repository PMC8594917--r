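#' Tsodyks-Pawelzik-Markram synapse parameters
#'
#' Kinetic constants of the short-term plasticity model.  `U_SE` is the
#' resting release probability (the utilization jump at a spike), `tau_in`
#' the neurotransmitter-release (inactivation) time constant, `tau_rec`
#' the recovery time constant and `tau_f` the facilitation time constant.
#'
#' Defaults: `tau_in = 3` ms; `tau_f = 50` ms and `tau_rec = 50` ms, a
#' weakly facilitating, fast-recovering regime in which the released
#' fraction tracks the synapse's release probability on every pulse of a
#' 20 Hz train (the regime the plasticity protocols probe; see
#' [calibrate_tpm()] and the methods vignette); `U_SE = 0.265`, the mean
#' of the control release-probability distribution ([fm_gamma_fits()]).
#'
#' @param U_SE release probability in `[0, 1]`.
#' @param tau_in,tau_rec,tau_f time constants, ms (all `> 0`).
#' @return An object of class `"tpm_params"`.
#' @seealso [tpm_state()], [tpm_spike_update()], [tpm_decay_step()]
#' @export
#' @examples
#' tpm_params(U_SE = 0.3)
tpm_params <- function(U_SE = 0.265, tau_in = 3, tau_rec = 50,
                       tau_f = 50) {
  stopifnot(is.numeric(U_SE), length(U_SE) == 1L, U_SE >= 0, U_SE <= 1,
            tau_in > 0, tau_rec > 0, tau_f > 0)
  structure(list(U_SE = U_SE, tau_in = tau_in, tau_rec = tau_rec,
                 tau_f = tau_f),
            class = "tpm_params")
}

#' Tsodyks-Pawelzik-Markram synapse state
#'
#' Resource fractions of the synapse: `x0` available, `x1` released
#' (active), `x2` recovering, with `x0 + x1 + x2 = 1` at all times, plus
#' the utilization variable `u0` and the current time `t` (ms).
#'
#' @param x0,x1,x2 resource fractions in `[0, 1]`, summing to 1.
#' @param u0 utilization in `[0, 1]`.
#' @param t current time, ms.
#' @return An object of class `"tpm_state"`.
#' @export
#' @examples
#' tpm_state()  # rest: all resources available
tpm_state <- function(x0 = 1, x1 = 0, x2 = 0, u0 = 0, t = 0) {
  stopifnot(x0 >= 0, x1 >= 0, x2 >= 0, x0 <= 1, x1 <= 1, x2 <= 1,
            u0 >= 0, u0 <= 1)
  if (abs(x0 + x1 + x2 - 1) > 1e-9)
    stop("resource fractions must sum to 1 (got ", x0 + x1 + x2, ")")
  structure(list(x0 = x0, x1 = x1, x2 = x2, u0 = u0, t = t),
            class = "tpm_state")
}

#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane constants of the point-neuron model.  The defaults give a
#' membrane time constant `Rm * Cm = 15` ms.  The reset potential is not
#' independently constrained by the model and defaults to the leak
#' reversal.
#'
#' @param Cm membrane capacitance, pF.
#' @param Rm membrane resistance, MOhm.
#' @param EL leak reversal potential, mV.
#' @param Vthre spike threshold, mV (must exceed `EL`).
#' @param Vreset post-spike reset potential, mV.
#' @param tau_ref absolute refractory period, ms.
#' @return An object of class `"lif_params"`.
#' @export
#' @examples
#' p <- lif_params()
#' p$Rm * p$Cm / 1000  # membrane time constant, ms
lif_params <- function(Cm = 150, Rm = 100, EL = -65, Vthre = -50,
                       Vreset = EL, tau_ref = 2) {
  stopifnot(Cm > 0, Rm > 0, Vthre > EL, tau_ref >= 0)
  structure(list(Cm = Cm, Rm = Rm, EL = EL, Vthre = Vthre,
                 Vreset = Vreset, tau_ref = tau_ref),
            class = "lif_params")
}

#' Synaptic coupling parameters
#'
#' Excitatory conductance kinetics and weight of the connection from
#' neuron 1 onto neuron 2.  On each presynaptic spike the conductance
#' jumps by `w * u0+ * x0-` (the released fraction scaled by the weight;
#' the `1/tau_syn_E` factor of the conductance equation's delta term is
#' absorbed into `w`, which is a calibrated constant).
#'
#' The default `w = 16` nS calibrates the synapse to span sub- to
#' supra-threshold influence over the postsynaptic neuron: a
#' maximal-release event (`U_SE` near 1) depolarizes the 15 ms membrane
#' by about 12 mV — enough to bridge a near-rheobase depolarization to
#' spike threshold — while a mean-release event (about 0.26) moves it
#' only about 3 mV.  This is the regime in which release-probability
#' diversity can gate spike-timing-dependent plasticity (see the
#' methods vignette).
#'
#' @param tau_syn_E excitatory conductance decay time constant, ms.
#' @param E_E excitatory reversal potential, mV.
#' @param w synaptic weight, nS (`>= 0`).
#' @return An object of class `"coupling_params"`.
#' @export
coupling_params <- function(tau_syn_E = 3, E_E = 0, w = 16) {
  stopifnot(tau_syn_E > 0, w >= 0)
  structure(list(tau_syn_E = tau_syn_E, E_E = E_E, w = w),
            class = "coupling_params")
}

#' LIF neuron state
#'
#' @param Vm membrane potential, mV.
#' @param gE excitatory conductance, nS (`>= 0`).
#' @param refractory_until end of the current refractory period, ms.
#' @param spike_times strictly increasing spike times, ms.
#' @return An object of class `"neuron_state"`.
#' @export
neuron_state <- function(Vm = -65, gE = 0, refractory_until = -Inf,
                         spike_times = numeric(0)) {
  stopifnot(gE >= 0)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike_times must be strictly increasing")
  structure(list(Vm = Vm, gE = gE, refractory_until = refractory_until,
                 spike_times = spike_times),
            class = "neuron_state")
}

#' Rectangular current-pulse train
#'
#' A stimulus made of rectangular current pulses of fixed amplitude and
#' width starting at the given onsets.
#'
#' @param pulse_onsets non-decreasing pulse onset times, ms.
#' @param amplitude pulse amplitude, pA.
#' @param pulse_width pulse width, ms (`> 0`).
#' @return An object of class `"stimulus_train"`.
#' @seealso [regular_train()], [poisson_train()]
#' @export
stimulus_train <- function(pulse_onsets, amplitude, pulse_width = 10) {
  stopifnot(is.numeric(pulse_onsets), pulse_width > 0,
            is.numeric(amplitude), length(amplitude) == 1L)
  if (is.unsorted(pulse_onsets)) stop("pulse_onsets must be non-decreasing")
  structure(list(pulse_onsets = as.numeric(pulse_onsets),
                 amplitude = amplitude, pulse_width = pulse_width),
            class = "stimulus_train")
}

#' Regular pulse train at a fixed rate
#'
#' @param n_pulses number of pulses.
#' @param rate pulse rate, Hz.
#' @param amplitude pulse amplitude, pA.
#' @param pulse_width pulse width, ms.
#' @param t_start onset of the first pulse, ms.
#' @return A [stimulus_train()].
#' @export
#' @examples
#' regular_train(10, rate = 20, amplitude = 500)  # 10 pulses, 50 ms apart
regular_train <- function(n_pulses, rate, amplitude, pulse_width = 10,
                          t_start = 0) {
  stopifnot(n_pulses >= 1, rate > 0)
  onsets <- t_start + (seq_len(n_pulses) - 1) * 1000 / rate
  stimulus_train(onsets, amplitude, pulse_width)
}

#' Homogeneous Poisson pulse train
#'
#' Pulse onsets drawn from a homogeneous Poisson process; uses R's RNG,
#' so call `set.seed()` for reproducibility.
#'
#' @param rate event rate, Hz.
#' @param duration train duration, ms.
#' @param amplitude pulse amplitude, pA.
#' @param pulse_width pulse width, ms.
#' @param t_start start of the observation window, ms.
#' @return A [stimulus_train()].
#' @export
poisson_train <- function(rate, duration, amplitude, pulse_width = 10,
                          t_start = 0) {
  stopifnot(rate >= 0, duration > 0)
  n <- stats::rpois(1L, rate * duration / 1000)
  onsets <- sort(stats::runif(n, 0, duration)) + t_start
  stimulus_train(onsets, amplitude, pulse_width)
}

#' STDP rule parameters
#'
#' Constants of the soft-bounded additive spike-timing-dependent
#' plasticity rule: potentiation `dw = lam * (w_max - w) *
#' exp(-(t_post - t_pre)/tau_plus)` for a post-after-pre pairing and
#' depression `dw = -lam * w * exp(-(t_pre - t_post)/tau_minus)` for a
#' pre-after-post pairing.  Exactly coincident spikes contribute zero.
#'
#' @param lam learning rate (dimensionless, `> 0`).
#' @param tau_plus,tau_minus potentiation/depression windows, ms.
#' @param w0 initial weight, nS.
#' @param w_max weight ceiling, nS; defaults to `2 * w0`.
#' @return An object of class `"stdp_params"`.
#' @export
#' @examples
#' stdp_params()  # lam = 0.1, 20 ms windows, w_max = 2 w0
stdp_params <- function(lam = 0.1, tau_plus = 20, tau_minus = 20,
                        w0 = 16, w_max = 2 * w0) {
  stopifnot(lam > 0, tau_plus > 0, tau_minus > 0, w0 > 0, w_max > w0)
  structure(list(lam = lam, tau_plus = tau_plus, tau_minus = tau_minus,
                 w0 = w0, w_max = w_max),
            class = "stdp_params")
}

#' @export
print.tpm_params <- function(x, ...) {
  cat("TPM synapse parameters\n")
  cat(sprintf("  U_SE = %.4g, tau_in = %g ms, tau_rec = %g ms, tau_f = %g ms\n",
              x$U_SE, x$tau_in, x$tau_rec, x$tau_f))
  invisible(x)
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF neuron parameters\n")
  cat(sprintf("  Cm = %g pF, Rm = %g MOhm (tau_m = %g ms)\n",
              x$Cm, x$Rm, x$Cm * x$Rm / 1000))
  cat(sprintf("  EL = %g mV, Vthre = %g mV, Vreset = %g mV, tau_ref = %g ms\n",
              x$EL, x$Vthre, x$Vreset, x$tau_ref))
  invisible(x)
}

#' Read or write model constants as a YAML config
#'
#' Serialises the full set of model constants (TPM, LIF, coupling, STDP)
#' to a YAML file and back, so that simulation runs can be configured
#' from a plain-text file.
#'
#' @param tpm,lif,coupling,stdp parameter objects (defaults used if missing).
#' @param path file path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a list with elements `tpm`, `lif`,
#'   `coupling`, `stdp`.
#' @export
write_model_config <- function(path, tpm = tpm_params(), lif = lif_params(),
                               coupling = coupling_params(),
                               stdp = stdp_params()) {
  cfg <- list(tpm = unclass(tpm), lif = unclass(lif),
              coupling = unclass(coupling), stdp = unclass(stdp))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(tpm = do.call(tpm_params, cfg$tpm),
       lif = do.call(lif_params, cfg$lif),
       coupling = do.call(coupling_params, cfg$coupling),
       stdp = do.call(stdp_params, cfg$stdp))
}
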