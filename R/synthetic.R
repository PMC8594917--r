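#' Design of a synthetic paired-pulse experiment
#'
#' Generative model emulating the statistical structure of paired-pulse
#' recordings from converging Schaffer-collateral inputs: each input's
#' release probability is drawn from a gamma signal distribution; sweep
#' amplitudes are quantal-binomial (release sites of fixed
#' `quantal_size`, the site count set per input so the mean first EPSC
#' matches the recording's working amplitude) plus Gaussian recording
#' noise; the second pulse's
#' release probability follows the TPM two-pulse response at 50 ms; the
#' drug period linearly shrinks each input's release probability toward
#' the population mean (`drug_shrink = 1` leaves it untouched — a null
#' experiment; `drug_shrink = 0` collapses the population to its mean —
#' variance down, mean unchanged).
#'
#' @param n_inputs number of inputs.
#' @param n_sweeps_per_period sweeps per period.
#' @param quantal_size quantal amplitude, pA.
#' @param n_sites release sites per input when `target_epsc1` is `NA`.
#' @param noise_sd Gaussian recording noise SD, pA.
#' @param drug_shrink shrink factor in `[0, 1]`.
#' @param seed integer seed.
#' @param use_distribution the release-probability [gamma_fit];
#'   defaults to the control FM1-43 fit.
#' @param target_epsc1 target mean first-EPSC amplitude, pA.  Recordings
#'   adjust the stimulation strength per input until the EPSC reaches a
#'   working amplitude, so the recruited site count — not the
#'   amplitude — varies with release probability; the generator
#'   emulates this by setting each input's site count to
#'   `target_epsc1 / (quantal_size * p1)`.  Set to `NA` to use a fixed
#'   `n_sites` instead (amplitudes then scale with release
#'   probability, and low-release inputs give noisy ratio estimates).
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(n_inputs = 30, n_sweeps_per_period = 20,
                              quantal_size = 10, n_sites = 10,
                              noise_sd = 2, drug_shrink = 0.5, seed = 1,
                              use_distribution = fm_gamma_fits()$control,
                              target_epsc1 = 80) {
  stopifnot(n_inputs >= 1, n_sweeps_per_period >= 1, n_sites >= 1,
            quantal_size > 0, noise_sd >= 0,
            drug_shrink >= 0, drug_shrink <= 1,
            inherits(use_distribution, "gamma_fit"),
            is.na(target_epsc1) || target_epsc1 > 0)
  structure(list(n_inputs = n_inputs,
                 n_sweeps_per_period = n_sweeps_per_period,
                 quantal_size = quantal_size, n_sites = n_sites,
                 noise_sd = noise_sd, drug_shrink = drug_shrink,
                 seed = as.integer(seed),
                 use_distribution = use_distribution,
                 target_epsc1 = target_epsc1),
            class = "experiment_design")
}

#' Generate FM1-43-like signal samples
#'
#' Draws `n` signals from the gamma distribution of a fit — the
#' generative stand-in for FM1-43 readily-releasable-pool measurements
#' (dye loaded by 40 action potentials at 20 Hz, one signal per
#' punctum).
#'
#' @param fit a [gamma_fit].
#' @param n number of signals (`>= 1`).
#' @param seed optional integer seed.
#' @return A vector of `n` positive signal values.
#' @export
#' @examples
#' z <- gen_fm_signals(fm_gamma_fits()$control, 1000, seed = 1)
#' mean(z)  # near k * theta = 37.1
gen_fm_signals <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "gamma_fit"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = fit$k, scale = fit$theta)
}

# TPM two-pulse released fractions at a given inter-pulse interval
tpm_two_pulse_release <- function(U, tpm_template, isi = 50) {
  p <- tpm_params(U_SE = U, tau_in = tpm_template$tau_in,
                  tau_rec = tpm_template$tau_rec,
                  tau_f = tpm_template$tau_f)
  up1 <- tpm_spike_update(tpm_state(), p)
  st <- tpm_decay_step(up1$state, p, isi)
  up2 <- tpm_spike_update(st, p)
  c(rel1 = up1$released, rel2 = up2$released)
}

#' Generate a synthetic paired-pulse EPSC experiment
#'
#' Per input, a release probability `U` is sampled from the design's
#' signal distribution; per sweep, the first EPSC amplitude is
#' `quantal_size * Binomial(n_sites, p1) + noise` (with the input's
#' site count set by the design's `target_epsc1`) and the second uses
#' the TPM two-pulse released fraction at 50 ms as its release
#' probability (so the expected PPR is exactly the TPM prediction).
#' For the drug period each input's `U` is shrunk linearly toward the
#' population mean: `U' = m + drug_shrink * (U - m)` with `m` the
#' distribution mean, and the amplitudes are regenerated.  Amplitudes
#' are floored at 0.1 pA (a detection floor, so recorded magnitudes
#' stay positive).
#'
#' @param design an [experiment_design()].
#' @param tpm_template a [tpm_params()] supplying the kinetic
#'   constants.
#' @param isi inter-pulse interval, ms.
#' @return A list with `sweeps` (the full sweep table: columns `sweep`,
#'   `epsc1`, `epsc2`, `input_id`, `period`) and `truth` (ground-truth
#'   record: per-input `U_baseline`, `U_drug`, and noiseless
#'   `ppr_baseline`, `ppr_drug` from the TPM recursion).
#' @export
#' @examples
#' ex <- gen_epsc_experiment(experiment_design(n_inputs = 4, seed = 2))
#' head(ex$sweeps)
gen_epsc_experiment <- function(design, tpm_template = tpm_params(),
                                isi = 50) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(tpm_template, "tpm_params"))
  set.seed(design$seed)
  fit <- design$use_distribution
  U_base <- sample_release_prob(fit, design$n_inputs)
  m <- min(fit$k * fit$theta / 140, 1)  # population mean release prob
  U_drug <- pmin(pmax(m + design$drug_shrink * (U_base - m), 0), 1)

  gen_period <- function(U, period, input_id) {
    rel <- tpm_two_pulse_release(U, tpm_template, isi)
    ns <- design$n_sweeps_per_period
    q <- design$quantal_size
    n_sites <- if (is.na(design$target_epsc1)) design$n_sites else
      max(1L, as.integer(round(design$target_epsc1 / (q * rel[["rel1"]]))))
    e1 <- q * stats::rbinom(ns, n_sites, rel[["rel1"]]) +
      stats::rnorm(ns, 0, design$noise_sd)
    e2 <- q * stats::rbinom(ns, n_sites, rel[["rel2"]]) +
      stats::rnorm(ns, 0, design$noise_sd)
    sweep_series(seq_len(ns), pmax(e1, 0.1), pmax(e2, 0.1),
                 input_id = input_id, period = period)
  }
  pieces <- vector("list", 2 * design$n_inputs)
  ppr_base <- ppr_drug <- numeric(design$n_inputs)
  for (i in seq_len(design$n_inputs)) {
    id <- sprintf("input%02d", i)
    pieces[[2 * i - 1]] <- gen_period(U_base[i], "baseline", id)
    pieces[[2 * i]] <- gen_period(U_drug[i], "drug", id)
    rb <- tpm_two_pulse_release(U_base[i], tpm_template, isi)
    rd <- tpm_two_pulse_release(U_drug[i], tpm_template, isi)
    ppr_base[i] <- rb[["rel2"]] / rb[["rel1"]]
    ppr_drug[i] <- rd[["rel2"]] / rd[["rel1"]]
  }
  sweeps <- do.call(rbind, pieces)
  list(sweeps = sweeps,
       truth = list(U_baseline = U_base, U_drug = U_drug,
                    ppr_baseline = ppr_base, ppr_drug = ppr_drug,
                    population_mean_U = m))
}
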