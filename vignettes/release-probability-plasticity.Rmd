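---
title: "Release-probability heterogeneity and the expression of STDP"
author: "synstdp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Release-probability heterogeneity and the expression of STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstdp)
```

## The scientific question

Glutamatergic synapses on a hippocampal CA1 pyramidal neuron differ
widely in presynaptic release probability, and that diversity is itself
regulated: pharmacological or genetic interference with astrocytic
NMDA-receptor signalling narrows the population distribution of
paired-pulse ratios (PPR, the amplitude ratio of two EPSCs evoked 50 ms
apart, inversely related to release probability) without changing its
mean — strong inputs weaken and weak inputs strengthen.  `synstdp`
implements the computational side of that line of work: a model of a
single plastic synapse between two spiking neurons, the
release-probability distributions estimated from FM1-43
readily-releasable-pool imaging, two in-silico plasticity protocols
that ask how the *width* of the release-probability distribution
affects the expression of spike-timing-dependent plasticity (STDP),
and the statistical pipeline used on paired-pulse recordings, together
with a synthetic-data generator so every stage can be tested end to
end.

## The synapse and neuron model

Short-term synaptic dynamics follow the Tsodyks–Pawelzik–Markram (TPM)
resource model.  The neurotransmitter resource is split into an
available fraction $x_0$, an active (just released) fraction $x_1$ and
a recovering fraction $x_2$, with $x_0+x_1+x_2=1$.  Between spikes

$$\dot x_1 = -x_1/\tau_{in},\qquad
  \dot x_2 = x_1/\tau_{in} - x_2/\tau_{rec},\qquad
  \dot u_0 = -u_0/\tau_f,$$

and at each presynaptic spike the utilization $u_0$ first jumps by
facilitation, $u_0^+ = u_0^- + U_{SE}(1-u_0^-)$, after which the
fraction $u_0^+ x_0^-$ is released from $x_0$ into $x_1$.  $U_{SE}$ is
the synapse's release probability, the quantity whose population
distribution is at issue.

Both neurons are leaky integrate-and-fire (LIF) units,

$$C_m \dot V_m = -(V_m - E_L)/R_m + I_{stim} + g_E (E_E - V_m),$$

with $C_m = 150$ pF, $R_m = 100$ MΩ (membrane time constant 15 ms),
$E_L = -65$ mV, threshold $-50$ mV, refractory period 2 ms, and the
reset potential set to $E_L$ (a conventional choice; the model does not
constrain it otherwise).  The excitatory conductance decays with
$\tau_{syn,E} = 3$ ms and $E_E = 0$ mV, and jumps by
$w\,u_0^+ x_0^-$ at each presynaptic spike.  The $1/\tau_{syn,E}$
factor that formally accompanies the delta term of the conductance
equation is absorbed into the weight $w$, which is a calibrated
constant anyway; only relative weight changes are ever reported.

The weight itself evolves under a soft-bounded additive STDP rule: for
a pre-at-$t_{pre}$/post-at-$t_{post}$ pairing,

$$\Delta w = \begin{cases}
  \lambda\,(w_{max}-w)\,e^{-(t_{post}-t_{pre})/\tau_+} & t_{post}>t_{pre}\\
  -\lambda\,w\,e^{-(t_{pre}-t_{post})/\tau_-} & t_{post}<t_{pre},
\end{cases}$$

with $\lambda = 0.1$, $\tau_+=\tau_-=20$ ms and $w_{max}=2w_0$; the
depression branch carries the negative sign of the classical additive
rule (potentiation for causal pairings, depression for anti-causal
ones), and exactly coincident spikes contribute nothing.  Pairing is
all-to-all, implemented with exponential pre/post traces processed in
time order (`apply_stdp_online()` also offers a nearest-neighbour
variant, where the opposite trace saturates at one).

### Integration scheme

`simulate_pair()` advances the coupled system with forward Euler on
the membrane potentials at `dt = 0.05` ms, while every first-order
decay — $x_1$, $x_2$, $u_0$, $g_E$ and the STDP traces — is advanced
by its exact exponential solution, so the synaptic state carries no
step-size error and resource conservation holds to $10^{-9}$ over
arbitrary simulations.  Within a step the event order at a presynaptic
spike is: facilitation jump, release, conductance jump, then decay
resumes.  Spikes are detected at step ends; the membrane is clamped to
the reset value for the refractory period.  Steps larger than one
tenth of the smallest time constant are rejected with a diagnostic,
and halving `dt` changes protocol outputs by well under 1 %.

## Release-probability distributions

Readily-releasable-pool estimates from FM1-43 destaining (one signal
$z$ per punctum, arbitrary fluorescence units) are modelled with a
gamma density

$$P(z; k, \theta) = \frac{1}{\Gamma(k)\,\theta^k} z^{k-1} e^{-z/\theta},$$

fitted by maximum likelihood.  `fit_gamma_mle()` profiles the scale
out analytically ($\hat\theta = \bar z / k$ at the optimum) and solves
a robust one-dimensional problem in $k$;
`fit_gamma_mle_fixed_mean()` maximises over the one-parameter family
$\theta = m/k$ so the fitted mean equals $m$ exactly.  The three
distributions the protocols use are built in
(`fm_gamma_fits()`):

```{r}
sapply(fm_gamma_fits(), function(f)
  c(k = f$k, theta = f$theta, mean_U = f$k * f$theta / 140))
```

The control condition is wide; the AP5 (NMDA-receptor-blocked)
condition is narrower with a slightly lower mean; the
`AP5_with_control_mean` refit pins the mean to the control value so
that only the width differs — the clean comparison for asking whether
the width per se matters.  Signals map to release probabilities as
$U_{SE} = z/140$, 140 being the maximal observed signal; the tiny tail
mass beyond 140 is clipped to $U_{SE}=1$ by default
(`sample_release_prob(..., tail = "resample")` redraws it instead —
the choice is immaterial at these parameter values, affecting ~2 % of
control draws).

## Calibration of the free constants

The LIF and STDP constants above are fixed; the constants the model
does not pin down are $\tau_f$, $\tau_{rec}$, the weight scale $w_0$
and the stimulus pulse geometry.  `calibrate_tpm()` implements the
generic calibration: a grid search over $(\tau_f, \tau_{rec})$ against
target 20 Hz EPSC peak ratios and the PPR variance under the release
distribution, with $w_0$ solved analytically from an absolute
first-peak target (every peak is proportional to $w$, so ratios and
variances cannot identify it).

The package defaults are a calibration to the operating regime the
plasticity protocols require, chosen as follows and then frozen:

* **Pulse geometry.** Stimulus "spikes" are 10 ms rectangles.  At
  $A_1 = 500$ pA the presynaptic neuron fires exactly once per pulse.
  For the postsynaptic neuron, a 10 ms pulse of amplitude $A_2$
  depolarises by $A_2 R_m (1 - e^{-10/15})/1000 \approx 0.049\,A_2$ mV,
  so the 180–200 pA range probed by the pairing protocol ends 4–6 mV
  short of threshold on its own.  Postsynaptic spiking there requires
  synaptic assistance — which is precisely what makes the protocol
  sensitive to the release-probability draw.
* **Weight scale.** $w_0 = 16$ nS, so that a maximal-release event
  ($U_{SE}\to 1$) produces a somatic EPSP of ~12 mV — able to bridge a
  near-rheobase depolarisation to threshold — while a mean-release
  event (~0.26) moves the membrane only ~3 mV.  Only upper-tail
  release probabilities can convert near-threshold drive into spikes,
  so the distributions' upper tails, where the control and AP5
  conditions differ most, govern LTP expression.  (A much smaller
  $w_0$ leaves the synapse irrelevant to postsynaptic spiking and all
  three conditions behave identically; a much larger one makes the
  task so easy that the bulk of every distribution succeeds and the
  comparison degenerates.)
* **Kinetics.** $\tau_f = \tau_{rec} = 50$ ms with
  $\tau_{in} = 3$ ms: a weakly facilitating, fast-recovering synapse
  whose released fraction tracks $U_{SE}$ on every pulse of a 20 Hz
  train (mean-release PPR at 50 ms ≈ 1.15, monotonically decreasing
  in $U_{SE}$).  Strongly facilitating or strongly depressing kinetics
  both erode the link between the drawn $U_{SE}$ and the train-long
  release, which is the quantity the protocols must discriminate.

## The pairing protocol

`run_pairing_protocol()` pairs 10 presynaptic spikes at 20 Hz
($A_1 = 500$ pA) with a postsynaptic train shifted rigidly by
$\Delta t$ and scaled to $A_2$.  For each $(\Delta t, A_2)$ cell the
release probability is drawn `n_draws = 200` times from the
condition's distribution (the identical draw set reused across all
cells of a condition), and the mean relative weight change
$(w_{final}-w_0)/w_0$ fills the grid.  Defaults cover
$\Delta t \in [-50, 50]$ ms in 5 ms steps and
$A_2 \in [0, 400]$ pA in 10 pA steps; the test suite and the
acceptance script use the coarser
$\Delta t \in \{-40,\dots,40\}$ ms step 10 / $A_2$ step 20 grid, which
resolves the same pattern at a quarter of the cost.

Two summaries mirror the figures of interest:
`ltp_threshold_A2()` reports, per $\Delta t$ and overall, the smallest
$A_2$ whose mean weight change exceeds the LTP criterion
$\varepsilon = 0.01$ (a grid without any LTP yields an `NA` sentinel,
not an error; ties resolve to the first grid crossing), and
`window_avg_max_dw()` averages across $\Delta t$ the per-shift maximum
over $A_2 \in [180, 200]$ pA.  The headline result — reproduced as an
acceptance test — is that the wide control distribution has a strictly
lower LTP threshold and a larger near-threshold window average than
both narrowed distributions, including the one with the identical
mean.

## The Poisson protocol

`run_poisson_protocol()` probes a more general regime: both neurons
receive independent homogeneous Poisson trains (10 Hz, 10 s) of brief
near-threshold pulses (3 ms; presynaptic 700 pA, postsynaptic
450 pA).  No single pulse reaches threshold; spikes arise when pulses
cluster in time, and the postsynaptic neuron is additionally recruited
when a strong release lands on a charging pulse.  This
coincidence-driven regime was chosen deliberately: if instead every
Poisson event is made suprathreshold, both spike trains are fully
determined by the stimulus, the weight trajectory becomes independent
of the release probability (up to millisecond latency shifts), and no
condition comparison is possible.  With near-threshold drive the
depression pathway (postsynaptic cluster spikes pairing with earlier
presynaptic spikes) stays largely release-insensitive while the
potentiation pathway (release-assisted postsynaptic spikes) is gated
by the distribution's upper tail.

Per trial the two trains are generated once and shared across
conditions, and the conditions' release probabilities are coupled
through a single uniform variate pushed through each condition's gamma
quantile function — a common-random-numbers design that removes
train-to-train and draw-to-draw noise from the between-condition
contrast.  `plasticity_reduction()` summarises a condition against
control as the sign-corrected mean difference
$\overline{\mathrm{sign}(\Delta w_{ctrl})\,(\Delta w_{ctrl}-\Delta w_{cond})}$,
optionally restricted to potentiating or depressing trials;
`binned_relative_diff()` reproduces the binned scatter summary.  Over
500 matched trials the reduction is positive for both narrowed
conditions, and under the equal-mean condition the potentiating trials
are hit harder than the depressing ones.

## The paired-pulse statistics pipeline

For recorded (or generated) sweep tables, `compute_ppr()` forms PPRs
from 5-sweep bins (the ratio of bin-mean amplitudes — more stable than
per-sweep ratios) and averages the last four complete bins of each
period, i.e. 10 min of a 20-sweep period; the drug effect per input is
the post-minus-baseline difference.  Population statistics follow:

* `fit_gaussian_to_ppr()` — the single-Gaussian description of a PPR
  sample; implemented as the Gaussian MLE on the raw values (mean and
  $n$-denominator SD), which is the bin-width-free equivalent of
  fitting the histogram; a binned least-squares mode exists for figure
  parity.
* `variance_f_test()` — the primary comparison: $F$ = baseline
  variance over experimental variance, one-tailed for variance
  *reduction*.  `variance_levene_test()` (Brown–Forsythe, one-tailed)
  is the robust alternative, selectable in `ppr_stats()`.
* `delta_ppr_regression()` — the change in PPR regressed on the
  baseline PPR; a variance change with a preserved mean produces a
  negative slope whose x-intercept sits at the baseline mean PPR.  A
  zero-variance change leaves the correlation undefined and is
  returned as a flagged `NA`, never silently zero.
* `inverse_cv_squared()` — $CV^{-2} = (\text{mean}/\text{SD})^2$ of
  the first EPSC over 20-sweep windows and its post/baseline ratio,
  the classical presynaptic-change indicator.
* `ppr_disparity()` — the absolute PPR difference between two
  independent inputs, the pairwise heterogeneity proxy.

One calibration subtlety is worth knowing: baseline and drug-period
PPRs of the *same* inputs share the underlying release probabilities,
so the independent-samples F test applied to that paired comparison is
conservative under the null.  The pipeline's type-I calibration is
therefore assessed on independent cohorts drawn from the same
generator (measured rate 0.054 at nominal 0.05 over 1000 null
comparisons), which is also how the suite tests it.

## The synthetic-data generator

`gen_epsc_experiment()` emulates the recordings the pipeline consumes.
Per input, a release probability is drawn from the chosen gamma
distribution; sweep amplitudes are quantal-binomial with 10 pA quanta
plus 2 pA Gaussian recording noise; the second pulse uses the TPM
two-pulse released fraction at 50 ms as its release probability, so
the noiseless PPR is exactly the model prediction (a tested
invariant).  Following recording practice — stimulation strength is
adjusted per input until EPSCs reach a working amplitude — the
per-input site count is set so the mean first EPSC is ~80 pA
regardless of release probability; tying the amplitude to the release
probability instead (available via `target_epsc1 = NA`) makes
low-release inputs' PPRs heavy-tailed ratio estimates and visibly
miscalibrates the variance test.  The drug period shrinks each input's
release probability linearly toward the population mean,
$U' = m + s\,(U - m)$: `drug_shrink = 1` is a null experiment,
`drug_shrink = 0` the limiting "variance gone, mean intact" construction,
and 0.5 the standard variance-halving effect used in the tests.
`gen_fm_signals()` provides the matching one-column FM1-43-like signal
samples for the fitting route.

What the generator does *not* emulate: series-resistance drift and
sweep exclusion, stimulation failures, spontaneous-EPSC contamination,
AMPA-receptor desensitisation or any postsynaptic contribution to PPR
changes, and correlations between converging inputs.  Passing tests
therefore show that the pipeline recovers the statistical structure the
generator encodes — variance changes with preserved means, regression
to the mean, quantal CV$^{-2}$ — not that real recordings are free of
those complications.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use: a 9 × 21 pairing grid
with 200 draws per cell and per condition; 500 Poisson trials of 10 s
at `dt = 0.05` ms; gamma recovery at $n = 10^5$ (5 % tolerance); 1000
null cohort pairs and 40 variance-shrunk experiments of 30 inputs for
the statistics pipeline.  These sizes resolve every qualitative
comparison with comfortable margins while keeping a full run in the
minutes range.  Tolerances follow the quantity: resource conservation
$10^{-9}$, two-spike PPR vs the analytic recursion $10^{-6}$, trace
STDP vs the all-pairs brute force $10^{-12}$, constrained-fit mean
$10^{-9}$, LIF latency within one integration step.  Degenerate inputs
(all-equal samples, zero variances, empty grids, unsorted spike lists)
raise errors; the one deliberate sentinel is the `NA` returned when no
grid cell reaches the LTP criterion.

## Known limitations

The model is a two-neuron caricature: no dendrites, conductance noise,
NMDA-receptor kinetics or network feedback, and a single synapse
carries all of the release-probability structure.  The STDP rule is
the classical additive all-to-all form; triplet or rate-dependent
rules are out of scope.  The stimulus geometry and weight scale are
calibrated to the near-threshold operating regime described above, and
the qualitative conclusions (threshold ordering, window ordering,
reduction signs and the LTP/LTD asymmetry) hold across the seeds and
grid resolutions tested, but quantitative values such as the LTP
threshold in pA are regime-dependent and should be read as model
quantities, not physiological predictions.  The gamma model of FM1-43
signals is a convenient two-parameter family; nothing in the pipeline
tests the family itself against alternatives.
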