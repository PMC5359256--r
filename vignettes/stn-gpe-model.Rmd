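---
title: "The STN-GPe circuit model and its analysis stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The STN-GPe circuit model and its analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stngpe)
```

This vignette is the package's account of its science: the model
equations and their assumptions, the parameters that matter, what the
synthetic inputs do and do not emulate, the numerical choices, and the
design decisions taken where the design was genuinely open.

## The circuit and its two regimes

The package simulates the reciprocally connected subthalamic nucleus
(STN, glutamatergic) and external globus pallidus (GPe, GABAergic) as a
random sparse network: 64 STN and 192 GPe neurons by default, each STN
neuron receiving GABAergic projections from 12 randomly selected GPe
neurons, each GPe neuron receiving single-contact glutamatergic synapses
from 6 randomly selected STN neurons, with 5-ms conduction delays both
ways and no GPe-GPe collaterals. Cortical drive is a 100-Hz Poisson
train per STN neuron through an alpha-function AMPA conductance
(tau = 1 ms, 1 nS).

A network state is set by three maximal conductances: the GPe intrinsic
noisy conductance (`g_ampa_gpe_int`, autonomous pacemaking), the
GPe->STN GABA-A conductance (`g_gaba_gpe_stn`) and the STN->GPe AMPA
conductance (`g_ampa_stn_gpe`). The two reference points are the
*normal* state (1.125, 3.65, 1.05 nS) — tonic, asynchronous firing —
and the *parkinsonian* state (0.0, 7.3, 1.35 nS), where the loss of
intrinsic GPe drive and doubled inhibition ignite a self-sustained
14-15 Hz cycle: GPe volleys hyperpolarise STN neurons, de-inactivating
the T-type calcium current (visible as a rising T-inactivation
variable); the post-inhibitory rebound burst excites GPe neurons 5 ms
later; their synchronous volley shuts the rebound off and re-primes the
next cycle. The oscillation frequency is set by the GABA kernel decay,
the delays and the rebound kinetics, not by any imposed rhythm.

## Neuron models

**STN.** Single-compartment conductance-based membrane with sodium,
delayed-rectifier potassium, A-type potassium, L-like calcium, T-type
calcium, calcium-activated potassium and leak currents:

$$C_m \dot V = -I_{Na} - I_K - I_A - I_{LCa} - I_T - I_{CaK} - I_{leak}
  - g_{AMPA}\,s\,(V - V_{exc}) - g_{GABA}\,s\,(V - V_{inh})$$

with eleven gating variables (m, h, n, a, b, c, d1, d2, p, q, r), a
first-order intracellular calcium pool driving the Nernst calcium
reversal, `V_exc` = 0 mV and `V_inh` = -84 mV. The gating kinetics
(Boltzmann steady states, bi-exponential voltage-dependent time
constants, calcium-dependent d2 and r) live in a swappable data table
(`stn_kinetics()`), reconstructed from the source model this cell is
based on. The behaviours the network mechanism relies on are verified by
the test suite rather than assumed: autonomous tonic firing (~6.5 Hz), a
monotone firing-rate-versus-current relationship, silence under
hyperpolarising current, and strong post-inhibitory rebound bursting.

Because ionic conductances are given per unit membrane area while
synaptic conductances arrive in nanosiemens, a membrane-area scale
converts between them (`s` above; `area_cm2` in `stn_params()`, default
`1.5e-5` cm^2). The printed area value for this cell is dimensionally
unusable as stated, so the scale was treated as a calibration constant;
see *Calibration* below.

**GPe.** Conductance-based leaky integrate-and-fire:
`C dV/dt = -g_leak (V - V_leak) - g_AMPA (V - V_exc)` with
`g_leak` = 16.66 nS, `V_leak` = -70 mV, threshold -55 mV, reset -60 mV,
2-ms absolute refractory period during which the membrane is held.
The capacitance is taken as 0.25 nF, giving the physiological 15-ms
membrane time constant; the printed picofarad reading would make the
membrane track its input in 15 microseconds, which is biophysically
implausible and is available only as an explicit override
(`gpe_params(cm = 2.5e-4)`).

## Synapse models

Kernels are a difference of exponentials ("beta"): GABA-A on STN with
rise 0.38 ms / decay 7.7 ms; AMPA on GPe with rise 5.0 ms / decay
12.4 ms, shared by STN input and the intrinsic noisy conductance; the
cortical input is an alpha function with tau = 1 ms. **Kernel
normalisation:** the package peak-normalises all kernels, so one event
of amplitude `g` reaches exactly `g` at its peak — the convention of
common simulator synapse models. The literal unnormalised
difference-of-exponentials (peak below `g`) is available via
`peak_normalize = FALSE`, but under it the GPe population cannot reach
its published normal-state firing rate at the printed conductances (the
mean drive stays far below the ~4.5 nS needed to cross threshold), so
normalisation is the default.

**GPe->STN short-term depression.** The transmission probability `P` of
a unitary projection recovers exponentially toward 1 (`tau_D`) and is
multiplied on each presynaptic spike by a decrement factor that relaxes
from `f_D` to 1 as `P` approaches its floor `P_bound`, with exponent
`n_bound` shaping the approach. Release is stochastic per contact: a
projection makes `N` contacts (log-normal, mean 15.50, SD 14.53,
moment-matched, rounded, floored at 1) and each transmits with
`mu = 1 - (1-P)^(1/N)`, so the probability of at least one release
equals `P`. Each released contact contributes one full-amplitude kernel
increment (a Bernoulli single-release variant is config-selectable).

**STN->GPe facilitation x depression.** Amplitude `A = F*D`; `F` and
`D` relax to 1 between spikes; on each spike `F` grows by a bounded
multiplicative rule (cap `F_bound`) and `D` is multiplied by `f_D`.
Each synapse is one of three fixed types (facilitation-dominant,
intermediate, depression-dominant) with printed constants, assigned
uniformly at random.

**GPe intrinsic noisy conductance.** A private 100-Hz Poisson pseudo
spike train per GPe neuron feeding the shared AMPA kernel. It stands in
for autonomous pacemaking; its maximal conductance is the
dopamine-depletion control parameter. A zero-variance control
(`gpe_int_deterministic`) replaces it by its time-average, and trading
rate against amplitude at constant mean reproduces the
variance-reduction manipulation.

## Calibration of the unprinted parameter groups

Four parameter groups are not fixed by published values, and the
published criterion for them is reproducing the observed firing
statistics. They were calibrated once against the two reference state
points and then frozen; every experiment reads them from the
configuration:

* depression constants `tau_D = 3000` ms, `f_D = 0.45`,
  `P_bound = 0.01`, `n_bound = 1.3` — strong frequency-dependent
  depression (steady-state `P` ~0.59 at 1 Hz down to ~0.11 at 100 Hz)
  with recovery over seconds, consistent with slice physiology of this
  synapse. `calibrate_depression_params()` fits these four constants to
  depression/recovery curves; the packaged target profile
  (`inst/extdata/gpe_stn_depression_targets_synthetic.csv`) is
  synthesised from the shipped constants (and labelled synthetic), and
  the calibration demonstrably recovers generating parameter sets in the
  test suite;
* the facilitation cap `F_bound = 4.6`;
* the STN membrane-area scale `1.5e-5` cm^2;
* the intrinsic-drive amplitude scale `gpe_int_scale = 1.45` (the
  effective per-event amplitude of the pseudo-synaptic conductance,
  which only matters where `g_ampa_gpe_int > 0`, i.e. not in the
  parkinsonian state).

With these frozen values the model reproduces, at the printed
conductance triples, the published population statistics: STN/GPe rates
of ~17/78 Hz (normal) and ~32/57 Hz (parkinsonian), no oscillatory STN
cells in the normal state, all of them in the parkinsonian state, a
14.2-14.4 Hz peak, and the published burst rates — as measured by the
acceptance script, not asserted here.

## Spike-train analysis

All analyses operate on spike trains binned at 1 kHz over a half-open
epoch (floor indexing; multiply-occupied bins clipped to one with a
reported tally).

**Compensated spectra.** The Welch spectrum of the binned train is
divided, bin by bin, by the mean spectrum of `n = 50` locally shuffled
surrogates (for cross-spectra: `n = 20` globally ISI-shuffled
surrogates; magnitude compensated, phase kept raw). Local surrogates
partition the epoch into windows of random length uniform on 175-225 ms
and shuffle spikes within each window, preserving the slow rate profile
exactly. The default rule redraws spike times uniformly within their
window, which removes *all* sub-window structure; for a Poisson train
the surrogate is then identical in law to the original, making the
compensation exactly unbiased (band means stay within a few percent of
1 in the tests). An ISI-permutation variant is provided
(`method = "isi"`): it preserves the interval distribution but retains
a fraction of strongly periodic structure, deflating the compensated
amplitude of near-metronomic oscillations such as the parkinsonian
14-Hz line; the package reports compensated mean band levels that
differ from refractoriness-preserving conventions accordingly.

Two frequency grids are computed from the same segments and surrogates:
a *reported* grid (2048-sample Hann segments, 50% overlap, ~0.49-Hz
bins) that resolves the amplitude of the narrow oscillation line, and a
*detection* grid (1024-sample segments, 75% overlap, ~0.98-Hz bins)
carrying the confidence level and classification. The confidence level
is the one-sided normal construction `mean + z_{0.99} * SD` over the
compensated density in 270-300 Hz, a band free of the oscillations of
interest; a cell is *oscillatory* when at least two adjacent detection
bins within 8-15 Hz exceed it. Keeping detection at ~1-Hz resolution
matters twice over: a spectral line leaks into exactly two adjacent
bins there, and the false-positive rate of the two-adjacent-bin rule on
homogeneous Poisson trains stays under 5% (measured over 200 seeds in
the acceptance suite); on a finer grid adjacent-bin correlations push
the false-positive rate to ~10%, and on a coarser one a line no longer
spans two bins.

**Phases.** The cross-spectral phase convention is positive when the
second train lags the first (shift theorem: a delayed copy acquires
phase `-2*pi*f*delta` in the raw cross-spectrum, reported negated).
`phase_difference()` reads the phase at the peak significant 8-15 Hz
bin and converts it to an equivalent lag.

**Bursts.** Poisson-surprise detection: the surprise of `n` spikes
spanning `T` ms is `S = -ln P(X >= n)`, `X ~ Poisson(rate * T)` with
the train's epoch-mean rate. A burst seeds where two consecutive
inter-spike intervals fall below half the mean interval, extends
forward while the surprise grows (10-spike look-ahead), is trimmed at
its start, and is kept when `S >= 3` with at least three spikes; bursts
never overlap.

**Population summaries.** Per neuron: firing rate, oscillatory flag,
mean and peak compensated 8-15 Hz density, frequency at the peak,
percentage of spikes in bursts, bursts per second. Neurons with fewer
than two spikes in the epoch are excluded with a reported count (which
is how a dopamine-depleted pallidal population loses a handful of
near-silent cells from the spectral statistics). Summaries pool neurons
across replicate simulations; mean band power is reported over all
cells, with an oscillatory-cells-only column alongside.

## Numerical choices

* Exponential-Euler updates for gating variables, synaptic kernel
  states and calcium (exact for the linear parts); forward update for
  the STN membrane potential; exact exponential subthreshold updates
  for the GPe membrane. Default `dt` = 0.025 ms, shared network-wide;
  the documented stability bound for the STN kinetics is 0.25 ms, and
  halving `dt` moves spike times by well under 0.1 ms per second of
  trajectory (tested).
* STN spikes are detected as upward crossings of -10 mV with a 1-ms
  guard (spikes overshoot 0 mV, so no subthreshold event can trigger).
* Delays are realised with per-target ring buffers; every synaptic
  event takes effect exactly one rounded-to-grid delay after its
  presynaptic spike (delay exactness is a tested contract).
* Each stochastic consumer — cortical drive, intrinsic GPe noise,
  release/feedback transmission — owns an independent, seeded
  generator stream, so a network realisation is reproducible
  component-wise and changing, say, the cortex seed cannot perturb the
  graph.
* Short-term plasticity state is updated lazily at presynaptic event
  times with exact exponential decay between events; amplitudes and
  release draws are applied at spike *arrival* (after the delay).
* The default analysis epoch is 10 s after a 1-s warm-up discard
  (durations are configurable; all shipped experiments use this one).
  Replicates default to 8 networks per condition, pooling 512 STN and
  1536 GPe neurons.

## The synthetic inputs, and what passing tests show

The generators emulate the study conditions — homogeneous and
rate-modulated Poisson trains for validating the analysis stack, the
100-Hz cortical and intrinsic drives, phasic rate steps (250/500/1000
Hz) for the stimulation protocol, and delay lines with 25% transmission
abstracting the cortico-basal-ganglia loop. They do not emulate
correlated cortical input, oscillatory cortical rhythms with their own
dynamics, heterogeneous cell parameters, or LFPs; conclusions about
real recordings therefore rest on the circuit mechanism, not on these
inputs being realistic cortex.

## Known limitations

* The STN gating-kinetics table is a reconstruction of the source
  model's published forms; its qualitative behaviours are tested, but
  absolute agreement with the original cell cannot be checked here.
* Four parameter groups are calibrated to the reference states rather
  than measured (see *Calibration*); other parameter regions inherit
  them unchanged.
* The compensated *mean* band level depends on the surrogate
  convention (uniform redistribution versus ISI permutation); peak
  values, classifications and all between-state orderings are robust to
  it, and both conventions ship.
* The model produces no 3-8 Hz oscillations, and normal-state GPe
  bursting is somewhat below, while parkinsonian GPe bursting is
  somewhat above, the published burst rates.
* NMDA conductances, GPe-GPe collaterals, explicit GPi/thalamus/cortex
  neurons and LFP synthesis are out of scope; the cortical loop is a
  delay-line abstraction.
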