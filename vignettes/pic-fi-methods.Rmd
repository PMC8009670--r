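---
title: "Quantifying persistent inward currents and F-I properties: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying persistent inward currents and F-I properties: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picquant)
```

## Scope

picquant implements the measurement and statistics chain used to compare
spinal motoneuron excitability between SOD1(G93A) mutant and wild-type
mice across disease progression: extraction of persistent-inward-current
(PIC) features from slow triangular voltage-clamp ramps, of
frequency-current (F-I) features from triangular current-clamp ramps,
assembly of a 21-feature per-cell table, and estimation statistics
(Hedges' *g* with BCa bootstrap intervals, Welch's *t*, regressions
against age, ANCOVA, PCA). Because the original in vivo dataset cannot be
regenerated, a conductance-based synthetic motoneuron supplies traces
with known ground truth; every stage of the pipeline is validated against
brute-force oracles on those traces.

## The synthetic motoneuron

The model is a single-compartment neuron with membrane capacitance $C$
(nF) and three currents (canonical units throughout: mV, nA, s, Hz, µS;
note µS = nA/mV, so conductances fall out of I-V slopes with no unit
conversion):

$$I(V) = g_\mathrm{leak}(V - E_\mathrm{rest})
       + g_\mathrm{PIC}\, m_\infty(V)\,(V - E_\mathrm{PIC})
       + g_\mathrm{out}\, n_\infty(V)\,(V - E_\mathrm{out})$$

with Boltzmann activations $m_\infty(V) = 1/(1+e^{-(V-V_{1/2})/k})$. The
PIC term lumps the Na and Ca components into one inward current (the
measurements only ever see the summed deflection); the opposing outward
current turns the leak-subtracted I-V back upward near the ramp apex, so
the curve has the characteristic interior negative peak between roughly
−55 and −40 mV. Optional first-order kinetics on the PIC
($\tau_\mathrm{PIC}$, default 0.3 s in cohort sampling, 0 = instantaneous)
produce ascending/descending hysteresis. In voltage clamp the command is
the triangular ramp and the response is $I(V)$ plus the capacitive current
$C\,dV/dt$ — a constant offset of opposite sign per limb, as in real ramp
recordings — plus Gaussian noise. In current clamp the membrane equation
is integrated with integrate-and-fire spiking: at each threshold crossing
a stereotyped action-potential waveform (0.4 ms rise at ~110 mV/ms, 45 mV
overshoot, 0.6 ms fall to the reset potential) is inserted into the trace
so that the downstream dV/dt detector operates exactly as on real data,
and a spike-triggered adaptation current (increment $b$, decay
$\tau_w$) is added. Current-clamp noise is a white voltage diffusion
(mV/√s); the resulting membrane-potential jitter near threshold is what
produces the high-variability subprimary firing range, without modeling
mixed-mode oscillations.

Key defaults: $V_{1/2,\mathrm{PIC}} = -50$ mV, $E_\mathrm{PIC} = +30$ mV;
outward current $V_{1/2} = -35$ mV, $k = 5$ mV, $E = -85$ mV; $C = 4$ nF;
$b = 0.12$ nA, $\tau_w = 0.25$ s. The PIC activation slope is
$k_\mathrm{PIC} = 2.5$ mV. A shallower slope (e.g. 4 mV) leaves a
percent-level PIC tail inside the −80 to −65 mV leak-fit window, which
biases the fitted conductance by ~2% and the extrapolated leak at the PIC
peak by ~0.3 nA; with $k = 2.5$ the PIC is closed below −65 mV by
construction (non-leak current < 0.5% of the leak range in the window),
which is what makes exact parameter recovery a meaningful test of the
measurement chain rather than of the fit bias.

### Rheobase and calibration oracles

Two brute-force oracles anchor all tests: `oracle_pic_features()`
minimizes the non-leak current on a 0.01 mV grid (ground-truth PIC
amplitude and peak voltage), and `rheobase_current()` maximizes the
steady-state current required on the path from rest to threshold — the
quasi-static escape current under a slow ramp. Cohort sampling inverts
both: per cell, $g_\mathrm{PIC}$ is solved (by `uniroot`, with the
outward conductance tied as $g_\mathrm{out} = 0.02 + 0.4\,g_\mathrm{PIC}$
so the interior peak survives) from a target PIC amplitude, and the spike
threshold is solved from a target recruitment current. Because the
quasi-static rheobase ignores membrane and PIC-activation lag under the
ramp, up to two corrective passes integrate the noiseless subthreshold
dynamics and shift the static target down by the realized lag.

### Cohort sampling

`table1_cohort_spec()` encodes the published per-group cell counts and
mean ± SD of input conductance, PIC amplitude, RMP, recruitment current
and PIC peak voltage for the six genotype × age-group blocks; these
printed summaries are the *inputs* that define the study conditions the
generator emulates. Draws use truncated-normal marginals (conductances
and currents truncated above zero) coupled through a Gaussian copula with
correlation 0.74 between cell size and PIC amplitude (matching the
published PIC-vs-conductance regression of r² ≈ 0.55). Two guards keep
draws physiological: the resting potential is capped 14 mV below the
drawn PIC peak voltage (so the PIC is essentially closed at rest — cells
violating this float depolarized and would fail the RMP quality rule),
and the PIC half-activation is placed 6 mV below the drawn peak voltage,
the offset the default model shape exhibits. Non-firing cells
(hypoexcitable cells that fire at most a few spikes to a ramp but still
spike to a step) are generated with a small target PIC (0.60 ± 0.49 nA)
and a large, slow adaptation increment (4 nA, τ = 3 s); the mechanism is
a modeling choice — the data constrain the phenotype, not its cause.
Per-cell sub-seeds derive deterministically from the master seed, so a
cohort is bit-reproducible.

What the generator does *not* emulate: electrode and discontinuous-clamp
artifacts, mixed-mode oscillations in the SPR, channel-level PIC
decomposition, temperature, and the full between-cell covariance of all
21 features (only the size-PIC correlation is imposed). Consequently the
synthetic ascending/descending concordances (r² ≈ 0.95–0.99) are tighter
than the published ones (0.75–0.90), and SPR/PR transition frequencies
and F-I gains emerge from the model rather than being calibrated — the
cohort-level tests therefore compare calibrated quantities (conductance,
PIC amplitude, RMP, recruitment) against their targets, and assert only
structural properties (positive gains, descending > ascending gain,
transition between recruitment and apex) for the uncalibrated ones.

## Voltage-clamp measurement rules

* **Limb splitting**: the command is denoised with a 5-point running
  median, split at its maximum; apex plateaus and baseline samples belong
  to neither limb, so each limb is strictly monotonic in command.
* **Leak fit**: OLS of current on command over −80 to −65 mV (≥ 10
  samples required). The fit is done per limb: the slope (input
  conductance) is reported from the ascending limb, while each limb's
  intercept absorbs its own capacitive offset. A single shared line would
  leave a constant $2C\,dV/dt$ artifact on the descending limb and break
  the exact ascending/descending symmetry that holds for an
  instantaneous, noiseless PIC.
* **Smoothing**: the leak-subtracted current is moving-averaged over a
  0.5 mV command window before extremum search (at 5 mV/s and 10 kHz one
  mV spans 2000 samples; a raw argmin would chase noise). Ties at the
  minimum resolve to the earliest ascending / latest descending sample.
* **Onset and end**: the published onset rule is visual ("starts to
  deviate downward"), so it is made explicit: onset is the first
  ascending voltage where the smoothed subtracted current stays below
  $-\max(3\,\sigma_\mathrm{res},\ 0.05\ \mathrm{nA})$ for a sustained
  1 mV of command, with $\sigma_\mathrm{res}$ the leak-fit residual SD;
  the end voltage applies the same criterion on the descending limb,
  taking the last sustained sample. All three constants are arguments
  with those defaults. When no sample qualifies the PIC is recorded as
  absent (onset and end missing). Voltages are reported as commanded
  voltage. With the synthetic model's steep activation, detected onsets
  sit closer to the peak than the published visual onsets for
  strongly-hyperpolarized-onset cells; onset is therefore validated
  against ordering invariants (onset ≤ peak) rather than printed group
  means.

## Current-clamp measurement rules

* **Spike detection**: dV/dt from a first difference smoothed over
  0.2 ms; a spike is an upward crossing of 10 mV/ms followed within 2 ms
  by a peak ≥ 20 mV above the crossing voltage, with a 2 ms refractory
  period. The crossing voltage of the first spike is the voltage
  threshold. Sampling below 5 kHz is rejected (the criterion needs the
  resolution).
* **Recruitment bookkeeping**: recruitment/de-recruitment currents at the
  first/last spike; ΔI is their difference; ΔF uses the first and last
  ISI (missing below 3 spikes). Whether the original analysis averaged
  several ISIs near recruitment is not stated; first/last is used and
  flagged here.
* **F-I relation**: one point per adjacent spike pair, frequency 1/ISI
  against the current at the ISI *time midpoint* (the assignment is not
  stated in the source; the midpoint minimizes ramp-slope bias), limbs
  split at the command apex.
* **SPR/PR segmentation**: the published rule is visual. The
  deterministic surrogate starts from a 10-point apex window, walks away
  from the apex, and stops when the candidate point's residual against
  the running linear fit exceeds $\max(2\,\sigma_\mathrm{apex},\ 3\ \mathrm{Hz})$
  (confirmed by the next point, so a single outlier ISI does not
  truncate the range) or when the local 10-point slope leaves twice the
  apex-window slope. Because the walk necessarily overshoots a slope
  break by a few points, the boundary is then refined as the two-segment
  least-squares changepoint in the neighbourhood of the stop; on a
  noiseless two-segment fixture (25 Hz/nA below 5 nA, 9 Hz/nA above)
  this recovers the kink within one point spacing. The three rule
  constants are exposed as arguments.
* **Gain**: OLS slope over the PR points only; missing when the PR has
  fewer than 4 points.
* **Classification**: non-firing = at most 4 ramp spikes ("a single or a
  few") while a step sweep, when present, evokes at least one.
* **RMP and stability**: RMP is the mean over the pre-ramp baseline
  (≥ 0.5 s); the "unstable RMP" exclusion — for which no number is
  published — is operationalized as a drift above 2 mV between the first
  and last fifth of the baseline.
* **ΔI quantization**: for a reset-based neuron the de-recruitment
  current is quantized by the post-spike recovery time, not by the
  sampling grid: even a noiseless symmetric cell shows
  |ΔI| ≈ ramp speed × recovery time (~0.03 nA at 1 nA/s) when it fires a
  full train. The sample-exact ΔI = 0 identity holds in the
  marginal-firing regime (ramp apex just above rheobase), which is the
  regime the acceptance check exercises; the multi-spike hysteresis is
  asserted as a bounded, direction-correct property.

## Estimation statistics

* **Hedges' g**: pooled-SD standardized mean difference with the exact
  gamma-ratio small-sample correction (computed via `lgamma`; the
  $1 - 3/(4\,df - 1)$ approximation is attached and agrees to 3 decimals
  for df ≥ 10). Sign convention: second group minus first, so cohort
  comparisons report mSOD1 − WT.
* **BCa interval**: per-group independent resampling (default 5000),
  bias correction from the bootstrap distribution's position relative to
  the point estimate, acceleration from a delete-one jackknife over all
  observations of both groups (set to 0 when either group has n < 3,
  where the jackknife is undefined). The BCa interval is implemented in
  the package — it is part of the statistical layer being reimplemented —
  and cross-checked in the tests against `boot::boot.ci(type = "bca")`
  with stratified resampling. Degenerate bootstrap distributions
  (constant samples) yield a degenerate interval rather than an error.
  Monte-Carlo calibration at the published young-adult group sizes
  (19, 15) gives 93–97% coverage.
* **Welch's t** is attached for information, with both the
  Welch–Satterthwaite df and the pooled df $n_1 + n_2 - 2$ — the printed
  "t(df)" strings use the pooled value, so both are reported.
* **ANCOVA**: `pic_amplitude_asc ~ input_conductance * genotype`; if the
  interaction is not significant at 0.05 (no α is published; 0.05 is the
  conventional reading of "no significant interaction") the additive
  model is refit. The covariate is centered, so the genotype coefficient
  is the effect at the mean conductance — identical in the additive
  model, and the meaningful contrast when the interaction happens to be
  retained.
* **PCA**: complete-case cells (the count dropped is logged), per-feature
  z-scoring with the n−1 SD, eigendecomposition via `prcomp`, five
  components retained, and the feature × component correlation matrix
  computed for the loadings heatmap analogue.
* **Regressions** against age use OLS with t-based slope intervals, and
  ages are expressed in weeks (days / 7) to match the printed slopes.

## Pipeline rules

Quality control excludes cells with RMP more depolarized than −50 mV — a
cell at exactly −50.0 mV is kept, the rule being "more depolarized than"
— or a drifting baseline. Age groups are the three half-open bins:
< 60 d, 60–89 d, ≥ 90 d. The feature table enforces the canonical
21-column schema; the derived columns satisfy exact identities
(relative voltage = absolute − RMP; normalized PIC = descending
amplitude / conductance; ΔI = de-recruitment − recruitment) which the
tests assert at 10⁻⁹. Cells, not animals, are the unit of analysis;
animal identifiers are retained for sensitivity reanalyses but none is
performed by default. Non-firing cells keep their voltage-clamp features
and have all F-I columns missing.

On-disk formats are two trace-bundle dialects — per-sweep CSV files
(`time_s, command, response`, full double precision) with one JSON
sidecar, and a single HDF5 container with one group per sweep and
attribute metadata — plus the feature-table CSV with empty-field missing
values (never 0). Both dialects round-trip losslessly; a `time_unit` of
"ms" in a sidecar is normalized to seconds on read, idempotently.

## Problem sizes and determinism

The test suite samples one reduced cohort (3 cells per genotype ×
age-group block plus 2 + 2 non-firing cells) at 5 kHz with a 2.5 nA/s
current ramp reaching 4 nA above each cell's rheobase; parameter-recovery
checks run 200 noiseless and 200 noisy single cells at 2 kHz (the
voltage-clamp contract allows ≥ 100 Hz); bootstrap calibration uses 500
replicate experiments at 1000 resamples. These sizes were chosen so the
full suite exercises every claim in minutes while keeping Monte-Carlo
margins comfortable. The analysis drivers run the full published group
sizes (116 cells) at the same rates. All randomness flows from explicit
seeds through per-cell derived sub-seeds; rerunning any stage with the
same seed is byte-identical, which the tests assert on the written JSON
and CSV outputs.

## Known limitations

The simulator's F-I shape (near-linear once clear of recruitment, gains
~15–30 Hz/nA, SPR produced purely by voltage noise) is not calibrated to
the published SPR/PR transition statistics, and its onset-voltage
distribution is compressed relative to the visual measurements; both are
consequences of the deliberately minimal one-compartment model.
Passing tests on synthetic cohorts therefore demonstrate correctness of
the measurement chain and statistics, not fidelity of the model to every
aspect of the in vivo data. The optional re-analysis of the deposited
experimental dataset (regression slopes, PCA variance fractions,
concordances) requires downloading that archive and is outside the test
surface.
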