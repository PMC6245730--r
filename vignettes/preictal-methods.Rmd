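---
title: "Methods: preictal and ictal analysis of interneuron activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preictal and ictal analysis of interneuron activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(preictal)
library(dplyr)
```

`preictal` analyses extracellular recordings collected around
chemoconvulsant-induced seizures: spike trains of sorted single units
(parvalbumin- and somatostatin-expressing interneurons identified by
optogenetic tagging, plus broad-waveform regular-spiking cells), one LFP
channel, and a table of calibrated laser pulses. This vignette documents
the models and procedures each stage implements, the tunable parameters
and their defaults, what the synthetic-session generator does and does not
emulate, and the numerical choices made where the design was open.

## Analysis periods

Seizure latency after a chemoconvulsant injection varies between animals,
so absolute time is not comparable across sessions. The package therefore
works in *normalised periods*:

* **baseline** — recording start to the injection;
* **P1–P4** — the injection-to-onset span divided into four equal,
  half-open quartiles;
* **I1–I4** — the first 60 s of the seizure in four 15 s quarters.

All intervals in the package are half-open `[start, end)` in seconds from
recording start, so adjacent periods never share a sample or a spike.

Ictal onset is detected from the LFP: each sample is z-scored against the
mean and SD of the pre-injection baseline, and onset is the first time
after the injection at which `|z|` exceeds `z_threshold` (default 5) for at
least `min_duration_ms` (default 10 ms) consecutively. The sustained-run
requirement exists because a single-sample excursion beyond 5 SD is
indistinguishable from instrument noise; 10 ms (ten samples at the 1 kHz
default) is short relative to an ictal spike but long enough to reject
isolated outliers. The z-score is computed on the raw samples — no
envelope, filtering or smoothing — so the detected time is directly
interpretable as a crossing of the voltage trace itself. If the trace
never crosses, the detector reports an explicit no-onset result rather
than an error.

Spontaneous-activity metrics must not include light-evoked spikes, so a
guard window is excised around every laser pulse before rates are
computed: the removed interval per pulse is
`[onset − guard_s/2, onset + duration + guard_s/2)` (total removed time
`duration + guard_s`, default guard 1 s), and all rates divide by the
*effective* (post-excision) duration. In awake recordings, locomotion
strongly modulates hippocampal firing; `mask_quiescence()` restricts
analysis to below-threshold wheel-speed intervals. This is a deliberate
simple-threshold stand-in — change-point segmentation of locomotion is out
of scope — and is flagged as such in its documentation.

## Unit classification

Mean spike waveforms are normalised to `[-1, +1]` by their maximum
absolute value. Three features are extracted: the peak-to-trough duration
(trough to the subsequent maximum), the raw peak-to-trough amplitude, and
the *repolarisation value* — the normalised voltage 0.9 ms after the
trough, read by linear interpolation between samples. Untagged units with
a repolarisation value strictly below −0.35 are classified as
regular-spiking (RS, putative excitatory); the waveform of fast-spiking
interneurons has recovered towards zero by 0.9 ms, while the broad RS
spike is still deep in its repolarisation. The 0.9 ms read-out is anchored
at the trough (the alignment point of the mean waveform); the amplitude
threshold applies to the normalised waveform, making the classification
scale-invariant. Narrow-waveform units that fail tagging are labelled
`unidentified-narrow` and excluded from RS-specific analyses rather than
forced into either class.

Optogenetic tagging relies on the short latency and low jitter of directly
light-evoked spikes. For each tagging pulse the first spike in the
response window (default 1–10 ms after onset) is collected; a unit is
tagged when (i) the median first-spike latency is at most 6 ms, (ii) the
SD of those latencies (jitter) is at most 1.5 ms, (iii) the evoked
probability is at least 0.3, and (iv) that probability significantly
exceeds — by a one-sided binomial test at α = 0.05 — the chance
probability `1 − exp(−r·w)` implied by the unit's own baseline rate `r` in
a window of length `w`. The numeric cutoffs are package defaults (all
configurable): they encode "short-latency, low-jitter" quantitatively and
keep the false-positive rate on independent units below 5%, which the test
suite verifies on 100 simulated Poisson units. Tagging is assessed on the
highest-intensity pulses only, because tagging protocols calibrate light
power so that evoked probability approaches one; including weak ladder
pulses would mix spontaneous first-spikes into the latency distribution
and inflate the jitter estimate for high-rate interneurons.

Spike-train quality is summarised by `isi_contamination()` — the fraction
of inter-spike intervals below the 1.5 ms refractory bound (well-isolated
units stay at or below 0.1%) — and `check_ictal_trackability()`, which
requires 60 s of post-onset tracking before a unit enters ictal analyses.

## Firing rate and temporal patterning

Per period, the mean rate is the spike count inside the period's
(pulse-excised) mask divided by the effective duration. Per-period changes
are reported relative to baseline; units with baseline rates below 0.1 Hz
are excluded, since a handful of baseline spikes makes the change estimate
meaningless. The change is a difference in Hz by default; a normalised
ratio is available via `method = "ratio"` because the difference-vs-ratio
choice is presentational, not substantive.

Two patterning statistics are computed from the ISIs *within* each period
(no interval spans a period boundary or an excised pulse epoch, since the
two sides of such a gap belong to different regimes):

* **Local variation**,
  `LV = 3/(n−1) · Σ ((ISI_i − ISI_{i+1})/(ISI_i + ISI_{i+1}))²`, a
  normalised statistic of consecutive-interval differences that is robust
  to slow rate drift: 1 for Poisson-like firing, below 1 for regular
  firing, above 1 for bursty firing. For a gamma-renewal process with
  shape κ its expectation is `3/(2κ+1)`, which the suite uses as a closed-
  form oracle.
* **ISI log-ratio**, `log10` of the fraction of ISIs in `[2, 10)` ms over
  the fraction in `[10, 100)` ms — a burst-propensity index. Base-10 logs
  are used; the bands are half-open so no interval is counted twice. An
  empty band yields `NaN` with a warning rather than a sentinel value.

## Spike-field coherence and LFP power

Spike-LFP phases are measured per spike and frequency: a Hanning-tapered
LFP segment of 7 cycles of the target frequency, centred on the spike, is
Fourier-transformed at that frequency and the coefficient's argument is
the phase. Centring on the spike is a choice (the alignment is otherwise
arbitrary); 7 cycles fixes the spectral bandwidth proportional to
frequency. Spikes whose window does not fit inside the recording are
dropped and counted.

Phase consistency is quantified by the **pairwise phase consistency**
(PPC): the mean cosine of all pairwise phase differences. Unlike the
resultant length, its expectation does not depend on the number of spikes,
so units with different rates are comparable and spikes can be subsampled
to bound run time without bias (the pipeline caps at 200 spikes per unit
and period by default). The implementation uses the algebraic identity
`(|Σe^{iθ}|² − n)/(n(n−1))`, which the tests verify against the explicit
O(n²) pairwise sum to 1e-12. The band summary is the unweighted mean PPC
over 20–28 Hz (band edges inclusive, 1 Hz sampling by default); theta
(4–10 Hz) and high-gamma (60–90 Hz) variants use the same operations with
different band parameters — those supplementary edges are assumptions, as
no canonical values exist.

LFP band power divides the signal into non-overlapping 1 s segments,
applies a Hanning taper and the DFT, and averages power over the 20–28 Hz
bins and then over segments. The spectrogram convolves the trace with
7-cycle Hanning-windowed complex oscillations (a wavelet-style transform),
normalises power by the summed power over all returned bins and reports
base-10 log, so the displayed matrix satisfies `sum(10^power) = 1`.

## Optogenetic input-output curves and RS inhibition

The probability that a pulse evokes a spike in the 2–15 ms window after
onset is modelled as a sigmoid of laser intensity:

`p(I) = B + S / (1 + exp(−(I − c)/A))`,

with baseline offset `B`, scale `S`, half-maximum intensity `c` (the c50)
and width `A` (slope `1/A`); `Rmax` is the fitted probability at the
maximum tested intensity. The fit minimises the **L1 norm** (sum of
absolute deviations) — robust to single outlying levels — with Nelder-Mead
simplex search restarted from 64 random initialisations; the restart with
the lowest error wins, ties going to the first found. Restart draws are
`B ∈ [0, 0.5]`, `S ∈ [0, 1]`, `c` across the tested range, `A ∈ [0.01,
range]`; the formula as written is unbounded, so the sigmoid is clipped to
`[0, 1]` inside the objective (a probability cannot leave the unit
interval). Fits need at least 4 distinct intensities; fewer is an error,
not a silent degenerate fit. The fit is deterministic given data and
restart seed, and more restarts can only improve the retained error —
both properties are under test.

For RS-inhibition analysis, two intensity classes are derived from the
driven interneurons' average response curve: **medium** is the tested
level whose probability is nearest 50%, **high** the level with maximal
probability (ties resolve to the larger intensity; an all-equal curve is
ambiguous and returns the maximum with a warning). The modulation of RS
firing around pulses of a class is

`y = (FR_post − FR_pre) / (FR_post + FR_pre)`,

with `FR_post` the rate in the 50 ms after onset and `FR_pre` the rate in
the 200 ms before, pooled across pulses (total spikes over total window
time). Pooling is robust when single-window counts are 0 or 1, which is
the norm at RS rates; per-pulse averaging is available via `pooled =
FALSE`. `y` is −1 for complete suppression, 0 for no change, and `NaN`
when both windows are empty (no evidence either way).

## Group statistics

Within-cell period contrasts use paired Wilcoxon signed-rank tests,
between-group comparisons the rank-sum test, and more than two groups
Kruskal-Wallis — nonparametric throughout, as rate and LV distributions
are skewed. When every within-cell difference is exactly zero the paired
test is degenerate; the package returns p = 1 (no evidence of an effect)
rather than `NaN`. Multiple comparisons over the four preictal periods use
Bonferroni correction: adjusted p `min(1, m·p)` and the per-test threshold
`α/m` (0.0125 at α = 0.05, m = 4).

The fraction-of-cells statistic asks how many cells increased their rate
between two periods: `k` of `n` cells with `rate_B > rate_A` (ties count
as non-increases — the conservative choice) is tested against 0.5 with an
exact two-sided binomial p defined as twice the smaller tail, capped at 1.
This doubled-tail definition is the one the package's contract states; it
differs from the minimum-likelihood definition used by
`stats::binom.test`, so the tests check it against a brute-force sum over
the outcome distribution.

## The synthetic-session generator

No public recordings accompany this analysis, so the package ships a
generator whose sessions have the statistical structure the analysis
assumes, with ground truth attached:

* **Spike trains** are gamma-renewal processes (shape κ, mean ISI
  `1/rate`) with piecewise-constant rates per period following each unit's
  multipliers. Piecewise-constant profiles (rather than smooth ramps) are
  used because the analysis only ever measures per-period means.
* **Phase locking** is produced by von Mises thinning: candidate spikes
  are accepted with probability `exp(κ_vm(cos φ − 1))` where φ is the
  instantaneous phase of the unit's locked LFP component, and the
  candidate rate is pre-scaled by `e^{κ_vm}/I₀(κ_vm)` so the mean rate is
  preserved. The resulting phase distribution is von Mises, giving the
  closed-form expected PPC `(I₁(κ_vm)/I₀(κ_vm))²` used for calibration.
* **LFP** is a sum of configured sinusoids plus Gaussian noise, with every
  sample amplitude multiplied by `ictal_gain` from the true onset onward.
  Gaussian noise is a stand-in — real baseline LFP noise statistics are
  not specified anywhere usable — and the abrupt gain step is an
  idealisation of ictal onset that makes detection accuracy measurable
  against truth.
* **Tagged units** fire after each pulse with probability given by their
  true sigmoid, at latency 3 ms with 0.3 ms Gaussian jitter — within the
  2–15 ms response window and satisfying the tagging criteria by
  construction. **RS units** lose each spike in the suppression window
  after a pulse with probability `suppression_depth`.
* Pulses form a regular baseline train cycling through the intensity
  ladder; a single LFP channel is modelled (no tetrode geometry), and
  waveforms are parameterised analytic templates, not biophysics.

The default configuration — 600 s at 1 kHz, injection at 120 s, onset at
420 s, 6 PV (late preictal surge, multipliers 1.2/1.5/2/4), 4 SST (early
plateau, 1.8/2/2/2), 8 RS (gradual ramp, 1.2/1.5/1.8/2.2), theta + beta
LFP components, ictal gain 10 — encodes the qualitative preictal
trajectories the analysis is designed to resolve, at firing rates typical
of CA1 fast-spiking (14 Hz), SST (8 Hz) and pyramidal (3 Hz) cells. For
the onset-detection calibration a single 24 Hz component (60 µV) over
8 µV noise is used: a beta-dominated trace in which the ×10 step is
unambiguous, so detection error measures the algorithm, not the fixture.

Because the generator *is* the test bed, passing tests show that each
stage recovers the structure it was pointed at — rates, locking strength,
sigmoid parameters, suppression depth, onset time — not that real tetrode
data are this clean. Real recordings add spike-sorting errors, waveform
drift, non-stationary noise, and seizure morphologies far richer than an
amplitude step; those failure modes are outside what these tests certify.

## Problem sizes and determinism

The shipped test suite uses desk-scale problems chosen to make sampling
error small relative to each tolerance: ≥10⁴ ISIs for LV closed-form
checks (2–3%), 10⁴ von Mises draws for the PPC value, 200 seeds per
condition for the unbiasedness comparison, 50 sessions for onset
detection, 50 Bernoulli datasets (8 levels × 200 pulses) for sigmoid
recovery, and the default 18-unit 600 s session for the end-to-end check.
Every stochastic step takes an explicit seed: a session is a pure function
of its configuration, an analysis of its session and settings, and
`scripts/acceptance.R` derives all of its randomness from `--seed`.

## Known limitations

* Spike sorting, isolation distance, histology and surgical protocols are
  upstream of this package and out of scope.
* The locomotion mask is a speed threshold, not change-point detection.
* The repolarisation read-out anchor (trough) and the tagging cutoffs are
  package conventions where no published values exist; both are
  configurable.
* Group-level biological conclusions require the real recordings; the
  statistics here are validated on synthetic ground truth only.

## A worked example

```{r example, eval = FALSE}
library(preictal)

sess <- simulate_session(simulation_config(seed = 1))
a <- analyze_session(sess)
glance(a)
a$fraction_tests

autoplot(fit_sigmoid(pulse_spike_probability(
  sess$units$spike_times[[1]], sess$pulses)))
plot_rate_trajectories(a$metrics)

write_analysis(a, "results")
```
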