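---
title: "Quantifying phrenic and diaphragm motor output: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phrenic and diaphragm motor output: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrenoscope)
```

# The measurement problem

Chemogenetic (DREADD) stimulation of phrenic motoneurons is read out
through three kinds of recordings: diaphragm EMG in spontaneously
breathing anesthetized mice, phrenic neurograms in ventilated rats, and
whole-body (barometric) plethysmography in unanesthetized rats. In all
three, the quantities of interest are per-event: the peak-to-peak
amplitude, tonic (between-burst) level and area under the curve of each
inspiratory burst; the tidal volume of each breath; the systolic,
diastolic and mean arterial pressure of each cardiac cycle. Cohort-level
claims (e.g. a sustained increase in inspiratory output after a DREADD
agonist such as J60) rest on epoch summaries of these event metrics,
normalized to each animal's own baseline, compared with
repeated-measures statistics.

phrenoscope implements that chain end to end, and pairs it with a
synthetic-data module that generates the same kinds of traces with exact
ground truth, so that every stage — filtering, envelope extraction,
event detection, metric computation, epoch bookkeeping, statistics — is
verifiable without animal recordings.

# Signal model and envelope extraction

## The synthetic EMG/neurogram

`simulateEmg()` models a raw recording as an interference pattern:
band-limited Gaussian carrier noise $c(t)$ amplitude-modulated by a
nonnegative modulation envelope

$$x(t) = c(t)\,\big[T(t) + \textstyle\sum_i A_i\, s\!\big(\tfrac{t -
t_i}{D}\big)\big] + \varepsilon(t),$$

where $T(t)$ is the tonic level, $A_i$ the per-burst phasic amplitude,
$D$ the burst duration, $s(\cdot)$ a raised-cosine burst shape (25% rise,
50% plateau, 25% fall — smooth, and integrable in closed form so the
stored per-burst AUC is exact: $\int s = 0.75\,D$), and $\varepsilon$
broadband noise. A ligand intervention multiplies $A$, $T$ and the burst
rate by configurable gains, ramped linearly over `rampS` seconds from
its onset and sustained to the end of the trace.

Defaults describe an anesthetized-mouse diaphragm rig: 10 kS/s
digitization, a 100–1000 Hz carrier (the hardware amplifier band), 90
bursts/min of 180 ms, tonic floor at 15% of the phasic amplitude, and a
broadband noise floor at 5%. These are representative values chosen
once; published reports rarely state their recordings' noise levels or
burst durations, so they are plausible rather than fitted.

One normalization choice matters downstream: the carrier is scaled so
that $\mathrm{median}\,|c| = 1$. The analysis envelope (below) starts
with a moving *median* of the rectified signal, which estimates
$m(t)\cdot\mathrm{median}|c|$; with this normalization the pipeline's
envelope is an (asymptotically) unit-gain estimator of the modulation
envelope, and ground truth can be stored on the modulation-envelope
scale.

## Rectified-integrated envelope

`signalEnvelope()` computes $|x|$ followed by a centered moving median
and then a centered moving average, with window widths in ms ("time
constants" are interpreted as full window widths, the conventional
reading for these filters). Typical settings are 50/50 ms for mouse
diaphragm EMG and phrenic neurograms and 75/175 ms for rat diaphragm
EMG. Windows are converted to odd sample counts (rounding half up) so
they are symmetric; edges are handled by window truncation. Whether such
windows are causal or centered is rarely stated in methods sections;
centered windows are used here because they preserve burst timing
(zero phase), at the cost of smearing the burst foot symmetrically —
which the detector corrects for (below).

`bandpassFilter()` applies the 2nd-order Butterworth band (100–1000 Hz
for EMG, 100–3000 Hz for phrenic) forward and backward. Zero-phase
filtering preserves onset timing; the effective magnitude roll-off is
doubled relative to a single pass. Two consequences are worth knowing:

* the forward–backward magnitude is the squared single-pass response,
  which the test suite verifies against the analytic
  (prewarped-bilinear) Butterworth formula at 20 probe frequencies;
* a 2nd-order bandpass has appreciable in-band droop away from its
  center frequency. Re-filtering a signal that is already band-limited
  to the same band (as the generated traces are, emulating the hardware
  filter) rescales the envelope by roughly 6% for a full-band carrier.
  All normalized quantities are unaffected. For absolute comparisons
  against simulation ground truth, the envelope is therefore computed
  directly on the generated (already band-limited) trace; for real
  recordings the digital filter stays in the chain, as it also removes
  out-of-band noise.

# Event detection

## Inspiratory bursts

`detectBursts()` defines its threshold from the data: the baseline floor
is the median of the quiet fraction of the envelope (the median of
values at or below the overall median — robust as long as the burst
duty cycle stays below roughly half after smoothing), and the spread is
a scaled-MAD estimate of that fraction's SD. Candidate bursts start
where the envelope crosses `floor + thresholdK * spread` and end where
it falls below a hysteresis level at 50% of the threshold excess.
Events shorter than `minBurstMs` are discarded; events separated by
less than `minIntervalMs` are merged (a split burst becomes one event).

Because baseline statistics are computed on whatever segment is passed
in, the study runners detect per epoch: sustained tonic shifts after the
ligand raise the floor, and a per-epoch threshold follows it, where a
single global threshold would not. The threshold is data-relative, so
detection is invariant to rescaling the envelope by any positive
constant.

Two defaults were set by measurement against simulation ground truth
rather than convention. First, `thresholdK = 4`: the smoothed envelope
floor fluctuates with a correlation time comparable to the smoothing
windows, and at `k = 3` those excursions survive the minimum-duration
filter often enough to cost several points of precision. Second, an
onset refinement step: a centered smoother spreads the burst foot
symmetrically, so a low threshold crossing precedes the true onset by
up to half the combined window (~10–15 ms at 50/50 ms). After
detection, each onset is re-located at the crossing of
`floor + 5% * (burst peak − floor)`, which empirically centers the
reported onset within a few ms of the true one. Offsets keep the
hysteresis crossing: the wider right edge lets the AUC integral
recapture burst mass that smoothing displaces outward.

## Breaths and cardiac cycles

`detectBreaths()` drift-corrects the chamber-pressure trace by
subtracting a running median (2 s default), smooths lightly (25 ms, well
below a breath duration, so broadband noise does not inflate the peak
deflection), and segments with the same threshold/hysteresis machinery.
The per-breath deflection — the quantity entering the tidal-volume
equation — is the maximum above the corrected baseline.

`detectCardiacCycles()` delimits cycles at diastolic troughs (local
minima at least 40 ms apart, within the lowest quarter of the pressure
range) and reads systolic/diastolic pressure as the per-cycle extremes.

# Event metrics

`burstMetrics()` reports, per burst: peak amplitude (envelope maximum in
the burst window), tonic activity (envelope minimum in a pre-onset
window), peak-to-peak amplitude (their difference) and AUC (trapezoidal
integral of the raw envelope over the burst — no baseline subtraction;
a tonic-subtracted `auc_net` is also returned). The tonic window
defaults to a fixed 75 ms immediately before the onset: the minimum of a
fluctuating envelope over a long window is biased low, and a window on
the order of the smoothing width measures the between-burst floor with
the least bias (the half-preceding-gap alternative is available via
`tonicWindowS = NULL`). The first burst of a segment has no preceding
gap; its tonic comes from the trailing gap and is flagged.

Known accuracy at the default study conditions, measured against
simulation ground truth (and enforced by the test suite): sensitivity
and precision above 95%, onset error median below 10 ms, mean
peak-to-peak error within 5%, mean AUC error within 5%. Two systematic
effects set these scales. The *max-statistic bias*: the burst peak is a
maximum over a fluctuating envelope (~8% CV after 50/50 ms smoothing),
biased upward by a few percent — a property of the measurement
definition itself, present equally in real recordings. The
*median-stage transition loss*: a moving median of a rectified noisy
carrier under steep modulation is biased low where the modulation
changes quickly (the half-normal sample distribution is heavy near
zero), which costs the AUC a few percent in the rise/fall regions,
partially recovered by the hysteresis-wide integration window.

## Ventilation

Tidal volume uses the barometric plethysmography equation
(Drorbaugh–Fenn):

$$V_T = P_T\,\frac{V_K}{P_K}\cdot
\frac{T_R\,(P_B - P_C)}{T_R\,(P_B - P_C) - T_C\,(P_B - P_R)}$$

with calibration volume $V_K$ producing deflection $P_K$, body and
chamber temperatures $T_R, T_C$ (Kelvin), barometric pressure $P_B$,
chamber vapor pressure $P_C$ (humidity × saturation at $T_C$) and
saturation vapor pressure at body temperature $P_R$. Saturation vapor
pressure uses the Magnus–Tetens approximation (accurate to ~0.1 mmHg
over 0–50 °C). The construction is validated by inversion:
`simulatePleth()` encodes a known volume through the inverse equation
and the analysis recovers it within 2% across a grid of calibrations.
`ventilationSummary()` adds weight-normalized volume (ml/kg), breathing
frequency (60 / median inter-onset interval — robust to an occasional
missed breath) and minute ventilation as their product.

Hemodynamics follow the standard formula MAP = DP + (SP − DP)/3 applied
to windowed means, with heart rate from the mean cycle duration.

# Study bookkeeping

Timelines are ordered, half-open `[start, end)` epochs; three presets
cover the mouse EMG protocol (10-min baseline, vehicle, then 90 min
post-ligand split at the 30/60/90-min points), the rat plethysmography
sessions (20-min baselines, 30-min post-infusion observations in 5-min
bins) and the rat phrenic protocol (15-min baseline, hypoxic episode,
recovery, vehicle, then the post-ligand period). A `scale` argument
shrinks a protocol proportionally for simulation studies.

Per-epoch summaries average the final `summaryWindowS` seconds of each
epoch (default 60 s). Published figures label time points without
stating the averaging window, so it is a visible, configurable
parameter; steady-state sampling near the end of each period is the
default reading. Baseline normalization divides by each subject's own
baseline-epoch mean (the baseline of the baseline is identically 100%).
Subjects that die mid-protocol are censored: rows whose epoch starts at
or after the death time are removed, earlier rows retained. Histology
grids (C3–C6 × four quadrants, positive/negative per animal) are
tallied per cohort, and an animal with no positive cell anywhere in
C3–C6 is flagged excluded. Deteriorating nerve preparations — maximal
chemoreceptor challenge response below either hypoxic response — are
excluded by `qcFlagPreparation()` before statistics.

# Statistics

The battery mirrors how such studies are analyzed:

* `oneWayRmAnova()` — univariate repeated-measures ANOVA by explicit
  sums of squares, incomplete subjects dropped listwise (matching death
  censoring). The uncorrected p is reported alongside a
  Greenhouse–Geisser-corrected p (epsilon from the double-centered
  covariance); sphericity is an assumption the user can see being made.
  The explicit decomposition is cross-checked against `stats::aov` in
  the tests and is fast enough for Monte-Carlo calibration (its type-I
  error at the 9-subject, 5-level design is verified to be 0.05 ± 0.015
  over 2000 null replicates).
* `twoWayRmAnova()` — fully within-subject treatment × time ANOVA via
  `stats::aov` with the `Error(subject/(A*B))` stratification.
* `pairedT()`, `pearsonCorr()`, `chiSquaredYates()` — the last computes
  the Yates-corrected statistic in closed form (correction clamped at
  zero) and is cross-checked against `stats::chisq.test`.
* `tukeyHsd()` — studentized-range post hoc on the RM-ANOVA error term.
* `normalityGate()` — Shapiro–Wilk on residuals (plus Bartlett across
  groups where applicable) at alpha = 0.05; on failure the auto
  wrappers dispatch the Friedman test (one-way RM) or Wilcoxon
  signed-rank (paired). The two-way design has no standard
  nonparametric equivalent; a failed gate there should be flagged for
  manual review, not silently rerouted.

All tests are two-sided at alpha = 0.05, and all statistics are
invariant to positive rescaling of the metric.

# Simulation scale and what passing tests show

The validation suite runs the full pipeline at desk scale: protocols
shrunk 30–120×, 1–10 kS/s sampling, cohorts of 4–9 subjects, a 500-rep
null calibration of the end-to-end chain and a 2000-rep null
calibration of the ANOVA. With a 2.5× amplitude gain and zero
inter-subject variability the cohort-mean normalized post-ligand
peak-to-peak amplitude comes back at 250% within 3%, and with unit gain
the time effect rejects at the nominal 5% rate — i.e., the pipeline
neither manufactures nor hides an effect of the size the biology
reports.

The generator emulates the *statistical* character of these signals:
interference-pattern carriers, quasi-periodic bursts with log-normal
inter-subject variability, pulsatile pressure, inverse-equation breath
deflections. It does not model motoneuron biophysics, lung mechanics,
anesthesia depth, blood gases, movement artifacts, electrode drift, or
ECG contamination of the EMG. Passing tests therefore demonstrate that
the analysis chain is correct and well-calibrated on signals with known
truth — not that it is robust to every artifact a real rig produces.

# Numerical conventions

All times are seconds from recording start; intervals are half-open.
Smoothing windows become odd sample counts (round half up). Envelope
values are nonnegative by construction. Identical configurations and
seeds give bit-identical traces, ground truth and output bundles; run
manifests record all parameters so a bundle is reproducible from its
manifest alone. Degenerate inputs fail loudly and specifically: Nyquist
violations, envelope windows longer than the trace, a plethysmograph
calibration whose correction denominator is not positive, zero-variance
paired differences, zero-margin contingency tables.
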