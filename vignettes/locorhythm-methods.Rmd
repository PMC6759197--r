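---
title: "Quantifying fictive locomotor rhythms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fictive locomotor rhythms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locorhythm)
```

## The measurement problem

Locomotor-like ("fictive") activity in the isolated neonatal rodent spinal
cord is recorded as extracellular discharge from lumbar ventral roots:
bilateral flexor-dominated roots (L1/L2) and an extensor-dominated root
(L5). An optogenetic perturbation — a 60 s light window that hyperpolarizes
a genetically defined interneuron class — changes the rhythm's frequency,
the burst pattern (durations, interburst intervals, amplitudes, duty
cycles), the phase relations between roots, the synaptic drive to
motoneurons, and the calcium activity of identified interneurons. This
package implements the full measurement chain for such experiments, and a
synthetic-recording generator with exact ground truth so every stage can be
validated by parameter recovery.

## Neurogram integration

Raw root recordings (nominally 10 kHz) are converted to integrated
neurograms by a fixed cascade: low-pass 200 Hz, high-pass 10 Hz, full-wave
rectification, low-pass 5 Hz for drug-induced episodes or 20 Hz for
stimulus-evoked episodes (`integrate_neurogram()`). The cascade order is
part of the definition — permuting stages changes the result, and the test
suite pins this down.

The filter family and order are not dictated by the definition; we use
4th-order Butterworth stages applied forward and backward (zero phase),
because every downstream metric — burst onsets, offsets, phase lags — is a
*timing* measurement, and causal filtering would delay envelope edges by a
frequency-dependent amount. Edge transients are suppressed by odd-reflection
padding, three times the longest impulse-response proxy (fs / lowest
corner). Envelopes are then decimated to 19 Hz (`resample_envelope()`): an
anti-aliasing low-pass at 0.45 x the target rate followed by interpolation
on the exact 19 Hz grid, so all trials share one time base.

Trials are aligned to the light (55 s retained before and after the window)
or, for evoked episodes, from 1 s before the first stimulus to 4.5 s after
the last — 15.5 s for the standard 4 Hz x 10 s train (`align_trials()`).

## Wavelet frequency and phase tracking

`wavelet_spectrogram()` computes a continuous wavelet transform with a
complex Morlet (center-frequency parameter 6) on a log-spaced grid (16
voices per octave) spanning the rhythm band — [0.05, 2] Hz for drug
episodes, [0.2, 4] Hz for evoked ones, bracketing all frequencies of
interest (0.10–0.89 Hz) with margin. The time axis is resampled to exactly
3,200 bins over the analysis window so all trials are directly comparable.

The frequency time series (`extract_frequency()`) is the per-bin ridge:
the argmax of the amplitude-normalized magnitude over the band, refined to
sub-bin precision by a parabolic fit on the log-frequency grid. Amplitude
normalization (dividing |W| by sqrt(scale)) makes a pulse train's
fundamental dominate its harmonics regardless of duty cycle; the parabola is
fitted to log-magnitude with the sqrt(f) normalization tilt removed, which
is exactly quadratic for a Morlet responding to a tone, so a stationary
rhythm is recovered without grid-quantization bias. A 5-bin median filter
suppresses bin flicker. Empty spectrogram columns yield missing values, not
zeros, and missingness propagates through normalization and averaging as
pairwise-complete means.

Inter-channel phase (`extract_phase()`) is the argument of the
cross-wavelet coefficient at the reference channel's ridge, wrapped to
[0, 360); the first-named channel (the flexor-dominated root in the
standard pairs) is the reference, and a positive phase means the second
channel lags. Phase is antisymmetric under channel exchange by
construction.

Because the wavelet smears information over roughly its e-folding time
(about 1.37 / f for this Morlet), two guards apply. First, 10 s are trimmed
from each end of every series (`trim_edges()`), removing the transform's
edge artifacts. Second, when epoch means are formed (`epoch_means()`), bins
within one e-folding time of an epoch boundary or of a masked-out segment
can be eroded (`guard_efold = 1`, used by the pipeline drivers): a frequency
step at the light onset is smeared symmetrically, so bins inside the smear
window mix the two regimes and would bias the epoch mean toward the
neighboring epoch's frequency.

Normalization to percent change (`normalize_percent_change()`) divides by
the pre-light epoch mean, subtracts 1 and multiplies by 100, so the control
period averages zero; it applies identically to frequency series and to
resampled integrated envelopes.

## Burst segmentation and pattern metrics

Troughs and peaks of the integrated envelope are detected with
prominence-based extrema detection (`detect_cycles()`). Two realities of
integrated neurograms shape the implementation. First, the 5 Hz output
corner leaves broadband ripple riding on burst tops; extrema are therefore
*located* on a detection-stage copy smoothed at twice the dominant rhythm
frequency (estimated from the envelope's periodogram; the smoothing is a
zero-phase frequency-domain low-pass, stable at any corner-to-rate ratio)
and then *refined* on the raw envelope, so reported peak and trough values
are unsmoothed. Second, no absolute threshold is hand-tuned: the minimum
prominence is 20% of the smoothed envelope's interquartile range (floored
at a quarter of its range, since the quartiles of a sparse low-duty train
collapse onto the baseline), the minimum peak separation is half the
dominant period, and refined cycles whose raw amplitude falls below a
quarter of the median cycle amplitude are rejected as smoothing artifacts.

Burst boundaries follow the fractional trough-to-peak rule
(`burst_bounds()`): the onset is the last upward crossing, before the peak,
of the level trough + 0.40 x (peak − trough); the offset is the first
downward crossing after the peak of the corresponding level referenced to
the *following* trough. Using the following trough for the falling edge
treats the two edges symmetrically and is robust to slow baseline drift.
Crossing times are interpolated linearly between samples: at 19 Hz a
whole-sample quantization of 53 ms would be too coarse for bursts of a few
hundred milliseconds. Whether crossings should be interpolated or taken at
sample resolution is not externally fixed; we interpolate and state it here.

`burst_metrics()` tabulates duration, interburst interval (offset to next
onset), amplitude (peak − preceding trough), period (onset to next onset)
and duty cycle (duration / period); duration + interburst interval equals
the period exactly by construction. Cycles are labeled by the epoch
containing the peak; a cycle whose extent crosses an epoch boundary mixes
two regimes (the frequency and duty change at the light edges) and is
excluded from per-epoch statistics — with 55–60 s epochs and periods of at
most 10 s this costs at most one cycle per boundary. Cycles overlapping a
detected tonic interval are likewise dropped, and the period of the cycle
bridging a tonic gap is set missing, mirroring the restriction of the
analysis to the rhythmically active part of the signal.

Summaries follow the averaging order trial -> experiment -> group
(`epoch_summary()`, `aggregate_epoch_summaries()`), with percent changes
relative to the pre-light epoch, whose normalized mean is zero by
definition.

## Tonic-segment flagging

In hemisected cords the light can evoke an initial period of tonic
(elevated, non-oscillatory) discharge before the rhythm resumes at a higher
frequency. `flag_tonic()` marks a bin tonic when its rhythm-band
oscillation amplitude is low while the envelope level exceeds the pre-light
median. Three details matter:

* the oscillation cue is a single-frequency Morlet amplitude at the
  light-epoch rhythm frequency, computed on the running-median-detrended
  envelope — detrending removes the slow pedestal of the tonic plateau
  itself, which would otherwise leak power into the rhythm band;
* the threshold is the midpoint between the light-epoch amplitude floor and
  its rhythmic level, so the tonic-to-rhythmic boundary is located at the
  half-rise of the wavelet's symmetric temporal smearing — an unbiased edge
  estimate;
* candidate bins are scoped to the light window (tonic onsets are a
  light-onset phenomenon; the pre-light epoch defines "rhythmic"), gaps
  shorter than a third of a cycle are closed, and runs shorter than ~0.8
  cycles are discarded, since tonic activity is sustained.

When several channels are recorded, the pipeline intersects the
per-channel masks (ignoring channels whose detector found no tonic
segment): tonic discharge is preparation-wide, so a bin counts as tonic
only while no channel oscillates — a channel whose post-tonic burst fuses
seamlessly with the plateau cannot, on its own, stretch the detected
segment. The reported tonic extent is the midpoint between the mask's end
(a lower bound — wavelet smearing pulls it early) and the first detected
burst onset after it (an upper bound — the oscillator resumes up to one
cycle before its first burst); across trials the extent is averaged over
trials in which a segment was detected, since a failed detection on a weak
trial is not a zero-length estimate. The criterion
delimiting the "rhythmically active part" is our operationalization; all
its parameters are exposed.

## Bootstrap comparison of time series

Two groups of experiments are compared pointwise
(`bootstrap_timeseries_test()`). The observed statistic per time bin is the
Welch t between the groups' experiment-level values (group sizes differ, so
pooled variance is not assumed). The null is built by centering each group
on the pooled mean at every bin and resampling *experiments* with
replacement within each group — experiments are the independent replicates
of the design; resampling trials or time points would understate the
between-preparation variance. The two-sided p-value uses the +1-corrected
empirical tail, p = (1 + #{|t*| >= |t_obs|}) / (B + 1), so p is never zero
at finite iterations; 10,000 iterations is the reference setting.
Significance is displayed in the conventional bands (ns, <0.05, <0.01,
<0.001, <0.0001) with strict inequalities — p = 0.05 is not significant.
Inference is pointwise with no multiplicity correction, mirroring the
banded display this reproduces. Calibration is verified by simulation:
type-I error per bin at the 0.05 band stays within binomial error of
nominal over 200 null replicates at the study's group sizes (16 vs 9).

## Circular statistics

Phase data live on the circle; `circ_mean_r()` returns the circular mean
and the mean resultant length R (the concentration of phases, 1 =
coincident, 0 = balanced). `rayleigh_test()` applies the standard
uniformity test with the finite-n correction. `watson_williams()` tests
equality of circular means across groups with the 1 + 3/(8 kappa)
concentration correction; when the pooled mean resultant length falls below
the test's usual validity range (0.45) a warning is attached rather than an
error, since locomotor phase samples are often small. `harrison_kanji()`
implements the two-way ANOVA for angles from cell/row/column resultant
decompositions: F tests with the concentration correction when the
estimated kappa exceeds 2, and the large-sample chi-squared variant with
doubled degrees of freedom at low concentration. We report the full (F, df,
p) triple. A Best–Fisher von Mises sampler (`rvonmises()`) supports the
Monte-Carlo calibration tests.

## Intracellular analysis

Spikes are detected at an absolute threshold (−20 mV) with a dV/dt
confirmation (10 V/s) and refractory enforcement (`detect_spikes()`); both
thresholds are configurable. For cycle-triggered averages of the locomotor
drive (`cycle_triggered_average()`), spikes are first removed with a 15 ms
running median — the drive is the slow synaptic envelope, and no standard
removal method is externally fixed, so the median filter (which preserves
slow ramps while clipping brief spikes) is our choice. Each cycle is
resampled onto 200 phase bins, averaged, and displayed over two duplicated
cycles; drive amplitude is max − min of the mean waveform and the trough
potential its minimum. Per-cycle extrema are available as an alternative
amplitude estimate; the CTA extremum is the default. Input resistance
(`input_resistance()`) is the OLS slope of the current/voltage relation
restricted to the linear range — the largest contiguous subset of steps
whose maximum residual stays below 2% of the fitted span. Liquid-junction
potentials are not corrected.

## Calcium-imaging chain

Registered stacks are reduced to ROI traces (`extract_trace()`: per-frame
pixel means) using either six equal rectangles tiling the field
dorsoventrally (`make_grid_rois()`; an indivisible height leaves the
remainder to the last rectangle) or cell ROIs paired with doughnut annuli
out to twice the cell radius, excluding all cell pixels
(`make_cell_rois()`; the annulus width is our choice, as no dimensions are
externally fixed). Processing is ordered and the order is enforced through
state flags: neuropil subtraction -> bleach correction -> dF/F ->
band-pass; out-of-order application (including double dF/F) is rejected.
Bleach correction fits a e^{-t/tau} + c and subtracts only the exponential
component — the constant offset is camera baseline, which never decays to
zero. The fit is bounded (|a| within twice the data range, tau between
1/100 and 20 record lengths) to keep it away from the degenerate a/c
tradeoff at tau much longer than the record, where an exponential is
indistinguishable from a line; a non-convergent fit falls back to a linear
detrend with a warning.
dF/F uses the trace minimum as f0, exactly as defined; a percentile f0 is
available but off by default. The band-pass is a zero-phase Butterworth in
[0.05, 0.8] Hz. Whether bleach correction preceded or followed neuropil
subtraction is ambiguous in the original description; we subtract neuropil
first (the shared signal is multiplicatively bleached in the same way, so
subtracting first removes it before the exponential fit) and the order is
configurable only by calling the stages directly.

## The synthetic-data generator

Because no raw recordings are publicly deposited, validation rests on
synthetic cohorts with exact ground truth (`simulate_neurograms()`,
`simulate_intracellular()`, `simulate_calcium()`). A common phase
oscillator with a piecewise-constant frequency profile drives per-channel
envelopes: periodic rectangular pulses of programmed duty cycle and phase
offset, smoothed by a raised-cosine edge of default width 10% of the
period (smooth enough to match integrated-neurogram morphology, narrow
enough that the programmed square boundaries remain the analytic truth).
The trace is baseline Gaussian noise plus the envelope times a zero-mean
broadband Gaussian carrier (a rate-modulated spike-train carrier is a
config option). Light modulation multiplies frequency, per-channel
amplitude and per-channel duty; the hemicord tonic onset freezes the
oscillator and clamps the envelope high for its programmed duration.
Ground truth records the frequency profile, all burst boundaries,
amplitudes, duty cycles and the seed; everything is bit-reproducible from
(spec, seed), with one RNG stream per channel and stage via counter-based
seed splitting so adding channels never perturbs existing ones.

Scenario presets program the study conditions: the whole-cord drug rhythm
(0.33 ± 0.06 Hz slowing by the factor 0.29/0.33 in light; pre-light duties
extensor 0.59 ± 0.04, flexor 0.53 ± 0.07; flexor burst duration x1.402 ±
0.1525 in light), the hemicord rhythm (0.10 ± 0.02 Hz, 10 s tonic onset,
then acceleration x1.7; duties flexor 0.35 ± 0.06, extensor 0.61 ± 0.09;
extensor burst duration x0.6061 ± 0.2236), and dorsal-root-evoked episodes
(0.89 Hz baseline; light reduction drawn from 21.6 ± 10.23%). Design
choices the printed values do not determine, stated once here:

* per-experiment parameters are drawn from normal distributions truncated
  at ±2 SD, avoiding pathological draws while matching the printed spread;
* within-experiment trial-to-trial frequency variability is 5% of the base
  frequency (no magnitude is printed for it), and three trials per
  experiment are simulated by default;
* the hemicord light acceleration is a per-experiment factor of mean 1.7
  with 5% relative SD: the printed ±0.06 spread of the light-epoch
  frequency and the very wide per-experiment percent increases partly
  reflect within-experiment measurement spread, which the generator's
  truth does not reproduce;
* the published hemicord light duty cycles are mutually inconsistent with
  the published burst-duration changes under the published frequency
  change; the presets are parametrized by the frequency and burst-duration
  factors (the quantities recovered downstream), and the light duty
  follows from them;
* independent ±2 SD draws of duty, duration factor and frequency factor
  can jointly imply a light duty cycle approaching 1 — a burst with no
  interburst gap, which no recorded rhythm shows and which makes the
  fundamental/harmonic distinction ill-posed; the implied light duty is
  capped at 0.85;
* the evoked preset's control frequency SD across experiments (0.10 Hz)
  is a realistic choice, as only the mean (0.89 Hz) is printed;
* evoked experiments are simulated as paired cohorts of control and lit
  15.5 s episodes (that is the experimental design), and the
  per-experiment frequency effect is the percent change between the two
  trial means.

What the generator does *not* emulate: cycle-to-cycle period wander
(available as a parameter, zero by default so that truth stays exact),
slow drug-washout drifts, motion artifacts in imaging (registration is out
of scope; stacks are assumed registered, with a frame-correlation warning
hook), and biophysical network dynamics. Passing recovery tests on these
cohorts therefore demonstrates that the measurement chain is unbiased and
correctly calibrated for signals with the study's morphology and noise
level — not that it is robust to every artifact of real recordings.

## Numerical choices and degenerate inputs

Constant envelopes yield empty cycle tables, not errors; all-zero
spectrogram columns yield missing frequencies; a quiescent (all-zero)
envelope is never flagged tonic (quiescence is not tonic activity).
Flat-topped cycles whose threshold level is never crossed are skipped with
a warning. Sampling-rate preconditions are checked at every stage
(integration corners, spike detection at >= 5 kHz, calcium band-pass
against the frame rate). Phase offsets outside [0, 360) are wrapped, not
rejected. Percent-change normalization refuses non-positive baselines.
Bootstrap p-values are never zero by construction. Problem sizes used by
the packaged checks — 2 kHz synthetic sampling (an order of magnitude above
the highest integration corner; the envelope chain is unchanged), cohorts
of 16/13/12 experiments with 3 trials each, 2,000 bootstrap iterations for
calibration sweeps and 10,000 as the single-test reference — are the
package's own validation settings.

## Known limitations

Ridge tracking assumes one dominant rhythm per channel; crossing rhythms
would need penalized ridge continuation. The Harrison–Kanji low-
concentration branch is a large-sample approximation. The tonic-segment
criterion is our operationalization of "the rhythmically active part" and
its accuracy is bounded by the wavelet's temporal resolution (about ±1 s
at the hemicord frequencies). The bootstrap test is pointwise; a
family-wise option exists but is off by default to mirror the banded
display convention.
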