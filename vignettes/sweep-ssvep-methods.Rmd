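---
title: "Sweep ssVEP threshold extraction: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep ssVEP threshold extraction: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepvep)
```

## The measurement problem

A sweep steady-state visually evoked potential (ssVEP) experiment estimates a
sensory threshold without asking the observer anything. A grating reverses at
20 patterns per second while one stimulus parameter — Michelson contrast (%),
spatial frequency (cycles/degree), or orientation tilt (degrees) — is stepped
through 18 logarithmically spaced values, one second per step, with the first
and last steps repeated as preview and postview (20 s per trial). The visual
cortex responds with an oscillation at the reversal rate; its 20 Hz spectral
amplitude grows with stimulus visibility, and the threshold is read off as
the stimulus level where that response emerges from the noise floor.

`sweepvep` implements this pipeline end to end — spectral estimation,
electrode selection, two threshold rules, a simulated QUEST behavioural arm,
and the reliability statistics used to compare them — together with a
synthetic-data generator so every stage can be validated against known
ground truth.

## Spectral model

Each retained 1-s epoch is averaged in the time domain across trials of the
same condition, direction, and step, then a single-bin discrete Fourier
transform at 1 Hz resolution gives amplitude and phase at 20 Hz. With the
normalisation `2|X_k|/N`, a sinusoid `a sin(2π f t + φ)` reads amplitude `a`
microvolt and phase `φ` (sine-basis convention, reported in (−π, π]); the
suite verifies this identity to 1e-9 and checks the single bin against a
direct-summation full transform.

The noise floor at 20 Hz is estimated from the 12 neighbouring 1 Hz bins —
six on each side, skipping the immediately adjacent 19 and 21 Hz bins — as
their mean and standard deviation (sample, n−1 normalisation; the convention
had to be fixed somewhere and the small-sample default is the conservative
choice). From these:

* adjusted amplitude `adj_amp = amp − noise_mean`,
* z-score `z = adj_amp / noise_sd`,
* signal-to-noise ratio `snr = amp / noise_mean`.

Rows with a zero noise SD or mean (e.g. an all-zero waveform) are flagged and
carry undefined `z`/`snr` rather than infinities.

## Electrode selection

Threshold extraction runs on a single electrode per condition: the one with
the highest mean z over the easiest half of steps (2.05–30 % contrast,
2.7–11.2 cpd, 0.34–4.96°). Ties break to the first electrode in montage
label order, so selection is deterministic.

## Threshold rules

**Sig rule.** Steps are marked significant when `z > 2.33` — the one-sided
standard-normal 1% point (strict inequality; undefined z counts as
non-significant). For a decreasing-intensity sweep the threshold is the
*last* non-significant step (in sweep-time order) with at least three
significant steps among the four immediately preceding; for an
increasing-intensity sweep the default rule is the time-mirror — the *first*
significant step with at least three non-significant among the preceding
four. Two readings of the increasing-intensity case are defensible; the
alternative (take the *last* such step) is available as
`selection_config(sig_rule = "swapped")`. Steps without a full four-step
history are never candidates, so a sweep's first four steps cannot be called
threshold. Intensity direction is derived from the design, not the parameter
direction: a spatial-frequency sweep towards higher cpd is a
decreasing-intensity sweep. Note that the decreasing-intensity reading
("last" qualifying step) sits one step deeper into the silent region than
the increasing-intensity mirror by construction; on clean data the two
directions' thresholds therefore bracket the true value rather than
coincide, which is why direction-combined scores use the mean on the
spacing scale.

**Reg rule.** A line is fitted by ordinary least squares to the raw 20 Hz
amplitude against the condition's fit axis — log10 contrast, linear
cycles/degree, log10 degrees of tilt (orientation is not covered by the
older extrapolation literature; the log axis matches its log-spaced sweep).
The fit window opens at the first amplitude peak (leftmost local maximum in
easy-to-hard order, plateaus counting) with SNR ≥ 3 and closes at the first
subsequent step whose amplitude drops below the mean noise floor (or the
last step). The threshold is the fitted line's zero crossing mapped back to
stimulus units. A result is valid only if

1. the slope has the amplitude-declining sign towards harder stimuli,
2. the zero crossing lies on the hard side of the fit window, and
3. the response phase is credible: constant or gradually leading for
   contrast, constant or lagging for spatial frequency, constant for
   orientation.

Phases are unwrapped first; "constant" means within π/4 of the window mean,
and leading/lagging means per-step increments within [0, π/4] or [−π/4, 0].
The tolerance is a package default — no numeric value is standard — and the
phase window is restricted to fit-window steps meeting the same SNR ≥ 3
criterion as the onset, because phase at or below the noise floor is
uniformly distributed and would veto otherwise clean fits.

**Combining directions.** One score per condition and repetition is the mean
of the increasing- and decreasing-sweep thresholds on the condition's
spacing scale: geometric mean in native units for contrast and orientation,
arithmetic for spatial frequency. A single valid direction passes through,
flagged.

## QUEST behavioural arm

The behavioural arm is a simulation, not a human protocol. An observer is a
cumulative Gaussian `p(x) = γ + (1 − γ − λ)Φ((x − α)/β)`; QUEST maintains a
discrete posterior over candidate thresholds (301-point grid, Gaussian
prior), updates it by Bayes rule after every response, and places the next
trial at the posterior mean (QUEST+-style; the mode is available via
`placement = "mode"`). Because the staircase's assumed likelihood is the
same cumulative-Gaussian family, the posterior-mean placement targets the
function's steepest point automatically: 75% correct for 2AFC (γ = 0.5),
62.5% for 4AFC (γ = 0.25). Sessions run 60 trials (30 for the 4AFC acuity
analogue); a minimum-testable floor (0.25° for orientation) clips proposed
levels. `fit_psychometric()` provides the matching maximum-likelihood
cumulative-Gaussian fit with fixed γ and λ.

The grid, prior, and placement rule are not prescribed by the QUEST
literature in any unique way; all are exposed in `session_config()` with the
defaults above.

## Statistics battery

* **Outlier removal** uses the modified z-score of absolute score
  differences: `Zdiff = 0.6745 (diff − median(diff)) / MAD` with
  `MAD = median(|diff − median(diff)|)`; pairs with `Zdiff > 3` are excluded
  symmetrically from both vectors. (The signed-median denominator sometimes
  printed for this statistic is identically ~0 and unusable; the 0.6745
  constant identifies the MAD-based modified z-score.) A zero MAD excludes
  nothing and warns.
* **Test-retest reliability** is ICC(3,1): two-way mixed-effects,
  consistency, single measure, computed from the ANOVA decomposition
  `r = (MSR − MSE)/(MSR + MSE)` with an F-test on (n−1, n−1) degrees of
  freedom. The test suite pins it to `aov()`-derived mean squares to 1e-10.
* **Between-test and between-method association** is Spearman's rank
  correlation (Pearson on mid-ranks), with an exact permutation p for n ≤ 9
  and the t approximation otherwise; Cohen's 0.1/0.3/0.5 bands label the
  magnitudes. p values are reported unadjusted, as is conventional for this
  battery.
* EEG test-retest pairing is configurable: `"directions"` (default) treats
  the increasing- and decreasing-sweep thresholds as the two measurements;
  `"repetition_halves"` scores each half of the trials separately, averaging
  directions within a half.

## Synthetic-data generator

The generator is statistical, not biophysical. A sweep recording is, per
step, a 20 Hz sinusoid (plus a 40 Hz harmonic at 30% amplitude) whose
amplitude is zero at and below a ground-truth threshold and rises linearly
on the condition's easiness scale (gain 4 µV per easiness unit, capped at
8 µV), multiplied by a Gaussian scalp topography centred on Oz
(σ = 0.15 layout units, making the response focal enough that the
occipital-mean reference retains most of the Oz signal — the regime in which
single-electrode selection at Oz is the right analysis), on top of 1/f noise
(2 µV SD) plus white noise (1 µV SD). Optional biphasic frontal "blink"
transients (default off) exist to exercise epoch rejection. Orientation
sweeps nominally start at 0°, which geometric spacing cannot represent; the
generator uses a 0.05° floor as the lowest step. The default sampling rate
is 256 Hz — the emulation targets 20/40 Hz content, so acquisition-grade
rates add nothing but runtime; 2048 Hz input is supported and downsampling
is part of the preprocessing chain.

Score tables come from a separate latent common-factor model whose expected
ICC per test and expected between-test Spearman (of repetition-averaged
scores) equal the requested targets; the loadings absorb the attenuation
from occasion noise, and the Gaussian rank-correlation identity
`ρ_Pearson = 2 sin(πρ_S/6)` converts the Spearman target.

What the generator does *not* emulate: pattern-reversal waveform morphology,
eye movements, volume conduction, alpha-band structure, non-stationary
noise, or inter-individual variation in response-curve shape. Passing tests
therefore demonstrate that the algorithms do what they claim on data with
known structure — not that real recordings satisfy that structure.

## Numerical choices

* Filters are zero-phase FIR (Hamming design, transition bandwidth 25% of
  the cutoff, forward-backward application), with taps normalised to exact
  unit DC gain. Downsampling applies this anti-alias filter at 80% of the
  new Nyquist and then evaluates on the new grid by linear interpolation;
  at a 20 Hz analysis frequency the interpolation error is far below the
  1% amplitude tolerance the tests enforce.
* Epoch rejection is an automated peak-to-peak criterion (default 150 µV)
  standing in for manual inspection; it is a tunable, not a calibrated
  reproduction of any reviewer's rejection rate.
* The occipital reference set defaults to {O1, O2, Oz, POz, Iz}
  (configurable); bad channels are interpolated by inverse-distance
  weighting over the four nearest neighbours on an idealised schematic
  layout.
* Degenerate inputs fail loudly and specifically: zero noise SD flags the
  row, an all-false significance mask returns an invalid result with a
  reason, a fit window shorter than two points refuses to extrapolate, a
  zero MAD warns and excludes nothing.

## Problem sizes used by the tests and the acceptance script

Simulation sizes are chosen so the whole validation is a desk-scale
computation: QUEST calibration uses 200 sessions per task; Sig-rule
recovery uses 100 single-electrode sweeps at two trials each (with the
response gain set so the ~8 suprathreshold steps clear the z criterion —
the operating regime the rule is designed for); the periodogram check pools
six increasing and six decreasing 19-channel sweeps per seed over ten
seeds; the end-to-end pipeline demonstration runs an 8-participant cohort
at 256 Hz. These sizes give stable Monte-Carlo estimates at the stated
tolerances while keeping a full run in minutes on one core.

## Known limitations

* The Sig rule is defined on steps; no interpolation between steps is
  attempted, so its resolution is one log step, and its two directions are
  intentionally asymmetric (see above).
* The Reg rule extrapolates; on data whose amplitude curve is convex rather
  than linear it is systematically biased, and its validity filter (phase,
  slope sign) then does the real work.
* ICC and Spearman are implemented for the paired (k = 2) designs this
  battery uses; the ICC is not a general k-rater implementation.
* The columnar text format is the only recording I/O; it is lossless for
  the simulator's output but makes no attempt to read vendor formats.
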