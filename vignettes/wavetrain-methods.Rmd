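---
title: "Wave-train analysis of EMG envelopes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-train analysis of EMG envelopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavetrain)
```

## The model

A *wave train* is a transient increase of a signal's power spectral
density localized in time and frequency. Surface EMG envelopes of
tremor patients contain such events in the classical tremor bands
(Parkinsonian ~3-8 Hz, physiological ~8-12 Hz, operationally up to
20 Hz), and the premise of the method is that the *number* of wave
trains per second, inside a suitable region of the event-attribute
space, discriminates patient groups even where average spectra do not.

The analysis chain is:

1. **Preprocessing** (`preprocess_emg()`): 50/100/150/200 Hz notch
   filters (second-order IIR, Q = 35, zero-phase), a 60-240 Hz
   fourth-order Butterworth band-pass applied forward and backward (so
   the effective magnitude response is the squared Butterworth response
   and the phase is exactly zero), the Hilbert envelope (modulus of the
   analytic signal), and 4x decimation with an anti-alias low-pass
   (zero-phase, cut-off 0.8x the target Nyquist). A 500 Hz recording
   becomes a 125 Hz envelope. The first and last second are flagged as
   filter transients and excluded from detection.

2. **Time-frequency analysis** (`cwt_spectrogram()`): the complex
   Morlet wavelet `psi(x) = (pi*Fb)^(-1/2) exp(2*pi*i*Fc*x) exp(-x^2/Fb)`
   with `Fb = Fc = 1`, scale `a = Fc/f`, on a regular frequency grid
   (0.1-50 Hz in 0.1 Hz steps by default). The wavelet's time and
   frequency widths at analysis frequency `f` are
   `sigma_t = (Fc/f) * sqrt(Fb/2)` and `sigma_f = 1/(2*pi*sigma_t)`.

3. **Adaptive smoothing** (`adaptive_smooth()`): a 2D Gaussian whose
   standard deviations are *half* the wavelet's own widths at each
   frequency, which suppresses the squared-modulus speckle without
   distorting blob shapes.

4. **Detection and measurement** (`detect_wavetrains()`): strict
   8-neighbour local maxima of the smoothed spectrogram; each maximum
   is characterized by its central frequency, maximal PSD, half-maximum
   duration (converted to periods by multiplying with the central
   frequency) and half-maximum bandwidth, with linear interpolation at
   the half-max crossings. Maxima whose half-max region is cut by the
   record edge, or whose slice rises above the peak before crossing the
   half level (a maximum engulfed by a larger neighbour), are rejected
   with coded reasons; events shorter than 1/10 period are dropped.

5. **Group comparison** (`auc_diagram_2d()`, `auc_diagram_3d()`,
   `refine_wavetrains()`): per-subject event rates inside parameter
   ranges are compared between groups by the area under the ROC curve,
   with the patients as the positive class (AUC > 0.5 = more wave
   trains in patients). A 2D AUC diagram scans all (lower, upper) bound
   pairs of one attribute; a 3D diagram stacks such scans over
   resolutions `R` with Mann-Whitney significance masks at the
   Sidak-form corrected level `alpha_B = 1 - (1 - alpha0)^(1/C)`,
   `C = R*(R+1)/2`.

## Calibration of the spectrogram

The power scale is the *tone-power calibration*: a stationary sinusoid
of amplitude `A` reads `A^2/2` at its own frequency at every analysis
frequency (`tone_peak_psd()`), and white noise of variance `sigma^2`
reads an expected floor `2*sigma^2*f/(fs*Fc*sqrt(2*pi*Fb))` that rises
with the analysis frequency in proportion to the widening wavelet
bandwidth (`noise_floor_psd()`).

This choice is deliberate. A per-Hz density normalization (dividing by
the wavelet's equivalent noise bandwidth) multiplies each row by a
factor proportional to `1/f`, which tilts the flat-topped profile of a
tone and biases its spectral argmax downward by `f/(4*pi^2)` - about
1.3 Hz at 50 Hz. Under the tone-power calibration the argmax of a pure
tone is unbiased to machine precision across the whole grid, and both
half-max slices of a Gaussian burst follow the Gaussian-convolution
closed forms without tilt. Absolute PSD thresholds (such as a
"minimum 30 uV^2/Hz" selection) are therefore configuration values on
this package's scale, not universal constants.

Two further numerical choices matter at the top of the frequency grid.
The transform runs on the *analytic signal* (halved): a real signal's
negative-frequency image folds across the Nyquist frequency into the
wide wavelet pass-band above ~45 Hz and can shift the very flat argmax
of a tone by a couple of grid steps; the analytic form removes the
image exactly, and also removes the `2*f` interference beating from
time slices. Wavelet kernels are truncated at +/-6 envelope standard
deviations (amplitude step ~1.5e-8) for the same flatness reason.

The smoothing is implemented in *scatter* form: every source row is
spread with the kernel of its own frequency, and the output is divided
by the deposited weight field. A gather implementation (output row's
kernel) pulls smoothed peaks toward higher frequencies by ~1.4% of `f`,
because kernels widen with frequency; the weight-normalized scatter
keeps constant fields exactly invariant and peak locations unbiased.

## Attribute accuracy and its limits

For an isolated Gaussian burst with squared-envelope FWHM of
`d` periods at `f0` Hz, the measured half-max widths follow the
convolution of Gaussians: the time slice has
`FWHM_t = 2*sqrt(2*ln 2 * ((s^2 + sigma_t^2)/2 + sigma_t^2/4))` with
`s = d/(2*f0*sqrt(ln 2))`, and the frequency slice the analogous form
with the spectral widths. Measured durations are therefore
*systematically longer* than the nominal burst duration - a 1-period
burst reads about 1.75 periods - which is inherent to measuring at
half maximum after wavelet filtering and smoothing, not an error.

The central frequency of a *short* burst carries a systematic upward
pull of order `sigma_bf^2/f` (with `sigma_bf` the burst's spectral
width): rows above the true frequency have wider collection bandwidths
and capture more of a broadband burst's energy. The pull is negligible
for tones, below 0.1 Hz for bursts of 3 periods and more in the tremor
bands, but grows past 1 Hz for sub-period bursts at high frequencies.
Attribute-accuracy validation therefore uses well-resolved bursts
(8-20 Hz, 2-4 periods, amplitude SNR 20); short bursts are still
detected and counted - which is all the rate statistics use - but
their measured frequencies should not be over-interpreted. Validation
runs at amplitude SNR 20 because the argmax of the flat slice profiles
jitters with the noise floor; at amplitude SNR below ~10 the frequency
jitter alone exceeds 0.2 Hz.

## The synthetic cohort generator

`cohort_spec()` / `synth_cohort()` emulate typical tremor-study conditions: 10
controls and 12 patients, 90 s single-channel records, 125 Hz envelope
sampling. Events are Gaussian-windowed sinusoids with Poisson onsets;
the defaults place a shared broadband background (1-50 Hz,
1.2 bursts/s) under a physiological-tremor band (8-20 Hz) in which
patients have three times the control rate (1.5 vs 0.5 bursts/s) -
per-subject rates at the scale the method reports on real tremor
cohorts. Burst amplitude is 25 uV over a 10 uV white-noise background
(bursts ~2.5x background, matching envelope recordings of real tremor bursts), and
burst durations are drawn from 0.5-2 periods (~1-period bursts
dominate the tremor-band regularity).

Each band's rate carries a per-subject lognormal multiplier (mean 1;
CV 0.5 for the background, 0.2 ... 0.4 for the tremor band). This
between-subject heterogeneity is essential, not cosmetic: with
clone-identical subjects, even a tiny but perfectly consistent
difference - for example the handful of background speckle maxima that
each strong burst's smoothed skirts absorb - saturates at AUC 0 and
outranks the genuine effect. No clinical cohort is homogeneous in this
sense.

What the generator does *not* model: real EMG background spectra
(unknown; white or band-limited Gaussian noise is an assumption),
motor-unit physiology, inter-muscle crosstalk, nonstationary tremor
amplitude drift, or any spatial structure across channels. Passing
synthetic tests therefore validates the *statistical machinery* -
detection geometry, attribute calculus, rate comparison, multiscale
correction - and not the clinical claims.

An important emergent property of the simulation, worth knowing when
reading diagrams of real data too: the smoothed spectrogram of any
continuous noise background carries on the order of one spurious local
maximum per resolution cell (about 4-5 per second over a 1-50 Hz grid,
independent of the noise variance, since detection is thresholdless).
These background events dilute unconstrained rate comparisons, and
strong bursts *suppress* nearby speckle maxima, which can produce
adjacent bands where patients have consistently *fewer* events. Both
phenomena reproduce the "multidirectional differences" visible in
published diagrams, and both are the reason the refinement's PSD
constraint is so effective: the background maxima sit at the noise
floor and are stripped by a minimal-PSD bound.

## The refinement loop and diagram reading

The exploratory refinement (`refine_wavetrains()`) is formalized as:
build all four diagrams under the current constraints (a diagram's own
parameter bounds are never applied to itself), apply the best cell -
the largest `|AUC - 0.5|`, ties broken toward the widest range (the
most conservative constraint), then the smallest lower bound - and
stop when the best score no longer improves by more than `eps = 0.01`
(`no_change`), degrades by more than `delta = 0.05` (revert,
`degraded`), or after `max_iter` steps. Cross-diagram ties compare the
covered *fraction* of each parameter's grid, since widths in Hz,
uV^2/Hz and periods are incommensurable.

The final reported box is produced by the *diagram reading* rule
(`core_cell()`), which formalizes how the diagrams are read by eye:
the near-diagonal cells (narrowest admissible ranges) locate where the
groups differ, and the characteristic range is the contiguous run of
same-colored near-diagonal cells whose score stays above half the peak
score. This stays informative where `best_cell()` saturates: once
constraints remove the diluting background, whole nested families of
ranges reach AUC 1 and "the widest perfect cell" is the uninformative
full range, while the diagonal run still marks the band. Parameters
the loop constrained explicitly keep their applied cells; the
remaining parameters are read sequentially (strongest diagonal
contrast first; PSD preferred on ties because it separates signal
events from background texture), rebuilding the diagrams between
reads.

Two caveats are documented deliberately. First, the half-peak run
threshold is a calibration of this package's formalization; the
manual reading it formalizes is human judgment. Second, the AUC-only cell
chooser can be hijacked on some data sets by a chance perfectly
separating cell in the enormous bandwidth scan (~126k cells with 22
subjects) - precisely the multiple-comparisons over-fitting that the
3D significance masking quantifies. When exploring real data, consult
the 3D diagrams and their corrected masks before trusting a refined
box, and prefer re-running the refinement from alternative starting
areas.

## Multiscale significance

Each 3D-diagram slice at resolution `R` partitions the range into `R`
equal bins and tests its `C = R*(R+1)/2` cells at
`alpha_B(R) = 1 - (1 - alpha0)^(1/C)`. Mann-Whitney p-values are exact
for group sizes up to 12 without ties, otherwise normally approximated
with tie and continuity corrections; with count data ties are the
norm, so the approximation path dominates in practice and is slightly
conservative. The horizontal slice is the unit of inference: one picks a resolution
(typically where the isosurface peaks) and reads that slice, and the
correction bounds the type-I error of each slice's full scan at
`alpha0`; this per-resolution control is verified by simulation in the
test suite. Family-wise error over a *whole stack* of slices is not
bounded by `alpha0` - the `R = 1` slice alone spends the entire
budget, so the union over resolutions runs near `2*alpha0` empirically
(both rates are reported by the acceptance script). Sharper
corrections that treat scale as an explicit dimension are a known
extension point and out of scope here.

## Problem sizes used in validation

The test suite and the acceptance script run the full chain at the
study's record length (90 s at 125 Hz) with detection grids of 0.1 Hz
(single-record attribute checks) or 0.2 Hz (the 22-subject cohort),
100/40 seeded bursts for attribute recovery, and 200/100 null cohorts
for the family-wise error check - sizes chosen so each property is
measured with useful precision by an ordinary laptop run.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
reported quantity from scratch: the corrected alpha of the Welch
comparison, the AUC/U identity, tone recovery, burst-attribute
recovery against the closed-form oracle, the synthetic cohort's
tremor-band AUC and refined frequency bounds, and the null
family-wise error rate of the 3D scan.
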