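---
title: "Acoustic cues to maturity and identity in male elephant rumbles: methods"
author: "rumblr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic cues to maturity and identity in male elephant rumbles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumblr)
```

## The scientific question

Male African elephants produce low-frequency, harmonically rich social
rumbles whose fundamental frequency (F0, roughly 8-20 Hz) is set by
vocal-fold vibration and whose spectral envelope is shaped by vocal
tract resonances (formants). Under the source-filter framework both
layers can carry information about the caller: formant spacing scales
inversely with vocal tract length and hence body size, and absolute F0
decreases with age and mass. `rumblr` implements the full analysis
chain used to quantify this information content: per-call acoustic
feature extraction, variable screening, PCA reduction, and a permuted
discriminant function analysis (pDFA) that respects the repeated-calls
structure of bioacoustic datasets. Because no recordings are deposited
with the study this package is modelled on, a synthetic source-filter
rumble generator with known ground truth closes the loop, so that every
stage is testable end to end.

## The reference cohort

The reference design is embedded in the package: ten male elephants in
two maturity groups (group 1: shoulder height above 3 m and age above
25 y; group 2 below both), retained by the inclusion rule of at least
10 analyzable calls per male, with calls capped at 20 per male by
seeded subsampling (`select_calls()`). Applied to the published call
counts (`table1_subjects()`), the rule retains 10 of 13 males with
group totals of 79 and 83 calls. Age and shoulder height are strongly
correlated in such cohorts (here r = 0.95), which is why the two are
collapsed into a single "maturity" factor. `table3_reference()` holds
the published group means and SDs of the five features that separate
the groups (formants 1-2, maximum/minimum/finish fundamental
frequency) and is the calibration target of the simulator.

## The synthetic rumble generator

`synthesize_rumble()` renders one call from a `synth_call_spec()`:

* **Source.** A sum of `harmonic_count` harmonics of the
  phase-integrated F0 contour (piecewise linear start -> mid -> end),
  with a -6 dB/octave amplitude rolloff. Only the spectral structure
  matters downstream, so no physical vocal-fold model is attempted.
* **Filter.** A cascade of two-pole resonators, one per formant, each
  gain-normalized at its centre frequency. Default bandwidths are 10%
  of the centre frequency, which keeps the peaks resolvable at
  infrasonic formant spacing.
* **Edges and noise.** A 0.15 s raised-cosine onset/offset ramp (calls
  start gradually; an abrupt edge would ring the narrow resonators
  unrealistically), then Gaussian noise at `noise_snr` dB, then peak
  normalization. The default sample rate is 4000 Hz; formant analysis
  downsamples to 2000 Hz regardless.

`sample_feature_cohort()` draws feature-level cohorts: per individual
one Gaussian intercept per feature (SD a fraction of the residual SD,
default 0.2), then per-call values around the shifted group mean.
Additive, feature-independent intercepts are the simplest structure
that makes individuality detectable by the pDFA; the study this package
follows reports no per-individual moments, so the intercept scale is a
free parameter chosen for testability, not biological fidelity.
`make_waveform_cohort()` renders each sampled row to audio (F0 rising
from the sampled minimum to the maximum and falling to the finish
frequency, call durations uniform on 3-6 s) and writes WAV files, an
annotation table and a ground-truth sidecar.

What the generator does **not** emulate: amplitude/propagation effects,
musth-rumble pulsation, nasal-versus-oral production differences,
correlated feature structure within calls, or recording-chain
artefacts. Passing round-trip tests on these fixtures therefore shows
that the estimators are correct for clean source-filter signals, not
that they are robust to every field recording.

## Tracing the fundamental

`trace_f0()` computes a short-time Fourier spectrogram (300 ms Hamming
frames, 40 ms hop, zero-padded to at most 0.5 Hz bin spacing) and picks
the dominant peak in a 5-50 Hz search band, refined by parabolic
interpolation. Two complications are specific to these calls:

1. **Octave errors.** The first resonance (about 21-30 Hz) sits on the
   second harmonic, which is therefore often stronger than the
   fundamental. Each frame checks the subharmonics at 1/2 and 1/3 of
   its peak; a subharmonic wins if it is a genuine interior spectral
   line (local maximum, above four times the median in-band level,
   separated from the parent peak by a valley) carrying at least 5% of
   the peak magnitude.
2. **Anchored continuity.** Near call onset the fundamental can be
   buried entirely. Simply carrying continuity forward from the first
   frame locks such errors in, so the contour is instead anchored at
   the voiced frame with the best harmonic support score (+1 for a
   spectral line at each integer multiple of the candidate, -1 for a
   line at each half-integer multiple, which distinguishes a true
   fundamental from its octave) and propagated outward, each frame
   constrained to within two native bins (2/frame_size = 6.7 Hz) of
   its neighbour. Where no line is resolvable near the predicted
   value, F0 is inferred from the strongest in-band harmonic divided
   by its continuity-implied harmonic number; failing that the frame
   is flagged unvoiced.

Frames are voiced if the in-band peak exceeds the median level by 10 dB
and the frame RMS is at least 10% of the median frame RMS. A call with
no voiced frames raises an "untraceable call" error and is excluded
(and logged) by the pipeline.

`extract_contour_features()` computes the standard descriptor set from
the voiced contour: start/mid/finish, min/max and mean frequency,
per-third means (equal-duration thirds; the alternative equal-count
convention is not used), durations and extremum locations, and the
shape measures COFM (sum of absolute successive differences / 10 000),
jitter factor (100 x mean absolute successive difference relative to
the mean), frequency variability index (10 x var/mean^2; sample
variance by default, switchable to the population convention), and
three slopes. The slope definition presumes at least 60 contour
points, so the contour is linearly resampled to 61 equally spaced
points and the slopes read at indices 1/20/40/60 - this makes slopes
well-defined for calls of any duration. Two descriptors mentioned in
exclusion lists of the source study, "peak by mean" and "inflection
factor", are nowhere defined and are deliberately not implemented.

## Formant estimation and vocal tract length

`estimate_formants()` downsamples to 2000 Hz and measures envelope
peaks over 0-500 Hz. The classical recipe - one long Hamming window,
LPC by the autocorrelation method, peak-picking of the all-pole
envelope - is available as `method = "lpc"` and works on broadband
(noise-excited) material. On strongly harmonic infrasonic calls it is
biased: with F0 only 2-3 times below the first resonance, the spectrum
samples the envelope at a handful of dwell-weighted lines, and the
fitted peak drifts toward whichever harmonic lingers near the
resonance (observed biases of 10-30% on ground-truthed fixtures).

The default `method = "harmonic"` therefore reconstructs the envelope
from the harmonics themselves: the F0 contour is traced, each
harmonic's magnitude is measured in overlapping frames, and natural
frequency modulation sweeps the harmonics across the resonances so
that over the whole call the envelope is sampled densely. Below 40 Hz
short (0.25 s) frames are used - the narrow first resonance must be
tracked through fast-swept excitation - and above 40 Hz long (0.5 s)
frames provide the resolution to separate closely spaced upper
harmonics. The window-gain-normalized log magnitudes are averaged in
1-Hz bins, smoothed by a 5-point moving average, and equalized by
removing the linear spectral tilt of the source rolloff (the
spectral-domain analogue of pre-emphasis). Formants are the local
maxima with at least 4 dB prominence and 10 Hz separation, ascending,
ties toward the lower frequency, restricted to the harmonically
covered range; an LPC smooth of the same envelope (default order 16,
order 8 as the common alternative) is returned for inspection. A call
with fewer than two measurable peaks raises an "unmeasurable formants"
error and is excluded. Formants below twice the call's minimum F0 sit
outside harmonic coverage and are genuinely unmeasurable for any
estimator; this is a physical, not algorithmic, limit.

`estimate_vtl()` converts the dispersion of the first two formants to
an estimated vocal tract length under the uniform-tube model,
VTL = c / (2 (F2 - F1)), with speed of sound c = 350 m/s (warm-air
convention; configurable). Because 1/x is convex, averaging per-call
VTLs over noisy formants inflates the mean above the VTL of the mean
formants by about 2% at realistic formant SDs (Jensen's inequality);
`simulate_vtl()` reproduces this per-call averaging and yields mean
VTLs of about 3.21 m and 2.36 m for the two reference groups - the
former plausible only for a nasally emitted call through the trunk.

## Variable screening

Two screens select candidate variables, mirroring the two questions:

* **Maturity (ANOVA screen).** `anova_screen()` retains features whose
  two-group one-way F (df 1, N-2; the square of the pooled t) is
  significant at alpha = 0.05, two-sided. No multiple-testing
  correction is applied, matching common practice for this screening
  step. `anova_f_from_moments()` reconstructs the same F from printed
  group moments; for the second formant of the reference cohort it
  gives 518.7 against the published 520.38 - agreement to the rounding
  of the 2-decimal inputs.
* **Individuality (PIC screen).** `pic_screen()` computes, per
  feature, the within-individual coefficient of variation
  CVw = 100 (1 + 1/(4n)) SD/mean (the small-sample-corrected CV;
  correction switchable, and deliberately applied to CVw only - the
  pooled CVb uses hundreds of calls and needs no correction), the
  between-individual CVb over the pooled sample, and the ratio
  PIC = CVb / mean(CVw). Features with PIC > 1 vary more between than
  within individuals and are retained. PIC is scale-invariant;
  a feature with zero within-individual variation yields PIC = Inf
  with a warning, and a zero pooled mean makes PIC undefined.

## PCA reduction

Because the number of DFA variables should not exceed the smallest
per-level case count, screened features are reduced by
`fit_factors()`: z-standardization, eigendecomposition of the
correlation matrix (correlation, not covariance - the features mix Hz,
s and percent), Kaiser retention (eigenvalues above 1.0), varimax
rotation (via `stats::varimax`, Kaiser-normalized, each factor signed
so its largest loading is positive), and regression-method score
coefficients W = R^-1 L. Principal components are used rather than
maximum-likelihood factors, matching the default of the statistics
packages this workflow descends from. Rotation conserves communalities
and total explained variance (asserted to 1e-8 in tests). Near the
Kaiser boundary (all eigenvalues close to 1, as with independent
features) the retained count is unstable by construction; this is
documented behaviour, not an error.

## Permuted discriminant function analysis

`run_pdfa()` is the inferential core, re-implemented from first
principles for two designs:

* **Nested** (maturity): test factor = maturity group, control factor
  = individual, every individual belonging to exactly one group. The
  unit of permutation is the *individual*: whole control levels are
  reassigned across groups, preserving group sizes. Permuting at the
  call level instead would treat 162 non-independent calls as 162
  independent observations and inflate significance - the test suite
  demonstrates this anti-pseudoreplication property directly.
* **Restricted** (individuality): test factor = individual,
  restriction factor = maturity group. Here the calls themselves are
  the repeated measures of the test factor, so test labels are
  shuffled across calls, but only *within* each maturity group.

Each evaluation draws a balanced training set (an equal number of
calls per unit, the minimum available, reduced by one when the design
is perfectly balanced so held-out calls always exist), fits Fisher
LDA (pooled within-class covariance, equal priors - balanced training
makes empirical priors equal anyway; a tiny ridge with a warning
handles singular pooling), and records percent correct among training
("original") and held-out ("cross-validated") calls. The observed
statistic averages `n_selections = 100` random selections; each of
`n_permutations = 1000` permutations is evaluated with
`n_perm_selections = 10` inner selections - only the permutation mean
and rank matter, and this keeps the run within seconds; setting it to
100 restores full symmetry. The p value follows the add-one
convention, (exceedances + 1)/(B + 1). Nested permutations that
reproduce the observed partition of individuals (identically or with
group labels exchanged) carry no information about the null and are
redrawn; without this, the attainable p floor with 10 subjects (126
distinct 5/5 partitions) would exceed 1/(B+1). One consequence of the
reduced inner-selection count is a conservative lean: the permuted
statistic is noisier than the observed one, so null rejection rates
sit at or below nominal. The expected chance level is reported as the
mean permuted cross-validated percentage - with balanced selection
from unbalanced groups it lands near 63% rather than the naive 50% -
and classification gain is normalized as
error reduction = 100 (observed - expected)/(100 - expected).

On cohorts simulated from the reference moments the nested design
classifies maturity at 97-100% cross-validated (98% is typical) with p
at the 1/1001 floor; the restricted design detects simulated
individuality well above its chance level. The published variance
percentages of the PCA (82.4%/81.6%) and the absolute individuality
accuracy (55%) depend on the undeposited real data's correlation
structure and are out of reach of any simulation calibrated only to
per-feature moments; they are not asserted anywhere.

## Reproducibility and problem sizes

Every randomized stage derives its seed deterministically from one
global seed plus the stage name; a full `run_maturity_analysis()` /
`run_individuality_analysis()` is bit-reproducible from that single
integer, and pipeline runs can write their resolved configuration and
a JSON report beside their outputs. The test suite exercises the
pipeline at the reference scale (162 calls, 100 selections, 1000
permutations, about 10 s), checks estimator round trips on a handful
of 5-s calls, runs the permutation size check at 100 null replicates
with 99 permutations each, and verifies the Monte-Carlo VTL means at
10^5 draws - sizes chosen so the whole suite completes in about a
minute while keeping every statistical check meaningful.

## Known limitations

* Formants below twice the minimum F0 are outside harmonic coverage
  and cannot be measured from a single call by any envelope method.
* The generator's independent-feature, additive-intercept cohort model
  cannot reproduce cross-feature correlation structure, so
  PCA-variance figures from real data are not reproducible targets.
* The F0 tracker assumes a single voiced source; overlapping calls or
  pulsated (musth-like) rumbles are out of scope.
* The uniform-tube VTL is an idealization; anatomical deviations from
  a uniform tube are deliberately not modelled, which is why the
  quantity is always reported as an *estimated* VTL.
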