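# rumblr

Source-filter acoustic analysis of male African elephant social
rumbles: does a rumble tell you how mature the caller is, and who he
is?

Male elephants grow throughout life, and both layers of the
source-filter production model track that growth. The *source* — passive
vocal-fold vibration — sets the fundamental frequency (F0, about
8–20 Hz, partly infrasonic), which falls with age and mass. The
*filter* — the resonances (formants) of an extremely elongated, largely
nasal vocal tract — spaces its peaks inversely with tract length: under
the uniform-tube model

```
VTL = c / (2 · (F2 − F1)),    c = 350 m/s
```

so lower, more closely spaced formants mean a longer tract and a bigger
animal. `rumblr` implements the complete analysis chain a bioacoustician
needs to quantify this information content from segmented call
recordings:

* **F0 contour tracing** (spectrogram peak tracking with octave-error
  correction and anchored continuity) and the standard contour
  descriptor set — absolute frequencies, extremum locations, COFM,
  jitter factor, frequency variability index, local slopes;
* **formant estimation** over 0–500 Hz (harmonic-sampled envelope by
  default, classical whole-call LPC as an option), formant dispersion
  and estimated vocal tract length;
* **variable screening**: a two-group ANOVA screen for maturity and the
  potential of individual coding, PIC = CVb / mean(CVw), for identity
  (retain PIC > 1);
* **PCA reduction** with Kaiser retention, varimax rotation and
  regression-method factor scores;
* **permuted discriminant function analysis (pDFA)** for nested and
  restricted designs — cross-validated classification with significance
  from permutations at the *subject* level, so repeated calls from the
  same individual cannot masquerade as independent evidence;
* a **synthetic rumble generator** (harmonic source → all-pole
  resonator cascade) and a cohort simulator calibrated to the reference
  study's published group statistics, giving every stage a
  ground-truthed test loop — the original recordings are not publicly
  deposited.

## Worked example

Simulate a cohort matching the reference study design (two maturity
groups of five males, 79 + 83 calls, features drawn from the published
group means and SDs), screen, reduce, and classify:

```r
library(rumblr)

cohort <- table3_cohort_spec(seed = 42)
calls  <- sample_feature_cohort(cohort)

screen <- anova_screen(calls[, table3_reference()$feature],
                       calls$maturity_group)
screen[, c("feature", "F", "p", "mean1", "mean2", "keep")]
#>       feature      F         p  mean1  mean2 keep
#> 1    formant1 315.94 1.029e-39 21.682  29.45 TRUE
#> 2    formant2 540.37 3.614e-53 76.218 104.11 TRUE
#> 3    max_freq  68.74 4.334e-14 13.774  16.24 TRUE
#> 4    min_freq 163.73 2.879e-26  9.867  12.37 TRUE
#> 5 finish_freq 135.64 4.306e-23 10.288  13.35 TRUE

model <- fit_factors(calls[, screen$feature[screen$keep]])
pd <- run_pdfa(model$scores,
               test    = calls$maturity_group,
               control = calls$individual,
               n_selections = 100, n_permutations = 1000, seed = 42)
pd
#> pDFA (nested design, 100 selections, 1000 permutations)
#>   correct, original data:      99.1%
#>   correct, cross-validated:    98.7%
#>   expected chance level:       63.5%
#>   error reduction:             96.3%
#>   p value:                     0.000999
```

All five features separate the groups strongly (the reconstructed
F(1,160) for formant 2 from the published moments is 518.7, matching
the published 520.38 to input rounding). The nested pDFA — maturity as
test factor, individual as control factor, whole individuals permuted
across groups — classifies held-out calls at 98.7%, far above the 63.5%
permutation chance level (96.3% error reduction), with p at the 1/1001
permutation floor. Per-call vocal tract length for the older group:

```r
mean(simulate_vtl(1e5, 21.53, 2.0, 77.14, 7.6, seed = 1))
#> [1] 3.21
```

— about 3.21 m, longer than any oral tract, consistent with nasal
emission through the trunk.

Waveform-level work uses the same surface:

```r
w  <- synthesize_rumble(synth_call_spec(10, 14, 11, duration = 5))
sf <- extract_contour_features(trace_f0(w))
fo <- estimate_formants(w)
estimate_vtl(fo$formants[1], fo$formants[2])
```

and `make_waveform_cohort()` / `extract_call_features()` run the whole
pipeline from WAV files plus an annotation CSV. A thin command-line
dispatcher with `synth`, `features`, `screen-anova`, `screen-pic`,
`reduce`, `pdfa`, `run-maturity` and `run-individuality` subcommands
lives at `inst/cli/rumblr.R`.

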