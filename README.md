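# qusrad

Quantitative-ultrasound (QUS) radiomics for recurrence risk stratification,
with texture derivatives.

Locally advanced breast tumours scanned with a clinical linear array
(7 MHz centre frequency, 4–9 MHz band, 40 MHz / 16-bit RF sampling) carry
microstructural information in the raw radiofrequency (RF) echo signal
that B-mode images discard. This package implements the full analysis
chain that turns such RF frames into a recurrence-risk model:

1. **Spectral features** — per 2 mm × 2 mm sliding sub-ROI, the power
   spectrum is normalized by a tissue-mimicking reference phantom and
   corrected for attenuation (ACE, estimated per frame by the
   spectral-difference method). A linear fit in dB gives the mid-band fit
   (MBF), spectral slope (SS) and 0-MHz intercept (SI); spectral
   periodicity gives the scatterer spacing (SAS); a spherical-Gaussian
   form-factor fit gives the effective scatterer diameter (ASD) and
   acoustic concentration (AAC).
2. **Texture (QUS-Tex¹)** — gray-level co-occurrence (GLCM) contrast,
   correlation, energy and homogeneity of each of the six parametric maps
   (16 gray levels, displacement 1, angle-averaged over 0°/45°/90°/135°):
   24 features.
3. **Texture derivatives (QUS-Tex¹-Tex²)** — texture maps are regenerated
   from local GLCM features of the MBF, SI, ASD and AAC maps and analysed
   by GLCM again: 64 third-order features. Total catalog:
   7 + 24 + 64 = **95 features** per patient (averaged over tumour
   slices).
4. **Statistics and classification** — Shapiro-Wilk-routed t /
   Mann-Whitney comparisons per feature; balanced-subset greedy forward
   selection (≤ 3 features) with KNN and SVM-RBF classifiers under
   leave-one-out cross-validation, on two feature pools (spectral +
   texture, and all 95) so the contribution of the texture derivatives is
   measurable.
5. **Survival** — Kaplan-Meier curves and log-rank tests comparing the
   *predicted* recurrence and non-recurrence groups for recurrence-free
   and overall survival, with 5-year survival per group.

Because clinical RF scans of this kind are not publicly deposited, the
package ships a point-scatterer RF simulator and outcome-labelled cohort
generator with known ground truth (spacing, diameter, attenuation,
heterogeneity, hazards), so every stage is testable end to end. See
`vignettes/qus-radiomics-methods.Rmd` for the models, defaults and
limitations.

## Worked example

```r
library(qusrad)

acq   <- acquisition_spec()                  # 40 MHz, 7 MHz centre, 4-9 MHz band
pulse <- pulse_model()
refs  <- make_reference_frames(acq, pulse, seed = 7)
cfg   <- qus_config(overlap = 0.5)

# diffuse tissue: 60 um scatterers, 0.7 dB/cm/MHz attenuation
tis <- diffuse_field(c(0.018, 0.0096), 1.2e8, seed = 31,
                     effective_diameter = 60e-6)
fr  <- simulate_rf_frame(tis, pulse, acq, attenuation = 0.7, seed = 31)
roi <- matrix(TRUE, nrow(fr$samples), ncol(fr$samples))
bm  <- build_parametric_maps(fr, roi, refs, cfg)

round(bm$ace, 2)                                  # true alpha: 0.7 dB/cm/MHz
#> [1] 0.69
round(mean(bm$maps$ASD$values, na.rm = TRUE) * 1e6)  # true diameter: 60 um
#> [1] 53
round(mean(bm$maps$SAS$valid_mask), 2)   # no periodicity in diffuse tissue:
#> [1] 0.07                              # spacing flagged invalid almost everywhere

# tissue with a 0.4 mm quasi-regular scatterer lattice
lat <- regular_field(c(0.018, 0.0096), 0.4e-3, acq, seed = 1, jitter_sd = 0.03,
                     amplitude = 5, diffuse_density = 1.2e8)
fr2 <- simulate_rf_frame(lat, pulse, acq, seed = 1)
bm2 <- build_parametric_maps(fr2, roi, refs, cfg)
round(median(bm2$maps$SAS$values, na.rm = TRUE) * 1e3, 2)  # true spacing: 0.4 mm
#> [1] 0.4
round(mean(bm2$maps$SAS$valid_mask), 2)
#> [1] 0.97
```

`extract_frame_features()` / `extract_patient_features()` turn maps into
the named 95-feature vectors; `run_protocol()` produces the four
classifier reports; `stratify_by_prediction()` produces the survival
comparison.

## The study workflow

The numbered scripts under `analysis/` run the whole study on a synthetic
83-patient cohort (28 recurrence / 55 non-recurrence, 3 tumour slices
each) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort, outcomes, ground truth
Rscript analysis/02_extract_features.R   # 83 x 95 feature matrix (~2.5 min)
Rscript analysis/03_compare_features.R   # routed univariate comparisons
Rscript analysis/04_classify.R           # KNN / SVM x two feature pools
Rscript analysis/05_survival.R           # KM + log-rank by predicted group
```

On this cohort the run prints: 42 of 95 features differ between groups at
p < 0.05 (heterogeneity-sensitive texture features such as `SI-COR` and
`MBF-CON` lead the table); all four classifiers select `MBF-CON` and reach
100 % LOOCV accuracy (the synthetic class contrast is deliberately clean —
see the vignette for what that does and does not establish); and the
predicted groups separate survival: 5-year recurrence-free survival 82 %
(predicted non-recurrence) vs 50 % (predicted recurrence), log-rank
p = 0.001.

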