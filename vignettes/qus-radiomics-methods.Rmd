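---
title: "Quantitative ultrasound radiomics with texture derivatives: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound radiomics with texture derivatives: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`qusrad` implements a complete quantitative-ultrasound (QUS) radiomics
pipeline for tumour radiofrequency (RF) echo data: spectral parameter
estimation from reference-phantom-normalized power spectra, gray-level
co-occurrence (GLCM) texture of the resulting parametric maps, a second
texture pass over regenerated texture maps ("texture derivatives"),
univariate group statistics, balanced forward-selection KNN/SVM
classification under leave-one-out cross-validation (LOOCV), and
Kaplan-Meier/log-rank survival stratification of the predicted groups.
Because clinical RF scans of this kind are not publicly available, the
package also contains a point-scatterer RF simulator and cohort generator
with known ground truth, so every stage is testable end to end.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data can and
cannot establish.

# The RF simulator

Tissue is modelled as a 2D field of sub-resolution point scatterers.
Per scan line, the scatterer impulse train (amplitudes placed at pulse-echo
delay $2z/c$, linearly interpolated onto the sample grid) is convolved with
a Gaussian-enveloped emission pulse (7 MHz centre, $-6$ dB fractional
bandwidth 0.71, chosen so the 4–9 MHz analysis band carries usable energy).
Two depth-dependent effects are applied in axial blocks of 128 samples,
each filtered at its centre depth:

* **Attenuation.** Linear-in-frequency power loss of
  $4\,\alpha\, z_{\mathrm{cm}} f_{\mathrm{MHz}}$ dB over the pulse-echo
  path, the same convention the downstream spectral-difference estimator
  and correction use, so attenuation estimation is exactly invertible in
  principle.
* **Scatterer size.** A spherical-Gaussian form factor
  $F(f) = \exp\!\big(-0.827\,(ka/2)^2\big)$, $k = 2\pi f/c$, applied as an
  amplitude filter $\sqrt F$ for the field's effective diameter $a$.

There is no lateral point-spread coupling and no diffraction model; the
simulator reproduces the *spectral and textural statistics* the estimators
consume, not full wave propagation. The reference phantom is a dense
diffuse field of point scatterers with zero attenuation, scanned five
times; phantom window spectra are averaged over lines and frames at
matched depth.

Relevant regimes, fixed once at design time:

* diffuse ("speckle") density $1.2\times 10^8$ scatterers/m²
  ($\approx 12$ per 2 mm axial window per line) — fully developed speckle,
  so band power is linear in density;
* a quasi-regular axial lattice (amplitude 5 × the diffuse sd, 3 %
  position jitter) superimposed on the diffuse background, giving the
  power spectrum a comb of period $\Delta f = c/(2d)$ that the scatterer
  spacing estimator recovers;
* 16-bit quantization applied when frames are written to the plain-text
  scan container.

# Spectral parameter estimation

The sliding sub-ROI grid uses 2 mm × 2 mm windows (104 samples × 20 lines
at 40 MHz sampling and 0.1 mm line pitch) with configurable overlap; the
clinical protocol value is 94 % (stride $\approx$ 0.12 mm). The analyses in
`analysis/` and the test suite run at 50 % overlap — a problem-size choice
that leaves the estimators untouched, since each window is processed
independently.

Per window: Hann-tapered per-line periodograms are averaged across lines
(dB), normalized by the matched-depth phantom spectrum (a dB subtraction),
and restricted to the 4–9 MHz band.

* **ACE** (attenuation coefficient estimate, dB/cm/MHz): per frequency,
  the normalized dB value is regressed against window depth over the whole
  frame; $\alpha = -\operatorname{mean}_f\,[\partial\text{dB}/\partial z]/(4
  f_{\mathrm{MHz}})$, clamped at zero. One estimate per frame (the depth
  regression needs the full depth range), applied to every window as
  $+4\alpha z_{\mathrm{cm}} f_{\mathrm{MHz}}$ dB before the fits.
  Simulation recovery is unbiased within $\pm 0.02$ at $\alpha = 0.5$ and
  $1.0$.
* **MBF / SS / SI**: ordinary least squares of corrected dB against
  frequency in MHz over the band; SS is the slope, SI the intercept at
  0 MHz, and MBF the fitted value at the band centre (6.5 MHz), so
  $\mathrm{MBF} = \mathrm{SS}\cdot f_c + \mathrm{SI}$ identically.
* **ASD / AAC**: fit of the spherical-Gaussian backscatter model
  $10\log_{10}\!\big(C f^4 e^{-0.827 (ka/2)^2}\big)$ by log-spaced grid
  search over the effective diameter (1–300 µm, 64 points, one local
  refinement), with the dB offset solved in closed form at each diameter.
  ASD is the minimizing diameter, AAC the offset (dB). Because the phantom
  normalization cancels both media's Rayleigh $f^4$ factors, the map
  pipeline restores the phantom's $40\log_{10} f_{\mathrm{MHz}}$ shape
  before fitting (`phantom_rayleigh = TRUE`); direct calls fit the model
  as given. Fits pinned at the search boundary are flagged invalid.
* **SAS** (scatterer spacing): see below.

Invalid-cell policy: every estimator failure or flag becomes an invalid
map cell (`valid_mask`), never an error; downstream statistics ignore
invalid cells. A map with no valid cell at all raises an error naming the
stage.

## The scatterer-spacing detector

Spacing estimation from a 2 mm window is the hardest stage: the band holds
only 13 frequency bins and 2–4 comb teeth. Two standard designs failed
under simulation and were replaced:

* integer-lag autocorrelation of the linear-power spectrum cannot resolve
  comb periods that are a non-integer number of bins, and at 13 bins its
  peak statistics barely separate combs from speckle;
* a single-harmonic periodogram on the *linear* spectrum saturates near
  0.17 for genuine combs (sharp teeth spread energy into harmonics) while
  correlated speckle reaches similar scores.

The implemented detector is a band-limited cepstral form. The dB band
spectrum is detrended by its own line fit (this also removes residual
attenuation tilt), and a normalized harmonic periodogram
$r(d) = \sum_{h=1}^{2} 2\,\big|\sum_j x_j e^{-2\pi i h f_j/\Delta f(d)}
\big|^2 / (n \sum_j x_j^2)$ is evaluated on a continuous grid of 160
candidate spacings in 0.1–2 mm. The peak is *located* on the
single-harmonic curve (pooling harmonics would tie the true spacing with
its half), the fundamental is chosen as the smallest spacing among strong
local maxima in the integer-ratio family of the best candidate, and the
final period is refined as the median separation of the actual spectral
teeth (parabolically interpolated local maxima within 8 dB of the
strongest). Validity demands a pooled score of at least `peak_min = 0.45`
*and* a score of at least `jk_min = 0.40` when any third of the band is
jackknifed out — a genuine comb spans the whole band, a speckle lump does
not. On simulated diffuse media about 3–6 % of windows pass (false
positives); on lattice media 50–97 % pass with the correct spacing.

In the map pipeline the SAS stage uses a 3× longer axial gate centred on
each sub-ROI (finer frequency resolution, standard for spacing estimators)
and averages normalized linear spectra over the 3 × 3 grid neighbourhood —
adjacent sub-ROIs are near-replicates under the protocol's heavy window
overlap, so this trades no meaningful resolution for substantial variance
reduction. Candidate spacings need at least 1.5 comb periods inside the
band and a period above two bins; with the 4–9 MHz band this bounds
resolvable spacings to roughly 0.23–0.55 mm at the 2 mm scale, which is
why the cohort generator draws patient spacings from 0.3–0.5 mm.

# Texture and texture derivatives

Each of the six parametric maps (no map for ACE) is quantized to
`n_levels = 16` uniform gray levels between its valid min and max
(constant maps collapse to level 1). GLCMs are computed at displacement 1
for the four angles 0°, 45°, 90°, 135°, symmetrically (each pair counted
both ways), normalized to sum 1; pairs touching invalid cells are skipped.
Features:

$$\mathrm{CON} = \sum_{ij}(i-j)^2 p_{ij},\quad
\mathrm{COR} = \tfrac{1}{\sigma_i \sigma_j}\sum_{ij}(i-\mu_i)(j-\mu_j)p_{ij},\quad
\mathrm{ENE} = \sum_{ij}p_{ij}^2,\quad
\mathrm{HOM} = \sum_{ij}\tfrac{p_{ij}}{1+|i-j|},$$

with COR defined as 0 when either marginal is degenerate. Features are
averaged over the four angles; angles with no valid pair are skipped with
a warning. This gives the 24 first-pass texture features (6 maps × 4).

For the texture derivatives, a *texture map* is regenerated for each of
MBF, SI, ASD and AAC (the SS and SAS texture maps are not used): per grid
cell, the GLCM features of the 5 × 5-cell neighbourhood centred there
(clipped at edges), using the map-global quantization so all local windows
share one gray scale. Each of the 16 resulting texture maps is then
re-quantized on its own min–max and analysed again, yielding the 64
third-order features named `PARAM-TEX1-TEX2` (e.g. `SI-COR-CON`). The
5 × 5 neighbourhood is the package's choice of the smallest window that
still yields stable co-occurrence statistics on desk-scale grids; it is a
configurable (`neighborhood`).

Catalog: 7 spectral + 24 texture + 64 texture-derivative = 95 features,
in a fixed, documented order. Patient vectors are the unweighted mean of
frame-level features over tumour slices, per feature ignoring frames where
that feature is invalid; a feature invalid in all frames of a patient is
an error naming both.

# Statistics, classification, survival

**Univariate comparisons** route each feature through a Shapiro-Wilk
screen at $\alpha = 0.05$ per group: both groups normal-looking → unpaired
(equal-variance) t-test; otherwise Mann-Whitney, exact when both groups
have at most 20 tie-free observations, normal approximation with tie and
continuity correction otherwise. Constant groups route to Mann-Whitney.
No multiplicity correction is applied, matching common practice for
descriptive feature tables; the routed procedure's type-I error is
$\approx 0.055$ at $n = 28/55$ (simulation).

**Classification.** The unbalanced cohort (28 vs 55) is rebalanced into
subsets that each contain all minority patients plus an equal-size random
draw of the majority, consumed in shuffled cyclic order so the subsets
cover the majority class. Greedy forward selection adds, per round, the
feature maximizing the mean LOOCV accuracy across subsets; at most 3
features are selected to limit overfitting. The final report is one LOOCV
over the full cohort with the selected features: per fold, features are
z-scored on the training rows only; KNN (k = 3, deterministic
index-order tie-breaking) scores the held-out patient by positive-vote
fraction, SVM-RBF (C = 1, $\gamma = 1/(d\cdot\overline{\mathrm{var}})$,
e1071) by signed decision value oriented toward recurrence; AUC is the
Mann-Whitney rank statistic of the held-out scores. Recurrence is the
positive class. The protocol runs both classifiers on two pools —
spectral + first-pass texture (31) and all 95 — so the contribution of
the texture-derivative tier is measurable.

**Survival.** Kaplan-Meier product-limit curves (survival package;
Greenwood variance), right-continuous step lookup, and the two-group
log-rank test, applied to the predicted recurrence vs predicted
non-recurrence groups for recurrence-free survival (RFS) and overall
survival (OS), both timed in months from treatment start; 5-year survival
per group is reported. Ties between events and censorings resolve events
first (the standard convention).

# The synthetic cohort

`cohort_spec()` defaults encode the study conditions: 28 recurrence (R)
and 55 non-recurrence (NR) patients; 3–7 tumour slices each (the analysis
scripts use 3 at desk scale); exponential RFS hazards of 0.0103 and
0.0031 /month and OS hazards of 0.0050 and 0.0027 /month, i.e. 5-year
survivals of about 54 %/83 % (RFS) and 74 %/85 % (OS); administrative
censoring at 84 months. RFS and OS times are drawn independently per
patient — a simplification that ignores the event-ordering constraint
between recurrence and death.

The class contrast is *spatial heterogeneity*, not a mean shift: patient
scatterer amplitudes are modulated by a smooth log-normal envelope
(bilinearly interpolated 6 × 6 Gaussian grid) with strength 0.6 for R and
0.15 for NR. This drives texture and texture-derivative features of the
MBF/SI/AAC maps apart while leaving the spectral means largely untouched.
Under these clean conditions the class separation is strong — the demo
classifiers reach 100 % LOOCV accuracy — so passing tests establish that
the pipeline *recovers a known heterogeneity signal*, not that clinical
discrimination of this quality is attainable. Real RF data add diffraction,
nonstationary attenuation, ROI segmentation error, class overlap and far
weaker effect sizes, none of which the generator emulates.

The texture-derivative advantage (the all-95 pool beating the
spectral+texture pool) is established at the feature-matrix level with a
dedicated generator that plants a standardized shift only in a
third-order feature; this isolates the property of the selection protocol
itself from the acoustics.

# Numerical and reproducibility notes

* All randomness flows through explicit integer seeds; cohorts, frames,
  maps and pipeline outputs are bit-identical across reruns with the same
  seed and configuration.
* Frequency resolution equals the window length (no zero padding); the
  grid stride floors to at least one sample/line.
* Periodogram dB values floor at the smallest positive double before
  `log10`; identically zero windows are an error.
* The form-factor search refines once between the neighbours of the
  best grid point; amplitude offsets separate exactly from the diameter.
* Degenerate inputs are errors with named causes: ROIs smaller than one
  window, single-depth attenuation estimation, single-class folds, empty
  predicted groups, negative times.
* Desk-scale problem sizes used throughout the analyses: 18 × 9.6 mm
  frames, 3 slices/patient, 50 % window overlap (≈ 130 sub-ROIs per
  frame), 83 patients.

# Known limitations

* The simulator is 1D-per-line; lateral speckle correlation is set by the
  line pitch alone, and no diffraction or beamforming effects exist.
* ACE is estimated per frame; strong within-frame heterogeneity biases it
  upward (visible in patchy recurrence-class frames), which is a real
  property of spectral-difference attenuation estimation.
* The spacing detector's resolvable range at the 2 mm window scale is
  roughly 0.23–0.55 mm; larger spacings leave too few lattice periods per
  window and are flagged invalid rather than guessed.
* SEM-based group summaries and the absence of multiplicity correction
  mirror descriptive clinical reporting; the comparison table is not a
  discovery procedure.
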