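---
title: "Quantifying left-ventricular trabecular complexity by box-counting fractal dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular trabecular complexity by box-counting fractal dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The inner (endocardial) surface of the left ventricle is lined with
trabeculae — muscular ridges whose geometric complexity increases under
chronic pressure load, as in hypertensive heart disease. On short-axis
bSSFP cine MR slices the trabeculated endocardial border appears as an
irregular interface between bright blood pool and darker myocardium. A
smooth border is a curve of dimension 1; a highly convoluted one fills
progressively more of the plane. The box-counting fractal dimension (FD)
turns that intuition into a scalar: cover the border with grids of boxes of
side $\varepsilon$ and count occupied boxes $N(\varepsilon)$; for a
self-similar set $N(\varepsilon) \propto \varepsilon^{-D}$, and the slope
of $\log N(\varepsilon)$ against $\log(1/\varepsilon)$ estimates $D$.

`trabfd` implements that measurement end to end — segmentation, edge
extraction, box counting, per-slice FD, regional summaries — together with
the cohort-level statistics used to evaluate FD as a diagnostic marker for
heart failure within a hypertensive population, and a synthetic-phantom
module so that every stage is testable without patient data.

## Segmentation model

Per slice, the pipeline (`binarize_blood_pool()`,
`extract_trabecular_edges()`):

1. **Upsampling.** The slice is upsampled ×4 by bilinear interpolation
   (configurable). Trabecular detail lives near the pixel scale; estimating
   a slope over dyadic box sizes needs several octaves of scale below the
   structure size, and sub-pixel interpolation reduces rasterization
   artifacts in the counts. Bilinear interpolation is used as the package's
   deterministic resampling choice.
2. **Initialization.** Intensities inside a circular ROI (operator-supplied
   `roi_circle()`, or `auto_roi()` which circumscribes the largest bright
   component) are split into three classes by exhaustive multi-level Otsu
   thresholding — background, myocardium, blood pool — and the brightest
   class seeds the pool.
3. **Refinement.** A Chan–Vese-style two-phase region evolution: pixels
   join the region (pool / non-pool) whose mean intensity they are closer
   to, and a Gaussian smoothing of the indicator (σ = 0.8 px) followed by
   re-thresholding plays the role of the curvature penalty. Fixed cap of 50
   iterations, convergence tolerance 10⁻³ on the fraction of pixels
   changing. The evolution is fully deterministic, so identical inputs give
   bit-identical masks.
4. **Component logic.** The largest connected bright component is the pool;
   detached bright islands are discarded. Holes inside the filled pool are
   papillary-muscle or trabecular cross-sections ("intracavity objects").
5. **Edges.** The Sobel gradient magnitude of the binary mask, thresholded
   at any genuine step response and thinned to the one-pixel inner
   boundary, gives the endocardial–trabecular edge set. Intracavity-object
   borders are **included** by default (`include_papillary = TRUE`): the
   papillary-segmentation step exists precisely to supply the final edge
   image, and a flag allows the alternative convention since reasonable
   tools differ here.

Degenerate inputs fail loudly: a constant ROI raises a "degenerate
intensity" error, an empty pool after thresholding "no blood pool
detected", an empty edge set "no edge"; the affected slice is excluded
downstream with a machine-readable reason.

## Box-counting design

`box_count()` uses a single fixed grid anchored at the image origin —
deterministic, and exact on the analytic fixtures (a straight line gives
slope exactly 1, a filled grid exactly 2). A 4-offset averaging mode
exists but is off by default.

**Box sizes.** Dyadic sizes $1, 2, 4, \dots$ up to the largest power of two
*strictly below* 25 % of the edge set's bounding-box extent
(`default_box_sizes()`). The upper anchor matters: boxes comparable to the
whole structure hold only a handful of cells and bias the fitted slope
upward. On rasterized validation figures the package's policy keeps a
circle within 0.95–1.02 and a level-5 Koch boundary within 0.01 of its
analytic dimension $\log 4 / \log 3 \approx 1.2619$, whereas anchoring the
largest box to ~45 % of the image side inflates the same estimates to
≈ 1.05–1.11 and ≈ 1.31 respectively. At least five sizes are required
(`min_sizes`, default 5) — structures too small to support them leave the
slice invalid rather than silently producing a two-point fit; the analytic
line/grid fixtures may lower `min_sizes` explicitly.

**Fit and validity.** Unweighted OLS of $\log N$ on $\log(1/\varepsilon)$
over all sizes (no automatic scaling-window selection; the window is the
size policy). A slice estimate is *valid* when $1 \le \hat D \le 2$ and
the fit $R^2 \ge 0.95$. In the smooth limit the estimator scatters around
1, so slightly-below-1 estimates are excluded by this rule — conservative,
and irrelevant for genuinely trabeculated borders.

**Regional summaries.** Valid slices of the apex-first stack are split at
the midpoint; with an odd count the middle slice goes to the **basal**
half ("midpoint-basal", configurable). Five summaries: global FD (mean of
all valid slices), mean and maximal apical FD, mean and maximal basal FD.
Invalid slices are excluded from all five and logged; subjects with fewer
than 4 valid slices are flagged "FD not computable" — the mechanical
analogue of excluding poor-quality stacks, with 4 chosen as the smallest
count for which an apical/basal split is meaningful.

## Phantom model

`generate_slice_phantom()` renders a bSSFP-like slice from an analytic
model: the endocardial border is
$r(\theta) = R\,\bigl(1 + \sum_{k=2}^{K} a_k \cos(k\theta + \varphi_k)\bigr)$
with $a_k = A\,k^{-\beta/2}$, random phases from the seed, amplitude $A$
(`trabecular_amplitude`), harmonic cutoff $K$ (`trabecular_count`, default
96) and spectral decay $\beta$ (`roughness_exponent`, default 1). This
gives a one-parameter family from smooth ($A = 0$, FD → 1) to highly
convoluted borders; with $K = 96$ the finest wiggles sit near the pixel
scale, so FD rises monotonically with $A$ over the working range
(≈ 1.03 at $A = 0.02$ to ≈ 1.28 at $A = 0.10$ on the rasterized true
border, spanning the plausible clinical range of ≈ 1.17–1.35).
Interfaces are rendered with one-pixel partial-volume ramps, as in
magnitude MR images; a hard-staircase rendering would itself add spurious
small-scale roughness. Papillary muscles are disks of myocardial intensity
inside the pool; noise is additive Gaussian by default with a
magnitude-Rician option (`noise_model = "rician"`) — what is under test
downstream is thresholding, not MR physics. Stacks
(`generate_stack_phantom()`) taper the cavity from a small apical to a
larger basal radius, taper amplitude apex→base, and carry slice geometry
(8 mm thickness, 3 mm gap, 8–13 slices typical) with an apex-first flag.

What the phantoms do **not** emulate: cine temporal dynamics (only an
end-diastolic frame is modelled), k-space acquisition and its artifacts,
coil-profile shading, true branching trabecular topology (the boundary is
a radial graph, so no overhangs or detached trabeculae), and realistic
papillary shapes. Passing phantom tests therefore demonstrates estimator
and pipeline correctness under controlled complexity — not clinical
segmentation accuracy on patient images, which the automatic ROI and the
threshold model only approximate.

## Cohort simulator

`generate_synthetic_cohort()` draws a three-group cohort — 34 healthy
controls, 69 hypertensives without HF, 77 with HF by default — with
per-group Gaussian parameters (`default_group_params()`) chosen to match a
typical 3 T hypertensive heart-failure cohort: global FD
1.189 ± 0.038 / 1.235 ± 0.040 / 1.258 ± 0.038 across the three groups,
analogous parameters for the four regional summaries, and group-typical
age, sex proportion, blood pressure, LV function and wall thickness.
Variables reported clinically as median (IQR) are simulated as Gaussians
with mean ≈ median and SD ≈ IQR/1.349. Choices made once and kept:

* Height and weight are drawn (controls ≈ 166/64, hypertensives ≈ 168/75)
  so that the derived BMI and Mosteller BSA
  ($\sqrt{h\,[\mathrm{cm}] \cdot w\,[\mathrm{kg}]/3600}$) land on the
  group-typical values; BMI, BSA and the indexed volumes are computed, not
  drawn, so the table's internal identities hold exactly.
* LVESV is truncated below LVEDV and stroke volume is their difference.
* The five FD summaries share a latent per-subject trabeculation factor
  (loading 0.7), and maximal wall thickness loads on the same factor so
  that each FD attains a target within-group Spearman correlation of 0.4
  with wall thickness (Gaussian copula; latent Pearson
  $2\sin(\pi\rho_S/6)$). Pooled across groups the observed rank
  correlation is higher (≈ 0.55–0.65) because group means co-vary.
* Healthy-control comorbidity prevalences are not part of the published
  group description and are set to plausible check-up-population values
  (diabetes 3 %, smoking/alcohol 25 %, dyslipidemia 20 %, AF 0 %); controls
  are NYHA class I.
* FD draws are clipped to [1, 2]; a zero SD yields a constant column with
  a warning.

Every generator is a pure function of (spec, seed).

## Statistical chain

`run_cohort()` reproduces the standard analysis sequence on a cohort
table:

* **Group comparisons** (`compare_groups()`): Shapiro–Wilk per group at
  α = 0.05 gates parametric vs nonparametric paths (the gate level and
  per-group application are configurable choices); t / Mann–Whitney for
  two groups, ANOVA / Kruskal–Wallis for three, χ² or Fisher (any expected
  cell < 5) for categoricals. Pairwise follow-ups are unadjusted by
  default — the convention for baseline tables — with `p.adjust` methods
  available. ANCOVA adds a partial-F group test in the additive model
  `outcome ~ covariates + group` (age and sex for the FD summaries); no
  interactions.
* **Correlations**: Spearman throughout; constant columns are flagged
  undefined (NA), never silently zero.
* **Logistic models** (`fit_logistic_univariate()`,
  `select_multivariable()`): HF vs non-HF within the hypertensive
  subgroups. FD enters **per 0.01 FD unit** (FD × 100): on the raw scale a
  clinically meaningful FD difference is ~0.01–0.05, and per-0.01 scaling
  puts odds ratios on the interpretable 1.03–1.17 order. Selection is
  (i) univariate screen at p < 0.1, (ii) iterative removal of the
  highest-VIF variable until all VIF ≤ 5 (VIF from the definition,
  $1/(1-R^2_j)$), (iii) forward selection by likelihood-ratio entry test
  at α = 0.05 — "forward selection" needs a criterion and the LRT is the
  likelihood-consistent one. Every decision lands in an audit trail.
  Complete separation is flagged and the CI reported as nonconvergent.
* **Nested models** (`build_nested_models()`): model 1 = age, male sex,
  BMI, diabetes, dyslipidemia, SBP; model 2 adds LVEF, LVEDV, LVESV, SV;
  model 3 adds maximal wall thickness; model 4 adds global and mean/max
  apical and mean basal FD (maximal basal FD is omitted — it is the one
  summary that does not discriminate the hypertensive groups). All models
  are fitted on the common complete-case rows; discrimination is
  **in-sample** (apparent) AUC with DeLong 95 % CI, adjacent models are
  compared by the paired DeLong test on fitted probabilities and by the
  −2 log-likelihood ratio test. No cross-validation is claimed.
* **AUC / DeLong** (`roc_auc()`, `delong_compare()`): AUC is the
  normalized Mann–Whitney U (ties half-weighted); rank-identical score
  pairs short-circuit to difference 0, p = 1 (the DeLong variance is zero
  there). Two-sided tests throughout.
* **Reproducibility** (`icc_agreement()`): ICC(2,1) — two-way random
  effects, absolute agreement, single measure — from ANOVA mean squares
  with McGraw–Wong F-based CI. Absolute agreement is the defensible choice
  for observer studies because it penalizes systematic offsets; the
  single-measure form matches one observer reading one image.

## Numerical choices and degenerate inputs

Deterministic throughout: fixed grid origin, fixed iteration caps, no
stochastic step anywhere in the measurement path; all simulation goes
through explicit seeds, and run manifests embed a config hash. Ties in
AUC count one half; the forward-selection tie-break is the smallest entry
p-value; exact collinearity reports infinite VIF; zero between-subject
variance flags the ICC degenerate rather than returning a number.

## Problem sizes

The shipped tests and the acceptance script run phantoms at 256² (×4
upsampled to 1024²), stacks of 10 slices, amplitude sweeps of 5 seeds × 3
amplitudes, cohort simulations of 180 subjects with up to 50 replicate
draws, logistic recovery at n = 2000–5000 with 100–200 replicates, and a
10⁵-resample bootstrap oracle on a 12-subject ROC fixture — sizes chosen
so the full suite exercises every claim in minutes on a single core while
keeping Monte-Carlo margins comfortable.

## Known limitations

* The segmentation is a deterministic stand-in for an interactive clinical
  tool: the exact level-set flavour and iteration budget of established
  software differ, and the automatic ROI assumes the ventricle is the
  largest bright central structure (true for phantoms, not guaranteed on
  patient images).
* Apparent (in-sample) AUCs are optimistic; the nested-model comparison
  quantifies incremental fit, not out-of-sample performance.
* FD estimates below 1 in the smooth limit are excluded by the validity
  rule, which slightly biases smooth-stack summaries upward; this is
  immaterial for trabeculated anatomy.
* The phantom boundary family is radial: it cannot represent detached or
  overhanging trabeculae, so the papillary/intracavity machinery is
  exercised by disks only.
* The cohort simulator draws most covariates independently within group;
  real covariate structure (e.g. age–LVEF coupling) is richer, so
  cohort-level results validate the statistical machinery, not clinical
  effect sizes.
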