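# trabfd — box-counting fractal analysis of left-ventricular trabeculation

Chronic hypertension remodels the left ventricle, and one of its subtler
signatures is the increasing geometric complexity of the endocardial
trabeculae visible on short-axis cine MR slices. `trabfd` quantifies that
complexity as a box-counting fractal dimension (FD) and evaluates it as a
diagnostic marker for heart failure within a hypertensive population. It is
aimed at cardiac-imaging researchers who want a fully scripted, testable
version of the measurement chain: no interactive steps, every stage
deterministic and covered by synthetic phantoms.

## The measurement

For a slice's trabeculated endocardial border, cover the edge set with
grids of boxes of side ε and count occupied boxes N(ε). For a
self-similar boundary

    N(ε) ∝ ε^(−D),   D = −d log N / d log ε,

so the OLS slope of log N(ε) against log(1/ε) estimates the fractal
dimension D: 1 for a smooth border, approaching 2 for a plane-filling one.
The pipeline per slice is: bilinear ×4 upsampling → 3-class Otsu
initialization inside an ROI → Chan–Vese-style region refinement →
largest-component blood pool with papillary cross-sections as intracavity
objects → Sobel edge extraction thinned to a 1-px boundary → box counting
over dyadic sizes up to 25 % of the edge extent → per-slice FD with an
R² ≥ 0.95 validity gate. Valid slices of the apex-first stack are split at
the midpoint into apical and basal halves, yielding five summaries: global
FD (mean over all valid slices), mean/max apical FD, mean/max basal FD.

On top of the imaging chain sits the full cohort-statistics chain used in
hypertensive-HF studies: normality-gated group comparisons with ANCOVA
adjustment, Spearman correlations, univariate logistic screening (FD per
0.01 unit), VIF-gated forward selection, nested diagnostic models compared
by DeLong's test and likelihood ratio, and ICC(2,1) observer
reproducibility.

## Worked example

Simulate a trabeculated short-axis stack, run the pipeline, and read off
the regional FD summaries:

```r
library(trabfd)

stack <- generate_stack_phantom(stack_phantom_spec(seed = 42))
res   <- run_subject(stack, run_config(seed = 42))
res$summary
#> Regional FD (9 valid slices; 4 apical / 5 basal)
#>   global        1.0825
#>   mean apical   1.0847
#>   max  apical   1.1113
#>   mean basal    1.0806
#>   max  basal    1.1371
```

The default stack tapers trabecular amplitude from apex to base, and the
summaries show it: apical means exceed basal means, and every value sits
above the smooth-limit baseline (an amplitude-zero stack returns all five
summaries within 1.0 ± 0.05). One slice was excluded by the validity gate;
`slice_fd_table(res)` lists the per-slice estimates and the
machine-readable exclusion reason.

Cohort level — simulate a three-group cohort (34 controls / 69 HTN non-HF
/ 77 HTN-HF) and run the statistics chain:

```r
tab <- generate_synthetic_cohort(cohort_sim_spec(seed = 42))
rep <- run_cohort(tab)
rep$nested$comparisons[, c("model", "auc", "minus2ll", "lrt_p_vs_prev")]
#>   model   auc minus2ll lrt_p_vs_prev
#>  model1 0.678    189.4            NA
#>  model2 0.905    111.5      4.75e-16
#>  model3 0.923    102.0      2.09e-03
#>  model4 0.965     70.4      2.33e-06
```

Model 4 adds the FD summaries to the clinical + LV-function + wall-thickness
model 3; the AUC gain and likelihood-ratio p quantify the incremental
diagnostic value of trabecular complexity in this simulated cohort (AUCs
are in-sample). The numbered scripts under `analysis/` walk the same
sequence as a narrated workflow — `01_simulate_phantoms.R` through
`05_diagnostic_models.R` — writing tables under `results/`.

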