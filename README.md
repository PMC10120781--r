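# collagenkit

Tools for studying the balance of type I vs type III collagen (Col1 vs
Col3) in the breast tumor microenvironment, from two complementary
directions:

1. **Bulk transcriptomics.** In bulk tumor RNA-seq, stromal transcripts
   such as the fibrillar collagens COL1A1, COL1A2 and COL3A1 are
   confounded with tumor purity: a sample with more cancer cells has
   less stroma and therefore less collagen signal, regardless of the
   biology of its stroma. `collagenkit` implements the
   stromal-normalizing expression-ratio statistic that removes this
   bias — each sample's Col1 transcripts are divided by its COL3A1
   expression,

   r<sub>1</sub> = COL1A1 / COL3A1,  r<sub>2</sub> = COL1A2 / COL3A1,

   so the shared stromal-fraction factor cancels — together with the
   transcriptome-wide Pearson purity screen (with Benjamini–Hochberg
   q-values) that demonstrates the bias, a dual-ratio quartile
   classification of patients (Col1:Col3 high / Col3:Col1 high / other),
   and first-principles Kaplan–Meier estimation and logrank testing over
   censored clinical endpoints (OS/DSS/DFS/PFS), with Fisher exact
   subtype-association tests and a generic hypergeometric
   over-representation test.

2. **Microscopy.** Quantification of fibrillar collagen architecture
   from second-harmonic-generation (SHG)-like images — integrated
   density with autofluorescence subtraction, FFT spectral anisotropy
   (alignment aspect ratio; 1 = isotropic), structure-tensor orientation
   histograms, and a fiber tracer reporting per-fiber length, width and
   straightness (chord/arc), with the conventional straight-fiber cutoff
   at 1/1.08 = 0.92593 — plus cell/nucleus morphometry (segmentation,
   compactness, nuclear fraction, orientation) and the scalar indices
   (percent marker-positive nuclei, caliper tumor volume V = L·W²/2).

Both halves ship with synthetic-data generators with exact ground truth
(a purity-confounded survival cohort; rendered fiber fields and cell
fixtures), so the whole analysis is testable end-to-end without any
external download. The package is aimed at computational biologists who
want either the de-biasing ratio statistic for their own bulk cohorts or
a scriptable, tested replacement for interactive fiber/morphometry
toolchains.

## Worked example

```r
library(collagenkit)

# a synthetic 300-patient cohort with purity-confounded collagen
# expression and a ratio-linked hazard
cohort <- generate_cohort(cohort_params(n_samples = 300, seed = 42))

# every collagen gene correlates strongly negatively with tumor purity
screen <- purity_correlation_screen(cohort$expression, cohort$clinical)
dplyr::filter(screen, gene_id %in% c("COL1A1", "COL1A2", "COL3A1"))
#> # A tibble: 3 × 5
#>   gene_id      r        p        q n_used
#>   <chr>    <dbl>    <dbl>    <dbl>  <int>
#> 1 COL1A1  -0.729 6.96e-51 3.58e-49    300
#> 2 COL1A2  -0.719 5.94e-49 2.04e-47    300
#> 3 COL3A1  -0.753 3.74e-56 3.86e-54    300

# the ratio features cancel the stromal fraction; quartile rule
# classifies the cohort into thirds
labels <- classify_patients(compute_ratio_features(cohort$expression))
table(labels$label)
#> COL1_HIGH COL3_HIGH     OTHER  EXCLUDED
#>        95       101       104         0

# Kaplan-Meier + logrank per endpoint: Col1:Col3-high patients do worse
res <- survival_by_group(cohort$clinical, labels,
                         endpoints = c("OS", "DFS"))
dplyr::select(res, endpoint, n_col1_high, n_col3_high, n_other, chi2, p)
#> # A tibble: 2 × 6
#>   endpoint n_col1_high n_col3_high n_other  chi2        p
#> 1 OS                95         101     104  54.1 1.91e-13
#> 2 DFS               95         101     104  56.3 6.10e-14

plot_km_groups(res$curves[[1]], title = "OS")   # step curves + censor ticks

# fiber architecture of a rendered SHG-like field
f <- render_fiber_field(fiber_field_params(n_fibers = 25, kappa = 4,
                                           mean_angle_deg = 25, seed = 9))
summarize_image(f$image)
#> # A tibble: 1 × 9
#>   integrated_density area_fraction alignment_aspect_ratio orientation_mode_deg ...
#> 1              9510.         0.183                   2.80                   21
```

The correlations in `screen` show the purity bias (r ≈ −0.73 to −0.75,
q ≪ 0.05); the ratio features correlate with purity at |r| < 0.05 on the
same data. The logrank chi-square of 54.1 on 1 df reflects the
generator's hazard ratio of e on the latent Col1-vs-Col3 phenotype. The
image summary recovers the rendered field's mean angle (21° vs a true
25° concentration center) and its alignment (aspect ratio 2.8 at κ = 4).

File-based workflows (`run_cohort_simulation()`, `run_ratio_survival()`,
`run_fiber_metrics()`, `run_fiber_simulation()`) read/write TSV/TIFF and
echo a provenance file; a thin command-line wrapper lives at
`inst/scripts/collagenkit-cli.R`.

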