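---
title: "Methods: stromal-normalizing collagen ratios and fiber architecture metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stromal-normalizing collagen ratios and fiber architecture metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical choices made where the design was
genuinely open.

## The stromal-fraction problem and the ratio statistic

A bulk tumor RNA-seq sample is an admixture of cancer cells and stroma.
Fibrillar collagen transcripts (COL1A1, COL1A2, COL3A1) are produced
almost exclusively by stromal mesenchymal cells, so their bulk
expression tracks one minus tumor purity: mining bulk cohorts for
associations between a single collagen gene and outcome largely recovers
variation in stromal content, not stromal biology. The de-biasing idea
is to normalize a stromal signal by a co-expressed stromal signal.
`compute_ratio_features()` forms, per sample,

$$r_1 = \frac{\mathrm{COL1A1}}{\mathrm{COL3A1}}, \qquad
  r_2 = \frac{\mathrm{COL1A2}}{\mathrm{COL3A1}},$$

in which the shared stromal-fraction factor cancels, leaving a measure
of Col1-vs-Col3 *balance* within the stroma. `purity_correlation_screen()`
quantifies the bias this removes: a transcriptome-wide Pearson
correlation of each gene's log2(x+1) expression with tumor purity,
two-sided t-based p-values, Benjamini–Hochberg q-values over all defined
p-values (zero-variance genes are flagged `NA` and excluded from the
adjustment; samples with missing purity are dropped pairwise).

**Ratio scale.** Whether "the ratio of their expression" divides
log2(x+1)-transformed values or linear values is an open reading; the
two orderings differ. The default (`ratio_scale = "log"`) divides the
transformed values, the literal order of operations (transform for
downstream analysis, then ratio); `ratio_scale = "linear"` divides
`2^v − 1`, i.e. a fold-ratio. Both are exposed; nothing downstream
assumes one or the other. A sample whose denominator is zero on the
chosen scale is flagged invalid rather than imputed.

## Dual-ratio quartile classification

`classify_patients()` computes quartile cutpoints of each ratio over the
valid samples with the linear-interpolation percentile convention
(`stats::quantile` type 7, the common spreadsheet/statistics default).
A sample is

* **COL1_HIGH** if it lies strictly above Q3 of $r_1$ *or* $r_2$ (and
  not strictly below Q1 of the other),
* **COL3_HIGH** symmetrically for the bottom quartiles,
* **OTHER** if it lies in the middle two quartiles of *both* ratios,
* **EXCLUDED** if it is in the top quartile of one ratio and the bottom
  quartile of the other (a conflict).

The union rule is the only reading under which the three groups can each
exceed $n/4$, which is what a roughly into-thirds split of a cohort
requires; an intersection rule caps the high/low groups at $n/4$. The
conflict case is rare when the two ratios are strongly rank-concordant
(they share a numerator gene family and a denominator), and with
perfectly concordant ratios the rule provably reduces to the
single-ratio quartile rule with no exclusions — one of the package's
property tests. Ties exactly at a cutpoint fall to the middle (strict
inequalities), which makes the degenerate all-tied case well defined:
everyone is OTHER, because no quartile separation exists.

## Survival machinery

`km_estimate()` is a first-principles product-limit estimator: at each
distinct event time $t_j$ with $d_j$ events among $n_j$ at risk,
$S \mapsto S\,(1 - d_j/n_j)$. Subjects censored exactly at an event time
remain in the risk set for that time (censoring processed after events),
the standard convention. Greenwood standard errors and log-scale
confidence bands are computed; the bands are clipped to $[0,1]$ and set
to 0 once the estimate reaches 0.

`logrank_test()` is the Mantel–Cox two-group test: per distinct event
time, observed events in group 1 minus the hypergeometric expectation
$d_j n_{1j}/n_j$, variance
$d_j (n_{1j}/n_j)(1-n_{1j}/n_j)(n_j-d_j)/(n_j-1)$ with all tied events
pooled into one draw, $\chi^2 = (O-E)^2/V$ on 1 df. With no events at
all the test is undefined; it returns $p = 1$ with a warning rather than
failing. The `survival` package appears only in the test suite, as an
independent oracle.

`survival_by_group()` iterates endpoints × strata, estimating curves for
all three groups but testing only COL1_HIGH vs COL3_HIGH — the OTHER
group is displayed, never tested. Groups with fewer than 2 usable
samples skip the test with a warning. Endpoint names are resolved
through an alias map (default `DFI → DFS`, `PFI → PFS`) because curated
survival resources and figure labels use different vocabularies; the
mapping is configuration, not a guess baked into code.

`subtype_association()` builds, per molecular subtype, the 2×2 table
(this subtype vs rest) × (COL1_HIGH vs COL3_HIGH) and applies the
two-sided Fisher exact test with the point-probability rule (all tables
with point probability ≤ the observed one), the convention of the
mainstream scientific stacks; mid-p variants exist but are not used.
`enrichment_test()` is the standard one-sided hypergeometric
over-representation test over user-supplied gene sets (curated pathway
databases are deliberately out of scope), BH-adjusted across sets.

## The synthetic cohort

`generate_cohort()` draws, in a fixed documented order under one root
seed: tumor purity $p_i \sim \mathrm{Beta}(5, 2)$ (right-skewed, typical
of curated purity estimates); a latent Col1-vs-Col3 balance phenotype
$r_i \sim N(0, 1)$; collagen expression mixed **on the linear scale**,

$$e_{gi} = (1 - p_i)\,2^{s_{gi}} + p_i\,2^{c},$$

with stromal log2 level $s_{gi} = 10 \pm r_i/2 + N(0, 0.5)$ (plus for
COL1A1/COL1A2, minus for COL3A1) and cancer-compartment level $c = 4$,
then log2(x+1)-transformed — admixture is physically linear in
transcript abundance, so mixing before the log is the faithful order;
100 purity-independent Gaussian background genes (true nulls for the
screen); subtype labels drawn multinomially (LumA 0.50, LumB 0.20,
Her2 0.10, Basal 0.15, Normal-like 0.05, the approximate frequencies in
breast-cancer cohorts) independently of $r_i$; and per endpoint
(OS/DSS/DFS/PFS) an exponential event time with hazard
$0.1\,e^{\beta r_i}$ ($\beta = 1$ by default) under independent
exponential censoring at rate 0.06, chosen to censor roughly 40% of
subjects, with an optional administrative cutoff.

What this emulates: the confounding structure (collagen ∝ stromal
fraction), the de-biasing (ratios cancel purity), and a survival signal
carried by the ratio phenotype. What it does not: realistic expression
covariance, batch effects, PAM50 centroid structure, or non-proportional
hazards. Tests passing on this cohort therefore validate the
*statistical machinery and its assumptions*, not the biological claim on
real data — the real-cohort analysis requires the corresponding public
download, to which the same pipeline applies unchanged
(`run_ratio_survival()` on the expression/clinical TSVs).

## Fiber architecture metrics

Conventions, stated once and used everywhere: images are numeric
matrices indexed (row, col), origin top-left, x = column; angles are
degrees in $[-90, 90)$, 0° along x, positive counter-clockwise in the
y-up view.

* `integrated_density()`: sum of intensities over foreground pixels
  (default threshold: Otsu over the *positive* pixels, since subtracted
  backgrounds are exactly zero), plus area fraction.
* `fft_alignment()`: mean-subtract, Hann-window, 2-D power spectrum,
  second-central-moment tensor of spectral power about the DC origin,
  statistic $\sqrt{\lambda_{\max}/\lambda_{\min}}$. The unpaired Nyquist
  bins are excluded so the spectral support is symmetric, which makes
  the statistic exactly invariant under 90° rotation and under intensity
  scaling; 1 means isotropic. No formula for the "FFT aspect ratio" is
  fixed by convention elsewhere, so this spectral-moment definition was
  chosen for being standard, rotation-equivariant and parameter-free.
* `orientation_histogram()`: per-pixel structure tensor (Gaussian
  derivative at σ = 1 px, tensor smoothing at σ = 2 px),
  gradient-energy-weighted histogram over $[-90, 90)$ in `bin_deg`-wide
  bins (must divide 180), mode = center of the heaviest bin.
* `trace_fibers()`: Otsu threshold → Guo–Hall thinning → junction
  removal → path ordering → moving-average smoothing (window 5 px) →
  per-fiber arc length, chord, straightness = chord/arc, width = twice
  the mean distance-transform value along the path minus the half-pixel
  boundary offset, chord angle. Three numerical choices deserve note:
  Guo–Hall thinning is used because the older Zhang–Suen scheme deletes
  2×2 blocks outright and destroys the staircase runs that
  near-diagonal fibers thin down to; junctions are detected by the
  Rutovitz crossing number (neighbor *transitions*, not neighbor
  counts, which over-call junctions on staircases) and cut with a
  one-pixel margin so arms of crossing fibers cannot remain connected;
  and the raw pixel chain is smoothed before measuring because
  chain-code arc length overestimates oblique segments by up to ~8%,
  which would leak into both length and straightness.
* `straight_fraction()`: a fiber is straight iff straightness
  **strictly exceeds** 1/1.08 = 0.92593 (`straight_threshold`); a fiber
  exactly at the threshold is not straight. Reported as a percentage of
  all fibers.

This tracer is a simplified stand-in for curvelet-based fiber extractors
(no curvelet preprocessing, no width profile fitting); it is validated
against the synthetic generator's exact ground truth, not against any
external program's output, and no attempt is made to match external
fiber counts.

## The synthetic fiber fields

`render_fiber_field()` draws fiber orientations from an axial von Mises
distribution (sample at $2\mu$ with concentration κ, halve; κ = 0 is
isotropic — sampler implemented in-package with the Best–Fisher
rejection scheme), lengths and widths from truncated normals, and
renders each fiber as a Gaussian-profile tube (FWHM = width) along a
sinusoidally perturbed line: two full periods per fiber, random phase,
relative amplitude `waviness_amp`. Whole periods make the chord exactly
the nominal length and the arc exactly chord × sinuosity, where the
sinuosity is the quadrature integral
$\frac{1}{2\pi}\int_0^{2\pi}\sqrt{1 + (2\pi a)^2\cos^2 u}\,du$ of the
relative amplitude $a$ — so per-fiber straightness ground truth is exact,
and `waviness_for_sinuosity()` inverts the relation. `waviness_spread`
jitters the amplitude per fiber (uniform on
$[1-\text{spread}, 1+\text{spread}]$ × amplitude) so that the straight
fraction responds smoothly to the waviness level instead of stepping
from 100 to 0 as the common straightness crosses the threshold; ground
truth stays exact per fiber. Intensity units are arbitrary (metrics are
scale-invariant or reported in a.u.); no optical point-spread or
polarization physics is modeled.

One recovery subtlety: sinusoidal waviness adds real intra-fiber
orientation dispersion, so a strongly wavy field at high κ is genuinely
less aligned than a straight field at moderate κ. Pooling a κ × waviness
grid into one rank correlation between κ and the FFT aspect ratio
therefore confounds two real effects and cannot approach 1. The
recovery claim is accordingly factorial: within every waviness level the
aspect ratio must rank κ perfectly, and within every κ level
100 − %straight must rank the waviness level perfectly — this is what
the acceptance checks compute.

## Morphometry

`segment_nuclei()` applies tiled adaptive Otsu thresholding (64-px
tiles; a tile's local threshold is trusted only when the tile has
appreciable contrast, otherwise the global Otsu value is used), labels
connected components, and discards objects with equivalent diameter
$2\sqrt{A/\pi}$ below 15 px — the stated minimum-size exclusion,
enforced exactly (a 15-px-diameter object survives; anything smaller
does not). `segment_cells()` thresholds the cytoskeleton channel with
the minimum-cross-entropy (Li) method — implemented in-package in its
standard iterative form — and grows cell territories from the nucleus
seeds with `EBImage::propagate()`. Propagation-style region growing is
the same algorithm family the original interactive pipelines use, so it
was preferred over a generic marker-based watershed; each cell inherits
its nucleus label and contains at least the nucleus footprint.

Per-cell measures: areas by pixel count; orientation from second central
moments (with the row axis negated so angles are counter-clockwise);
compactness $P^2 / (4\pi A)$, which is 1 for a perfect circle — the
definition adopted here for "a measure of cell irregularity", since no
formula is fixed by the name alone; nuclear fraction = nuclear
area / cell area. The perimeter $P$ is the closed outer contour length
from a Moore-neighbor trace with the Vossepoel–Smeulders corner
correction ($0.980\,n_{\text{even}} + 1.406\,n_{\text{odd}} -
0.091\,n_{\text{corners}}$) rather than plain 1/√2 step weights: the
plain chain-code length overestimates smooth digital boundaries by
about 5%, which doubles in the squared compactness and would push a
perfect circle to ≈1.10; the corrected estimator keeps digital circles
within ~1% of $4\pi A/P^2 = 1$ across radii.

`orientation_correlation()` is plain Pearson on paired angle lists in
$[-90, 90)$, with the linear-regression slope reported. The caveat is
circularity: angles near ±90° wrap, so for fields oriented near the
wrap-around the linear correlation understates co-alignment. The
convention is kept because it is how cell–matrix co-alignment is
ordinarily reported; users with near-vertical fields should rotate their
angle origin first.

`positive_fraction()` (100 · positive/total nuclei) and
`tumor_volume()` ($V = L W^2/2$, axes normalized so $L \ge W$ with a
message when swapped) are the scalar indices; counts and calipers are
inputs, not derived from images.

## Problem sizes and tolerances used in the checks

The test suite and `scripts/acceptance.R` exercise: de-biasing on
1000-sample cohorts over multiple seeds; logrank type-I error on 1000
null cohorts of 200 samples and power on 100 cohorts of 1000 samples at
the design hazard coefficient; Kaplan–Meier/logrank agreement with the
`survival` package to 10⁻⁸ on dozens of random censored datasets; Fisher
two-sided p against direct hypergeometric enumeration over all 2×2
tables with margins up to 12; fiber recovery on 256-px, 30-fiber fields
over a 3×3 κ × waviness grid; and the morphometric identities on
rendered disks and rectangles (circle compactness within 5% of 1, exact
nuclear fractions, the 15-px exclusion, $V(10,5)=125$). These sizes were
chosen so each property is measured with comfortable Monte-Carlo margin
while the whole suite stays quick to run.

## Known limitations

* Synthetic expression units are arbitrary; real cohorts should be
  supplied on their native scale with `expression_scale = "raw"` (the
  transform is then applied once, and double transformation is refused).
* The cohort generator's independence assumptions (censoring, subtypes)
  are idealized; the logrank calibration shown is under the generator's
  own null.
* The fiber tracer merges or drops fibers in dense crossings (junction
  pixels are cut, short fragments are discarded below `min_length_px`,
  default 30 px), so absolute fiber counts are conservative; per-fiber
  shape metrics are accurate on the fibers it does trace.
* Pearson on angles ignores circular wrap, as noted.
* Greenwood bands are pointwise, not simultaneous.
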