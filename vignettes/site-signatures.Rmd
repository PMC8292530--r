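---
title: "Site signatures, batch effect, and preserved-site cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site signatures, batch effect, and preserved-site cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitefold)
```

## The problem

Multi-site histology repositories pool hematoxylin-and-eosin slides from
dozens of contributing hospitals. Every step between the biopsy and the
digital file — fixation, sectioning, stain formulation, staining time,
scanner model and calibration — differs between institutions, so each
site's slides carry a *site-specific signature*: a joint shift in color and
texture that has nothing to do with tumor biology. When the clinical
outcome a model is asked to predict is unevenly distributed across sites
(and in practice almost every demographic, clinical and genomic variable
is), a model evaluated with folds that mix sites can reach high apparent
accuracy by recognizing the submitting site instead of the biology. The
inflation disappears — and with it, often, the "signal" — when every site
is confined to a single cross-validation fold.

sitefold provides the full chain needed to study and correct this problem
offline: a synthetic multi-site cohort generator with controllable
signatures and confounding, the classical image statistics that quantify a
signature, stain normalization and augmentation, heterogeneity tests, an
optimal preserved-site fold assigner, and an evaluation harness.

## Quantifying the signature

The signature is measured with twenty classical image statistics per tile
or slide: per RGB channel the mean, population standard deviation,
skewness $m_3/m_2^{3/2}$, kurtosis $m_4/m_2^2$ (central moments with $1/N$
normalization) and Shannon entropy of the 256-bin intensity histogram
(natural log, $0\log 0 = 0$, hence bounded by $\log 256$); plus five
second-order Haralick features of the gray-level co-occurrence matrix
$\mathbf{P}$ at distance 1 — contrast $\sum P_{ij}(i-j)^2$, dissimilarity
$\sum P_{ij}|i-j|$, homogeneity $\sum P_{ij}/(1+(i-j)^2)$, angular second
moment $\sum P_{ij}^2$, and correlation — averaged over the four offsets
0°, 45°, 90°, 135°. The GLCM uses 256 gray levels, ordered
(non-symmetric) pairs, and ITU-R 601 luminance (0.299, 0.587, 0.114,
rounded); slide-level statistics are computed after area-average
downsampling to 5 µm/px. Degenerate inputs follow explicit conventions
instead of silent NaN: a constant sample reports skewness and kurtosis as
`NA`, a constant image reports GLCM correlation as 1, and one-way ANOVA
with zero within- and between-group variance reports `NA` (pure
separation gives `Inf`).

Heterogeneity across sites is tested exactly as one would for a cohort
table: Pearson chi-squared (no continuity correction) for categorical
outcomes on sites with at least 20 slides, a one-way ANOVA F per image
characteristic, and Benjamini–Hochberg correction across all rows of one
report. Missing outcomes are dropped per feature (pairwise deletion), and
untestable rows are kept as explicitly skipped entries.

## Preserved-site fold assignment

Let $n_{s,f}$ be the number of patients from site $s$ in outcome class
$f$, and $m_{s,c} \in \{0,1\}$ indicate assignment of site $s$ to fold
$c$ of $k$. The stratification error

$$\mathrm{Error} = \sum_{f,\,c}\Bigl(\sum_s m_{s,c}\,n_{s,f} -
\sum_s \frac{n_{s,f}}{k}\Bigr)^2,
\qquad \sum_c m_{s,c} = 1 \;\; \forall s,$$

is minimized subject to every site landing in exactly one fold. Zero error
is *perfect stratification*: every fold holds exactly $1/k$ of each class.
`preserved_folds()` solves this integer quadratic program with a
depth-first branch-and-bound: sites are processed in decreasing size,
fold labels are symmetry-broken (a site may only open the next unused
fold), and a continuous per-class water-filling relaxation provides the
lower bound. Up to 15 sites the returned assignment is the proven global
optimum (`optimal = TRUE`); larger instances fall back to a seeded
multi-start local search over single-site moves and pairwise swaps.
`brute_force_folds()` — exhaustive enumeration after fixing the first
site, ties broken lexicographically — is kept as the independent oracle.
Two deliberate conventions: each fold must receive at least one site (an
empty validation fold is useless), and patients with a missing outcome are
excluded from $n$ but follow their site into its fold. Continuous
outcomes are quantile-binned (`bin_continuous()`, default quartiles,
rank-based with deterministic tie-breaks) before optimization.

The comparison splits are patient-level: `standard_folds()` stratifies by
outcome irrespective of site (per class, seeded shuffle then round-robin
deal), and `site_balanced_folds()` represents every site equally in all
folds — the split used when the *site itself* is the prediction target.

## The synthetic cohort generator

No external images are required: `make_confounded_scenario()` builds a
cohort in which the two quantities of interest are dials.

* **Confounding** $c \in [0,1]$: alternate sites lean positive/negative
  with prevalence $0.5 \pm c/2$, so $c=0$ makes outcome independent of
  site and $c=1$ makes it a deterministic function of site.
* **Stain strength** $\sigma \in [0,1]$: each site draws an independent
  chroma shift — multiplicative factors on hue (span $\pm 4.5\%\sigma$)
  and saturation (span $\pm 9\%\sigma$, wider because a saturation
  multiplier moves pixel values much less than an equal hue multiplier at
  histology-like colors). Value is left to within-site variation, since
  brightness varies more slide-to-slide than site-to-site. All multipliers
  stay within the profile's ±10% band.

Tiles are a minimal, learnable stand-in for histology: dark elliptical
"nuclei" (Poisson count, default 12/tile) on an eosin-pink background
with Gaussian noise; the outcome class can modulate nucleus density
(`class_effect`), giving a *biologic* texture signal independent of any
stain. Site signatures are deliberately multi-factor, as in real
repositories where fixation, sectioning and digitization differ along
with stain: each site also draws its own acquisition texture (noise level
4–13, nucleus radius 2.5–6 px, eccentricity, stain darkness ±30%).
Within a site, every slide draws its own jitter: hue/saturation
multipliers U(0.985, 1.015), value U(0.94, 1.06) (brightness moves far
more than color balance between sections), cellularity ±20%, and noise
level ±15%. All randomness is keyed by `(seed, slide_id)`, so a slide's
pixels never depend on how many other slides exist, identical seeds give
byte-identical cohorts, and the returned ground-truth log records every
generating parameter.

The within-site value jitter is what makes grayscale normalization
informative in the artifact experiment: two uniform brightness
distributions of width 12% whose centers differ by the 5% artifact
overlap enough that luminance alone cannot separate them perfectly, while
the chroma footprint remains nearly noiseless — so color models detect
the artifact essentially perfectly and grayscale models detect it well
but imperfectly, the qualitative pattern reported for real slides.

What the generator does **not** emulate: real nuclear morphology and
tissue architecture, scanner compression artifacts (JPEG quality is a
known confounder, deliberately out of scope), pyramidal whole-slide
formats, and intra-slide spatial heterogeneity (one stain jitter per
slide). Green tests therefore certify the statistical machinery and the
direction and structure of the batch-effect phenomenon, not performance
on real histology.

## Stain operations

Reinhard normalization matches channel means and standard deviations in
Ruderman's decorrelated log (lαβ) space; the inverse LMS→RGB matrix is
computed as the exact inverse of the forward matrix rather than the
published 4-digit rounding, so self-normalization is an identity within
integer rounding. A zero-variance channel is set flat at the reference
mean. Macenko normalization works in optical density
$OD = -\log((I+1)/256)$ with background threshold β = 0.15 and robust
angle percentile α = 1; stain vectors come from the extreme angles in the
plane of the top two eigenvectors of the OD covariance, concentrations
from least squares, rescaled to the reference's 99th-percentile maxima.
Hue multiplication wraps modulo 1 (hue is circular); saturation and value
clip to [0, 1]. Light HSV augmentation multiplies H, S and V by
independent U(0.9, 1.1) scalars; heavy multiplies H and S by U(0.7, 1.3)
and leaves V untouched. `standardize()` gives exact zero mean and unit
population variance. Because binary fixtures do not ship with source-only
packages, the default normalization references are derived from a
deterministic synthetic H&E-like tile generated in code
(`default_reference_tile()`), making normalization runs reproducible
offline.

## Evaluation harness

The tile scorer behind the experiments is a seeded, class-balanced
(downsampled) ridge classifier on the 20-value signature — an explicit
desk-scale surrogate for a convolutional network, not a reimplementation
of one. Its default penalty is deliberately small (λ = 0.001): the
phenomenon under study is a high-capacity model *memorizing* per-site
signatures, and a strongly regularized linear model cannot memorize a
dozen site clusters. AUROC is the rank statistic with ties counted ½,
macro-averaged one-vs-rest for multiclass; evaluation aggregates tile
scores to slide means before ranking (the ×10 bootstrap resamples slides,
the independent sampling unit). Fold-level comparisons use the classical
t statistics of threefold cross-validation: paired two-sided (df 2),
pooled two-sample one-sided (df 4) for standard-vs-preserved, one-sample
one-sided against AUROC 0.5 (df 2); exact ties and zero-variance cases
return explicit markers (p = 1, or t = ±∞). BH correction is applied
across the comparisons of one experiment.

`run_confounding_experiment()` generates a fully confounded cohort
(default: 12 sites × 6 patients × 12 tiles of 96 px, chosen so the whole
experiment is a half-minute of CPU while leaving enough sites for three
preserved folds), scores it under standard and preserved folds, and
tests the gap. `run_artifact_grid()` rebuilds the artificial-artifact
design: 23 target and 46 background slides from one site, a biologic
fraction (targets given the denser texture class) and an artifact
fraction (targets given the 5% HSV shift) varied independently, with
optional normalization before feature extraction. The artifact is folded
into each slide's single multiplicative HSV transform; applying it as a
second pass over already-quantized pixels would stamp a re-quantization
footprint (visible in entropy and ASM) that has nothing to do with the
stain shift.

## Power at desk scale, and other limitations

With threefold cross-validation the standard-vs-preserved comparison has
three AUROC values per arm and four degrees of freedom. A preserved fold
contains only four held-out sites, so its AUROC is close to an ordering
statistic of four clusters: its fold-to-fold standard deviation is
large, and the df-4 t-test is correspondingly blunt — cohorts exist (by
chance of the site draw) in which a genuine gap of 0.3 is not
FDR-significant, and a fraction of null site-geometry draws shows
noticeable chance alignment between stain and outcome across sites. The
reported experiments use one fixed simulated cohort per scenario; this
is a real limitation of fold-level inference at 12 sites, not of the
optimizer, and it mirrors the difficulty of validating rare outcomes in
small multi-site cohorts. At repository scale (dozens of sites, hundreds
of patients) the same machinery concentrates sharply.

Other limitations: the exact branch-and-bound is bounded at 15 sites by
default (beyond that the heuristic is used and flagged); Haralick
features are computed on luminance, not per channel; the chi-squared
tests error on zero marginals rather than guessing a merge; and the
baseline scorer's linear capacity caps how many sites it can memorize —
about the feature dimension — which bounds the cohort sizes the
confounding demonstration can use.
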