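---
title: "digitalCMS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{digitalCMS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model, the
tunable parameters and why they have the defaults they do, what the
synthetic-cohort generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem and the model

HPV-positive cervical squamous cell carcinoma divides into two consensus
molecular subtypes, C1 and C2, with different prognoses (C2 worse).
The subtype is ordinarily determined from expression or methylation
data; `digitalCMS` predicts it from routine H&E histology instead.
Because subtype labels exist only per patient, not per tissue region,
prediction is cast as multiple-instance learning: a patient is a *bag*
of patch embeddings $\{f_1,\dots,f_K\}$, $f \in \mathbb{R}^{1024}$,
produced by an external feature extractor outside this package's scope.

An MLP ($1024 \to 512 \to 1$, ReLU) scores each patch; the sigmoid of
its output is the patch digital-CMS score in $[0,1]$ and the bag
(patient) score is the mean of the patch scores. Training samples
triplets — one C2 bag with score $x^p$, two distinct C1 bags with
scores $x^{n1}, x^{n2}$ — and minimizes

$$L = [\alpha_1 - (x^p - x^{n1})]_+ + [\alpha_1 - (x^p - x^{n2})]_+
      + [\lVert x^{n1}-x^{n2}\rVert_2^2 - \alpha_2]_+$$

which is zero exactly when the C2 score clears both C1 scores by the
inter-class margin $\alpha_1$ and the two C1 scores differ by at most
$\sqrt{\alpha_2}$. The margins default to $\alpha_1 = 0.5$,
$\alpha_2 = 0.1$, the values conventional for this ranking-MIL loss.

Assumptions worth making explicit: (i) subtype-informative morphology is
carried by a *subset* of patches, so a bag-level mean over patch scores
can rank patients even though most patches are uninformative; (ii) a
higher score means "more C2-like" everywhere in the package — survival
stratification, heatmap colouring and exemplar selection all inherit
this orientation; (iii) embeddings from different cohorts live in a
shared feature space, which is what makes cross-cohort transfer
meaningful.

## Optimization and its open choices

SGD with learning rate $3\times10^{-3}$, momentum $0.9$, weight decay
$10^{-4}$, learning rate $\times 0.1$ every 10 epochs, at most 20
epochs. Early stopping monitors the mean triplet loss on a held-out
fold (a fixed set of monitoring triplets, so the curve is comparable
across epochs) with patience 3; the returned checkpoint is the one with
the lowest monitoring loss, while "best-performing model" across CV
folds is selected by validation-fold AUC.

Two points the loss specification leaves open were resolved as follows.

* **Where the sigmoid sits.** The loss operates on *post-sigmoid* bag
  scores: patch outputs are squashed to $[0,1]$, then averaged. This
  keeps patch and patient scores on one interpretable scale (the margin
  $\alpha_1 = 0.5$ then spans half the score range) and makes
  "probability of being C2" language meaningful for patch maps.
* **Triplets per epoch.** The package draws $4\times$ the number of C2
  training bags per epoch. One triplet per C2 bag per epoch — the most
  literal reading of "drawn in each iteration" — gives SGD so few steps
  (tens per epoch) that on some data realizations the scorer plateaus
  before the first learning-rate decay; four ranking comparisons per C2
  bag per epoch is still a small budget but converges robustly. This is
  a deliberate deviation from the minimal reading, exposed as
  `triplets_per_epoch`.

Bags are built per *patient*: embeddings of all of a patient's slides
are concatenated, with the slide id kept per patch. Slide-level bags
would multiply correlated training units sharing one label; patient-level
bags match how the label is defined.

## Survival stratification

The discovery set (the merged training cohorts, scored by the selected
model) supplies the ROC; the cutoff maximizes Youden's
$J = \text{sensitivity} + \text{specificity} - 1$ over the candidate
thresholds ($-\infty$, midpoints of adjacent distinct scores, $+\infty$;
a patient is high-risk when score $\ge$ cutoff). On ties in $J$ the
*lowest* qualifying threshold is returned, assigning patients to
high-risk only when forced. Kaplan–Meier curves and the log-rank test
compare the risk groups on disease-specific and disease-free survival;
multivariate Cox models (Breslow ties) adjust for HPV type, stage, age
and treatment against conventional reference levels (HPV-16, stage I,
surgery). Concordance is Harrell's C over comparable pairs; DeLong's
test compares two classifications' AUCs against the binary subtype
labels, with the degenerate zero-variance case (identical scores)
defined as $p = 1$ rather than a division by zero.

The AUC is computed from average ranks (the Mann–Whitney estimate, ties
counted ½), which equals the trapezoidal area and is invariant under
monotone score transforms; the test suite checks it against $O(n^2)$
pair enumeration, and the Youden scan against an exhaustive oracle.

## Preprocessing

Tiles are cut on a non-overlapping 256-px grid assumed to be at
0.5 microns per pixel (resampling from other resolutions is a documented
pre-step, not performed here); partial edge tiles are dropped so each
patch has exactly $256^2$ pixels, keeping density denominators exact. A
patch is kept when its tissue-mask coverage *strictly* exceeds 0.8. The
tissue mask thresholds the HSV saturation channel by Otsu after
excluding near-white and near-black pixels, with two guards: a constant
saturation channel falls back to a fixed 0.15 threshold, and the Otsu
threshold is capped at 0.25 because glass background is always
low-saturation — an Otsu split above that reflects contrast *within*
tissue (e.g. the two stains of an H-DAB image), not tissue-vs-glass.

## TME profiling

For each detector dialect (5-class: neoplastic, inflammatory,
connective, necrosis, non-neoplastic; 6-class: neutrophil, epithelial,
lymphocyte, plasma, eosinophil, connective — never merged, joined only
by region), a region profile holds per-type count $N$, density
$\rho = N/A$ with $A$ in $\mu m^2$ ($A = \text{px area} \times
\text{mpp}^2$), $\ln\rho$, ratio $N/\text{total}$, and mean/median/SD of
nucleus area ($\mu m^2$, shoelace formula) and perimeter ($\mu m$).
Missing-value rules mirror the exclusion of absent cell types:
$\ln\rho$ is missing when $N = 0$, the neutrophil-to-lymphocyte ratio is
missing (not $\infty$) when no lymphocyte was detected, morphology rows
are missing for absent types. The tumour-rich lymphocyte density bins
nuclei by centroid into half-open $128\times128\,\mu m^2$ cells and
pools lymphocytes over cells with *strictly more than* 50 neoplastic
nuclei; a slide with no qualifying cell yields a missing value, not
zero.

Group comparisons report Welch's two-tailed t (chosen over the pooled
variant since group variances are not assumed equal), the Mann–Whitney U
(normal approximation with tie correction), and Cliff's
$\delta = (\#(x>y) - \#(x<y))/(n_1 n_2)$, with Benjamini–Hochberg
adjustment across the features tested in one call (the family boundary
is the analysis panel, configurable by passing the feature list) at
level 0.05. Spearman correlation is Pearson on average ranks with a
two-sided t-approximation p.

CD8+ scoring deconvolves the image in optical-density space with the
standard H-DAB stain vectors, thresholds the DAB channel at 0.15 OD
(configurable; no canonical value exists), and reports positive pixels
over tissue pixels.

## The synthetic-cohort generator

The generator is first-class, tested code. It emulates the statistical
*structure* the analysis assumes, not the appearance of tissue:

* **Bags.** Background patches are standard normal in 1024 dimensions;
  in C2 bags a known fraction (default 0.3) of patches is shifted by
  `effect_size` (default 2, in feature-SD units) along one random unit
  direction. The indices of the shifted patches are recorded, giving a
  ground truth for localisation tests. Cohorts sharing `signal_seed`
  share the direction — cross-cohort transfer presumes the subtype
  signal is common biology — while all other draws differ.
* **Bag size.** `patches_per_bag` defaults to 100–200. A whole-slide
  image at 0.5 mpp yields thousands of tissue patches; 100–200 is a
  desk-scale subsample that keeps the bag-mean noise
  ($\sim\!1/\sqrt{K}$ per direction) small enough that the planted
  signal is learnable from tens of bags, which is the regime the
  learning tests probe. (With much smaller bags the per-bag noise
  dominates the 0.6-SD bag-level shift and no estimator could separate
  the classes well at these sample sizes.)
* **Survival.** Exponential times with a class hazard ratio (default 2,
  C2 worse; baseline median 2000 days) and *independent* exponential
  censoring calibrated to the requested censoring fraction —
  independence keeps Cox estimates unbiased, giving closed-form
  recovery targets.
* **Nuclei.** Poisson counts per type with class-conditional rates
  (per $128\times128\,\mu m^2$), regular 12-gons with normal areas at
  uniformly placed, non-coinciding centroids, so area and perimeter
  have analytic values given the radius. The default profile plants the
  reported effect directions: higher lymphocyte density and larger
  lymphocytes in C1; higher neutrophil ratio, NLR, eosinophil ratio and
  larger, more variable neoplastic and connective nuclei in C2.
* **IHC tiles.** Beer–Lambert transmission through the H-DAB vectors
  with an exactly planted DAB pixel fraction.

What it does **not** emulate — staining variation between cohorts,
scanner artefacts, spatial correlation of patches, realistic embedding
geometry (foundation-model features are far from isotropic Gaussian),
or any visual realism. Passing tests therefore demonstrate that the
machinery is correct and that the pipeline recovers known planted
structure; they do not certify performance on real cohorts.

## Numerical details and degenerate inputs

* k-means for exemplar mining uses 10 random restarts under a fixed
  seed, retried with a fresh seed on the rare empty-cluster failure;
  exemplars are medoids (nearest real patch to each centroid), so every
  exported exemplar is an actual patch.
* The score heatmap uses a diverging blue–white–red map centred at the
  stratification threshold via a piecewise-linear ramp, so "neutral"
  means "at the cutoff" rather than "0.5".
* `roc_auc` requires both classes; `youden_cutoff` refuses all-identical
  scores; `km_logrank` refuses empty groups; `fit_coxph` refuses
  zero-event data and flags likely separation/collinearity instead of
  reporting absurd hazard ratios silently.
* All randomness flows from explicit integer seeds: generators,
  fold splits, triplet sampling and initialization are reproducible
  bitwise under a fixed seed.

## Problem sizes used by the checks

The test suite trains on cohorts of 40 bags per class (100–200 patches
per bag); null-model and label-permutation checks average the held-out
AUC over 5 and 3 seeded replicates respectively, which narrows the
Monte-Carlo spread of the estimate without touching the acceptance
band. Survival calibration uses 200 log-rank replicates at $n = 100$
and Cox recovery at $n = 500$ with 20% censoring. The pipeline runs in
`scripts/acceptance.R` use three cohorts of 20 patients per class with
80–120 patches per bag — sizes chosen so the full study flow remains a
coffee-break computation on one CPU while keeping every stage's
statistics meaningful.

## Known limitations

* The MLP is trained in plain R; it is adequate for desk-scale bags but
  not for production-scale cohorts with thousands of patches per slide.
* Exact reproduction of published cohort-level numbers (AUCs around
  0.78–0.85 on real cohorts, specific log-rank p-values, the CD8
  correlation of −0.22) requires the restricted real cohorts and the
  external feature extractor, both outside this package's scope.
* Survival machinery covers right-censoring only: no competing risks,
  time-varying covariates or interval censoring.
* The two nuclei vocabularies are joined spatially, not biologically; a
  nucleus detected by both detectors is counted once per dialect.
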