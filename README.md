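# digitalCMS

Digital consensus-molecular-subtype (CMS) scoring of HPV-positive cervical
squamous cell carcinoma histology, with downstream survival stratification
and tumour-microenvironment (TME) profiling.

HPV-positive cervical squamous cell carcinoma splits into two prognostic
consensus molecular subtypes, C1 and C2 (C2 carries the worse prognosis).
Determining the subtype normally requires expression or methylation assays.
This package implements the digital alternative: a multiple-instance
learner that maps the patch embeddings of a routine H&E whole-slide image
to a **digital-CMS score** in [0, 1] (higher = more C2-like), at both
patch and patient level, and then quantifies what that score implies —
survival separation, exemplar histological patterns, and cellular
composition of the microenvironment.

The package is aimed at computational-pathology researchers who already
have patch embeddings (e.g. from a histology foundation model) and
nuclei-detection output (HoverNet-style JSON) and want the full scoring
and profiling pipeline, plus a seeded synthetic-cohort generator that
emulates those external tools so everything is testable offline.

## The model

Each patient is a **bag** of K patch embeddings (f ∈ R^1024). An MLP
(1024 → 512 → 1, ReLU) scores every patch; the sigmoid of the output is
the patch digital-CMS score and the bag score is the patch-score mean.
Training draws triplets — one C2 bag (score x_p) and two distinct C1 bags
(x_n1, x_n2) — and minimizes the ranking loss

    L = [α₁ − (x_p − x_n1)]₊ + [α₁ − (x_p − x_n2)]₊ + [‖x_n1 − x_n2‖² − α₂]₊

with inter-class margin α₁ = 0.5 and intra-class bound α₂ = 0.1, by SGD
(lr 3×10⁻³, momentum 0.9, weight decay 10⁻⁴, lr ×0.1 every 10 epochs,
≤ 20 epochs with early stopping). Cross-cohort evaluation merges two
cohorts for stratified three-fold cross-validation and holds the third
out for testing; the best fold model (by validation AUC) scores the
held-out cohort. Patients are split into low-/high-risk at the Youden
cutoff of the discovery-set ROC and compared by Kaplan–Meier/log-rank
and multivariate Cox models. Patch-level scores drive exemplar mining
(top-20 patches per patient, k-means into nine patterns per subtype) and
region-level TME statistics (densities ρ = N/A, ln densities, cell-type
ratios, neutrophil-to-lymphocyte ratio, nuclear area/perimeter stats,
tumour-rich lymphocyte density, DAB-deconvolution CD8+ area fraction).

## Worked example

Train on two folds of a seeded synthetic cohort and evaluate the third:

```r
library(digitalCMS)
spec   <- synthetic_spec(n_patients_per_class = 20,
                         patches_per_bag = c(80, 120), seed = 1)
cohort <- generate_cohort(spec, "DEMO")
labels <- vapply(cohort$bags, function(b) b$label, numeric(1))
fold   <- stratified_folds(labels, k = 3, seed = 2)
model  <- train_triplet_mil(cohort$bags[fold != 1],
                            monitor_bags = cohort$bags[fold == 1], seed = 3)
model
#> Triplet-MIL digital-CMS scorer
#>  MLP: 1024 -> 512 -> 1 (ReLU, sigmoid)
#>  best epoch: 3 (monitor loss 0.9029)

held <- score_bags(model, cohort$bags[fold == 1])
head(held, 3)
#>   patient_id digital_cms_score label
#> 1   DEMO-002             0.467     0
#> 2   DEMO-004             0.425     0
#> 3   DEMO-008             0.489     0

roc <- roc_auc(held$digital_cms_score, held$label)
roc
#> ROC over 14 samples; AUC = 1

cutoff <- youden_cutoff(roc)       # 0.49: scores >= cutoff are high-risk
clin <- cohort$clinical[match(held$patient_id, cohort$clinical$patient_id), ]
km <- km_logrank(clin$dss_time, clin$dss_event,
                 ifelse(held$digital_cms_score >= cutoff,
                        "high-risk", "low-risk"))
#> log-rank chi-square: 3.04  p = 0.0814
```

The held-out fold is ranked perfectly (AUC 1), and even at n = 14 the
high-risk group trends toward worse disease-specific survival (the
generator plants a true hazard ratio of 2 between subtypes; significance
at this n is not expected every draw).

`run_all(default_config("run_dir", seed = 1))` executes the whole study
flow — three synthetic cohorts, nine cross-validated models, score
tables, KM/Cox outputs, exemplar manifests, TME comparison tables and
CD8+ recovery — into one run directory with a provenance manifest. A
thin command-line wrapper with `synth` / `train` / `stratify` / `run-all`
subcommands lives at `inst/cli/digitalcms.R`.

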