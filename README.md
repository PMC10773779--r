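# strokefuse

Multimodal prognosis scoring for acute ischemic stroke (AIS): a cross-modal
attention network that fuses a 2-D brain MRI slice with 19 tabular clinical
fields to classify patients as good outcome ("eusemia") vs poor prognosis —
plus a fully seeded synthetic lesion-image + metadata cohort generator, a
patient-level training/evaluation/cross-validation harness with a 4-arm
ablation, and Grad-CAM saliency with a lesion-localization score. The entire
neural-network engine (convolutions, batch/layer norm, multi-head
self-attention, Adam, and every backward pass) is written in base R and
verified by finite-difference gradient checks.

## Who this is for

Researchers who want a transparent, dependency-light reference implementation
of image + tabular fusion with attention gating — to study the architecture,
to benchmark on synthetic cohorts with known ground truth, or to adapt to
their own 2-D imaging + metadata problems.

## The model

```
image ──▶ frozen VGG16-style backbone ──▶ taps at strides 4/8/16
             │ (coarse-to-fine top-down fusion between scales)
             ▼
         GLAM per scale:  Fg = X' + MLP(LN(X')),  X' = X + MHSA(LN(X))   (global)
                          F' = Attc(F)∘F,  Fl = Atts(F')∘F'             (local)
                          joint = F + conv1x1(unpatch(Fg) + Fl)
             ▼
         GAP + concat  ──▶  F1
metadata ──▶ dense→BN→ReLU→dropout(.25)→dense→BN→ReLU ──▶ F2
F = concat(F1, F2);  A = σ(FC(ReLU(BN(FC(F)))));  Fo = A ∘ F ──▶ linear ──▶ softmax
```

Metrics: accuracy, precision, sensitivity/recall, specificity, F1
(harmonic mean), rank-based AUC; patient-level stratified k-fold
cross-validation; the ablation arms are (1) single-scale baseline,
(2) +multi-scale, (3) +GLAM, (4) +metadata MLP with CMAM gating.

## Worked example

```r
library(strokefuse)

## 1. simulate a 40-patient cohort (9 slices each, 64 px) and split it
cohort <- generate_cohort(40, slices_per_patient = 9, seed = 11)
cohort <- split_cohort(cohort, test_frac = 0.2, seed = 3)
cohort
#> sf_cohort: 40 patients x 9 slices (64px), 20 poor / 20 eusemia

## 2. train the full model (desk profile: 64 px, 30 epochs, Adam 1e-3)
tr <- cohort_subset(cohort, cohort$patients$patient_id[cohort$patients$split == "train"])
te <- cohort_subset(cohort, cohort$patients$patient_id[cohort$patients$split == "test"])
fit <- train_model(sf_config("desk"), tr, val_set = te, seed = 1)
round(tail(fit$history, 3), 3)        # per-epoch mean cross-entropy
#> [1] 0.015 0.010 0.017
fit$val$patient                       # held-out patients (n = 8)
#> accuracy 0.8750  precision 1  sensitivity 0.75  specificity 1  F1 0.8571
fit$val$patient_auc
#> [1] 1

## 3. where does the model look? Grad-CAM vs the true lesion masks
pos <- Filter(function(s) s$label == 1 && any(s$image$lesion_mask), te$samples)
scores <- sapply(pos, function(s)
  localization_score(grad_cam(fit$model, s$image, s$metadata, target_class = 1),
                     s$image$lesion_mask))
c(median = median(scores), frac_gt_1 = mean(scores > 1))
#>    median frac_gt_1
#>      1.09      0.69
```

All numbers above are the actual output of this script on the package's
seeded generator. Reading them: the model classifies 7 of the 8 held-out
patients correctly and ranks them perfectly (AUC 1); saliency is
lesion-concentrated (score > 1) on 69% of the 36 poor-prognosis test slices —
at this small training size (32 patients) localization is noticeably weaker
than in the 120-patient acceptance run, where ~80% of positive slices are
lesion-concentrated and accuracies fall in the 0.83–0.96 range.

The same pipeline is scriptable end to end:

```sh
Rscript inst/exec/strokefuse simulate --n-patients 40 --seed 1 --out data/
Rscript inst/exec/strokefuse train    --manifest data/manifest.csv --out run/
Rscript inst/exec/strokefuse evaluate --manifest data/manifest.csv --model run/model.rds --out eval/
Rscript inst/exec/strokefuse ablate   --manifest data/manifest.csv --epochs 5 --out abl/
Rscript inst/exec/strokefuse explain  --manifest data/manifest.csv --model run/model.rds --out cam/
```

## Scope and honesty notes

The clinical results that motivated this architecture come from a private
single-center cohort and are not reproducible here; this package asserts
in-table arithmetic consistency and property-level behaviour on synthetic
cohorts only. The backbone is frozen at a seeded random initialisation (no
pre-trained weights are available offline); see the methods vignette
(`vignettes/multimodal-stroke-prognosis.Rmd`) for the full account of the
model, the synthetic world, and every numerical design choice.
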