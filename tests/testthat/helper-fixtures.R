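## Shared fixtures and oracles. Everything is generated in code at test time;
## expensive objects are memoised in this environment for the session.

sf_ns <- asNamespace("strokefuse")
.fixtures <- new.env(parent = emptyenv())

## Tiny architecture used wherever the test only needs wiring, not capacity.
tiny_config <- function(...) {
  cfg <- sf_config("desk",
                   image_size = 32,
                   backbone = list(stage_channels = c(2L, 3L, 3L, 4L, 4L),
                                   convs_per_stage = rep(1L, 5)),
                   glam = list(patch_size = 2L, embed_dim = 4L, heads = 2L,
                               mlp_hidden = 8L, reduction = 2L),
                   meta_width = 8L,
                   epochs = 2L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

## Small shared cohort (memoised): 20 patients x 2 slices at 32 px.
tiny_cohort <- function() {
  if (is.null(.fixtures$tiny_cohort))
    .fixtures$tiny_cohort <- generate_cohort(20, slices_per_patient = 2,
                                             image_size = 32, seed = 7)
  .fixtures$tiny_cohort
}

## Central-difference gradient of f at theta restricted to indices idx.
num_grad <- function(f, theta, idx, eps = 1e-5) {
  vapply(idx, function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}

## Random C x H x W feature array.
rand_feature <- function(C, H, W, seed = 1) {
  withr::with_seed(seed, array(rnorm(C * H * W), dim = c(C, H, W)))
}

## Independent metric oracle: plain counting, no shared code with the package.
oracle_metrics <- function(y, p) {
  tp <- sum(y == 1 & p == 1); fp <- sum(y == 0 & p == 1)
  tn <- sum(y == 0 & p == 0); fn <- sum(y == 1 & p == 0)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       accuracy = (tp + tn) / length(y),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

## Exhaustive pairwise AUC oracle (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}
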