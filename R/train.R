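## Training protocol, evaluation, cross-validation and the ablation harness.
## Cross-entropy loss minimised by Adam (lr 1e-3, batch 32 by default) for a
## fixed epoch budget with no early stopping. Splits and folds are always at
## the patient level: slices of one patient never straddle train/test.

check_patient_disjoint <- function(train_ids, val_ids) {
  overlap <- intersect(unique(train_ids), unique(val_ids))
  if (length(overlap))
    stopf("patient(s) present in both splits: %s",
          paste(utils::head(overlap, 5), collapse = ", "))
  invisible(TRUE)
}

## Per-slice design: cached backbone features, metadata matrix, labels, ids.
prepare_xy <- function(model, cohort, feats = NULL, stats = NULL) {
  images <- lapply(cohort$samples, function(s) s$image$pixels)
  if (is.null(feats)) feats <- backbone_features(model$backbone, images)
  meta_X <- NULL
  if (model$arms$mlp) {
    if (is.null(stats)) stopf("metadata stats required for the mlp arm")
    meta_X <- do.call(rbind, lapply(cohort$samples, function(s)
      vectorize_metadata(s$metadata, train_stats = stats)))
  }
  list(feats = feats, meta_X = meta_X,
       y = cohort_slice_labels(cohort),
       pids = cohort_slice_patients(cohort))
}

## One-record-per-patient metadata list, for fitting stats on the train split.
patient_records <- function(cohort) {
  pids <- cohort_slice_patients(cohort)
  first <- !duplicated(pids)
  lapply(cohort$samples[first], function(s) s$metadata)
}

## Precise-BN: after the final epoch the batch-norm running statistics are
## re-estimated with one exact-averaging pass over the training set (dropout
## off, parameters fixed). The EMA collected during training lags the final
## weights, which systematically shifts inference-time logits.
recalibrate_bn <- function(model, xy, bs) {
  if (length(model$state) == 0) return(model)
  drop_saved <- model$config$meta_dropout
  model$config$meta_dropout <- 0
  n <- length(xy$y)
  i <- 0L
  for (start in seq(1L, n, by = bs)) {
    ii <- start:min(start + bs - 1L, n)
    if (length(ii) < 2L) next
    i <- i + 1L
    fb <- feats_rows(xy$feats, ii)
    mb <- if (is.null(xy$meta_X)) NULL else xy$meta_X[ii, , drop = FALSE]
    fwd <- model_forward(model, fb, mb, length(ii), mode = "train",
                         bn_momentum = 1 / i)
    model$state <- fwd$state
  }
  model$config$meta_dropout <- drop_saved
  model
}

#' Train a prognosis model
#'
#' Minimises cross-entropy with Adam at `config$learning_rate` for
#' `config$epochs` epochs (batch `config$batch_size`, reshuffled each epoch,
#' no early stopping). Metadata standardisation statistics are fitted on the
#' training split only. Deterministic for a fixed `(config, seed)` on one
#' machine. Errors if any patient appears in both splits.
#'
#' @param config from [sf_config()].
#' @param train_set,val_set `"sf_cohort"` objects with disjoint patients;
#'   `val_set` may be `NULL`.
#' @param seed training seed (parameter init, shuffling, dropout).
#' @param feats,val_feats optional precomputed backbone features for the two
#'   cohorts (frozen backbone, so they are reusable across seeds and arms).
#' @param verbose print per-epoch loss.
#' @return An `"sf_fit"`: `model`, `history` (per-epoch mean training loss),
#'   and `val` (an [evaluate_model()] report, if `val_set` was given).
#' @export
train_model <- function(config, train_set, val_set = NULL,
                        seed = config$seed %||% 1L,
                        feats = NULL, val_feats = NULL, verbose = FALSE) {
  if (!is.null(val_set))
    check_patient_disjoint(cohort_slice_patients(train_set),
                           cohort_slice_patients(val_set))
  model <- sf_model(config, seed)
  stats <- fit_metadata_stats(patient_records(train_set))
  model$meta_stats <- stats
  xy <- prepare_xy(model, train_set, feats, stats)
  n <- length(xy$y)
  bs <- min(config$batch_size, n)

  theta <- flatten_params(model$params)
  ad <- adam_init(length(theta))
  history <- numeric(config$epochs)
  set.seed(derive_seed(seed, 424242))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      ii <- ord[start:min(start + bs - 1L, n)]
      B <- length(ii)
      fb <- feats_rows(xy$feats, ii)
      mb <- if (is.null(xy$meta_X)) NULL else xy$meta_X[ii, , drop = FALSE]
      fwd <- model_forward(model, fb, mb, B, mode = "train")
      model$state <- fwd$state
      ce <- softmax_ce(fwd$logits, xy$y[ii])
      losses <- c(losses, ce$loss)
      bwd <- model_backward(model, fwd$cache, ce$dlogits)
      st <- adam_step(theta, flatten_params(bwd$grads), ad,
                      lr = config$learning_rate)
      theta <- st$theta
      ad <- st$state
      model$params <- unflatten_params(theta, model$params)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, history[ep]))
  }
  model <- recalibrate_bn(model, xy, bs)
  val <- if (!is.null(val_set))
    evaluate_model(model, val_set, feats = val_feats) else NULL
  structure(list(model = model, history = history, val = val,
                 config = config, seed = seed),
            class = "sf_fit")
}

#' Evaluate a trained model on a cohort
#'
#' Slice-level poor-prognosis probabilities are averaged per patient; the
#' patient is predicted poor when the mean probability reaches the decision
#' threshold (ties predict positive). Reports confusion counts, the metric
#' suite and AUC at both slice and patient level.
#'
#' @param model a trained `"sf_model"` (from [train_model()]).
#' @param cohort an `"sf_cohort"`.
#' @param feats optional precomputed backbone features.
#' @return list with `patient` / `slice` metric reports (+`auc`), the
#'   patient-level score table and slice probabilities.
#' @export
evaluate_model <- function(model, cohort, feats = NULL) {
  xy <- prepare_xy(model, cohort, feats, model$meta_stats)
  probs <- model_predict_feats(model, xy$feats, xy$meta_X)
  th <- model$config$threshold %||% 0.5
  slice_pred <- as.integer(probs >= th)
  slice_rep <- compute_metrics(confusion_counts(xy$y, slice_pred))
  agg <- stats::aggregate(probs, by = list(patient_id = xy$pids), FUN = mean)
  names(agg)[2] <- "prob_poor"
  lab <- stats::aggregate(xy$y, by = list(patient_id = xy$pids), FUN = max)
  stopifnot(identical(agg$patient_id, lab$patient_id))
  agg$label <- lab$x
  agg$pred <- as.integer(agg$prob_poor >= th)
  pat_rep <- compute_metrics(confusion_counts(agg$label, agg$pred))
  pat_auc <- if (length(unique(agg$label)) == 2)
    roc_auc(agg$prob_poor, agg$label) else NA_real_
  slice_auc <- if (length(unique(xy$y)) == 2) roc_auc(probs, xy$y) else NA_real_
  list(patient = pat_rep, patient_auc = pat_auc,
       slice = slice_rep, slice_auc = slice_auc,
       patients = agg, slice_probs = probs)
}

#' Stratified patient-level fold assignment
#'
#' Depends only on `(patient_ids, labels, k, seed)`: patients are shuffled
#' within class and dealt round-robin.
#'
#' @param patient_ids character vector (unique).
#' @param labels patient labels (0/1).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..k) per patient.
#' @export
fold_assignment <- function(patient_ids, labels, k, seed = 1) {
  stopifnot(length(patient_ids) == length(labels), !anyDuplicated(patient_ids))
  fold <- integer(length(patient_ids))
  with_seed(seed, for (cl in c(0, 1)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stopf("class %d has %d patients, fewer than k = %d folds",
            cl, length(idx), k)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' k-fold patient-level cross-validation
#'
#' Folds partition patients (never slices). Each fold is evaluated at patient
#' level; the report carries per-fold metrics plus their mean and standard
#' deviation.
#'
#' @param config from [sf_config()].
#' @param cohort an `"sf_cohort"`.
#' @param k number of folds (default 5).
#' @param seed seed for fold assignment and training.
#' @return An `"sf_cv"` list: `folds` (per-fold data frame), `mean`, `sd`,
#'   `assignment`.
#' @export
cross_validate <- function(config, cohort, k = 5, seed = 1) {
  pat <- cohort$patients
  fold <- fold_assignment(pat$patient_id, pat$label, k, seed)
  model0 <- sf_model(config, seed)
  images <- lapply(cohort$samples, function(s) s$image$pixels)
  feats <- backbone_features(model0$backbone, images)
  pids <- cohort_slice_patients(cohort)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te_ids <- pat$patient_id[fold == f]
    tr_ids <- pat$patient_id[fold != f]
    tr <- cohort_subset(cohort, tr_ids)
    te <- cohort_subset(cohort, te_ids)
    if (length(unique(te$patients$label)) < 2)
      stopf("fold %d test set lacks a class; use fewer folds", f)
    fit <- train_model(config, tr, seed = derive_seed(seed, f),
                       feats = feats_rows(feats, which(pids %in% tr_ids)))
    ev <- evaluate_model(fit$model, te,
                         feats = feats_rows(feats, which(pids %in% te_ids)))
    rows[[f]] <- data.frame(fold = f,
                            accuracy = ev$patient$accuracy,
                            precision = ev$patient$precision,
                            sensitivity = ev$patient$sensitivity,
                            specificity = ev$patient$specificity,
                            f1 = ev$patient$f1,
                            auc = ev$patient_auc)
  }
  folds <- do.call(rbind, rows)
  m <- colMeans(folds[, -1], na.rm = TRUE)
  s <- apply(folds[, -1], 2, stats::sd, na.rm = TRUE)
  structure(list(folds = folds, mean = m, sd = s, assignment = fold, k = k,
                 seed = seed),
            class = "sf_cv")
}

#' Ablation harness
#'
#' Trains and evaluates the nested configurations of the component ablation
#' (arm 1: single-scale baseline; arm 2: + multi-scale; arm 3: + GLAM;
#' arm 4: + metadata MLP with CMAM fusion) on identical patient-level splits
#' and seeds, and reports per-arm mean and standard deviation over seeds.
#'
#' @param cohort an `"sf_cohort"`.
#' @param base_config from [sf_config()]; arm flags are overridden per arm.
#' @param seeds integer vector of training seeds.
#' @param arms subset of `1:4`.
#' @param test_frac held-out patient fraction per seed's split.
#' @return An `"sf_ablation"` list: `runs` (arm x seed data frame), `summary`
#'   (per-arm mean +/- sd), `flags`.
#' @export
run_ablation <- function(cohort, base_config = sf_config("desk"),
                         seeds = 1:3, arms = 1:4, test_frac = 0.2) {
  if (4 %in% arms && is.null(cohort$samples[[1]]$metadata))
    stopf("arm 4 needs cohort metadata")
  backbone <- backbone_init(base_config)
  images <- lapply(cohort$samples, function(s) s$image$pixels)
  feats <- backbone_features(backbone, images)
  pids <- cohort_slice_patients(cohort)
  runs <- list()
  for (sd_i in seeds) {
    split <- split_cohort(cohort, test_frac, seed = derive_seed(sd_i, 555))
    tr_ids <- split$patients$patient_id[split$patients$split == "train"]
    te_ids <- split$patients$patient_id[split$patients$split == "test"]
    tr <- cohort_subset(cohort, tr_ids)
    te <- cohort_subset(cohort, te_ids)
    f_tr <- feats_rows(feats, which(pids %in% tr_ids))
    f_te <- feats_rows(feats, which(pids %in% te_ids))
    for (arm in arms) {
      cfg <- base_config
      cfg$arms <- arm_flags(arm)
      fit <- train_model(cfg, tr, seed = sd_i, feats = f_tr)
      ev <- evaluate_model(fit$model, te, feats = f_te)
      runs[[length(runs) + 1L]] <- data.frame(
        arm = arm, seed = sd_i,
        ms = cfg$arms$ms, glam = cfg$arms$glam, mlp = cfg$arms$mlp,
        accuracy = ev$patient$accuracy, precision = ev$patient$precision,
        sensitivity = ev$patient$sensitivity, f1 = ev$patient$f1,
        auc = ev$patient_auc, n_params = model_n_params(fit$model))
    }
  }
  runs <- do.call(rbind, runs)
  metric_cols <- c("accuracy", "precision", "sensitivity", "f1", "auc")
  summ <- do.call(rbind, lapply(sort(unique(runs$arm)), function(a) {
    sub <- runs[runs$arm == a, ]
    data.frame(arm = a, ms = sub$ms[1], glam = sub$glam[1], mlp = sub$mlp[1],
               t(colMeans(sub[metric_cols], na.rm = TRUE)),
               sd_accuracy = stats::sd(sub$accuracy),
               n_params = sub$n_params[1])
  }))
  structure(list(runs = runs, summary = summ, seeds = seeds, arms = arms),
            class = "sf_ablation")
}
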