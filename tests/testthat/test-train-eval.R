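test_that("confusion_counts tallies with positive = poor prognosis", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(c1)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L), ignore_attr = TRUE)
  c2 <- confusion_counts(c(1, 1, 1, 0, 0, 0, 0, 1, 1, 0),
                         c(1, 1, 0, 1, 0, 0, 0, 0, 1, 0))
  expect_equal(c2$TP, 3); expect_equal(c2$FN, 2)
  expect_equal(c2$FP, 1); expect_equal(c2$TN, 4)
  c3 <- confusion_counts(rep(0, 5), rep(1, 5))
  expect_equal(c3$FP, 5); expect_equal(c3$TP + c3$TN + c3$FN, 0)
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
  expect_error(confusion_counts(c(0, 1), c(1)), "lengths differ")
})

test_that("compute_metrics evaluates the metric formulas and flags zero denominators", {
  r <- compute_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(r$accuracy, 0.7)
  expect_equal(r$precision, 0.75)
  expect_equal(r$sensitivity, 0.6)
  expect_equal(r$specificity, 0.8)
  expect_equal(r$f1, 2 * 0.75 * 0.6 / 1.35)

  perf <- compute_metrics(list(TP = 5, FP = 0, TN = 7, FN = 0))
  expect_true(all(unlist(perf[c("accuracy", "precision", "sensitivity",
                                "specificity", "f1")]) == 1))

  und <- compute_metrics(list(TP = 0, FP = 0, TN = 4, FN = 2))
  expect_true(is.na(und$precision))
  expect_true("precision" %in% und$undefined)
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("compute_metrics agrees with an independent counting oracle", {
  withr::with_seed(17, {
    for (i in 1:200) {
      n <- sample(5:40, 1)
      y <- rbinom(n, 1, 0.5); p <- rbinom(n, 1, 0.5)
      cc <- confusion_counts(y, p)
      r <- compute_metrics(cc)
      o <- oracle_metrics(y, p)
      expect_identical(cc$TP, o$TP); expect_identical(cc$FP, o$FP)
      expect_identical(cc$TN, o$TN); expect_identical(cc$FN, o$FN)
      expect_equal(r$accuracy, o$accuracy)
      expect_equal(r$precision, o$precision)
      expect_equal(r$sensitivity, o$sensitivity)
      expect_equal(r$specificity, o$specificity)
    }
  })
})

test_that("roc_auc: limits, pairwise oracle, monotone invariance", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  withr::with_seed(23, {
    s <- c(rnorm(25), rnorm(25, 1))
    s[sample(50, 6)] <- s[1]                    # inject ties
    y <- rep(c(0, 1), each = 25)
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(exp(2 * s) + 3, y), roc_auc(s, y), tolerance = 1e-12)
  })
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("training contract: smoke, determinism, monotone toy, leakage guard", {
  co <- split_cohort(tiny_cohort(), 0.25, seed = 5)
  tr_ids <- co$patients$patient_id[co$patients$split == "train"]
  te_ids <- co$patients$patient_id[co$patients$split == "test"]
  tr <- cohort_subset(co, tr_ids); te <- cohort_subset(co, te_ids)

  cfg <- tiny_config(epochs = 1L)
  fit <- train_model(cfg, tr, val_set = te, seed = 2)
  expect_length(fit$history, 1L)
  expect_true(is.finite(fit$history))
  expect_true(is.finite(fit$val$patient$accuracy))

  ## same (config, seed) twice -> identical validation accuracy
  fit2 <- train_model(cfg, tr, val_set = te, seed = 2)
  expect_identical(fit$val$patient$accuracy, fit2$val$patient$accuracy)
  expect_identical(fit$history, fit2$history)

  ## patient overlap between splits is an error naming the patient
  expect_error(train_model(cfg, tr, val_set = cohort_subset(co, tr_ids[1])),
               tr_ids[1], fixed = TRUE)

  ## reduced to the classifier head on separable 2-feature data the epoch
  ## losses decrease monotonically (convex logistic objective)
  withr::with_seed(31, {
    X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
    y <- rep(c(0L, 1L), each = 20)
    head <- list(W = matrix(0, 2, 2), b = numeric(2))
    theta <- sf_ns$flatten_params(head)
    ad <- sf_ns$adam_init(length(theta))
    losses <- numeric(20)
    for (ep in 1:20) {
      head <- sf_ns$unflatten_params(theta, head)
      d <- sf_ns$dense_fwd(X, head$W, head$b)
      ce <- sf_ns$softmax_ce(d$Y, y)
      losses[ep] <- ce$loss
      bk <- sf_ns$dense_bwd(ce$dlogits, d, head$W)
      st <- sf_ns$adam_step(theta, sf_ns$flatten_params(list(W = bk$dW, b = bk$db)),
                            ad, lr = 0.05)
      theta <- st$theta; ad <- st$state
    }
    expect_true(all(diff(losses) < 1e-8))
  })
})

test_that("fold assignment partitions patients, stratified and seed-stable", {
  ids <- sprintf("P%03d", 1:100)
  labs <- rep(c(0, 1), 50)
  f <- fold_assignment(ids, labs, k = 5, seed = 9)
  expect_true(all(table(f) == 20))
  expect_true(all(table(f[labs == 1]) == 10))   # stratified
  expect_identical(f, fold_assignment(ids, labs, k = 5, seed = 9))
  expect_false(identical(f, fold_assignment(ids, labs, k = 5, seed = 10)))
  expect_error(fold_assignment(ids[1:6], c(1, 1, 1, 1, 1, 0), k = 5), "fewer")
})

test_that("cross_validate partitions patients and reports mean/sd correctly", {
  co <- tiny_cohort()
  cv <- cross_validate(tiny_config(epochs = 1L), co, k = 4, seed = 3)
  expect_equal(nrow(cv$folds), 4L)
  ## every patient in exactly one test fold
  expect_true(all(table(cv$assignment) >= 4))
  expect_length(cv$assignment, nrow(co$patients))
  ## mean/sd match direct recomputation from the per-fold table
  expect_equal(unname(cv$mean["accuracy"]), mean(cv$folds$accuracy))
  expect_equal(unname(cv$sd["accuracy"]), sd(cv$folds$accuracy))
})

test_that("run_ablation emits the four nested arms with growing capacity", {
  co <- tiny_cohort()
  ab <- run_ablation(co, tiny_config(epochs = 1L), seeds = 1, arms = 1:4,
                     test_frac = 0.25)
  expect_equal(nrow(ab$summary), 4L)
  expect_equal(ab$summary$arm, 1:4)
  flags <- ab$summary[, c("ms", "glam", "mlp")]
  expect_equal(unname(as.matrix(flags)),
               matrix(c(FALSE, FALSE, FALSE,
                        TRUE, FALSE, FALSE,
                        TRUE, TRUE, FALSE,
                        TRUE, TRUE, TRUE), 4, 3, byrow = TRUE))
  np <- ab$summary$n_params
  expect_true(np[4] > np[1])
  expect_true(all(diff(np) > 0))                # nested arms add parameters
  expect_true(all(is.finite(ab$runs$accuracy)))
})
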