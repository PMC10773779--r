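test_that("concat_features is ordered, additive, and degenerate-safe", {
  f1 <- withr::with_seed(1, runif(768))
  f2 <- withr::with_seed(2, runif(256))
  joint <- concat_features(f1, f2)
  expect_length(joint, 1024L)
  expect_identical(joint[1:768], f1)
  expect_identical(joint[769:1024], f2)
  expect_identical(concat_features(f1), f1)      # image-only ablation
})

test_that("attention_mask: zero-weight limit, shape, manual forward oracle", {
  cm <- cmam_params(8, seed = 3)
  cm0 <- cm
  cm0$params <- sf_ns$zero_like(cm0$params)
  m <- attention_mask(withr::with_seed(4, rnorm(8)), cmam = cm0)
  expect_equal(m, rep(0.5, 8))                   # sigmoid(0) everywhere

  x <- withr::with_seed(5, rnorm(8))
  m2 <- attention_mask(x, cmam = cm)
  expect_length(m2, 8L)
  expect_true(all(m2 > 0 & m2 < 1))

  ## 4-dim hand-set weights, batch of 3 in train mode: explicit arithmetic
  ## through FC -> BN(batch stats) -> ReLU -> FC -> sigmoid
  cm4 <- cmam_params(4, bottleneck = 2, seed = 1)
  W1 <- matrix(c(0.5, -1, 0.2, 0.3, 1, 0.1, -0.4, 0.7), 4, 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(0.3, -0.6, 1.2, 0.05, -0.9, 0.4, 0.2, 0.8), 2, 4)
  b2 <- c(0, 0.1, -0.1, 0.2)
  cm4$params$W1 <- W1; cm4$params$b1 <- b1
  cm4$params$W2 <- W2; cm4$params$b2 <- b2
  X <- matrix(c(1, 0, -1, 2, 0.5, 1, -0.5, 0, 1.5, -1, 0.2, 0.4), 3, 4,
              byrow = TRUE)
  got <- attention_mask(X, cmam = cm4, mode = "train")
  Z1 <- sweep(X %*% W1, 2, b1, "+")
  mu <- colMeans(Z1); va <- colMeans(sweep(Z1, 2, mu)^2)
  Zh <- sweep(sweep(Z1, 2, mu), 2, sqrt(va + 1e-5), "/")
  A_manual <- 1 / (1 + exp(-(sweep(pmax(Zh, 0) %*% W2, 2, b2, "+"))))
  expect_equal(got, A_manual, tolerance = 1e-10)
})

test_that("apply_mask is the elementwise product", {
  joint <- withr::with_seed(6, rnorm(16))
  mask <- withr::with_seed(7, runif(16))
  gated <- apply_mask(mask, joint)
  for (i in 1:16) expect_equal(gated[i], mask[i] * joint[i])
  expect_equal(apply_mask(rep(0.5, 16), joint), joint / 2)
  sat <- 1 / (1 + exp(-50))                       # saturated logit
  expect_lt(max(abs(apply_mask(rep(sat, 16), joint) - joint)), 1e-3)
  expect_error(apply_mask(runif(4), joint), "length")
})

test_that("classify: tie-break, saturation, softmax normalisation", {
  head0 <- list(W = matrix(0, 4, 2), b = c(0, 0))
  p <- classify(rep(1, 4), head = head0)
  expect_equal(p$prob_poor, 0.5)
  expect_identical(p$label_hat, 1L)              # tie predicts poor prognosis

  head_sat <- list(W = matrix(0, 4, 2), b = c(-10, 10))
  expect_gt(classify(rep(1, 4), head = head_sat)$prob_poor, 0.999)

  Z <- withr::with_seed(8, matrix(rnorm(2000), 1000, 2))
  P <- sf_ns$softmax_rows(Z)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
})

test_that("Fo = A o F holds on full forward passes; disabling the gate yields plain concat", {
  cfg <- tiny_config(meta_dropout = 0)
  model <- sf_model(cfg, seed = 11)
  B <- 4L
  imgs <- withr::with_seed(3, lapply(1:B, function(i) matrix(runif(32 * 32), 32, 32)))
  feats <- sf_ns$backbone_features(model$backbone, imgs)
  fb <- sf_ns$feats_rows(feats, 1:B)
  mx <- withr::with_seed(4, matrix(rnorm(B * 22), B))
  for (mode in c("train", "infer")) {
    fwd <- sf_ns$model_forward(model, fb, mx, B, mode = mode)
    expect_identical(fwd$cache$G, fwd$cache$A * fwd$cache$FJ)
    expect_true(all(fwd$cache$A > 0 & fwd$cache$A < 1))
  }
  ## inference determinism
  l1 <- sf_ns$model_forward(model, fb, mx, B, mode = "infer")$logits
  l2 <- sf_ns$model_forward(model, fb, mx, B, mode = "infer")$logits
  expect_identical(l1, l2)

  cfg_ng <- tiny_config(meta_dropout = 0, cmam = list(gate = FALSE))
  m2 <- sf_model(cfg_ng, seed = 11)
  fwd2 <- sf_ns$model_forward(m2, fb, mx, B, mode = "infer")
  expect_identical(fwd2$cache$G, fwd2$cache$FJ)  # ungated concatenation fusion
})
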