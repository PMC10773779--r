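test_that("patchify produces L = HW/P^2 tokens and validates divisibility", {
  f <- rand_feature(1, 224, 224, seed = 1)
  ps <- patchify(f, patch_size = 16, embed_dim = 8)
  expect_equal(ncol(ps$tokens), 196L)          # 224*224/16^2
  expect_equal(nrow(ps$tokens), 8L)

  f1 <- rand_feature(2, 4, 4, seed = 2)
  expect_equal(ncol(patchify(f1, 4, 6)$tokens), 1L)   # H = W = P -> one patch

  expect_error(patchify(rand_feature(1, 6, 4, 3), 4, 8), "height 6")
  expect_error(patchify(rand_feature(1, 4, 6, 3), 4, 8), "width 6")
})

test_that("identity patch embedding reproduces the flattened patch", {
  f <- array(c(1, 2, 3, 4), dim = c(1, 2, 2))   # f[1,h,w]
  par <- patchify_params(1, 2, 4, L = 1, seed = 1)
  par$We <- diag(4); par$be <- numeric(4); par$pos[] <- 0
  ps <- patchify(f, 2, 4, params = par)
  ## within-patch order is column-major: (1,1),(2,1),(1,2),(2,2)
  expect_equal(as.vector(ps$tokens), c(f[1, 1, 1], f[1, 2, 1], f[1, 1, 2], f[1, 2, 2]))
})

test_that("patchify/unpatchify round-trips under identity embeddings", {
  C <- 2L; H <- 4L; W <- 4L; P <- 2L; D <- P^2 * C
  f <- rand_feature(C, H, W, seed = 9)
  pe <- patchify_params(C, P, D, L = 4, seed = 1)
  pe$We <- diag(D); pe$be <- numeric(D); pe$pos[] <- 0
  ue <- list(Wu = diag(D), bu = numeric(D))
  ps <- patchify(f, P, D, params = pe)
  back <- unpatchify(ps, C, params = ue)
  expect_equal(back, f, tolerance = 1e-12)
})

test_that("global attention block: identity limit, shape, manual oracle", {
  D <- 4L; L <- 6L
  x <- withr::with_seed(3, matrix(rnorm(D * L), D, L))
  par <- gab_params(D, heads = 2, mlp_hidden = 8, seed = 2)

  ## zeroed sublayer output projections -> exact identity
  par0 <- par
  par0$attn$Wo[] <- 0; par0$attn$bo[] <- 0
  par0$mlp$W2[] <- 0; par0$mlp$b2[] <- 0
  expect_equal(global_attention_block(x, params = par0, heads = 2), x,
               tolerance = 1e-14)

  ## shape contract
  y <- global_attention_block(x, params = par, heads = 2)
  expect_equal(dim(y), dim(x))

  ## single-head from-scratch oracle (explicit loops, pre-norm wiring)
  D2 <- 2L; L2 <- 2L
  xt <- matrix(c(0.5, -1, 2, 0.3), D2, L2)
  p2 <- gab_params(D2, heads = 1, mlp_hidden = 3, seed = 5)
  manual_ln <- function(M, g, b) {      # per token (row), explicit arithmetic
    xh <- t(apply(M, 1, function(v) {
      mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-5)
      (v - mu) / s
    }))
    sweep(sweep(xh, 2, g, "*"), 2, b, "+")
  }
  Xc <- t(xt)                            # tokens as rows
  ln1 <- manual_ln(Xc, p2$ln1$g, p2$ln1$b)
  Q <- ln1 %*% p2$attn$Wq + matrix(p2$attn$bq, 2, 2, byrow = TRUE)
  K <- ln1 %*% p2$attn$Wk + matrix(p2$attn$bk, 2, 2, byrow = TRUE)
  V <- ln1 %*% p2$attn$Wv + matrix(p2$attn$bv, 2, 2, byrow = TRUE)
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  O <- A %*% V %*% p2$attn$Wo + matrix(p2$attn$bo, 2, 2, byrow = TRUE)
  X1 <- Xc + O
  ln2 <- manual_ln(X1, p2$ln2$g, p2$ln2$b)
  Hh <- pmax(ln2 %*% p2$mlp$W1 + matrix(p2$mlp$b1, 2, 3, byrow = TRUE), 0)
  Fg <- X1 + Hh %*% p2$mlp$W2 + matrix(p2$mlp$b2, 2, 2, byrow = TRUE)
  got <- global_attention_block(xt, params = p2, heads = 1)
  expect_equal(got, t(Fg), tolerance = 1e-10)
})

test_that("local attention block: masks, saturation limit, loop oracle", {
  C <- 3L; H <- 4L; W <- 4L
  f <- rand_feature(C, H, W, seed = 21)
  par <- lab_params(C, reduction = 2, seed = 3)

  ## saturated logits push both masks to ~1, so Fl ~ F
  psat <- par
  psat$bc2[] <- 50; psat$bs <- 50
  out_sat <- local_attention_block(f, params = psat)
  expect_lt(max(abs(out_sat$feature_map - f)), 1e-3)

  ## masks strictly inside (0,1) across random inputs
  for (i in 1:100) {
    o <- local_attention_block(rand_feature(2, 4, 4, seed = 100 + i),
                               params = lab_params(2, 2, seed = i))
    expect_true(all(o$attention$channel_mask > 0 & o$attention$channel_mask < 1))
    expect_true(all(o$attention$spatial_mask > 0 & o$attention$spatial_mask < 1))
  }

  ## Fl equals Atts * Attc * F elementwise (explicit triple loop)
  out <- local_attention_block(f, params = par)
  for (c in 1:C) for (h in 1:H) for (w in 1:W)
    expect_equal(out$feature_map[c, h, w],
                 out$attention$spatial_mask[1, h, w] *
                   out$attention$channel_mask[c, 1, 1] * f[c, h, w],
                 tolerance = 1e-12)
})

test_that("glam fuses branches by residual sum + 1x1 projection", {
  C <- 2L; H <- 4L; W <- 4L
  f <- rand_feature(C, H, W, seed = 31)
  par <- glam_params(C, H, W, patch_size = 2, embed_dim = 4, heads = 2,
                     mlp_hidden = 8, reduction = 2, seed = 6)
  out <- glam(f, params = par, patch_size = 2, embed_dim = 4, heads = 2)

  ## shape contract
  expect_identical(dim(out$joint_feature), dim(f))

  ## declared fusion rule, by explicit arithmetic on the returned branches
  G <- sf_ns$feature_to_mat(out$global_map)
  Lf <- sf_ns$feature_to_mat(out$local_feature)
  joint_manual <- sf_ns$feature_to_mat(f) +
    ((G + Lf) %*% par$fuse$Wf + matrix(par$fuse$bf, H * W, C, byrow = TRUE))
  expect_equal(sf_ns$feature_to_mat(out$joint_feature), joint_manual,
               tolerance = 1e-12)

  ## zeroed global pathway: joint reduces to the local contribution
  par0 <- par
  par0$unpatch$Wu[] <- 0; par0$unpatch$bu[] <- 0
  out0 <- glam(f, params = par0, patch_size = 2, embed_dim = 4, heads = 2)
  expect_true(all(out0$global_map == 0))
  joint0 <- sf_ns$feature_to_mat(f) +
    (sf_ns$feature_to_mat(out0$local_feature) %*% par$fuse$Wf +
       matrix(par$fuse$bf, H * W, C, byrow = TRUE))
  expect_equal(sf_ns$feature_to_mat(out0$joint_feature), joint0,
               tolerance = 1e-12)
})

test_that("multiscale_forward: determinism, F1 length, GAP oracle, finiteness", {
  cfg <- tiny_config()
  model <- sf_model(cfg, seed = 3)
  img <- withr::with_seed(8, matrix(runif(32 * 32), 32, 32))
  f1a <- multiscale_forward(img, model = model)
  f1b <- multiscale_forward(img, model = model)
  expect_identical(f1a, f1b)
  expect_length(f1a, sum(cfg$backbone$stage_channels[3:5]))

  ## construction-time resolution check
  expect_error(sf_model(tiny_config(image_size = 48)), "divisible")

  ## with MS and GLAM disabled F1 is the GAP of the deepest stage
  cfg1 <- tiny_config(arms = list(ms = FALSE, glam = FALSE, mlp = FALSE))
  m1 <- sf_model(cfg1, seed = 3)
  f1 <- multiscale_forward(img, model = m1)
  taps <- sf_ns$backbone_forward_one(m1$backbone, img)
  expect_equal(f1, colMeans(taps$s5), tolerance = 1e-12)
  expect_length(f1, cfg$backbone$stage_channels[5])

  ## finite output across sizes and seeds
  for (sz in c(32, 64)) {
    cfgs <- tiny_config(image_size = sz)
    ms <- sf_model(cfgs, seed = 1)
    for (i in 1:4) {
      x <- withr::with_seed(i, matrix(runif(sz * sz), sz, sz))
      expect_true(all(is.finite(multiscale_forward(x, model = ms))))
    }
  }
  cfg224 <- tiny_config(image_size = 224)
  m224 <- sf_model(cfg224, seed = 1)
  x224 <- withr::with_seed(99, matrix(runif(224 * 224), 224, 224))
  expect_true(all(is.finite(multiscale_forward(x224, model = m224))))
})
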