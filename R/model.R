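## Full network assembly: frozen backbone taps -> (optional top-down
## multi-scale fusion) -> (optional GLAM at each scale) -> global average
## pooling into F1 -> (optional metadata encoder F2 + CMAM gate) -> linear
## classifier. Ablation arms toggle the ms / glam / mlp flags.

#' Build a prognosis model
#'
#' @param config from [sf_config()]; `config$arms` selects the ablation arm.
#' @param seed seed for trainable-parameter initialisation (the frozen
#'   backbone uses `config$backbone$seed` so its features are shared across
#'   training seeds and arms).
#' @return An `"sf_model"`.
#' @export
sf_model <- function(config = sf_config("desk"), seed = config$seed %||% 1L) {
  P <- config$glam$patch_size
  if (config$image_size %% (16L * P) != 0)
    stopf("image_size %d must be divisible by coarsest stride x patch size = %d",
          config$image_size, 16L * P)
  backbone <- backbone_init(config)
  dims <- backbone_tap_dims(config$image_size, backbone$channels)
  arms <- config$arms
  g <- config$glam
  idx <- list()
  for (nm in c("s3", "s4", "s5")) {
    idx[[paste0("pidx_", nm)]] <- patch_idx_mat(dims[[nm]]$H, dims[[nm]]$W, P)
    idx[[paste0("idx7_", nm)]] <- conv_gather_idx(dims[[nm]]$H, dims[[nm]]$W, 7L)
  }
  idx$up5 <- upsample2_parent_idx(dims$s5$H, dims$s5$W)   # j5 -> s4 grid
  idx$up4 <- upsample2_parent_idx(dims$s4$H, dims$s4$W)   # j4 -> s3 grid

  params <- list()
  state <- list()
  sdd <- function(k) derive_seed(seed, k)
  mk_glam <- function(nm, k)
    glam_params(dims[[nm]]$C, dims[[nm]]$H, dims[[nm]]$W, P, g$embed_dim,
                g$heads, g$mlp_hidden, g$reduction, sdd(k))
  if (arms$glam) params$glam5 <- mk_glam("s5", 5)
  if (arms$ms) {
    if (arms$glam) {
      params$glam4 <- mk_glam("s4", 4)
      params$glam3 <- mk_glam("s3", 3)
    }
    params$td4 <- with_seed(sdd(14), list(W = xavier_mat(dims$s5$C, dims$s4$C),
                                          b = numeric(dims$s4$C)))
    params$td3 <- with_seed(sdd(13), list(W = xavier_mat(dims$s4$C, dims$s3$C),
                                          b = numeric(dims$s3$C)))
  }
  nF1 <- if (arms$ms) dims$s3$C + dims$s4$C + dims$s5$C else dims$s5$C
  nF <- nF1
  if (arms$mlp) {
    enc <- metadata_encoder(metadata_vector_length(), config$meta_width,
                            config$meta_dropout, sdd(21))
    params$meta <- enc$params
    state$meta <- enc$state
    nF <- nF1 + config$meta_width
    if (config$cmam$gate) {
      cm <- cmam_params(nF, max(1L, nF %/% config$cmam$bottleneck_ratio), sdd(22))
      params$cmam <- cm$params
      state$cmam <- cm$state
    }
  }
  params$head <- with_seed(sdd(30), list(W = xavier_mat(nF, 2L), b = numeric(2)))

  structure(list(config = config, arms = arms, backbone = backbone,
                 dims = dims, idx = idx, params = params, state = state,
                 nF1 = nF1, nF = nF, seed = seed,
                 meta_stats = NULL),
            class = "sf_model")
}

#' @export
print.sf_model <- function(x, ...) {
  cat(sprintf(
    "sf_model (%s profile): arms MS=%s GLAM=%s MLP=%s; F1=%d, F=%d, %d trainable params\n",
    x$config$profile, x$arms$ms, x$arms$glam, x$arms$mlp, x$nF1, x$nF,
    n_params(x$params)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `"sf_model"`.
#' @return integer count.
#' @export
model_n_params <- function(model) n_params(model$params)

#' Valid Grad-CAM target layers
#' @param model an `"sf_model"`.
#' @return character vector, finest scale first (deepest last).
#' @export
gradcam_layers <- function(model) {
  if (model$arms$ms) c("joint3", "joint4", "joint5") else "joint5"
}

## Extract the rows of cached backbone features for a set of slice indices.
feats_rows <- function(feats, idx) {
  dims <- feats$dims
  out <- list(dims = dims, n = length(idx))
  for (nm in c("s3", "s4", "s5")) {
    S <- dims[[nm]]$S
    rows <- rep((idx - 1L) * S, each = S) + rep(seq_len(S), length(idx))
    out[[nm]] <- feats[[nm]][rows, , drop = FALSE]
  }
  out
}

## Forward pass over a batch. feats: tap matrices for B samples; meta_X:
## B x 22 metadata matrix (NULL unless the mlp arm is on).
model_forward <- function(model, feats, meta_X, B, mode = "infer",
                          f1_only = FALSE, bn_momentum = 0.1) {
  arms <- model$arms; par <- model$params; dims <- model$dims
  P <- model$config$glam$patch_size; nh <- model$config$glam$heads
  idx <- model$idx
  cache <- list(B = B)
  state <- model$state

  run_scale <- function(nm, X, pkey) {
    d <- dims[[nm]]
    if (arms$glam) {
      gc <- glam_fwd(X, par[[pkey]], B, d$C, d$H, d$W, P, nh,
                     idx[[paste0("pidx_", nm)]], idx[[paste0("idx7_", nm)]])
      list(J = gc$Y, cache = gc)
    } else list(J = X, cache = NULL)
  }

  s5 <- run_scale("s5", feats$s5, "glam5")
  cache$g5 <- s5$cache
  j5 <- s5$J
  if (arms$ms) {
    u4 <- upsample2_fwd(j5, dims$s5$H, dims$s5$W, B, idx$up5)
    t4 <- dense_fwd(u4, par$td4$W, par$td4$b)
    x4 <- feats$s4 + t4$Y
    s4 <- run_scale("s4", x4, "glam4")
    j4 <- s4$J
    u3 <- upsample2_fwd(j4, dims$s4$H, dims$s4$W, B, idx$up4)
    t3 <- dense_fwd(u3, par$td3$W, par$td3$b)
    x3 <- feats$s3 + t3$Y
    s3 <- run_scale("s3", x3, "glam3")
    j3 <- s3$J
    cache$t4 <- t4; cache$t3 <- t3; cache$g4 <- s4$cache; cache$g3 <- s3$cache
    F1 <- cbind(gap_fwd(j3, dims$s3$S, B), gap_fwd(j4, dims$s4$S, B),
                gap_fwd(j5, dims$s5$S, B))
    cache$joints <- list(joint3 = j3, joint4 = j4, joint5 = j5)
  } else {
    F1 <- gap_fwd(j5, dims$s5$S, B)
    cache$joints <- list(joint5 = j5)
  }
  cache$F1 <- F1
  if (f1_only) return(list(cache = cache, state = state))

  if (arms$mlp) {
    mf <- meta_fwd(par$meta, state$meta, meta_X, model$config$meta_dropout, mode,
                   bn_momentum)
    state$meta <- mf$state
    F2 <- mf$Y
    FJ <- cbind(F1, F2)
    cache$meta <- mf$cache
    if (model$config$cmam$gate) {
      cm <- cmam_fwd(par$cmam, state$cmam, FJ, mode, bn_momentum)
      state$cmam <- cm$state
      A <- cm$A
      G <- A * FJ
      cache$cmam <- cm$cache
      cache$A <- A
    } else G <- FJ
    cache$FJ <- FJ
    cache$F2 <- F2
  } else {
    FJ <- F1
    G <- F1
    cache$FJ <- FJ
  }
  hd <- dense_fwd(G, par$head$W, par$head$b)
  cache$head <- hd
  cache$G <- G
  list(logits = hd$Y, cache = cache, state = state)
}

## Backward pass; returns grads mirroring model$params plus the gradient
## flowing into each captured joint feature (for Grad-CAM).
model_backward <- function(model, cache, dlogits) {
  arms <- model$arms; par <- model$params; dims <- model$dims
  P <- model$config$glam$patch_size; nh <- model$config$glam$heads
  idx <- model$idx; B <- cache$B
  grads <- zero_like(par)
  djoints <- list()

  hb <- dense_bwd(dlogits, cache$head, par$head$W)
  grads$head$W <- hb$dW; grads$head$b <- hb$db
  dG <- hb$dX
  if (arms$mlp) {
    if (model$config$cmam$gate) {
      dA <- dG * cache$FJ
      dFJ <- dG * cache$A
      cb <- cmam_bwd(dA, cache$cmam, par$cmam)
      grads$cmam <- cb$grads
      dFJ <- dFJ + cb$dF
    } else dFJ <- dG
    dF1 <- dFJ[, seq_len(model$nF1), drop = FALSE]
    dF2 <- dFJ[, (model$nF1 + 1L):model$nF, drop = FALSE]
    mb <- meta_bwd(dF2, cache$meta, par$meta)
    grads$meta <- mb$grads
  } else dF1 <- dG

  bwd_scale <- function(nm, dJ, gcache, pkey) {
    d <- dims[[nm]]
    if (arms$glam) {
      gb <- glam_bwd(dJ, gcache, par[[pkey]], B, d$C, d$H, d$W, P, nh,
                     idx[[paste0("pidx_", nm)]], idx[[paste0("idx7_", nm)]])
      grads[[pkey]] <<- gb$grads
      gb$dX
    } else dJ
  }

  if (arms$ms) {
    c3 <- dims$s3$C; c4 <- dims$s4$C; c5 <- dims$s5$C
    dj3 <- gap_bwd(dF1[, 1:c3, drop = FALSE], dims$s3$S, B)
    dj4 <- gap_bwd(dF1[, (c3 + 1):(c3 + c4), drop = FALSE], dims$s4$S, B)
    dj5 <- gap_bwd(dF1[, (c3 + c4 + 1):(c3 + c4 + c5), drop = FALSE], dims$s5$S, B)
    djoints$joint3 <- dj3
    dx3 <- bwd_scale("s3", dj3, cache$g3, "glam3")
    t3b <- dense_bwd(dx3, cache$t3, par$td3$W)
    grads$td3$W <- t3b$dW; grads$td3$b <- t3b$db
    dj4 <- dj4 + upsample2_bwd(t3b$dX, dims$s4$H, dims$s4$W, B, idx$up4)
    djoints$joint4 <- dj4
    dx4 <- bwd_scale("s4", dj4, cache$g4, "glam4")
    t4b <- dense_bwd(dx4, cache$t4, par$td4$W)
    grads$td4$W <- t4b$dW; grads$td4$b <- t4b$db
    dj5 <- dj5 + upsample2_bwd(t4b$dX, dims$s5$H, dims$s5$W, B, idx$up5)
    djoints$joint5 <- dj5
    invisible(bwd_scale("s5", dj5, cache$g5, "glam5"))
  } else {
    dj5 <- gap_bwd(dF1, dims$s5$S, B)
    djoints$joint5 <- dj5
    invisible(bwd_scale("s5", dj5, cache$g5, "glam5"))
  }
  list(grads = grads, djoints = djoints)
}

## Slice-level poor-prognosis probabilities for cached features.
model_predict_feats <- function(model, feats, meta_X) {
  n <- feats$n
  probs <- numeric(n)
  bs <- 64L
  for (start in seq(1L, n, by = bs)) {
    ii <- start:min(start + bs - 1L, n)
    fb <- feats_rows(feats, ii)
    out <- model_forward(model, fb,
                         if (is.null(meta_X)) NULL else meta_X[ii, , drop = FALSE],
                         length(ii), mode = "infer")
    probs[ii] <- softmax_rows(out$logits)[, 2]
  }
  probs
}

#' Image-branch forward pass: image to feature vector F1
#'
#' Runs one image through the frozen backbone, applies GLAM at each active
#' scale with top-down coarse-to-fine propagation, global-average-pools each
#' scale's joint feature and concatenates them into F1. Deterministic in
#' inference mode.
#'
#' @param image an `"sf_image"`, or an H x W pixel matrix in `[0, 1]`.
#' @param model an `"sf_model"`; built from `config` if `NULL`.
#' @param config used when `model` is `NULL`.
#' @param seed parameter seed when `model` is `NULL`.
#' @return Numeric F1 vector (length = sum of active per-scale channel
#'   widths).
#' @export
multiscale_forward <- function(image, model = NULL,
                               config = sf_config("desk"), seed = 1) {
  pixels <- if (inherits(image, "sf_image")) image$pixels else image
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  if (is.null(model)) {
    config$image_size <- nrow(pixels)
    model <- sf_model(config, seed)
  }
  taps <- backbone_forward_one(model$backbone, pixels)
  feats <- c(taps, list(dims = model$dims, n = 1L))
  out <- model_forward(model, feats, NULL, 1L, mode = "infer", f1_only = TRUE)
  as.vector(out$cache$F1)
}
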