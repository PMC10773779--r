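## VGG16-style convolutional backbone. Five stages of 3x3 convolutions with
## ReLU and 2x2 max-pooling between stages; the multi-scale branch taps the
## outputs of stages 3, 4 and 5 (strides 4, 8, 16). Weights are seeded-random
## (He init) and frozen: stage features are a fixed, deterministic image
## embedding, computed once per cohort and cached, and all learning happens in
## the attention modules and heads on top. See the methods vignette for why
## this regime replaces fine-tuning at desk scale.

backbone_init <- function(cfg) {
  bb <- cfg$backbone
  chans <- bb$stage_channels
  convs <- bb$convs_per_stage
  stopifnot(length(chans) == 5, length(convs) == 5)
  with_seed(bb$seed %||% 90210L, {
    stages <- vector("list", 5)
    cin <- 3L
    for (s in 1:5) {
      layers <- vector("list", convs[s])
      for (j in seq_len(convs[s])) {
        layers[[j]] <- list(K = he_mat(9L * cin, chans[s]), b = numeric(chans[s]))
        cin <- chans[s]
      }
      stages[[s]] <- layers
    }
    structure(list(stages = stages, channels = chans,
                   image_size = cfg$image_size), class = "sf_backbone")
  })
}

## Spatial dims of the three taps for a given input size.
backbone_tap_dims <- function(image_size, channels) {
  s3 <- image_size %/% 4L; s4 <- image_size %/% 8L; s5 <- image_size %/% 16L
  list(s3 = list(C = channels[3], H = s3, W = s3, S = s3 * s3),
       s4 = list(C = channels[4], H = s4, W = s4, S = s4 * s4),
       s5 = list(C = channels[5], H = s5, W = s5, S = s5 * s5))
}

## Forward one image (H x W matrix in [0,1]) through the frozen backbone.
## Grayscale is replicated to 3 channels and centred. Returns the three tap
## feature maps as S x C matrices.
backbone_forward_one <- function(backbone, pixels) {
  n <- nrow(pixels)
  if (n != backbone$image_size)
    stopf("backbone built for %dpx input, got %dpx", backbone$image_size, n)
  x <- (as.vector(pixels) - 0.5) * 2
  X <- cbind(x, x, x)
  H <- n; W <- n
  idx_cache <- list()
  taps <- list()
  for (s in 1:5) {
    key <- paste(H, W)
    if (is.null(idx_cache[[key]])) idx_cache[[key]] <- conv_gather_idx(H, W, 3L)
    idx <- idx_cache[[key]]
    for (layer in backbone$stages[[s]]) {
      cols <- im2col(X, H, W, idx, 3L)
      X <- cols %*% layer$K
      X <- X + rep(layer$b, each = nrow(X))
      X <- X * (X > 0)
    }
    if (s >= 3) taps[[paste0("s", s)]] <- X
    if (s < 5) {
      X <- maxpool2(X, H, W)
      H <- H %/% 2L; W <- W %/% 2L
    }
  }
  taps
}

#' Compute (and cache) frozen backbone features for a cohort
#'
#' Runs every slice through the frozen VGG16-style backbone once and stacks
#' the three tap feature maps into sample-major `(N*S) x C` matrices. Because
#' the backbone is frozen the result depends only on the backbone seed and the
#' images, so it is shared across training seeds, folds and ablation arms.
#'
#' @param backbone object from the internal backbone builder (stored in models).
#' @param images list of H x W pixel matrices.
#' @return list with `s3`, `s4`, `s5` feature matrices and `dims`.
#' @keywords internal
backbone_features <- function(backbone, images) {
  dims <- backbone_tap_dims(backbone$image_size, backbone$channels)
  N <- length(images)
  out <- list(s3 = matrix(0, N * dims$s3$S, dims$s3$C),
              s4 = matrix(0, N * dims$s4$S, dims$s4$C),
              s5 = matrix(0, N * dims$s5$S, dims$s5$C))
  for (i in seq_len(N)) {
    taps <- backbone_forward_one(backbone, images[[i]])
    for (nm in c("s3", "s4", "s5")) {
      S <- dims[[nm]]$S
      out[[nm]][((i - 1L) * S + 1L):(i * S), ] <- taps[[nm]]
    }
  }
  out$dims <- dims
  out$n <- N
  out
}
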