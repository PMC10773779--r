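## Grad-CAM over the image branch, plus a lesion-localization score against
## the synthetic ground-truth masks. The class score differentiated is the
## pre-softmax logit of the target class (softmax gradients vanish at
## saturation, and the logit makes the map invariant to adding a constant to
## all logits).

## Core Grad-CAM arithmetic on S x C activation/gradient matrices.
gradcam_map <- function(acts, grads, H, W, out_hw) {
  w <- colMeans(grads)                       # spatial mean of d(score)/d(act)
  m <- as.vector(acts %*% w)
  m[m < 0] <- 0
  M <- matrix(m, H, W)
  M <- upsample_bilinear(M, out_hw[1], out_hw[2])
  rng <- range(M)
  flagged <- FALSE
  if (rng[2] - rng[1] < 1e-12) {
    M[] <- 0
    flagged <- TRUE
  } else {
    M <- (M - rng[1]) / (rng[2] - rng[1])
  }
  list(values = M, flagged_constant = flagged)
}

#' Saliency from activations and gradients
#'
#' The Grad-CAM recipe in isolation: channel weights are the spatial mean of
#' the gradients, the map is `ReLU(sum_c w_c * act_c)` bilinearly upsampled to
#' `out_hw` and min-max normalised (an all-constant raw map becomes all zeros
#' and is flagged).
#'
#' @param activations,gradients C x H x W arrays.
#' @param out_hw output `(H, W)`.
#' @return list with `values` (H x W in `[0, 1]`) and `flagged_constant`.
#' @export
saliency_from_grads <- function(activations, gradients, out_hw) {
  d <- dim(activations)
  stopifnot(length(d) == 3, identical(d, dim(gradients)))
  gradcam_map(feature_to_mat(activations), feature_to_mat(gradients),
              d[2], d[3], out_hw)
}

#' Grad-CAM saliency map
#'
#' Differentiates the pre-softmax logit of `target_class` with respect to the
#' activations of `target_layer` (one of the per-scale joint features of the
#' image branch; the default is the finest scale, whose grid actually
#' resolves lesion-sized structure), weights each channel by its
#' spatial mean gradient, rectifies the weighted sum, upsamples bilinearly to
#' the input size and min-max normalises.
#'
#' @param model a trained `"sf_model"`.
#' @param image an `"sf_image"` or H x W pixel matrix.
#' @param metadata an `"sf_metadata"` record (required for the mlp arm).
#' @param target_class 0 or 1 (default 1 = poor prognosis).
#' @param target_layer layer name; see [gradcam_layers()]. Defaults to the
#'   finest available joint feature.
#' @return A `"saliency_map"`: `values` (H x W in `[0, 1]`), `target_layer`,
#'   `target_class`, `flagged_constant`.
#' @export
grad_cam <- function(model, image, metadata = NULL, target_class = 1,
                     target_layer = NULL) {
  valid <- gradcam_layers(model)
  if (is.null(target_layer)) target_layer <- valid[1L]
  if (!target_layer %in% valid)
    stopf("unknown target layer '%s'; valid layers: %s", target_layer,
          paste(valid, collapse = ", "))
  stopifnot(target_class %in% c(0, 1))
  pixels <- if (inherits(image, "sf_image")) image$pixels else image
  taps <- backbone_forward_one(model$backbone, pixels)
  feats <- c(taps, list(dims = model$dims, n = 1L))
  meta_X <- NULL
  if (model$arms$mlp) {
    if (is.null(metadata)) stopf("this model fuses metadata; pass the record")
    if (is.null(model$meta_stats)) stopf("model has no fitted metadata stats")
    meta_X <- matrix(vectorize_metadata(metadata, train_stats = model$meta_stats),
                     nrow = 1)
  }
  fwd <- model_forward(model, feats, meta_X, 1L, mode = "infer")
  dlogits <- matrix(0, 1, 2)
  dlogits[1, target_class + 1L] <- 1
  bwd <- model_backward(model, fwd$cache, dlogits)
  nm <- target_layer
  d <- model$dims[[paste0("s", substr(nm, 6, 6))]]
  sal <- gradcam_map(fwd$cache$joints[[nm]], bwd$djoints[[nm]], d$H, d$W,
                     dim(pixels))
  structure(list(values = sal$values, target_layer = target_layer,
                 target_class = target_class,
                 flagged_constant = sal$flagged_constant),
            class = "saliency_map")
}

#' Lesion-localization score of a saliency map
#'
#' Mean saliency inside the lesion mask divided by mean saliency outside;
#' values above 1 indicate lesion-concentrated attention. A zero outside-mean
#' with positive inside-mean returns `Inf`.
#'
#' @param saliency a `"saliency_map"` or H x W matrix.
#' @param mask binary H x W lesion mask with at least one positive pixel.
#' @return Nonnegative real (possibly `Inf`).
#' @export
localization_score <- function(saliency, mask) {
  v <- if (inherits(saliency, "saliency_map")) saliency$values else saliency
  if (!identical(dim(v), dim(mask)))
    stopf("saliency (%s) and mask (%s) shapes differ",
          paste(dim(v), collapse = "x"), paste(dim(mask), collapse = "x"))
  inside <- v[mask > 0]
  outside <- v[mask == 0]
  if (length(inside) == 0) stopf("empty lesion mask")
  mi <- mean(inside)
  mo <- mean(outside)
  if (mo == 0) return(if (mi > 0) Inf else 1)
  mi / mo
}
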