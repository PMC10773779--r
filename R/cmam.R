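## Cross-modal attention module (CMAM): concatenate the image feature F1 and
## metadata feature F2 into F, derive a sigmoid attention mask
## A = sigmoid(FC(ReLU(BN(FC(F))))), gate Fo = A o F elementwise, classify.

#' Concatenate image and metadata features
#'
#' `F = Concat(F1, F2)`; `f1` comes first, lengths add. An empty `f2`
#' (image-only ablation) returns `f1` unchanged.
#'
#' @param f1,f2 numeric vectors (or matrices with one sample per row).
#' @return The joint feature.
#' @export
concat_features <- function(f1, f2 = numeric(0)) {
  if (is.matrix(f1) || is.matrix(f2)) {
    if (length(f2) == 0) return(f1)
    stopifnot(nrow(f1) == nrow(f2))
    return(cbind(f1, f2))
  }
  stopifnot(all(is.finite(f1)), all(is.finite(f2)))
  c(f1, f2)
}

#' Initialise the cross-modal attention gate
#'
#' @param n_in joint feature length |F|.
#' @param bottleneck hidden width of the first FC (default |F|/4).
#' @param seed integer seed.
#' @return An `"sf_cmam"` with `params` and BN `state`.
#' @export
cmam_params <- function(n_in, bottleneck = max(1L, n_in %/% 4L), seed = 1) {
  par <- with_seed(seed, list(
    W1 = he_mat(n_in, bottleneck), b1 = numeric(bottleneck),
    bn = list(g = rep(1, bottleneck), b = numeric(bottleneck)),
    W2 = xavier_mat(bottleneck, n_in), b2 = numeric(n_in)))
  structure(list(params = par, state = list(bn = bn_state(bottleneck)),
                 n_in = n_in, bottleneck = bottleneck), class = "sf_cmam")
}

cmam_fwd <- function(par, state, FJ, mode, bn_momentum = 0.1) {
  d1 <- dense_fwd(FJ, par$W1, par$b1)
  n1 <- bn_fwd(d1$Y, par$bn$g, par$bn$b, state$bn, mode, bn_momentum)
  r1 <- relu_fwd(n1$Y)
  d2 <- dense_fwd(r1$Y, par$W2, par$b2)
  A <- sigmoid(d2$Y)
  list(A = A, cache = list(d1 = d1, n1 = n1, r1 = r1, d2 = d2, A = A),
       state = list(bn = n1$state))
}

cmam_bwd <- function(dA, cache, par) {
  dz <- dA * cache$A * (1 - cache$A)
  b2 <- dense_bwd(dz, cache$d2, par$W2)
  dr <- relu_bwd(b2$dX, cache$r1)
  bb <- bn_bwd(dr, cache$n1$cache)
  b1 <- dense_bwd(bb$dX, cache$d1, par$W1)
  list(dF = b1$dX,
       grads = list(W1 = b1$dW, b1 = b1$db,
                    bn = list(g = bb$dgamma, b = bb$dbeta),
                    W2 = b2$dW, b2 = b2$db))
}

#' Compute the cross-modal attention mask
#'
#' `A = sigmoid(FC2(ReLU(BN(FC1(F)))))`, same length as the joint feature,
#' entries strictly in (0, 1). With all FC weights and biases zero and BN in
#' its unit-affine state every entry is exactly 0.5.
#'
#' @param joint joint feature vector (or matrix, one sample per row).
#' @param cmam an [cmam_params()] object; seeded-random if `NULL`.
#' @param mode `"infer"` uses BN running statistics; `"train"` uses batch
#'   statistics (requires a matrix with >= 2 rows).
#' @param seed seed for default initialisation.
#' @return Mask with the shape of `joint`.
#' @export
attention_mask <- function(joint, cmam = NULL, mode = c("infer", "train"),
                           seed = 1) {
  mode <- match.arg(mode)
  X <- if (is.matrix(joint)) joint else matrix(joint, nrow = 1)
  stopifnot(all(is.finite(X)))
  if (is.null(cmam)) cmam <- cmam_params(ncol(X), seed = seed)
  out <- cmam_fwd(cmam$params, cmam$state, X, mode)
  if (is.matrix(joint)) out$A else as.vector(out$A)
}

#' Apply the attention mask to the joint feature
#'
#' `Fo = A o F`, the elementwise product.
#'
#' @param mask,joint equal-length vectors (or equal-dim matrices).
#' @return The gated feature `Fo`.
#' @export
apply_mask <- function(mask, joint) {
  if (length(mask) != length(joint))
    stopf("mask length %d does not match joint feature length %d",
          length(mask), length(joint))
  mask * joint
}

#' Classify a gated feature vector
#'
#' Single fully connected layer to 2 logits followed by softmax. The decision
#' threshold is applied to the poor-prognosis probability; a tie at the
#' threshold predicts the positive (poor-prognosis) class.
#'
#' @param gated feature vector (or matrix, one sample per row).
#' @param head list with `W` (n x 2) and `b` (length 2); seeded-random if
#'   `NULL`.
#' @param threshold decision threshold on `prob_poor`.
#' @param seed seed for default initialisation.
#' @return For a vector input, a `"prediction"` list with `logits`,
#'   `prob_poor`, `label_hat`; for a matrix, a data frame of the same.
#' @export
classify <- function(gated, head = NULL, threshold = 0.5, seed = 1) {
  X <- if (is.matrix(gated)) gated else matrix(gated, nrow = 1)
  stopifnot(all(is.finite(X)))
  if (is.null(head))
    head <- with_seed(seed, list(W = xavier_mat(ncol(X), 2L), b = numeric(2)))
  Z <- X %*% head$W
  Z <- Z + rep(head$b, each = nrow(Z))
  P <- softmax_rows(Z)
  prob <- P[, 2]
  lab <- as.integer(prob >= threshold)
  if (is.matrix(gated))
    return(data.frame(prob_poor = prob, label_hat = lab,
                      logit0 = Z[, 1], logit1 = Z[, 2]))
  structure(list(logits = as.vector(Z), prob_poor = prob[1],
                 label_hat = lab[1]), class = "prediction")
}
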