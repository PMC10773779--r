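## Adaptive lesion-awareness image branch.
##
## Internally, a batch of feature maps lives in a (B*S) x C matrix (sample-
## major rows, spatial index s = h + (w-1)*H) and a batch of token sequences
## in a (B*L) x D matrix. The exported operations work on single samples in
## the conventional C x H x W / D x L orientation and wrap the batched code.

## ---- orientation helpers ---------------------------------------------------

feature_to_mat <- function(feature) {
  d <- dim(feature)
  stopifnot(length(d) == 3)
  t(matrix(feature, nrow = d[1]))          # S x C
}

mat_to_feature <- function(X, C, H, W) array(t(X), dim = c(C, H, W))

## ---- patch embedding -------------------------------------------------------

## Spatial gather indices: patch_idx[l, p] = spatial index of within-patch
## position p of patch l (both column-major).
patch_idx_mat <- function(H, W, P) {
  gh <- H %/% P; gw <- W %/% P
  L <- gh * gw
  idx <- matrix(0L, L, P * P)
  gi <- rep(seq_len(gh), times = gw)
  gj <- rep(seq_len(gw), each = gh)
  p <- 0L
  for (pj in seq_len(P)) {
    for (pi in seq_len(P)) {
      p <- p + 1L
      idx[, p] <- (pi + P * (gi - 1L)) + (pj + P * (gj - 1L) - 1L) * H
    }
  }
  idx
}

#' Parameters for the patch embedding
#' @param C,patch_size,embed_dim,L channel count, patch side, embedding
#'   dimension, number of patches.
#' @param seed integer seed.
#' @return list with projection `We` ((P^2 C) x D), bias `be`, and learnable
#'   positional embeddings `pos` (L x D).
#' @export
patchify_params <- function(C, patch_size, embed_dim, L, seed = 1) {
  with_seed(seed, list(We = xavier_mat(patch_size^2 * C, embed_dim),
                       be = numeric(embed_dim),
                       pos = matrix(stats::rnorm(L * embed_dim, sd = 0.02), L, embed_dim)))
}

## Batched gather rows: column p holds, for every (sample, patch) token row,
## the (B*S)-row index of within-patch position p.
patch_rows <- function(pidx, B, S) {
  L <- nrow(pidx); P2 <- ncol(pidx)
  off <- rep((seq_len(B) - 1L) * S, each = L)
  rows <- matrix(0L, B * L, P2)
  for (p in seq_len(P2)) rows[, p] <- rep(pidx[, p], times = B) + off
  rows
}

## Batched: X (B*S) x C -> tokens (B*L) x (P^2 C), then linear + positions.
patchify_fwd <- function(X, B, C, H, W, P, pidx, par, rows = NULL) {
  S <- H * W; L <- nrow(pidx); P2 <- P * P
  if (is.null(rows)) rows <- patch_rows(pidx, B, S)
  T0 <- matrix(0, B * L, P2 * C)
  for (c in seq_len(C)) {
    Xc <- X[, c]
    for (p in seq_len(P2)) T0[, (c - 1L) * P2 + p] <- Xc[rows[, p]]
  }
  Tk <- T0 %*% par$We
  Tk <- Tk + rep(par$be, each = nrow(Tk)) + par$pos[rep(seq_len(L), B), , drop = FALSE]
  list(Y = Tk, T0 = T0, rows = rows)
}

patchify_bwd <- function(dT, cache, B, C, H, W, P, pidx, par) {
  S <- H * W; L <- nrow(pidx); P2 <- P * P
  D <- ncol(dT)
  dpos <- matrix(0, L, D)
  for (d in seq_len(D)) dpos[, d] <- .rowSums(matrix(dT[, d], L, B), L, B)
  g <- list(We = crossprod(cache$T0, dT), be = colSums(dT), pos = dpos)
  dT0 <- dT %*% t(par$We)
  dX <- matrix(0, B * S, C)
  rows <- cache$rows
  for (c in seq_len(C)) {
    dXc <- numeric(B * S)
    for (p in seq_len(P2)) dXc[rows[, p]] <- dT0[, (c - 1L) * P2 + p]
    dX[, c] <- dXc
  }
  list(dX = dX, grads = g)
}

unpatchify_params <- function(C, patch_size, embed_dim, seed = 1) {
  with_seed(seed, list(Wu = xavier_mat(embed_dim, patch_size^2 * C),
                       bu = numeric(patch_size^2 * C)))
}

unpatchify_fwd <- function(Tk, B, C, H, W, P, pidx, par, rows = NULL) {
  S <- H * W; L <- nrow(pidx); P2 <- P * P
  if (is.null(rows)) rows <- patch_rows(pidx, B, S)
  G <- Tk %*% par$Wu
  G <- G + rep(par$bu, each = nrow(G))
  X <- matrix(0, B * S, C)
  for (c in seq_len(C)) {
    Xc <- numeric(B * S)
    for (p in seq_len(P2)) Xc[rows[, p]] <- G[, (c - 1L) * P2 + p]
    X[, c] <- Xc
  }
  list(Y = X, Tk = Tk, rows = rows)
}

unpatchify_bwd <- function(dX, cache, B, C, H, W, P, pidx, par) {
  L <- nrow(pidx); P2 <- P * P
  C <- ncol(dX)
  dG <- matrix(0, B * L, P2 * C)
  rows <- cache$rows
  for (c in seq_len(C)) {
    dXc <- dX[, c]
    for (p in seq_len(P2)) dG[, (c - 1L) * P2 + p] <- dXc[rows[, p]]
  }
  list(dT = dG %*% t(par$Wu),
       grads = list(Wu = crossprod(cache$Tk, dG), bu = colSums(dG)))
}

## ---- multi-head self-attention ---------------------------------------------

## Scores for all (sample, head) blocks are stacked into one matrix so the
## softmax (and its backward) run vectorised; only the tiny per-block matmuls
## stay in loops.
mhsa_fwd <- function(Z, par, B, L, nh) {
  D <- ncol(Z); dh <- D %/% nh
  Q <- Z %*% par$Wq; Q <- Q + rep(par$bq, each = nrow(Q))
  K <- Z %*% par$Wk; K <- K + rep(par$bk, each = nrow(K))
  V <- Z %*% par$Wv; V <- V + rep(par$bv, each = nrow(V))
  Sb <- matrix(0, B * nh * L, L)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      r0 <- ((b - 1L) * nh + h - 1L) * L
      Sb[(r0 + 1L):(r0 + L), ] <-
        Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  A <- softmax_rows(Sb)
  O <- matrix(0, nrow(Z), D)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      r0 <- ((b - 1L) * nh + h - 1L) * L
      O[rows, cols] <- A[(r0 + 1L):(r0 + L), , drop = FALSE] %*%
        V[rows, cols, drop = FALSE]
    }
  }
  Y <- O %*% par$Wo
  Y <- Y + rep(par$bo, each = nrow(Y))
  list(Y = Y, Q = Q, K = K, V = V, O = O, A = A, Z = Z)
}

mhsa_bwd <- function(dY, cache, par, B, L, nh) {
  D <- ncol(dY); dh <- D %/% nh
  dO <- dY %*% t(par$Wo)
  gWo <- crossprod(cache$O, dY); gbo <- colSums(dY)
  A <- cache$A
  dA <- matrix(0, B * nh * L, L)
  dV <- matrix(0, nrow(dY), D)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      r0 <- ((b - 1L) * nh + h - 1L) * L
      a <- A[(r0 + 1L):(r0 + L), , drop = FALSE]
      do <- dO[rows, cols, drop = FALSE]
      dA[(r0 + 1L):(r0 + L), ] <- do %*% t(cache$V[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(a, do)
    }
  }
  dS <- A * (dA - rowSums(A * dA))
  dQ <- matrix(0, nrow(dY), D); dK <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      r0 <- ((b - 1L) * nh + h - 1L) * L
      ds <- dS[(r0 + 1L):(r0 + L), , drop = FALSE]
      dQ[rows, cols] <- ds %*% cache$K[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- crossprod(ds, cache$Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  Z <- cache$Z
  dZ <- dQ %*% t(par$Wq) + dK %*% t(par$Wk) + dV %*% t(par$Wv)
  grads <- list(Wq = crossprod(Z, dQ), bq = colSums(dQ),
                Wk = crossprod(Z, dK), bk = colSums(dK),
                Wv = crossprod(Z, dV), bv = colSums(dV),
                Wo = gWo, bo = gbo)
  list(dZ = dZ, grads = grads)
}

## ---- global attention block (pre-norm transformer) -------------------------

#' Parameters for the global attention block
#' @param embed_dim token dimension D.
#' @param heads number of attention heads (must divide D).
#' @param mlp_hidden hidden width of the token MLP.
#' @param seed integer seed.
#' @return nested list: `ln1`, `attn` (Wq/Wk/Wv/Wo + biases), `ln2`, `mlp`.
#' @export
gab_params <- function(embed_dim, heads = 2, mlp_hidden = 2 * embed_dim, seed = 1) {
  stopifnot(embed_dim %% heads == 0)
  with_seed(seed, list(
    ln1 = list(g = rep(1, embed_dim), b = numeric(embed_dim)),
    attn = list(Wq = xavier_mat(embed_dim, embed_dim), bq = numeric(embed_dim),
                Wk = xavier_mat(embed_dim, embed_dim), bk = numeric(embed_dim),
                Wv = xavier_mat(embed_dim, embed_dim), bv = numeric(embed_dim),
                Wo = xavier_mat(embed_dim, embed_dim), bo = numeric(embed_dim)),
    ln2 = list(g = rep(1, embed_dim), b = numeric(embed_dim)),
    mlp = list(W1 = he_mat(embed_dim, mlp_hidden), b1 = numeric(mlp_hidden),
               W2 = xavier_mat(mlp_hidden, embed_dim), b2 = numeric(embed_dim))))
}

## Pre-norm residual wiring: X' = X + MHSA(LN(X)); Fg = X' + MLP(LN(X')).
gab_fwd <- function(Tk, par, B, L, nh) {
  l1 <- ln_fwd(Tk, par$ln1$g, par$ln1$b)
  mh <- mhsa_fwd(l1$Y, par$attn, B, L, nh)
  X1 <- Tk + mh$Y
  l2 <- ln_fwd(X1, par$ln2$g, par$ln2$b)
  d1 <- dense_fwd(l2$Y, par$mlp$W1, par$mlp$b1)
  r1 <- relu_fwd(d1$Y)
  d2 <- dense_fwd(r1$Y, par$mlp$W2, par$mlp$b2)
  list(Y = X1 + d2$Y, l1 = l1, mh = mh, X1 = X1, l2 = l2, d1 = d1, r1 = r1, d2 = d2)
}

gab_bwd <- function(dY, cache, par, B, L, nh) {
  b2 <- dense_bwd(dY, cache$d2, par$mlp$W2)
  dr <- relu_bwd(b2$dX, cache$r1)
  b1 <- dense_bwd(dr, cache$d1, par$mlp$W1)
  l2b <- ln_bwd(b1$dX, cache$l2$cache)
  dX1 <- dY + l2b$dX
  mhb <- mhsa_bwd(dX1, cache$mh, par$attn, B, L, nh)
  l1b <- ln_bwd(mhb$dZ, cache$l1$cache)
  dT <- dX1 + l1b$dX
  grads <- list(ln1 = list(g = l1b$dgamma, b = l1b$dbeta),
                attn = mhb$grads,
                ln2 = list(g = l2b$dgamma, b = l2b$dbeta),
                mlp = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
  list(dT = dT, grads = grads)
}

## ---- local attention block (channel then spatial) ---------------------------

#' Parameters for the local attention block
#' @param C channel count of the input feature map.
#' @param reduction channel-attention bottleneck reduction ratio.
#' @param seed integer seed.
#' @return list: shared channel MLP `Wc1/bc1/Wc2/bc2`, 7x7 spatial kernel
#'   `Ks` (98 x 1, over stacked mean/max maps) and bias `bs`.
#' @export
lab_params <- function(C, reduction = 4, seed = 1) {
  Ch <- max(1L, as.integer(round(C / reduction)))
  with_seed(seed, list(Wc1 = he_mat(C, Ch), bc1 = numeric(Ch),
                       Wc2 = xavier_mat(Ch, C), bc2 = numeric(C),
                       Ks = xavier_mat(2L * 49L, 1L), bs = 0))
}

## Channel attention strictly before spatial attention:
## F' = Attc(F) o F, then Fl = Atts(F') o F'.
lab_fwd <- function(X, par, B, H, W, idx7) {
  S <- H * W; C <- ncol(X)
  gp <- gap_fwd(X, S, B)
  mx <- spatial_max(X, S, B)
  da <- dense_fwd(gp, par$Wc1, par$bc1); ra <- relu_fwd(da$Y)
  oa <- dense_fwd(ra$Y, par$Wc2, par$bc2)
  dm <- dense_fwd(mx$vals, par$Wc1, par$bc1); rm <- relu_fwd(dm$Y)
  om <- dense_fwd(rm$Y, par$Wc2, par$bc2)
  attc <- sigmoid(oa$Y + om$Y)                      # B x C
  attc_x <- attc[rep(seq_len(B), each = S), , drop = FALSE]
  Fp <- X * attc_x
  mean_map <- rowMeans(Fp)
  amx <- max.col(Fp, ties.method = "first")
  max_map <- Fp[cbind(seq_len(nrow(Fp)), amx)]
  COLS <- im2col_batch(cbind(mean_map, max_map), H, W, idx7, 7L, B)
  z <- as.vector(COLS %*% par$Ks) + par$bs
  atts <- sigmoid(z)                                # length B*S
  Fl <- Fp * atts
  list(Y = Fl, X = X, gp = gp, mx = mx, da = da, ra = ra, oa = oa,
       dm = dm, rm = rm, om = om, attc = attc, attc_x = attc_x, Fp = Fp,
       amx = amx, COLS = COLS, atts = atts)
}

lab_bwd <- function(dFl, cache, par, B, H, W, idx7) {
  S <- H * W; C <- ncol(dFl)
  datts <- rowSums(dFl * cache$Fp)
  dFp <- dFl * cache$atts
  dz <- datts * cache$atts * (1 - cache$atts)
  gKs <- crossprod(cache$COLS, dz)
  gbs <- sum(dz)
  ## input gradient of a same-padded correlation = correlation of the output
  ## gradient with the spatially reversed kernel (conv-transpose as gather)
  Krev <- cbind(rev(par$Ks[1:49, 1]), rev(par$Ks[50:98, 1]))
  dmm <- im2col_batch(matrix(dz, ncol = 1L), H, W, idx7, 7L, B) %*% Krev
  dFp <- dFp + matrix(dmm[, 1L] / C, B * S, C)
  idx <- cbind(seq_len(B * S), cache$amx)
  dFp[idx] <- dFp[idx] + dmm[, 2L]
  dattc <- blocksum(dFp * cache$X, S, B)
  dX <- dFp * cache$attc_x
  dsig <- dattc * cache$attc * (1 - cache$attc)
  boa <- dense_bwd(dsig, cache$oa, par$Wc2)
  dra <- relu_bwd(boa$dX, cache$ra)
  bda <- dense_bwd(dra, cache$da, par$Wc1)
  bom <- dense_bwd(dsig, cache$om, par$Wc2)
  drm <- relu_bwd(bom$dX, cache$rm)
  bdm <- dense_bwd(drm, cache$dm, par$Wc1)
  dX <- dX + gap_bwd(bda$dX, S, B)
  for (c in seq_len(C)) {
    ar <- cache$mx$arg[, c]
    dX[cbind(ar, c)] <- dX[cbind(ar, c)] + bdm$dX[, c]
  }
  grads <- list(Wc1 = bda$dW + bdm$dW, bc1 = bda$db + bdm$db,
                Wc2 = boa$dW + bom$dW, bc2 = boa$db + bom$db,
                Ks = gKs, bs = gbs)
  list(dX = dX, grads = grads)
}

## ---- GLAM: GAB + LAB in parallel, fused ------------------------------------

#' Parameters for one global-local attention module
#' @param C,H,W feature-map dimensions at this scale.
#' @param patch_size,embed_dim,heads,mlp_hidden,reduction architecture settings
#'   (see [sf_config()]).
#' @param seed integer seed.
#' @return nested list with `patch`, `gab`, `unpatch`, `lab`, `fuse` blocks.
#' @export
glam_params <- function(C, H, W, patch_size = 2, embed_dim = 16, heads = 2,
                        mlp_hidden = 2 * embed_dim, reduction = 4, seed = 1) {
  if (H %% patch_size != 0)
    stopf("feature height %d not divisible by patch size %d", H, patch_size)
  if (W %% patch_size != 0)
    stopf("feature width %d not divisible by patch size %d", W, patch_size)
  L <- (H %/% patch_size) * (W %/% patch_size)
  list(patch = patchify_params(C, patch_size, embed_dim, L, derive_seed(seed, 1)),
       gab = gab_params(embed_dim, heads, mlp_hidden, derive_seed(seed, 2)),
       unpatch = unpatchify_params(C, patch_size, embed_dim, derive_seed(seed, 3)),
       lab = lab_params(C, reduction, derive_seed(seed, 4)),
       fuse = with_seed(derive_seed(seed, 5),
                        list(Wf = xavier_mat(C, C), bf = numeric(C))))
}

glam_fwd <- function(X, par, B, C, H, W, P, nh, pidx, idx7) {
  rows <- patch_rows(pidx, B, H * W)
  pt <- patchify_fwd(X, B, C, H, W, P, pidx, par$patch, rows)
  L <- nrow(pidx)
  gb <- gab_fwd(pt$Y, par$gab, B, L, nh)
  up <- unpatchify_fwd(gb$Y, B, C, H, W, P, pidx, par$unpatch, rows)
  lb <- lab_fwd(X, par$lab, B, H, W, idx7)
  fsum <- up$Y + lb$Y
  fj <- dense_fwd(fsum, par$fuse$Wf, par$fuse$bf)
  ## residual wiring: the module starts near the identity and learns a
  ## global/local refinement on top of the incoming feature map
  list(Y = X + fj$Y, pt = pt, gb = gb, up = up, lb = lb, fj = fj, gmap = up$Y)
}

glam_bwd <- function(dJ, cache, par, B, C, H, W, P, nh, pidx, idx7) {
  fb <- dense_bwd(dJ, cache$fj, par$fuse$Wf)
  ub <- unpatchify_bwd(fb$dX, cache$up, B, C, H, W, P, pidx, par$unpatch)
  L <- nrow(pidx)
  gb <- gab_bwd(ub$dT, cache$gb, par$gab, B, L, nh)
  pb <- patchify_bwd(gb$dT, cache$pt, B, C, H, W, P, pidx, par$patch)
  lb <- lab_bwd(fb$dX, cache$lb, par$lab, B, H, W, idx7)
  list(dX = dJ + pb$dX + lb$dX,
       grads = list(patch = pb$grads, gab = gb$grads, unpatch = ub$grads,
                    lab = lb$grads, fuse = list(Wf = fb$dW, bf = fb$db)))
}

## ---- exported single-sample operations -------------------------------------

#' Patch-embed a feature map into a token sequence
#'
#' Splits a C x H x W feature map into non-overlapping `patch_size`-square
#' patches (L = H*W / patch_size^2 of them), flattens each, applies a
#' learnable linear map to `embed_dim` dimensions and adds learnable 1-D
#' positional embeddings.
#'
#' @param feature numeric array with dims `c(C, H, W)`.
#' @param patch_size patch side P; H and W must be divisible by it.
#' @param embed_dim token dimension D.
#' @param params optional [patchify_params()]; seeded-random if `NULL`.
#' @param seed seed for default parameter initialisation.
#' @return A `"feature_sequence"`: list with `tokens` (D x L), `patch_size`,
#'   `source_hw`, and the `params` used.
#' @export
patchify <- function(feature, patch_size, embed_dim, params = NULL, seed = 1) {
  d <- dim(feature)
  if (is.null(d) || length(d) != 3) stopf("feature must be a C x H x W array")
  C <- d[1]; H <- d[2]; W <- d[3]
  if (H %% patch_size != 0)
    stopf("height %d is not divisible by patch size %d", H, patch_size)
  if (W %% patch_size != 0)
    stopf("width %d is not divisible by patch size %d", W, patch_size)
  stopifnot(all(is.finite(feature)))
  pidx <- patch_idx_mat(H, W, patch_size)
  if (is.null(params))
    params <- patchify_params(C, patch_size, embed_dim, nrow(pidx), seed)
  out <- patchify_fwd(feature_to_mat(feature), 1L, C, H, W, patch_size, pidx, params)
  structure(list(tokens = t(out$Y), patch_size = patch_size,
                 source_hw = c(H, W), params = params),
            class = "feature_sequence")
}

#' Invert a patch embedding back to a feature map
#'
#' Projects tokens to flattened patches with a learnable linear map and
#' scatters them back to C x H x W. With `params$Wu` set to the transpose of
#' an identity patch embedding this exactly round-trips [patchify()].
#'
#' @param x a `"feature_sequence"` (or D x L token matrix).
#' @param C target channel count.
#' @param params optional `unpatchify` parameter list (`Wu`, `bu`).
#' @param source_hw,patch_size required if `x` is a bare matrix.
#' @param seed seed for default parameter initialisation.
#' @return C x H x W array.
#' @export
unpatchify <- function(x, C, params = NULL, source_hw = NULL, patch_size = NULL,
                       seed = 1) {
  if (inherits(x, "feature_sequence")) {
    tokens <- x$tokens; source_hw <- x$source_hw; patch_size <- x$patch_size
  } else tokens <- x
  H <- source_hw[1]; W <- source_hw[2]
  D <- nrow(tokens)
  if (is.null(params)) params <- unpatchify_params(C, patch_size, D, seed)
  pidx <- patch_idx_mat(H, W, patch_size)
  out <- unpatchify_fwd(t(tokens), 1L, C, H, W, patch_size, pidx, params)
  mat_to_feature(out$Y, C, H, W)
}

#' Global attention block
#'
#' Pre-norm transformer block over a token sequence:
#' `X' = X + MHSA(LN(X))`, `Fg = X' + MLP(LN(X'))`. Shape-preserving; with the
#' MHSA and MLP output projections zeroed it is exactly the identity.
#'
#' @param x a `"feature_sequence"` or a D x L token matrix.
#' @param params optional [gab_params()].
#' @param heads number of heads used for default initialisation.
#' @param seed seed for default parameter initialisation.
#' @return Same type as `x` (tokens D x L).
#' @export
global_attention_block <- function(x, params = NULL, heads = 2, seed = 1) {
  tokens <- if (inherits(x, "feature_sequence")) x$tokens else x
  stopifnot(is.matrix(tokens), all(is.finite(tokens)))
  D <- nrow(tokens); L <- ncol(tokens)
  if (is.null(params)) params <- gab_params(D, heads, 2 * D, seed)
  out <- gab_fwd(t(tokens), params, 1L, L, heads)
  if (inherits(x, "feature_sequence")) {
    x$tokens <- t(out$Y)
    x
  } else t(out$Y)
}

#' Local attention block
#'
#' Sequential channel-then-spatial sigmoid attention:
#' `F' = Attc(F) o F`, `Fl = Atts(F') o F'`. Channel attention is a shared
#' two-layer bottleneck over global-average- and global-max-pooled channel
#' descriptors; spatial attention is a 7x7 convolution over the channelwise
#' mean and max maps. `o` is the elementwise product with broadcasting.
#'
#' @param feature numeric array with dims `c(C, H, W)`.
#' @param params optional [lab_params()].
#' @param reduction bottleneck reduction for default initialisation.
#' @param seed seed for default parameter initialisation.
#' @return list with `feature_map` (Fl, C x H x W) and `attention`
#'   (`channel_mask` C x 1 x 1, `spatial_mask` 1 x H x W, entries in (0,1)).
#' @export
local_attention_block <- function(feature, params = NULL, reduction = 4, seed = 1) {
  d <- dim(feature)
  if (is.null(d) || length(d) != 3) stopf("feature must be a C x H x W array")
  stopifnot(all(is.finite(feature)))
  C <- d[1]; H <- d[2]; W <- d[3]
  if (is.null(params)) params <- lab_params(C, reduction, seed)
  idx7 <- conv_gather_idx(H, W, 7L)
  out <- lab_fwd(feature_to_mat(feature), params, 1L, H, W, idx7)
  list(feature_map = mat_to_feature(out$Y, C, H, W),
       attention = list(channel_mask = array(out$attc[1, ], dim = c(C, 1, 1)),
                        spatial_mask = array(out$atts, dim = c(1, H, W))),
       params = params)
}

#' Global-local attention module at one scale
#'
#' Runs the global attention block (through the patch embedding) and the local
#' attention block in parallel on the same feature map, maps the token
#' sequence back to a C x H x W map, and fuses the two branches by elementwise
#' sum followed by a 1x1 convolutional projection, added residually to the
#' input map: `joint = F + conv1x1(Gmap + Fl)`.
#'
#' @param feature numeric array with dims `c(C, H, W)`.
#' @param params optional [glam_params()].
#' @param patch_size,embed_dim,heads,mlp_hidden,reduction settings for default
#'   initialisation.
#' @param seed seed for default parameter initialisation.
#' @return list with `global_feature` (tokens D x L after the GAB),
#'   `local_feature` (Fl), `global_map` (unpatchified GAB output),
#'   `joint_feature` (fused C x H x W) and `params`.
#' @export
glam <- function(feature, params = NULL, patch_size = 2, embed_dim = 16,
                 heads = 2, mlp_hidden = 2 * embed_dim, reduction = 4, seed = 1) {
  d <- dim(feature)
  if (is.null(d) || length(d) != 3) stopf("feature must be a C x H x W array")
  C <- d[1]; H <- d[2]; W <- d[3]
  if (is.null(params))
    params <- glam_params(C, H, W, patch_size, embed_dim, heads, mlp_hidden,
                          reduction, seed)
  P <- patch_size
  pidx <- patch_idx_mat(H, W, P)
  idx7 <- conv_gather_idx(H, W, 7L)
  out <- glam_fwd(feature_to_mat(feature), params, 1L, C, H, W, P, heads, pidx, idx7)
  list(global_feature = t(out$gb$Y),
       local_feature = mat_to_feature(out$lb$Y, C, H, W),
       global_map = mat_to_feature(out$gmap, C, H, W),
       joint_feature = mat_to_feature(out$Y, C, H, W),
       params = params)
}
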