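## Minimal neural-network engine: every layer is a pure fwd/bwd pair on
## matrices whose rows are batch items (or batch x spatial positions) and whose
## columns are features/channels. All backward passes are exercised by
## finite-difference gradient checks in the test suite.

he_mat <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
xavier_mat <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)

## ---- dense -----------------------------------------------------------------

dense_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, X = X)
}

dense_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

## ---- elementwise -----------------------------------------------------------

relu_fwd <- function(X) {
  Y <- X * (X > 0)
  list(Y = Y, mask = X > 0)
}
relu_bwd <- function(dY, cache) dY * cache$mask

sigmoid <- function(X) 1 / (1 + exp(-X))
sigmoid_bwd <- function(dY, Y) dY * Y * (1 - Y)

## Inverted dropout; draws from the current RNG stream (seeded by the caller).
dropout_fwd <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0) return(list(Y = X, mask = NULL))
  keep <- (stats::runif(length(X)) >= rate) / (1 - rate)
  mask <- array(keep, dim = dim(X))
  list(Y = X * mask, mask = mask)
}
dropout_bwd <- function(dY, cache) if (is.null(cache$mask)) dY else dY * cache$mask

## ---- batch normalisation (over rows, per column) --------------------------

bn_state <- function(C) list(mean = numeric(C), var = rep(1, C))

bn_fwd <- function(X, gamma, beta, state, mode, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (mode == "train" && n > 1) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    v <- colMeans(xc * xc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- state$mean
    v <- state$var
    xc <- X - rep(mu, each = n)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = n)
  Y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(Y = Y, cache = list(xhat = xhat, istd = istd, gamma = gamma, train = (mode == "train" && n > 1)),
       state = state)
}

bn_bwd <- function(dY, cache) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = n)
  if (!cache$train) {
    dX <- dxhat * rep(cache$istd, each = n)
  } else {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dX <- (dxhat - rep(s1 / n, each = n) - cache$xhat * rep(s2 / n, each = n)) *
      rep(cache$istd, each = n)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- layer normalisation (per row) -----------------------------------------

ln_fwd <- function(X, gamma, beta, eps = 1e-5) {
  D <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(Y = Y, cache = list(xhat = xhat, istd = istd, gamma = gamma))
}

ln_bwd <- function(dY, cache) {
  n <- nrow(dY); D <- ncol(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = n)
  s1 <- rowMeans(dxhat)
  s2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - s1 - cache$xhat * s2) * cache$istd
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- softmax / cross-entropy ----------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z)
  E / rowSums(E)
}

## y in {0,1}; columns of logits = (class0, class1). Returns mean CE loss and
## gradient wrt logits.
softmax_ce <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, probs = P, dlogits = dZ / n)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad * grad
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  theta <- theta - lr * mh / (sqrt(vh) + eps)
  list(theta = theta, state = st)
}

## ---- parameter flattening ---------------------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

## Rebuild the nested structure of `skel` from flat vector `theta`.
unflatten_params <- function(theta, skel) {
  pos <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  rec(skel)
}

## Zero-filled copy of a nested parameter list (gradient accumulator template).
zero_like <- function(p) {
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    y <- x; y[] <- 0; y
  }
  rec(p)
}

n_params <- function(p) length(flatten_params(p))

## ---- spatial index helpers --------------------------------------------------
## Feature maps are stored as (B*S) x C matrices, sample-major; within a sample
## the spatial index is s = h + (w-1)*H (column-major of the H x W matrix,
## origin top-left, h = row).

## k x k convolution gather indices into the zero-padded (H+2p) x (W+2p) plane.
conv_gather_idx <- function(H, W, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  hh <- rep(seq_len(H), times = W)
  ww <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, k * k)
  j <- 0L
  for (dw in seq_len(k)) {
    for (dh in seq_len(k)) {
      j <- j + 1L
      idx[, j] <- (hh + dh - 1L) + (ww + dw - 2L) * Hp
    }
  }
  idx
}

## Embed an H x W channel (as vector, column-major) into the padded plane.
pad_plane <- function(v, H, W, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  M <- matrix(0, Hp, Wp)
  M[(p + 1L):(p + H), (p + 1L):(p + W)] <- v
  as.vector(M)
}

unpad_plane <- function(vp, H, W, p) {
  Hp <- H + 2L * p
  M <- matrix(vp, Hp)
  as.vector(M[(p + 1L):(p + H), (p + 1L):(p + W)])
}

## im2col for one sample: X is S x C, returns S x (k*k*C).
im2col <- function(X, H, W, idx, k) {
  p <- (k - 1L) %/% 2L
  C <- ncol(X)
  out <- matrix(0, H * W, k * k * C)
  for (c in seq_len(C)) {
    vp <- pad_plane(X[, c], H, W, p)
    out[, ((c - 1L) * k * k + 1L):(c * k * k)] <- vp[idx]
  }
  out
}

## Batched im2col: X is (B*S) x C sample-major, returns (B*S) x (k*k*C).
im2col_batch <- function(X, H, W, idx, k, B) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  S <- H * W
  C <- ncol(X)
  hh <- rep(seq_len(H), times = W)
  ww <- rep(seq_len(W), each = H)
  inner <- (hh + p) + (ww + p - 1L) * Hp
  out <- matrix(0, B * S, k * k * C)
  for (c in seq_len(C)) {
    PM <- matrix(0, Hp * Wp, B)
    PM[inner, ] <- matrix(X[, c], S, B)
    for (j in seq_len(k * k)) {
      out[, (c - 1L) * k * k + j] <- PM[idx[, j], ]
    }
  }
  out
}

## Adjoint of im2col: scatter-add column gradients back to the S x C plane.
col2im <- function(dcols, H, W, idx, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  C <- ncol(dcols) / (k * k)
  dX <- matrix(0, H * W, C)
  iv <- as.vector(idx)
  for (c in seq_len(C)) {
    block <- dcols[, ((c - 1L) * k * k + 1L):(c * k * k)]
    acc <- rowsum(as.vector(block), iv)
    vp <- numeric(Hp * Wp)
    vp[as.integer(rownames(acc))] <- acc[, 1L]
    dX[, c] <- unpad_plane(vp, H, W, p)
  }
  dX
}

## 2x2 max-pool child indices: list of 4 index vectors of length (H/2)*(W/2).
pool_child_idx <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  f <- function(dh, dw) (2L * ho - 2L + dh) + (2L * wo - 2L + dw - 1L) * H
  list(f(1L, 1L), f(2L, 1L), f(1L, 2L), f(2L, 2L))
}

maxpool2 <- function(X, H, W) {
  ch <- pool_child_idx(H, W)
  pmax(X[ch[[1L]], , drop = FALSE], X[ch[[2L]], , drop = FALSE],
       X[ch[[3L]], , drop = FALSE], X[ch[[4L]], , drop = FALSE])
}

## Nearest-neighbour x2 upsampling parent index: for each fine position (2H x 2W)
## the coarse spatial index it copies from.
upsample2_parent_idx <- function(H, W) {
  Hf <- 2L * H; Wf <- 2L * W
  hf <- rep(seq_len(Hf), times = Wf)
  wf <- rep(seq_len(Wf), each = Hf)
  ((hf + 1L) %/% 2L) + ((wf + 1L) %/% 2L - 1L) * H
}

## Batched nearest x2: X is (B*S) x C with spatial dims H x W.
upsample2_fwd <- function(X, H, W, B, pidx) {
  S <- H * W
  rows <- rep((seq_len(B) - 1L) * S, each = length(pidx)) + rep(pidx, B)
  X[rows, , drop = FALSE]
}

## Adjoint of nearest x2: each coarse cell sums its four fine children.
upsample2_bwd <- function(dY, H, W, B, pidx) {
  S <- H * W; Sf <- 4L * S
  ch <- pool_child_idx(2L * H, 2L * W)
  off <- rep((seq_len(B) - 1L) * Sf, each = S)
  dY[off + rep(ch[[1L]], B), , drop = FALSE] +
    dY[off + rep(ch[[2L]], B), , drop = FALSE] +
    dY[off + rep(ch[[3L]], B), , drop = FALSE] +
    dY[off + rep(ch[[4L]], B), , drop = FALSE]
}

## Bilinear upsampling of a single H x W matrix to Ho x Wo (pixel-centre
## alignment); used by Grad-CAM and image resizing.
upsample_bilinear <- function(M, Ho, Wo) {
  H <- nrow(M); W <- ncol(M)
  if (H == Ho && W == Wo) return(M)
  yo <- ((seq_len(Ho) - 0.5) * H / Ho) - 0.5
  xo <- ((seq_len(Wo) - 0.5) * W / Wo) - 0.5
  y0 <- pmin(pmax(floor(yo), 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(pmax(floor(xo), 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- pmin(pmax(yo - y0, 0), 1); wx <- pmin(pmax(xo - x0, 0), 1)
  A <- M[y0 + 1, x0 + 1, drop = FALSE]; Bm <- M[y1 + 1, x0 + 1, drop = FALSE]
  Cc <- M[y0 + 1, x1 + 1, drop = FALSE]; D <- M[y1 + 1, x1 + 1, drop = FALSE]
  top <- A * (1 - wy) + Bm * wy
  bot <- Cc * (1 - wy) + D * wy
  top * rep(1 - wx, each = Ho) + bot * rep(wx, each = Ho)
}

## Per-sample, per-column sum over spatial rows: X (B*S) x C -> B x C.
## Columns of X are (b,s)-major so each (sample, column) block is contiguous.
blocksum <- function(X, S, B) {
  C <- ncol(X)
  matrix(.colSums(X, S, B * C), B, C)
}

## Per-sample global average pooling: X (B*S) x C -> B x C.
gap_fwd <- function(X, S, B) blocksum(X, S, B) / S
gap_bwd <- function(dY, S, B) {
  dY[rep(seq_len(B), each = S), , drop = FALSE] / S
}

## Per-sample, per-column max over spatial rows. Returns B x C values and the
## (B*S)-row index of each argmax for the backward scatter.
spatial_max <- function(X, S, B) {
  C <- ncol(X)
  vals <- matrix(0, B, C)
  arg <- matrix(0L, B, C)
  for (c in seq_len(C)) {
    m <- matrix(X[, c], S, B)
    a <- max.col(t(m), ties.method = "first")
    vals[, c] <- m[cbind(a, seq_len(B))]
    arg[, c] <- (seq_len(B) - 1L) * S + a
  }
  list(vals = vals, arg = arg)
}
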