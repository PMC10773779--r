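## MLP patient-metadata encoder (MLP-FE): vectorise the 19 clinical fields and
## encode them into a 256-d feature vector F2.

#' Metadata schema
#'
#' Declares the 19 clinical fields, their types, category levels and ranges,
#' and the fixed encoding order used by [vectorize_metadata()].
#' @return list with `fields`, `binary_fields`, `hospital_levels`,
#'   `consciousness_levels`, `ability_range`.
#' @export
metadata_schema <- function() {
  list(fields = metadata_field_names(),
       binary_fields = c("gender", "disorder", "hemiplegia", "pneumonia",
                         "aphasia", "swallowing_disorder", "facial_paralysis",
                         "dementia", "cognitive_impairment", "depression",
                         "hypertension", "diabetes", "atrial_fibrillation",
                         "coronary_heart_disease", "hyperlipidemia",
                         "hyperhomocysteinemia"),
       hospital_levels = c("A", "B", "C"),
       consciousness_levels = 0:3,
       ability_range = c(0, 100))
}

#' Fit standardisation statistics on training metadata
#'
#' Means and standard deviations of the continuous fields (`age`,
#' `first_ability_score`), to be fitted on the training split only and reused
#' for every later vectorisation (no test-set leakage).
#'
#' @param records list of `"sf_metadata"` records (training split).
#' @return An `"sf_meta_stats"` object.
#' @export
fit_metadata_stats <- function(records) {
  age <- vapply(records, function(r) r$age, numeric(1))
  ab <- vapply(records, function(r) r$first_ability_score, numeric(1))
  structure(list(age_mean = mean(age), age_sd = max(stats::sd(age), 1e-6),
                 ability_mean = mean(ab), ability_sd = max(stats::sd(ab), 1e-6),
                 n = length(records)),
            class = "sf_meta_stats")
}

#' Vectorise one metadata record
#'
#' Binary fields map to 0/1, `hospital` to a one-hot triple, `consciousness`
#' to its ordinal level scaled to `[0, 1]`, and `age` /
#' `first_ability_score` to z-scores under `train_stats`. The concatenation
#' order is fixed by the schema; an unseen hospital category is an error (no
#' silent bucket).
#'
#' @param record an `"sf_metadata"` record (or named list with the 19 fields).
#' @param schema see [metadata_schema()].
#' @param train_stats an `"sf_meta_stats"` fitted on the training split.
#' @return Named numeric vector of length 22 with attribute `field_slices`
#'   mapping each field to its index range.
#' @export
vectorize_metadata <- function(record, schema = metadata_schema(), train_stats) {
  if (missing(train_stats) || !inherits(train_stats, "sf_meta_stats"))
    stopf("train_stats must be an 'sf_meta_stats' fitted on the training split")
  missing_f <- setdiff(schema$fields, names(record))
  if (length(missing_f))
    stopf("metadata record is missing field(s): %s",
          paste(missing_f, collapse = ", "))
  if (!record$hospital %in% schema$hospital_levels)
    stopf("unseen hospital category '%s' (known: %s)", record$hospital,
          paste(schema$hospital_levels, collapse = ", "))
  hos <- as.numeric(schema$hospital_levels == record$hospital)
  names(hos) <- paste0("hospital_", schema$hospital_levels)
  bin <- vapply(schema$binary_fields, function(f) {
    v <- as.numeric(record[[f]])
    if (!v %in% c(0, 1)) stopf("field '%s' must be binary, got %s", f, v)
    v
  }, numeric(1))
  con <- c(consciousness = record$consciousness / max(schema$consciousness_levels))
  age <- c(age = (record$age - train_stats$age_mean) / train_stats$age_sd)
  ab <- c(first_ability_score =
            (record$first_ability_score - train_stats$ability_mean) /
            train_stats$ability_sd)
  v <- c(hos, bin, con, age, ab)
  slices <- list()
  pos <- 1L
  add <- function(field, len) {
    slices[[field]] <<- pos:(pos + len - 1L)
    pos <<- pos + len
  }
  add("hospital", 3L)
  for (f in schema$binary_fields) add(f, 1L)
  add("consciousness", 1L); add("age", 1L); add("first_ability_score", 1L)
  attr(v, "field_slices") <- slices
  v
}

metadata_vector_length <- function(schema = metadata_schema()) {
  3L + length(schema$binary_fields) + 3L
}

#' Initialise the metadata encoder
#'
#' Two dense layers of `width` neurons, each followed by batch normalisation
#' and ReLU; 25% dropout after the first dense block.
#'
#' @param in_dim input vector length (22 for the default schema).
#' @param width layer width (256 in the reference design).
#' @param dropout dropout rate after the first block.
#' @param seed integer seed.
#' @return An `"sf_meta_encoder"`: `params` (dense + BN affine), `state`
#'   (BN running statistics), `dropout`.
#' @export
metadata_encoder <- function(in_dim = metadata_vector_length(), width = 256,
                             dropout = 0.25, seed = 1) {
  par <- with_seed(seed, list(
    W1 = he_mat(in_dim, width), b1 = numeric(width),
    bn1 = list(g = rep(1, width), b = numeric(width)),
    W2 = he_mat(width, width), b2 = numeric(width),
    bn2 = list(g = rep(1, width), b = numeric(width))))
  structure(list(params = par, state = list(bn1 = bn_state(width),
                                            bn2 = bn_state(width)),
                 dropout = dropout, width = width, in_dim = in_dim),
            class = "sf_meta_encoder")
}

## Batched forward. X: n x in_dim. Returns Y (n x width, F2), cache, state.
meta_fwd <- function(par, state, X, dropout, mode, bn_momentum = 0.1) {
  d1 <- dense_fwd(X, par$W1, par$b1)
  n1 <- bn_fwd(d1$Y, par$bn1$g, par$bn1$b, state$bn1, mode, bn_momentum)
  r1 <- relu_fwd(n1$Y)
  dp <- dropout_fwd(r1$Y, dropout, mode)
  d2 <- dense_fwd(dp$Y, par$W2, par$b2)
  n2 <- bn_fwd(d2$Y, par$bn2$g, par$bn2$b, state$bn2, mode, bn_momentum)
  r2 <- relu_fwd(n2$Y)
  list(Y = r2$Y, cache = list(d1 = d1, n1 = n1, r1 = r1, dp = dp, d2 = d2,
                              n2 = n2, r2 = r2),
       state = list(bn1 = n1$state, bn2 = n2$state))
}

meta_bwd <- function(dY, cache, par) {
  dr2 <- relu_bwd(dY, cache$r2)
  b2 <- bn_bwd(dr2, cache$n2$cache)
  dd2 <- dense_bwd(b2$dX, cache$d2, par$W2)
  ddp <- dropout_bwd(dd2$dX, cache$dp)
  dr1 <- relu_bwd(ddp, cache$r1)
  b1 <- bn_bwd(dr1, cache$n1$cache)
  dd1 <- dense_bwd(b1$dX, cache$d1, par$W1)
  list(dX = dd1$dX,
       grads = list(W1 = dd1$dW, b1 = dd1$db,
                    bn1 = list(g = b1$dgamma, b = b1$dbeta),
                    W2 = dd2$dW, b2 = dd2$db,
                    bn2 = list(g = b2$dgamma, b = b2$dbeta)))
}

#' Encode metadata vectors into F2
#'
#' `dense(width) -> BN -> ReLU -> dropout -> dense(width) -> BN -> ReLU`.
#' Dropout is active only in `"train"` mode; inference uses BN running
#' statistics and is deterministic. The output is elementwise nonnegative
#' (final ReLU).
#'
#' @param encoder an [metadata_encoder()].
#' @param x a metadata vector (from [vectorize_metadata()]) or a matrix with
#'   one vector per row.
#' @param mode `"train"` or `"infer"`.
#' @return Embedding matrix (n x width); a single input returns a length-
#'   `width` vector (F2).
#' @export
encode_metadata <- function(encoder, x, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  stopifnot(all(is.finite(X)), ncol(X) == encoder$in_dim)
  out <- meta_fwd(encoder$params, encoder$state, X, encoder$dropout, mode)
  if (is.matrix(x)) out$Y else as.vector(out$Y)
}
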