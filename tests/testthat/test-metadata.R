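make_record <- function(...) {
  base <- sample_metadata(0, seed = 1)
  over <- list(...)
  base[names(over)] <- over
  base
}

test_that("vectorize_metadata matches hand-computed encodings", {
  schema <- metadata_schema()
  recs <- list(
    make_record(hospital = "A", gender = 1, age = 70, consciousness = 3,
                hemiplegia = 1, first_ability_score = 40),
    make_record(hospital = "B", gender = 0, age = 60, consciousness = 0,
                hemiplegia = 0, first_ability_score = 80),
    make_record(hospital = "C", gender = 1, age = 80, consciousness = 1,
                hemiplegia = 1, first_ability_score = 60))
  stats <- fit_metadata_stats(recs)
  expect_equal(stats$age_mean, 70)
  expect_equal(stats$age_sd, 10)

  v <- vectorize_metadata(recs[[1]], schema, stats)
  expect_length(v, 22L)
  expect_equal(unname(v[1:3]), c(1, 0, 0))                  # hospital one-hot
  expect_equal(unname(v[["consciousness"]]), 1)             # 3/3
  expect_equal(unname(v[["age"]]), 0)                       # z-score of mean
  expect_equal(unname(v[["first_ability_score"]]),
               (40 - 60) / sd(c(40, 80, 60)))
  expect_equal(unname(v[["hemiplegia"]]), 1)
  sl <- attr(v, "field_slices")
  expect_equal(sl$hospital, 1:3)
  expect_equal(sl$first_ability_score, 22L)

  ## identical records -> identical vectors
  expect_identical(vectorize_metadata(recs[[2]], schema, stats),
                   vectorize_metadata(recs[[2]], schema, stats))

  ## standardisation uses the supplied (training) stats only
  stats2 <- fit_metadata_stats(recs[2:3])
  expect_false(isTRUE(all.equal(
    vectorize_metadata(recs[[1]], schema, stats)[["first_ability_score"]],
    vectorize_metadata(recs[[1]], schema, stats2)[["first_ability_score"]])))
})

test_that("vectorize_metadata errors name the offending field", {
  recs <- list(make_record(), make_record(age = 50))
  stats <- fit_metadata_stats(recs)
  broken <- make_record()
  broken$atrial_fibrillation <- NULL
  expect_error(vectorize_metadata(broken, train_stats = stats),
               "atrial_fibrillation")
  odd <- make_record(hospital = "Z")
  expect_error(vectorize_metadata(odd, train_stats = stats), "unseen hospital")
  expect_error(vectorize_metadata(make_record(), train_stats = NULL),
               "sf_meta_stats")
})

test_that("metadata encoder obeys the F2 contract", {
  enc <- metadata_encoder(seed = 4)              # reference width 256
  x <- withr::with_seed(2, rnorm(22))
  f2 <- encode_metadata(enc, x, mode = "infer")
  expect_length(f2, 256L)
  expect_true(all(is.finite(f2)))
  expect_true(all(f2 >= 0))                      # final ReLU
  expect_identical(f2, encode_metadata(enc, x, mode = "infer"))

  ## zero network with unit-affine BN emits exactly zero
  enc0 <- metadata_encoder(seed = 4)
  enc0$params <- sf_ns$zero_like(enc0$params)
  expect_true(all(encode_metadata(enc0, x) == 0))

  ## nonnegativity across random weights and inputs
  for (i in 1:10) {
    e <- metadata_encoder(width = 16, seed = i)
    xx <- withr::with_seed(50 + i, matrix(rnorm(3 * 22), 3))
    expect_true(all(encode_metadata(e, xx, mode = "infer") >= 0))
  }
})

test_that("train-mode dropout removes ~25% with inverted scaling", {
  X <- matrix(1, 100, 100)                       # 10,000 units
  withr::with_seed(99, {
    out <- sf_ns$dropout_fwd(X, 0.25, "train")
  })
  frac <- mean(out$Y == 0)
  expect_gt(frac, 0.23); expect_lt(frac, 0.27)
  expect_equal(mean(out$Y), 1, tolerance = 0.02) # E[inverted dropout] = input
  ## inactive at inference
  expect_identical(sf_ns$dropout_fwd(X, 0.25, "infer")$Y, X)
})
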