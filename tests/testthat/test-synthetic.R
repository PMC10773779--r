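test_that("render_slice honours the lesion specification", {
  ## no lesion -> empty mask
  img0 <- render_slice(lesion_spec(c(32, 32), 0), image_size = 64, seed = 3)
  expect_true(all(img0$lesion_mask == 0))
  expect_true(all(img0$pixels >= 0 & img0$pixels <= 1))

  ## seeded determinism, bit-identical
  a <- render_slice(lesion_spec(c(30, 28), 7), image_size = 64, seed = 11)
  b <- render_slice(lesion_spec(c(30, 28), 7), image_size = 64, seed = 11)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$lesion_mask, b$lesion_mask)

  ## circular lesion vs brute-force rasterisation oracle
  img <- render_slice(lesion_spec(c(31.5, 31.5), 8, shape_irregularity = 0),
                      image_size = 64, seed = 5)
  hh <- matrix(seq_len(64), 64, 64)
  ww <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  oracle <- sqrt((hh - 32.5)^2 + (ww - 32.5)^2) <= 8
  expect_identical(unname(img$lesion_mask), unname(oracle))
  area <- sum(img$lesion_mask)
  expect_lt(abs(area - pi * 64) / (pi * 64), 0.15)
})

test_that("render_slice rejects invalid specifications", {
  expect_error(render_slice(lesion_spec(c(200, 10), 5), image_size = 64),
               "outside image bounds")
  expect_error(lesion_spec(c(10, 10), -1), "nonnegative")
  expect_error(lesion_spec(c(10, 10), 5, shape_irregularity = 1.5), "\\[0, 1\\]")
})

test_that("sample_metadata matches its label-conditional contract", {
  ## identical record for identical seed
  r1 <- sample_metadata(1, seed = 42)
  r2 <- sample_metadata(1, seed = 42)
  expect_identical(r1, r2)
  expect_named(r1, sf_ns$metadata_field_names())

  ## unknown field is an error
  expect_error(sample_metadata(0, effect_sizes = c(bogus_field = 1)),
               "bogus_field")

  ## zero effects: label-conditional distributions coincide (frequency oracle)
  n <- 5000
  zero_eff <- setNames(numeric(0), character(0))
  draw <- function(lab, off) vapply(seq_len(n), function(i) {
    r <- sample_metadata(lab, effect_sizes = zero_eff, seed = off + i)
    c(r$hemiplegia, r$pneumonia, r$hypertension, r$consciousness > 0)
  }, numeric(4))
  f0 <- rowMeans(draw(0, 0))
  f1 <- rowMeans(draw(1, 0))       # same seeds: identical streams when eff = 0
  expect_lt(max(abs(f0 - f1)), 0.03)

  ## positive effect raises the conditional frequency
  m <- 2000
  eff <- c(hemiplegia = 2.0)
  h0 <- mean(vapply(seq_len(m), function(i)
    sample_metadata(0, eff, seed = 10000 + i)$hemiplegia, numeric(1)))
  h1 <- mean(vapply(seq_len(m), function(i)
    sample_metadata(1, eff, seed = 20000 + i)$hemiplegia, numeric(1)))
  expect_gt(h1, h0)
})

test_that("generate_cohort counts, balance and burden structure", {
  co <- generate_cohort(10, slices_per_patient = 3, image_size = 32, seed = 2)
  expect_length(co$samples, 30L)
  expect_length(unique(vapply(co$samples, function(s) s$image$patient_id,
                              character(1))), 10L)

  ## class balance: binomial 99% interval around 100/200
  cb <- generate_cohort(200, slices_per_patient = 1, image_size = 32, seed = 9)
  expect_gte(sum(cb$patients$label == 1), 80)
  expect_lte(sum(cb$patients$label == 1), 120)

  ## argument validation
  expect_error(generate_cohort(10, class_balance = 1.2), "class_balance")
  expect_error(generate_cohort(1), "n_patients")
})

test_that("a 100-patient cohort satisfies all type invariants and is learnable", {
  co <- generate_cohort(100, slices_per_patient = 2, image_size = 32, seed = 13)
  pat <- co$patients
  expect_true(all(pat$label %in% c(0, 1)))
  meta_by_pid <- list()
  for (s in co$samples) {
    img <- s$image
    expect_true(all(is.finite(img$pixels)))
    expect_true(all(img$pixels >= 0 & img$pixels <= 1))
    expect_identical(dim(img$lesion_mask), dim(img$pixels))
    expect_length(s$metadata, length(sf_ns$metadata_field_names()))
    expect_gt(s$metadata$age, 0)
    expect_true(s$metadata$first_ability_score >= 0 &&
                  s$metadata$first_ability_score <= 100)
    pid <- img$patient_id
    if (is.null(meta_by_pid[[pid]])) meta_by_pid[[pid]] <- s$metadata
    else expect_identical(meta_by_pid[[pid]], s$metadata)  # shared per patient
  }
  ## poor-prognosis patients carry more lesion area on average
  expect_gt(mean(pat$area_frac[pat$label == 1]),
            mean(pat$area_frac[pat$label == 0]))
  ## trivial area-threshold patient-level classifier clears 0.7 accuracy
  best <- max(vapply(sort(unique(pat$area_frac)), function(th)
    mean((pat$area_frac > th) == pat$label), numeric(1)))
  expect_gt(best, 0.7)
})

test_that("generation is a pure function of (parameters, seed)", {
  a <- generate_cohort(6, slices_per_patient = 2, image_size = 32, seed = 77)
  b <- generate_cohort(6, slices_per_patient = 2, image_size = 32, seed = 77)
  expect_identical(a$patients, b$patients)
  expect_identical(lapply(a$samples, function(s) s$image$pixels),
                   lapply(b$samples, function(s) s$image$pixels))
  d <- generate_cohort(6, slices_per_patient = 2, image_size = 32, seed = 78)
  expect_false(identical(a$samples[[1]]$image$pixels,
                         d$samples[[1]]$image$pixels))
})

test_that("split_cohort and cohort_subset are patient-level", {
  co <- split_cohort(tiny_cohort(), test_frac = 0.25, seed = 4)
  expect_setequal(unique(co$patients$split), c("train", "test"))
  te <- co$patients$patient_id[co$patients$split == "test"]
  sub <- cohort_subset(co, te)
  expect_setequal(unique(vapply(sub$samples, function(s) s$image$patient_id,
                                character(1))), te)
})
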