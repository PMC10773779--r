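## Synthetic cohort generator: lesion-bearing brain-like 2-D slices with ground
## truth masks, plus label-correlated clinical metadata. This is a stated
## stand-in for the private hospital cohort the model family was designed for:
## lesions vary in location, size and appearance, a configurable fraction of
## poor-prognosis patients carry small ("mild") lesions, and the patient label
## is drawn from a logistic link on lesion burden and selected metadata.

#' Lesion specification
#'
#' @param center numeric length-2 `(row, col)` in 0-based pixel coordinates,
#'   origin top-left.
#' @param radius lesion radius in pixels; `0` means no lesion.
#' @param intensity_delta contrast added to the background (DWI-like bright
#'   lesions are positive).
#' @param shape_irregularity boundary perturbation amplitude in `[0, 1]`;
#'   `0` gives an exact disc.
#' @return An object of class `"lesion_spec"`.
#' @export
lesion_spec <- function(center, radius, intensity_delta = 0.35,
                        shape_irregularity = 0.3) {
  if (length(center) != 2 || !all(is.finite(center)))
    stopf("center must be two finite pixel coordinates")
  if (!is_scalar_num(radius) || radius < 0)
    stopf("radius must be a nonnegative number, got %s", format(radius))
  if (!is_scalar_num(shape_irregularity) || shape_irregularity < 0 ||
      shape_irregularity > 1)
    stopf("shape_irregularity must be in [0, 1]")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 intensity_delta = as.numeric(intensity_delta),
                 shape_irregularity = as.numeric(shape_irregularity)),
            class = "lesion_spec")
}

## Dense Gaussian smoothing operator (row matrix); n is small so an n x n
## matrix product is the simplest exact implementation.
smooth_mat <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

## Render one slice from a list of lesion_spec. Internal; the exported
## render_slice() wraps the single-lesion case.
render_slice_impl <- function(specs, image_size, noise_sd, seed,
                              patient_id = "P000", slice_index = 0L) {
  n <- as.integer(image_size)
  if (n < 16) stopf("image_size must be >= 16, got %d", n)
  for (sp in specs) {
    if (any(sp$center < 0) || any(sp$center > n - 1))
      stopf("lesion center (%.1f, %.1f) outside image bounds [0, %d]",
            sp$center[1], sp$center[2], n - 1)
  }
  with_seed(seed, {
    h <- matrix(seq_len(n), n, n)          # row index
    w <- matrix(seq_len(n), n, n, byrow = TRUE)
    c0 <- (n + 1) / 2
    a <- 0.45 * n; b <- 0.38 * n
    rr <- sqrt(((h - c0) / a)^2 + ((w - c0) / b)^2)
    brain <- rr <= 1
    Sm <- smooth_mat(n, sigma = 2)
    tex <- Sm %*% matrix(stats::rnorm(n * n), n, n) %*% t(Sm)
    tex <- tex / max(stats::sd(tex), 1e-9) * noise_sd
    pixels <- matrix(0.02, n, n)
    pixels[brain] <- 0.35 + 0.1 * (1 - rr[brain]) + tex[brain]
    mask <- matrix(FALSE, n, n)
    for (sp in specs) {
      if (sp$radius <= 0) next
      ch <- sp$center[1] + 1; cw <- sp$center[2] + 1    # to 1-based
      d <- sqrt((h - ch)^2 + (w - cw)^2)
      theta <- atan2(h - ch, w - cw)
      amp <- stats::rnorm(3)
      phi <- stats::runif(3, 0, 2 * pi)
      s <- (amp[1] * cos(2 * theta + phi[1]) + amp[2] * cos(3 * theta + phi[2]) +
              amp[3] * cos(4 * theta + phi[3])) / (sum(abs(amp)) + 1e-9)
      rb <- sp$radius * (1 + sp$shape_irregularity * s)
      lm <- (d <= rb) & brain
      lm[round(ch), round(cw)] <- TRUE                  # radius > 0 => nonempty
      pixels <- pixels + sp$intensity_delta * sigmoid((rb - d) / 0.8) * brain
      mask <- mask | lm
    }
    pixels <- pmin(pmax(pixels, 0), 1)
    structure(list(pixels = pixels, patient_id = patient_id,
                   slice_index = as.integer(slice_index),
                   lesion_mask = mask),
              class = "sf_image")
  })
}

#' Render one synthetic brain slice
#'
#' Draws a smooth elliptical brain silhouette with Gaussian-smoothed texture
#' noise and renders the lesion as an irregular blob of shifted intensity.
#' Deterministic given `seed`.
#'
#' @param spec a [lesion_spec()].
#' @param image_size side length in pixels (>= 16).
#' @param noise_sd standard deviation of the background texture.
#' @param seed integer seed.
#' @return An `"sf_image"`: list with `pixels` (H x W in `[0, 1]`),
#'   `patient_id`, `slice_index`, and binary `lesion_mask` (nonzero iff
#'   `radius > 0`).
#' @export
render_slice <- function(spec, image_size = 64, noise_sd = 0.04, seed = 1) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (!is_scalar_num(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  render_slice_impl(list(spec), image_size, noise_sd, seed)
}

#' Default label-conditional metadata effect sizes
#'
#' Log-odds shifts for binary fields and the ordinal consciousness level, and
#' additive mean shifts (years / score points) for `age` and
#' `first_ability_score`, applied for the poor-prognosis class.
#' @return Named numeric vector whose names are metadata fields.
#' @export
default_effect_sizes <- function() {
  c(disorder = 0.8, consciousness = 2.0, hemiplegia = 2.0, pneumonia = 1.0,
    aphasia = 0.8, swallowing_disorder = 1.0, facial_paralysis = 0.5,
    dementia = 0.6, cognitive_impairment = 0.8, depression = 0.3,
    hypertension = 0.3, diabetes = 0.3, atrial_fibrillation = 0.8,
    coronary_heart_disease = 0.4, hyperlipidemia = 0.2,
    hyperhomocysteinemia = 0.3, age = 4, first_ability_score = -35)
}

## Static generator settings for the 19 fields.
metadata_gen_config <- function() {
  list(
    hospital_levels = c("A", "B", "C"),
    hospital_probs = c(0.5, 0.3, 0.2),
    base_probs = c(gender = 0.5, disorder = 0.3, hemiplegia = 0.35,
                   pneumonia = 0.2, aphasia = 0.25, swallowing_disorder = 0.2,
                   facial_paralysis = 0.3, dementia = 0.1,
                   cognitive_impairment = 0.15, depression = 0.15,
                   hypertension = 0.55, diabetes = 0.3,
                   atrial_fibrillation = 0.15, coronary_heart_disease = 0.2,
                   hyperlipidemia = 0.35, hyperhomocysteinemia = 0.2),
    consciousness_probs = c(0.7, 0.2, 0.07, 0.03),  # alert .. coma (0..3)
    age = list(mean = 68, sd = 10, range = c(30, 95)),
    ability = list(mean = 70, sd = 15, range = c(0, 100))
  )
}

metadata_field_names <- function() {
  c("hospital", "gender", "age", "disorder", "consciousness", "hemiplegia",
    "pneumonia", "aphasia", "swallowing_disorder", "facial_paralysis",
    "dementia", "cognitive_impairment", "depression", "first_ability_score",
    "hypertension", "diabetes", "atrial_fibrillation",
    "coronary_heart_disease", "hyperlipidemia", "hyperhomocysteinemia")
}

#' Draw one label-conditional clinical metadata record
#'
#' Binary fields are Bernoulli with label-conditional probabilities obtained by
#' shifting the base log-odds by `effect_sizes[field]` for the positive class;
#' consciousness is an ordinal (0 alert .. 3 coma) drawn through a shifted
#' latent logistic; `age` and `first_ability_score` are truncated normals whose
#' means shift additively. With all effect sizes zero the two label-conditional
#' distributions coincide exactly. Deterministic given `seed`.
#'
#' @param label 0 (eusemia) or 1 (poor prognosis).
#' @param effect_sizes named numeric vector, names a subset of the 19 fields;
#'   see [default_effect_sizes()].
#' @param seed integer seed.
#' @return An `"sf_metadata"` record: named list of the 19 clinical fields.
#' @export
sample_metadata <- function(label, effect_sizes = default_effect_sizes(),
                            seed = 1) {
  stopifnot(label %in% c(0, 1))
  cfg <- metadata_gen_config()
  bad <- setdiff(names(effect_sizes), metadata_field_names())
  if (length(bad))
    stopf("unknown metadata field(s) in effect_sizes: %s",
          paste(bad, collapse = ", "))
  eff <- function(f) if (f %in% names(effect_sizes)) effect_sizes[[f]] else 0
  with_seed(seed, {
    rec <- list()
    rec$hospital <- sample(cfg$hospital_levels, 1, prob = cfg$hospital_probs)
    for (f in names(cfg$base_probs)) {
      p <- stats::plogis(stats::qlogis(cfg$base_probs[[f]]) + label * eff(f))
      rec[[f]] <- stats::rbinom(1, 1, p)
    }
    cuts <- stats::qlogis(cumsum(cfg$consciousness_probs)[1:3])
    u <- stats::rlogis(1, location = label * eff("consciousness"))
    rec$consciousness <- sum(u > cuts)
    rec$age <- min(max(stats::rnorm(1, cfg$age$mean + label * eff("age"),
                                    cfg$age$sd), cfg$age$range[1]),
                   cfg$age$range[2])
    rec$first_ability_score <- min(max(
      stats::rnorm(1, cfg$ability$mean + label * eff("first_ability_score"),
                   cfg$ability$sd), cfg$ability$range[1]), cfg$ability$range[2])
    structure(rec[metadata_field_names()], class = "sf_metadata")
  })
}

#' Default patient-level label model
#'
#' Logistic link on lesion burden and metadata:
#' `logit P(poor) = b0 + 16 * (20 * area_frac) + 2 * count + 4 * meta`,
#' where `area_frac` is the mean lesion-mask fraction across the patient's
#' slices, `count` the number of rendered lesions, and
#' `meta = hemiplegia + consciousness/3 - (first_ability_score - 50)/30`.
#' The intercept `b0` (if `NULL`) is calibrated at generation time so the
#' marginal positive rate equals `class_balance`. The coefficient scale keeps
#' the Bayes accuracy of the task around 0.97 (patient level): label noise
#' exists but the cohort is, by construction, clearly separable.
#' @return list of coefficients.
#' @export
default_label_model <- function() {
  list(beta0 = NULL, beta_area = 16, beta_count = 2, beta_meta = 4)
}

meta_score <- function(rec) {
  rec$hemiplegia + rec$consciousness / 3 - (rec$first_ability_score - 50) / 30
}

#' Generate a synthetic patient cohort
#'
#' Each patient gets an intended-severity class (Bernoulli `class_balance`),
#' label-conditional lesions (poor-prognosis patients receive larger and more
#' lesions on average; a `small_lesion_fraction` of them receive "mild"
#' sub-threshold lesions), label-conditional metadata, and
#' `slices_per_patient` rendered slices sharing the patient's lesions (with
#' per-slice radius scaling and centre jitter, emulating adjacent cuts).
#' The final patient label is then drawn from the logistic `label_model` on
#' (lesion area, lesion count, metadata score). Pure function of its
#' arguments and `seed`.
#'
#' @param n_patients number of patients (>= 2).
#' @param slices_per_patient slices per patient (>= 1); default 9 mirrors the
#'   ~9.2 slices/patient ratio of the reference cohort.
#' @param class_balance intended positive fraction, in (0, 1).
#' @param small_lesion_fraction fraction of intended-poor patients receiving
#'   small ("mild") lesions, in `[0, 1]`.
#' @param label_model see [default_label_model()].
#' @param image_size slice side length in pixels.
#' @param noise_sd background texture SD.
#' @param effect_sizes metadata effects, see [default_effect_sizes()].
#' @param seed integer seed.
#' @return An `"sf_cohort"`: list with `samples` (one element per slice:
#'   `image`, `metadata`, `label`), `patients` (data frame with per-patient
#'   label, lesion burden and metadata score) and the generation parameters.
#' @export
generate_cohort <- function(n_patients, slices_per_patient = 9,
                            class_balance = 0.5, small_lesion_fraction = 0.4,
                            label_model = default_label_model(),
                            image_size = 64, noise_sd = 0.04,
                            effect_sizes = default_effect_sizes(), seed = 1) {
  if (n_patients < 2) stopf("n_patients must be >= 2")
  if (slices_per_patient < 1) stopf("slices_per_patient must be >= 1")
  if (!is_scalar_num(class_balance) || class_balance <= 0 || class_balance >= 1)
    stopf("class_balance must lie strictly inside (0, 1)")
  if (small_lesion_fraction < 0 || small_lesion_fraction > 1)
    stopf("small_lesion_fraction must be in [0, 1]")
  n <- as.integer(image_size)

  patients <- vector("list", n_patients)
  samples <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d", i)
    sev <- with_seed(derive_seed(seed, i * 101 + 1), stats::rbinom(1, 1, class_balance))
    plan <- with_seed(derive_seed(seed, i * 101 + 2), {
      if (sev == 1) {
        n_les <- 1 + stats::rbinom(1, 2, 0.4)
        mild <- stats::runif(1) < small_lesion_fraction
        radii <- if (mild) stats::runif(n_les, 0.025, 0.055) * n
                 else stats::runif(n_les, 0.125, 0.25) * n
      } else {
        n_les <- stats::rbinom(1, 1, 0.7)
        mild <- FALSE
        radii <- if (n_les > 0) stats::runif(n_les, 0.02, 0.125) * n else numeric(0)
      }
      specs <- lapply(seq_len(n_les), function(j) {
        repeat {
          ctr <- c(stats::runif(1, 0.25 * n, 0.75 * n),
                   stats::runif(1, 0.25 * n, 0.75 * n))
          c0 <- (n + 1) / 2
          if (((ctr[1] + 1 - c0) / (0.35 * n))^2 +
              ((ctr[2] + 1 - c0) / (0.30 * n))^2 <= 1) break
        }
        lesion_spec(ctr, radii[j], intensity_delta = stats::runif(1, 0.25, 0.45),
                    shape_irregularity = stats::runif(1, 0.2, 0.5))
      })
      list(n_les = n_les, mild = mild, specs = specs)
    })
    meta <- sample_metadata(sev, effect_sizes, derive_seed(seed, i * 101 + 3))
    areas <- numeric(slices_per_patient)
    for (k in seq_len(slices_per_patient)) {
      sseed <- derive_seed(seed, i * 101 + 10 + k)
      sl_specs <- with_seed(sseed, lapply(plan$specs, function(sp) {
        f <- stats::runif(1, 0.6, 1)
        ctr <- pmin(pmax(sp$center + stats::rnorm(2, 0, 0.01 * n), 0), n - 1)
        lesion_spec(ctr, sp$radius * f, sp$intensity_delta, sp$shape_irregularity)
      }))
      img <- render_slice_impl(sl_specs, n, noise_sd, derive_seed(sseed, 7),
                               patient_id = pid, slice_index = k - 1L)
      areas[k] <- mean(img$lesion_mask)
      samples[[length(samples) + 1L]] <- list(image = img, metadata = meta,
                                              label = NA_integer_)
    }
    patients[[i]] <- data.frame(
      patient_id = pid, intended = sev, lesion_count = plan$n_les,
      mild = plan$mild, area_frac = mean(areas), meta_score = meta_score(meta),
      stringsAsFactors = FALSE)
  }
  pat <- do.call(rbind, patients)

  lm <- label_model
  eta <- lm$beta_area * 20 * pat$area_frac + lm$beta_count * pat$lesion_count +
    lm$beta_meta * pat$meta_score
  b0 <- lm$beta0
  if (is.null(b0)) {
    f <- function(b) mean(stats::plogis(b + eta)) - class_balance
    b0 <- stats::uniroot(f, c(-50, 50))$root
  }
  p_poor <- stats::plogis(b0 + eta)
  pat$label <- vapply(seq_len(nrow(pat)), function(i)
    with_seed(derive_seed(seed, i * 101 + 99), stats::rbinom(1, 1, p_poor[i])),
    integer(1))
  pat$p_poor <- p_poor

  lab_of <- stats::setNames(pat$label, pat$patient_id)
  for (j in seq_along(samples))
    samples[[j]]$label <- unname(lab_of[samples[[j]]$image$patient_id])

  structure(list(samples = samples, patients = pat,
                 image_size = n, slices_per_patient = as.integer(slices_per_patient),
                 class_balance = class_balance, label_model = c(lm, list(beta0_used = b0)),
                 seed = seed),
            class = "sf_cohort")
}

#' @export
print.sf_cohort <- function(x, ...) {
  cat(sprintf("sf_cohort: %d patients x %d slices (%dpx), %d poor / %d eusemia\n",
              nrow(x$patients), x$slices_per_patient, x$image_size,
              sum(x$patients$label == 1), sum(x$patients$label == 0)))
  invisible(x)
}

#' Assign a patient-level stratified train/test split
#'
#' @param cohort an `"sf_cohort"`.
#' @param test_frac fraction of patients per class held out.
#' @param seed integer seed.
#' @return The cohort with a `split` column (`"train"`/`"test"`) in `patients`.
#' @export
split_cohort <- function(cohort, test_frac = 0.2, seed = 1) {
  pat <- cohort$patients
  split <- rep("train", nrow(pat))
  with_seed(seed, for (cl in c(0, 1)) {
    idx <- which(pat$label == cl)
    nt <- max(1L, round(length(idx) * test_frac))
    split[sample(idx, nt)] <- "test"
  })
  cohort$patients$split <- split
  cohort
}

#' Subset a cohort by patient id
#' @param cohort an `"sf_cohort"`.
#' @param patient_ids character vector of patient ids to keep.
#' @return The sub-cohort.
#' @export
cohort_subset <- function(cohort, patient_ids) {
  keep <- vapply(cohort$samples, function(s) s$image$patient_id %in% patient_ids,
                 logical(1))
  cohort$samples <- cohort$samples[keep]
  cohort$patients <- cohort$patients[cohort$patients$patient_id %in% patient_ids, ,
                                     drop = FALSE]
  cohort
}

cohort_slice_labels <- function(cohort)
  vapply(cohort$samples, function(s) as.integer(s$label), integer(1))

cohort_slice_patients <- function(cohort)
  vapply(cohort$samples, function(s) s$image$patient_id, character(1))
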