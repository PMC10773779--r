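## Readers and writers. Slices and masks are stored as PGM (binary P5 by
## default, ASCII P2 optionally) - a standard, self-describing grayscale
## format writable without external codecs; CSV matrices are also accepted.
## Metadata, manifests, metrics and ablation tables are CSV; configs and
## metric reports are JSON. All writes are atomic (temp file + rename).

#' Write a grayscale image as PGM
#'
#' @param mat numeric H x W matrix in `[0, 1]`.
#' @param path output path.
#' @param ascii write plain-text P2 instead of binary P5.
#' @return the path, invisibly.
#' @export
write_pgm <- function(mat, path, ascii = FALSE) {
  stopifnot(is.matrix(mat), all(is.finite(mat)))
  v <- round(pmin(pmax(mat, 0), 1) * 255)
  atomic_write(path, function(tmp) {
    if (ascii) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines(c("P2", paste(ncol(mat), nrow(mat)), "255"), con)
      ## row-major pixel order per the format
      write(as.integer(t(v)), con, ncolumns = 12L)
    } else {
      con <- file(tmp, "wb")
      on.exit(close(con))
      writeChar(sprintf("P5\n%d %d\n255\n", ncol(mat), nrow(mat)), con,
                eos = NULL)
      writeBin(as.raw(as.integer(t(v))), con)
    }
  })
}

#' Read a PGM image
#' @param path a P2 or P5 PGM file.
#' @return numeric H x W matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stopf("image file '%s' not found", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  n <- length(raw)
  ## header: magic, width, height, maxval separated by whitespace; '#'
  ## comments; parsed on raw bytes (the P5 payload is binary)
  ws <- as.raw(c(9L, 10L, 11L, 12L, 13L, 32L))
  pos <- 1L
  tokens <- character(0)
  while (length(tokens) < 4L && pos <= n) {
    b <- raw[pos]
    if (b == as.raw(35L)) {                       # '#'
      while (pos <= n && raw[pos] != as.raw(10L)) pos <- pos + 1L
    } else if (b %in% ws) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= n && !(raw[pos] %in% ws)) pos <- pos + 1L
      tokens <- c(tokens, rawToChar(raw[start:(pos - 1L)]))
    }
  }
  if (length(tokens) < 4L || !tokens[1] %in% c("P2", "P5"))
    stopf("'%s' is not a P2/P5 PGM file", path)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (tokens[1] == "P5") {
    ## exactly one whitespace byte separates the maxval token from the data
    vals <- as.integer(raw[(pos + 1L):(pos + h * w)])
  } else {
    toks <- strsplit(gsub("#[^\n]*", "", rawToChar(raw)), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- as.integer(toks[5:(4L + h * w)])
  }
  matrix(vals / maxval, h, w, byrow = TRUE)
}

#' Load a slice image
#'
#' Reads a PGM (or CSV matrix) file, min-max scales intensities to `[0, 1]`
#' per slice (a constant image becomes all zeros) and bilinearly resizes to
#' `target_size`.
#'
#' @param path image path (`.pgm` or `.csv`).
#' @param target_size output side length (square).
#' @return numeric `target_size` x `target_size` matrix in `[0, 1]`.
#' @export
load_image <- function(path, target_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  M <- switch(ext,
              pgm = read_pgm(path),
              csv = as.matrix(utils::read.csv(path, header = FALSE)),
              stopf("unsupported image format '%s' for '%s' (use pgm or csv)",
                    ext, path))
  if (!all(is.finite(M))) stopf("non-finite pixels in '%s'", path)
  rng <- range(M)
  M <- if (rng[2] - rng[1] < 1e-12) matrix(0, nrow(M), ncol(M))
       else (M - rng[1]) / (rng[2] - rng[1])
  if (!is.null(target_size) && (nrow(M) != target_size || ncol(M) != target_size))
    M <- pmin(pmax(upsample_bilinear(M, target_size, target_size), 0), 1)
  unname(M)
}

#' Write / read a metadata CSV
#'
#' One row per patient: `patient_id`, the 19 clinical fields, and optionally
#' `label`. Reading enforces the schema: a missing column or an uncoercible
#' value is an error naming the column / row.
#'
#' @param records list of `"sf_metadata"` records.
#' @param patient_ids character vector aligned with `records`.
#' @param labels optional 0/1 vector.
#' @param path CSV path.
#' @param schema see [metadata_schema()].
#' @return `load_metadata_csv()` returns a list with `records`,
#'   `patient_ids`, and `labels` (NULL if absent).
#' @export
write_metadata_csv <- function(records, patient_ids, path, labels = NULL) {
  stopifnot(length(records) == length(patient_ids))
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(r[metadata_field_names()], stringsAsFactors = FALSE)))
  df <- cbind(data.frame(patient_id = patient_ids, stringsAsFactors = FALSE), df)
  if (!is.null(labels)) df$label <- labels
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
}

#' @rdname write_metadata_csv
#' @export
load_metadata_csv <- function(path, schema = metadata_schema()) {
  if (!file.exists(path)) stopf("metadata file '%s' not found", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", schema$fields)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("metadata CSV is missing column(s): %s", paste(miss, collapse = ", "))
  num_fields <- setdiff(schema$fields, "hospital")
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v))
    if (length(bad))
      stopf("column '%s' has a non-numeric or missing value at row %d",
            f, bad[1])
    df[[f]] <- v
  }
  if (any(!nzchar(df$hospital)))
    stopf("column 'hospital' has an empty value at row %d",
          which(!nzchar(df$hospital))[1])
  records <- lapply(seq_len(nrow(df)), function(i)
    structure(as.list(df[i, schema$fields]), class = "sf_metadata"))
  labels <- if ("label" %in% names(df)) as.integer(df$label) else NULL
  list(records = records, patient_ids = df$patient_id, labels = labels)
}

#' Write a cohort to disk
#'
#' One PGM per slice, one PGM mask per slice, a per-patient metadata CSV and
#' a manifest CSV (slice path, mask path, patient id, slice index, split,
#' label). Paths in the manifest are relative to `dir`.
#'
#' @param cohort an `"sf_cohort"` (split with [split_cohort()] first if you
#'   want a train/test column; otherwise split is `"none"`).
#' @param dir output directory.
#' @param ascii write P2 instead of P5 PGM.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, ascii = FALSE) {
  dir.create(file.path(dir, "slices"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  pat <- cohort$patients
  split <- if ("split" %in% names(pat))
    stats::setNames(pat$split, pat$patient_id)
  else stats::setNames(rep("none", nrow(pat)), pat$patient_id)
  rows <- lapply(cohort$samples, function(s) {
    base <- sprintf("%s_s%02d", s$image$patient_id, s$image$slice_index)
    sp <- file.path("slices", paste0(base, ".pgm"))
    mp <- file.path("masks", paste0(base, "_mask.pgm"))
    write_pgm(s$image$pixels, file.path(dir, sp), ascii = ascii)
    write_pgm(s$image$lesion_mask * 1, file.path(dir, mp), ascii = ascii)
    data.frame(slice_path = sp, mask_path = mp,
               patient_id = s$image$patient_id,
               slice_index = s$image$slice_index,
               split = unname(split[s$image$patient_id]),
               label = s$label, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  first <- !duplicated(pat$patient_id)
  recs <- patient_records(cohort)
  write_metadata_csv(recs, pat$patient_id[first], file.path(dir, "metadata.csv"),
                     labels = pat$label[first])
  mpath <- file.path(dir, "manifest.csv")
  atomic_write(mpath, function(tmp)
    utils::write.csv(manifest, tmp, row.names = FALSE, quote = FALSE))
  invisible(mpath)
}

#' Read a manifest and reconstruct a cohort
#'
#' Validates that every referenced file exists and that the train/test split
#' is patient-disjoint (a leaked patient is an error naming it).
#'
#' @param manifest_path manifest CSV (paths relative to its directory).
#' @param image_size optional resize applied on load.
#' @return An `"sf_cohort"`.
#' @export
load_cohort <- function(manifest_path, image_size = NULL) {
  if (!file.exists(manifest_path)) stopf("manifest '%s' not found", manifest_path)
  dir <- dirname(manifest_path)
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("slice_path", "patient_id", "split", "label")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stopf("manifest is missing column(s): %s", paste(miss, collapse = ", "))
  sp <- unique(mf[, c("patient_id", "split")])
  dup <- sp$patient_id[duplicated(sp$patient_id)]
  if (length(dup))
    stopf("patient '%s' appears in more than one split", dup[1])
  md <- load_metadata_csv(file.path(dir, "metadata.csv"))
  rec_of <- stats::setNames(md$records, md$patient_ids)
  samples <- lapply(seq_len(nrow(mf)), function(i) {
    p <- file.path(dir, mf$slice_path[i])
    if (!file.exists(p)) stopf("slice file '%s' not found", p)
    px <- load_image(p, image_size)
    mask <- NULL
    if (!is.null(mf$mask_path) && nzchar(mf$mask_path[i])) {
      mp <- file.path(dir, mf$mask_path[i])
      if (!file.exists(mp)) stopf("mask file '%s' not found", mp)
      mask <- load_image(mp, image_size) > 0.5
    }
    img <- structure(list(pixels = px, patient_id = mf$patient_id[i],
                          slice_index = mf$slice_index[i] %||% (i - 1L),
                          lesion_mask = mask), class = "sf_image")
    list(image = img, metadata = rec_of[[mf$patient_id[i]]],
         label = as.integer(mf$label[i]))
  })
  first <- !duplicated(mf$patient_id)
  patients <- data.frame(patient_id = mf$patient_id[first],
                         label = as.integer(mf$label[first]),
                         split = mf$split[first], stringsAsFactors = FALSE)
  structure(list(samples = samples, patients = patients,
                 image_size = nrow(samples[[1]]$image$pixels),
                 slices_per_patient = as.integer(round(nrow(mf) / nrow(patients))),
                 seed = NA_integer_),
            class = "sf_cohort")
}
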