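#' Read an iEEG clip file
#'
#' Two on-disk dialects are supported. `kaggle_mat` is the contest layout: a
#' MAT v5 file holding one struct (any top-level name) with fields `data`
#' (channels x samples), `sampling_frequency`, `data_length_sec`, `channels`
#' (cell of labels) and `sequence`; extra fields are ignored. `native` is the
#' package's own container: one JSON header line followed by the sample matrix
#' as little-endian float32, channel by channel. In both dialects the class
#' label and segment index come from the *file name* (tokens
#' `interictal`/`preictal`/`test`), mirroring the contest layout where labels
#' are never stored inside the recording files.
#'
#' @param path File path, e.g. `Dog_1_interictal_segment_0012.mat`.
#' @param dialect `"kaggle_mat"` or `"native"`.
#' @return An [ieeg_clip()].
#' @export
read_clip <- function(path, dialect = c("kaggle_mat", "native")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("unreadable file: '%s' does not exist", path))
  }
  meta <- parse_clip_filename(path)
  if (dialect == "kaggle_mat") {
    vars <- read_mat5(path)
    is_struct <- vapply(vars, inherits, logical(1), "mat5_struct")
    if (!any(is_struct)) {
      abort(sprintf("missing field: no segment struct found in '%s'", path))
    }
    seg <- vars[[which(is_struct)[1L]]]
    for (f in c("data", "sampling_frequency", "data_length_sec", "channels",
                "sequence")) {
      if (is.null(seg[[f]])) {
        abort(sprintf("missing field '%s' in segment struct of '%s'", f, path))
      }
    }
    data <- seg$data
    if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
    if (nrow(data) == 0L) abort("empty channel axis: data matrix has 0 channels")
    labels <- seg$channels
    if (is.list(labels)) labels <- vapply(labels, as.character, character(1))
    ieeg_clip(
      data = data,
      sampling_rate_hz = as.numeric(seg$sampling_frequency)[1L],
      subject_id = meta$subject_id,
      segment_kind = meta$segment_kind,
      segment_index = meta$segment_index,
      sequence_index = as.integer(as.numeric(seg$sequence)[1L]),
      channel_labels = labels,
      duration_sec = as.numeric(seg$data_length_sec)[1L]
    )
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    header_bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) abort(sprintf("unreadable file: no header line in '%s'", path))
      if (b == charToRaw("\n")) break
      header_bytes <- c(header_bytes, b)
    }
    hdr <- tryCatch(jsonlite::fromJSON(rawToChar(header_bytes)),
                    error = function(e) abort(sprintf(
                      "unreadable file: malformed JSON header in '%s'", path)))
    for (f in c("n_channels", "n_samples", "sampling_rate_hz", "channel_labels",
                "duration_sec", "sequence_index")) {
      if (is.null(hdr[[f]])) abort(sprintf("missing field '%s' in header of '%s'", f, path))
    }
    nch <- as.integer(hdr$n_channels)
    ns <- as.integer(hdr$n_samples)
    if (nch == 0L) abort("empty channel axis: header declares 0 channels")
    vals <- readBin(con, "double", n = nch * ns, size = 4L, endian = "little")
    if (length(vals) != nch * ns) {
      abort(sprintf("shape mismatch: expected %d float32 values, found %d",
                    nch * ns, length(vals)))
    }
    ieeg_clip(
      data = matrix(vals, nrow = nch, byrow = TRUE),
      sampling_rate_hz = as.numeric(hdr$sampling_rate_hz),
      subject_id = meta$subject_id,
      segment_kind = meta$segment_kind,
      segment_index = meta$segment_index,
      sequence_index = as.integer(hdr$sequence_index),
      channel_labels = as.character(hdr$channel_labels),
      duration_sec = as.numeric(hdr$duration_sec)
    )
  }
}

#' Write an iEEG clip file
#'
#' @inheritParams read_clip
#' @param clip An [ieeg_clip()].
#' @return `path`, invisibly.
#' @seealso [read_clip()] for the dialect definitions; the round trip
#'   `read_clip(write_clip(clip))` restores the clip (bitwise for
#'   `kaggle_mat`, to float32 precision for `native`).
#' @export
write_clip <- function(clip, path, dialect = c("kaggle_mat", "native")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(clip, "ieeg_clip"))
  if (dialect == "kaggle_mat") {
    seg <- list(
      data = clip$data,
      data_length_sec = clip$duration_sec,
      sampling_frequency = clip$sampling_rate_hz,
      channels = as.list(clip$channel_labels),
      sequence = as.numeric(clip$sequence_index)
    )
    vars <- setNames(list(seg), sprintf("%s_segment_%d", clip$segment_kind,
                                        clip$segment_index))
    write_mat5(vars, path)
  } else {
    hdr <- jsonlite::toJSON(list(
      format = "seizecast-native-v1",
      subject_id = clip$subject_id,
      segment_kind = clip$segment_kind,
      segment_index = clip$segment_index,
      sequence_index = clip$sequence_index,
      sampling_rate_hz = clip$sampling_rate_hz,
      duration_sec = clip$duration_sec,
      n_channels = nrow(clip$data),
      n_samples = ncol(clip$data),
      channel_labels = clip$channel_labels,
      storage = "float32le-by-channel"
    ), auto_unbox = TRUE, digits = NA)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(as.character(hdr), "\n")), con)
    writeBin(as.numeric(t(clip$data)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Default clip file name for a dialect
#' @param clip An [ieeg_clip()].
#' @param dialect `"kaggle_mat"` or `"native"`.
#' @return File name (no directory).
#' @export
clip_filename <- function(clip, dialect = c("kaggle_mat", "native")) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "kaggle_mat") ".mat" else ".seeg"
  paste0(clip_name(clip), ext)
}

parse_clip_filename <- function(path) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  m <- regmatches(stem, regexec("^(.*)_(interictal|preictal|test)_segment_([0-9]+)$", stem))[[1]]
  if (length(m) != 4L) {
    abort(sprintf(
      "missing field: cannot derive label from file name '%s' (expected <subject>_<kind>_segment_<index>)",
      basename(path)
    ))
  }
  list(subject_id = m[2], segment_kind = m[3], segment_index = as.integer(m[4]))
}

#' Build a clip manifest from a directory
#'
#' Scans a directory for clip files, derives labels from file names and
#' returns the manifest ordered lexicographically by subject, kind and
#' segment index (deterministic enumeration).
#'
#' @param dir Directory containing clip files.
#' @param dialect Dialect of the files in `dir`.
#' @return Tibble with columns `path`, `subject_id`, `segment_kind`,
#'   `segment_index`, `sequence_index`.
#' @export
build_manifest <- function(dir, dialect = c("kaggle_mat", "native")) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "kaggle_mat") "\\.mat$" else "\\.seeg$"
  files <- list.files(dir, pattern = ext, full.names = TRUE)
  rows <- purrr::map(files, function(f) {
    meta <- parse_clip_filename(f)
    clip <- read_clip(f, dialect)
    tibble::tibble(
      path = f, subject_id = meta$subject_id, segment_kind = meta$segment_kind,
      segment_index = meta$segment_index, sequence_index = clip$sequence_index
    )
  })
  manifest <- dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id,
                             .data$segment_kind, .data$segment_index)
  validate_manifest(manifest)
  manifest
}

validate_manifest <- function(manifest) {
  needed <- c("path", "subject_id", "segment_kind", "segment_index",
              "sequence_index")
  missing <- setdiff(needed, names(manifest))
  if (length(missing) > 0L) {
    abort(paste0("manifest missing column(s): ", paste(missing, collapse = ", ")))
  }
  key <- paste(manifest$subject_id, manifest$segment_kind,
               manifest$segment_index)
  if (anyDuplicated(key)) {
    abort("manifest keys (subject_id, segment_kind, segment_index) must be unique")
  }
  invisible(manifest)
}

#' Read / write a clip manifest CSV
#' @param path CSV path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
read_manifest <- function(path) {
  manifest <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  manifest$segment_index <- as.integer(manifest$segment_index)
  manifest$sequence_index <- as.integer(manifest$sequence_index)
  validate_manifest(manifest)
  manifest
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Write contest-format predictions
#'
#' Writes the `clip,preictal` CSV consumed by the contest scoring framework,
#' one row per clip, probabilities serialized with full precision.
#'
#' @param predictions Data frame with columns `clip` (unique names) and
#'   `preictal` (probabilities in \[0, 1\]); the tibble returned by
#'   [predict_clips()] is accepted directly.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  nm <- names(predictions)
  if ("clip_name" %in% nm && !("clip" %in% nm)) {
    predictions <- dplyr::rename(predictions, clip = "clip_name")
  }
  if ("preictal_probability" %in% nm && !("preictal" %in% nm)) {
    predictions <- dplyr::rename(predictions, preictal = "preictal_probability")
  }
  stopifnot(all(c("clip", "preictal") %in% names(predictions)))
  if (anyDuplicated(predictions$clip)) {
    abort("duplicate clip_name in predictions")
  }
  p <- predictions$preictal
  if (any(p < 0 | p > 1 | !is.finite(p))) {
    abort("preictal probabilities must lie in [0, 1]")
  }
  lines <- c("clip,preictal",
             sprintf("%s,%s", predictions$clip,
                     formatC(p, digits = 8, format = "g")))
  writeLines(lines, path)
  invisible(path)
}
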