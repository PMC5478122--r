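#' Construct a labeled iEEG clip
#'
#' An `ieeg_clip` is the unit of prediction: one ten-minute (by convention)
#' multichannel intracranial EEG segment, labeled preictal (the hour before a
#' seizure), interictal (baseline far from any seizure) or test (unlabeled).
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Must be
#'   finite everywhere.
#' @param sampling_rate_hz Sampling rate in Hz (400 for the canine recordings,
#'   5000 for the human ones).
#' @param subject_id Subject identifier, e.g. `"Dog_1"`.
#' @param segment_kind One of `"interictal"`, `"preictal"`, `"test"`.
#' @param segment_index Positive integer index of the segment within its kind.
#' @param sequence_index Integer in 1..6: position of the clip inside its
#'   one-hour sequence of six ten-minute segments.
#' @param channel_labels Character vector of electrode names, one per row of
#'   `data`. Defaults to `ch_1 ... ch_n`.
#' @param duration_sec Clip duration in seconds; defaults to
#'   `ncol(data) / sampling_rate_hz` and must be consistent with it.
#'
#' @return An object of class `ieeg_clip`.
#' @export
ieeg_clip <- function(data, sampling_rate_hz, subject_id = "subject",
                      segment_kind = c("interictal", "preictal", "test"),
                      segment_index = 1L, sequence_index = 1L,
                      channel_labels = NULL, duration_sec = NULL) {
  segment_kind <- match.arg(segment_kind)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  if (nrow(data) < 1L) abort("empty channel axis: `data` has 0 channels.")
  if (ncol(data) < 1L) abort("empty sample axis: `data` has 0 samples.")
  if (anyNA(data) || any(!is.finite(data))) {
    abort("`data` contains NaN/Inf; clip values must be finite.")
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a positive scalar.")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch_", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` length must equal the number of channels.")
  }
  if (is.null(duration_sec)) duration_sec <- ncol(data) / sampling_rate_hz
  if (ncol(data) != round(duration_sec * sampling_rate_hz)) {
    abort(sprintf(
      "shape mismatch: %d samples != round(duration_sec * sampling_rate_hz) = %d",
      ncol(data), round(duration_sec * sampling_rate_hz)
    ))
  }
  segment_index <- as.integer(segment_index)
  sequence_index <- as.integer(sequence_index)
  if (segment_index < 1L) abort("`segment_index` must be a positive integer.")
  if (sequence_index < 1L || sequence_index > 6L) {
    abort("`sequence_index` must lie in 1..6.")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      segment_kind = segment_kind,
      segment_index = segment_index,
      sequence_index = sequence_index,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      channel_labels = as.character(channel_labels),
      data = data,
      duration_sec = as.numeric(duration_sec)
    ),
    class = "ieeg_clip"
  )
}

#' @export
print.ieeg_clip <- function(x, ...) {
  cat(sprintf(
    "<ieeg_clip> %s %s segment %d (sequence slot %d)\n  %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$segment_kind, x$segment_index, x$sequence_index,
    nrow(x$data), ncol(x$data), x$sampling_rate_hz, x$duration_sec
  ))
  invisible(x)
}

#' Canonical clip file stem, e.g. `Dog_1_interictal_segment_0012`
#' @param clip An `ieeg_clip`.
#' @return A character scalar.
#' @export
clip_name <- function(clip) {
  stopifnot(inherits(clip, "ieeg_clip"))
  sprintf("%s_%s_segment_%04d", clip$subject_id, clip$segment_kind,
          clip$segment_index)
}

#' @exportS3Method generics::tidy
tidy.ieeg_clip <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    segment_kind = x$segment_kind,
    segment_index = x$segment_index,
    sequence_index = x$sequence_index,
    channel = x$channel_labels,
    rms_uv = apply(x$data, 1, function(v) sqrt(mean(v^2)))
  )
}
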