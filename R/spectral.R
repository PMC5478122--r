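#' Sliding-window specification
#'
#' Defaults follow the forecasting pipeline: 60-second Hamming windows with a
#' 30-second step (i.e. 30 s of overlap), which slice a 600 s clip into 19
#' windows.
#'
#' @param window_sec Window length in seconds (> 0).
#' @param step_sec Step between window starts in seconds; must satisfy
#'   `0 < step_sec <= window_sec`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_sec = 60, step_sec = 30) {
  if (!(window_sec > 0) || !(step_sec > 0) || step_sec > window_sec) {
    abort("require 0 < step_sec <= window_sec")
  }
  structure(list(window_sec = window_sec, step_sec = step_sec),
            class = "window_spec")
}

#' Number of sliding windows in a clip
#' @param duration_sec Clip duration (s).
#' @param spec A [window_spec()].
#' @return Integer window count, `floor((duration - window) / step) + 1`.
#' @export
n_windows <- function(duration_sec, spec = window_spec()) {
  if (duration_sec < spec$window_sec) {
    abort("clip shorter than one window")
  }
  as.integer(floor((duration_sec - spec$window_sec) / spec$step_sec) + 1)
}

#' Slice a clip into Hamming-tapered windows
#'
#' @param clip An [ieeg_clip()] at least one window long.
#' @param spec A [window_spec()].
#' @return List with `windows` (array `[windows x channels x window_samples]`,
#'   each window multiplied by a Hamming taper), `window_starts_sec`, and
#'   `sampling_rate_hz`.
#' @export
sliding_windows <- function(clip, spec = window_spec()) {
  stopifnot(inherits(clip, "ieeg_clip"))
  nw <- n_windows(clip$duration_sec, spec)
  wsamp <- round(spec$window_sec * clip$sampling_rate_hz)
  step <- spec$step_sec * clip$sampling_rate_hz
  taper <- as.numeric(signal::hamming(wsamp))
  nch <- nrow(clip$data)
  out <- array(NA_real_, dim = c(nw, nch, wsamp))
  starts <- (seq_len(nw) - 1) * spec$step_sec
  for (w in seq_len(nw)) {
    s0 <- round((w - 1) * step)
    seg <- clip$data[, (s0 + 1):(s0 + wsamp), drop = FALSE]
    out[w, , ] <- sweep(seg, 2L, taper, `*`)
  }
  list(windows = out, window_starts_sec = starts,
       sampling_rate_hz = clip$sampling_rate_hz)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Log-compressed magnitude spectra of tapered windows
#'
#' Each window is zero-padded to the next power of two, Fourier transformed,
#' and reduced to the `fft_length / 2` positive-frequency magnitude bins
#' (the DC bin is excluded). By default the magnitudes are compressed with
#' `log1p` here, before any filtering (`log_order = "pre"`); with
#' `log_order = "post"` the raw (magnitude or power) bins are kept and
#' [apply_filters()] applies `log1p` after the weighted sum instead.
#'
#' @param windows Output of [sliding_windows()], or a compatible list with
#'   `windows` and `sampling_rate_hz`.
#' @param rate Sampling rate in Hz; defaults to the rate carried by `windows`.
#' @param spectrum `"magnitude"` (|FFT|) or `"power"` (|FFT|^2).
#' @param log_order `"pre"` (log1p applied to bins now) or `"post"` (log1p
#'   deferred to after filtering).
#' @return A `spectral_tensor`: list with `values`
#'   (`[windows x channels x bins]`), `freq_hz` (bin centre frequencies,
#'   `freq_hz[j] = j * rate / fft_length` on the DC-excluded axis),
#'   `window_starts_sec`, `sampling_rate_hz`, `fft_length`, `spectrum`,
#'   `log_order`.
#' @export
log_spectrum <- function(windows, rate = NULL,
                         spectrum = c("magnitude", "power"),
                         log_order = c("pre", "post")) {
  spectrum <- match.arg(spectrum)
  log_order <- match.arg(log_order)
  w <- windows$windows
  rate <- rate %||% windows$sampling_rate_hz
  stopifnot(is.array(w), length(dim(w)) == 3L)
  wsamp <- dim(w)[3L]
  if (wsamp < 2L) abort("windows must contain at least 2 samples")
  nfft <- next_pow2(wsamp)
  nbins <- nfft / 2L
  nw <- dim(w)[1L]; nch <- dim(w)[2L]
  vals <- array(NA_real_, dim = c(nw, nch, nbins))
  buf <- matrix(0, nrow = nfft, ncol = nch)
  for (iw in seq_len(nw)) {
    m <- w[iw, , , drop = FALSE]
    dim(m) <- c(nch, wsamp)
    buf[seq_len(wsamp), ] <- t(m)
    sp <- stats::mvfft(buf)
    mag <- Mod(sp[2L:(nbins + 1L), , drop = FALSE])
    if (spectrum == "power") mag <- mag^2
    if (log_order == "pre") mag <- log1p(mag)
    vals[iw, , ] <- t(mag)
    buf[] <- 0
  }
  structure(
    list(
      values = vals,
      freq_hz = seq_len(nbins) * rate / nfft,
      window_starts_sec = windows$window_starts_sec %||% rep(NA_real_, nw),
      sampling_rate_hz = rate,
      fft_length = nfft,
      spectrum = spectrum,
      log_order = log_order
    ),
    class = "spectral_tensor"
  )
}

#' @export
print.spectral_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<spectral_tensor> %d windows x %d channels x %d bins (fft %d @ %g Hz, %s, log %s)\n",
    d[1], d[2], d[3], x$fft_length, x$sampling_rate_hz, x$spectrum, x$log_order
  ))
  invisible(x)
}

#' The six canonical EEG frequency bands
#'
#' delta (0.1-4 Hz), theta (4-8), alpha (8-12), beta (12-30), low gamma
#' (30-70) and high gamma (70-180). Band intervals are half-open
#' `[low, high)` so adjacent bands share no bin.
#'
#' @return Tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
canonical_bands <- function() {
  tibble::tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
                  levels = c("delta", "theta", "alpha", "beta", "low_gamma",
                             "high_gamma")),
    low_hz = c(0.1, 4, 8, 12, 30, 70),
    high_hz = c(4, 8, 12, 30, 70, 180)
  )
}

#' Map frequency bands to FFT bin ranges
#'
#' Bin `j` (1-based, DC excluded) has centre frequency `j * rate / fft_length`;
#' band `b` collects bins with `low_hz <= freq < high_hz`. Bands reaching above
#' the Nyquist frequency are truncated there; bands left with no bins are
#' flagged `empty`.
#'
#' @param rate Sampling rate (Hz).
#' @param fft_length FFT length (bins retained = `fft_length / 2`).
#' @param bands Band definition tibble (`band`, `low_hz`, `high_hz`); defaults
#'   to [canonical_bands()].
#' @return Tibble with `band`, `low_hz`, `high_hz`, `first_bin`, `last_bin`,
#'   `n_bins`, `empty`. Bin indices are 1-based on the DC-excluded axis.
#' @export
band_bin_ranges <- function(rate, fft_length, bands = canonical_bands()) {
  stopifnot(rate > 0, fft_length >= 2)
  nbins <- floor(fft_length / 2)
  freq <- seq_len(nbins) * rate / fft_length
  out <- purrr::pmap(bands, function(band, low_hz, high_hz, ...) {
    idx <- which(freq >= low_hz & freq < high_hz)
    tibble::tibble(
      band = band, low_hz = low_hz, high_hz = high_hz,
      first_bin = if (length(idx)) min(idx) else NA_integer_,
      last_bin = if (length(idx)) max(idx) else NA_integer_,
      n_bins = length(idx),
      empty = length(idx) == 0L
    )
  })
  out <- dplyr::bind_rows(out)
  if (all(out$empty)) {
    abort("all requested bands are empty at this sampling rate / FFT length")
  }
  out
}

band_bins <- function(range_row) {
  if (range_row$empty) integer(0) else range_row$first_bin:range_row$last_bin
}
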