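# Synthetic iEEG with planted class-dependent spectral structure.
#
# Clips are synthesized by spectral shaping: a complex Gaussian half-spectrum
# scaled to a target amplitude spectrum (1/f baseline plus class-dependent
# multiplicative power factors on planted frequency intervals), inverse
# transformed to a real signal. This gives exact control of the planted band
# power and a direct correspondence with the pipeline's FFT features.

#' Synthetic subject configuration
#'
#' Defaults describe a canine-like subject: 16 channels at 400 Hz, ten-minute
#' clips, 2 preictal and 27 interictal one-hour sequences of six clips
#' (93.1% interictal), a 1/f^2 baseline spectrum with a floor, clip-level
#' log-amplitude gain jitter (s.d. 0.2) emulating electrode/state
#' nonstationarity, and one planted preictal effect: power multiplied by 4
#' on 38-42 Hz for channels 1-3.
#'
#' @param subject_id Subject name.
#' @param channels Number of channels.
#' @param sampling_rate_hz Sampling rate (400 dog-like, 5000 human-like).
#' @param clip_duration_sec Clip length in seconds (600 = contest layout;
#'   reducible for fast runs).
#' @param n_interictal,n_preictal Number of one-hour sequences (6 clips each)
#'   per class.
#' @param psd_exponent Exponent of the 1/f^a baseline power spectrum.
#' @param psd_floor Additive white floor, relative to power at 1 Hz.
#' @param amplitude Overall amplitude scale (arbitrary microvolt-like units).
#' @param clip_gain_sd Standard deviation of the per-clip log-amplitude gain.
#' @param effects Tibble of planted effects with columns `low_hz`, `high_hz`,
#'   `factor` (multiplicative power factor for preictal clips),
#'   `variance_only` (logical: keep mean power, jitter the per-clip factor
#'   with across-clip log-s.d. `log(factor)/2` instead) and `channels` (list
#'   column of channel indices). Use a zero-row tibble for a null
#'   configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(subject_id = "synth_1", channels = 16L,
                         sampling_rate_hz = 400, clip_duration_sec = 600,
                         n_interictal = 27L, n_preictal = 2L,
                         psd_exponent = 2, psd_floor = 0.05,
                         amplitude = 30, clip_gain_sd = 0.2,
                         effects = default_effects(channels)) {
  stopifnot(channels >= 1L, sampling_rate_hz > 0, clip_duration_sec > 0,
            n_interictal >= 1L, n_preictal >= 1L, amplitude > 0,
            clip_gain_sd >= 0)
  effects <- as_effects(effects)
  if (nrow(effects) > 0L) {
    stopifnot(all(c("low_hz", "high_hz", "factor", "variance_only",
                    "channels") %in% names(effects)))
    if (any(effects$factor <= 0)) abort("effect factors must be > 0")
    if (any(effects$low_hz < 0) || any(effects$low_hz >= effects$high_hz)) {
      abort("effect intervals must satisfy 0 <= low < high")
    }
    if (any(effects$high_hz > sampling_rate_hz / 2)) {
      abort("effect interval above Nyquist")
    }
    if (any(unlist(effects$channels) > channels)) {
      abort("effect channel outside configured channel range")
    }
  }
  structure(
    list(subject_id = subject_id, channels = as.integer(channels),
         sampling_rate_hz = sampling_rate_hz,
         clip_duration_sec = clip_duration_sec,
         n_interictal = as.integer(n_interictal),
         n_preictal = as.integer(n_preictal),
         psd_exponent = psd_exponent, psd_floor = psd_floor,
         amplitude = amplitude, clip_gain_sd = clip_gain_sd,
         effects = effects),
    class = "synth_config"
  )
}

# accept effects as a tibble, a single plain list (e.g. from YAML), or a
# list of such lists; normalize `channels` into a list column of integers
as_effects <- function(effects) {
  if (is.data.frame(effects)) {
    eff <- tibble::as_tibble(effects)
    if (nrow(eff) > 0L && !is.list(eff$channels)) {
      eff$channels <- as.list(eff$channels)
    }
    return(eff)
  }
  if (is.list(effects)) {
    if (length(effects) == 0L) return(default_effects(1L)[0, ])
    if (!is.null(names(effects))) effects <- list(effects)
    rows <- lapply(effects, function(e) tibble::tibble(
      low_hz = as.numeric(e$low_hz), high_hz = as.numeric(e$high_hz),
      factor = as.numeric(e$factor),
      variance_only = isTRUE(e$variance_only),
      channels = list(as.integer(unlist(e$channels)))
    ))
    return(dplyr::bind_rows(rows))
  }
  abort("`effects` must be a data frame or a list of effect descriptions")
}

#' @rdname synth_config
#' @export
default_effects <- function(channels = 16L) {
  tibble::tibble(
    low_hz = 38, high_hz = 42, factor = 4, variance_only = FALSE,
    channels = list(seq_len(min(3L, channels)))
  )
}

#' Reduced configuration for fast end-to-end runs
#'
#' 8 channels, 400 Hz, 120 s clips (3 windows per clip under the default
#' 60/30 window spec), 2 preictal and 6 interictal sequences.
#'
#' @param ... Overrides passed to [synth_config()].
#' @export
synth_config_small <- function(...) {
  args <- modifyList(
    list(channels = 8L, clip_duration_sec = 120, n_interictal = 6L,
         n_preictal = 2L),
    list(...)
  )
  if (is.null(args$effects)) args$effects <- default_effects(args$channels)
  do.call(synth_config, args)
}

#' @export
print.synth_config <- function(x, ...) {
  n_clips <- 6L * (x$n_interictal + x$n_preictal)
  cat(sprintf(
    "<synth_config> %s: %d ch @ %g Hz, %g s clips, %d interictal + %d preictal sequences (%d clips, %.1f%% interictal), %d planted effect(s)\n",
    x$subject_id, x$channels, x$sampling_rate_hz, x$clip_duration_sec,
    x$n_interictal, x$n_preictal, n_clips,
    100 * x$n_interictal / (x$n_interictal + x$n_preictal), nrow(x$effects)
  ))
  invisible(x)
}

# target one-sided amplitude spectrum (sd of each complex Fourier
# coefficient) for one channel/kind at the clip's rFFT frequencies
synth_amplitude <- function(config, freq_hz, kind, channel,
                            effect_factors = NULL) {
  base <- config$amplitude *
    sqrt(pmax(freq_hz, 1e-3)^(-config$psd_exponent) + config$psd_floor)
  if (kind == "preictal" && nrow(config$effects) > 0L) {
    for (e in seq_len(nrow(config$effects))) {
      if (!(channel %in% config$effects$channels[[e]])) next
      fac <- if (is.null(effect_factors)) config$effects$factor[e] else
        effect_factors[e]
      sel <- freq_hz >= config$effects$low_hz[e] &
        freq_hz < config$effects$high_hz[e]
      base[sel] <- base[sel] * sqrt(fac)
    }
  }
  base
}

#' Target power spectrum of the generator
#'
#' Expected squared magnitude of the clip-length DFT at each requested
#' frequency, per class, for one channel (clip gain averaged out; the factor
#' `n` comes from the DFT length).
#'
#' @param config A [synth_config()].
#' @param freq_hz Frequencies (Hz).
#' @param kind `"interictal"` or `"preictal"`.
#' @param channel Channel index.
#' @return Numeric vector of expected clip-periodogram values.
#' @export
synth_target_psd <- function(config, freq_hz, kind, channel) {
  gain2 <- exp(2 * config$clip_gain_sd^2)  # E[g^2] for lognormal gain
  n <- round(config$clip_duration_sec * config$sampling_rate_hz)
  n * gain2 * synth_amplitude(config, freq_hz, kind, channel)^2
}

synth_clip_signal <- function(config, kind) {
  n <- round(config$clip_duration_sec * config$sampling_rate_hz)
  stopifnot(n %% 2L == 0L)
  half <- n %/% 2L
  freq <- seq_len(half) * config$sampling_rate_hz / n
  gain <- exp(stats::rnorm(1L, 0, config$clip_gain_sd))
  effect_factors <- NULL
  if (kind == "preictal" && nrow(config$effects) > 0L) {
    effect_factors <- vapply(seq_len(nrow(config$effects)), function(e) {
      if (isTRUE(config$effects$variance_only[e])) {
        # mean-one lognormal factor whose +/-2 s.d. log range spans
        # [1/factor, factor]: same expected power, inflated across-clip spread
        s <- log(config$effects$factor[e]) / 2
        exp(stats::rnorm(1L, -s^2 / 2, s))
      } else {
        config$effects$factor[e]
      }
    }, numeric(1))
  }
  data <- matrix(NA_real_, config$channels, n)
  for (ch in seq_len(config$channels)) {
    amp <- gain * synth_amplitude(config, freq, kind, ch, effect_factors)
    re <- stats::rnorm(half, 0, 1 / sqrt(2))
    im <- stats::rnorm(half, 0, 1 / sqrt(2))
    coef <- complex(real = amp * re, imaginary = amp * im)
    coef[half] <- complex(real = sqrt(2) * amp[half] * re[half], imaginary = 0)
    full <- complex(length.out = n)
    full[1L] <- 0
    full[2L:(half + 1L)] <- coef
    full[n:(half + 2L)] <- Conj(coef[seq_len(half - 1L)])
    data[ch, ] <- Re(stats::fft(full, inverse = TRUE)) / sqrt(n)
  }
  data
}

#' Generate a labeled synthetic subject
#'
#' Produces the full clip set for one subject: `n_interictal` plus
#' `n_preictal` one-hour sequences of six clips each, with
#' `sequence_index` 1..6 inside every sequence and consecutive
#' `segment_index` within each class. Preictal clips differ from interictal
#' clips only on the planted frequency intervals (in expectation).
#' Reproducible: the same `config` and `seed` give identical clips.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param on_clip Optional callback `function(clip)` invoked for every clip
#'   as it is generated; when supplied the clips are *not* accumulated in the
#'   returned list, which keeps memory flat for large subjects (the pipeline's
#'   synth stage writes each clip to disk this way).
#' @return List with `clips` (list of [ieeg_clip()]; empty when `on_clip` is
#'   given), `truth` (a `planted_truth` object describing the planted
#'   intervals) and `manifest` (tibble: `clip_name`, `segment_kind`,
#'   `segment_index`, `sequence_index`, `seq_id`).
#' @export
generate_subject <- function(config, seed = 1L, on_clip = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(as.integer(seed), {
    rows <- list()
    clips <- list()
    idx <- 0L
    for (kind in c("interictal", "preictal")) {
      n_seq <- if (kind == "interictal") config$n_interictal else config$n_preictal
      seg <- 0L
      for (s in seq_len(n_seq)) {
        for (pos in 1:6) {
          seg <- seg + 1L
          idx <- idx + 1L
          data <- synth_clip_signal(config, kind)
          clip <- ieeg_clip(
            data = data, sampling_rate_hz = config$sampling_rate_hz,
            subject_id = config$subject_id, segment_kind = kind,
            segment_index = seg, sequence_index = pos
          )
          if (is.null(on_clip)) clips[[idx]] <- clip else on_clip(clip)
          rows[[idx]] <- tibble::tibble(
            clip_name = clip_name(clip), segment_kind = kind,
            segment_index = seg, sequence_index = pos, seq_id = s
          )
        }
      }
    }
    truth <- structure(
      list(effects = config$effects, sampling_rate_hz = config$sampling_rate_hz),
      class = "planted_truth"
    )
    list(clips = clips, truth = truth, manifest = dplyr::bind_rows(rows))
  })
}

#' Planted bins for one channel and band
#'
#' Bin indices (1-based, DC-excluded axis at the given FFT length) inside a
#' band that fall in any planted interval affecting the channel.
#'
#' @param truth `planted_truth` from [generate_subject()].
#' @param fft_length FFT length of the spectral tensor.
#' @param channel Channel index.
#' @param band_range One row of [band_bin_ranges()].
#' @return Integer vector of bin indices (possibly empty).
#' @export
planted_bins <- function(truth, fft_length, channel, band_range) {
  bins <- band_bins(band_range)
  freq <- bins * truth$sampling_rate_hz / fft_length
  sel <- rep(FALSE, length(bins))
  eff <- truth$effects
  for (e in seq_len(nrow(eff))) {
    if (!(channel %in% eff$channels[[e]])) next
    sel <- sel | (freq >= eff$low_hz[e] & freq < eff$high_hz[e])
  }
  bins[sel]
}

#' Fraction of squared filter weight on planted bins
#'
#' @param weights A [estimate_filter()] bank (per-channel scope).
#' @param truth `planted_truth` from [generate_subject()].
#' @param channel Channel index.
#' @param band Band name (as in the bank's band table).
#' @return Recovery score in `[0, 1]`: `sum(u[planted]^2) / sum(u^2)`.
#' @export
recovery_score <- function(weights, truth, channel, band) {
  stopifnot(inherits(weights, "filter_weights"),
            weights$scope == "per_channel")
  ranges <- weights$band_ranges
  bi <- which(as.character(ranges$band) == band)
  if (length(bi) != 1L) abort(sprintf("unknown band '%s'", band))
  bins <- band_bins(ranges[bi, ])
  planted <- planted_bins(truth, weights$fft_length, channel, ranges[bi, ])
  if (length(planted) == 0L) abort("no planted bins in this band/channel")
  u <- weights$weights[[channel]][[bi]]
  sum(u[match(planted, bins)]^2) / sum(u^2)
}

# split a generated subject's sequences into train / test deterministically:
# the last preictal sequence and every third interictal sequence are held out
synth_split <- function(manifest) {
  m <- manifest
  test_pre <- max(m$seq_id[m$segment_kind == "preictal"])
  inter_ids <- sort(unique(m$seq_id[m$segment_kind == "interictal"]))
  test_int <- inter_ids[seq_along(inter_ids) %% 3L == 0L]
  is_test <- (m$segment_kind == "preictal" & m$seq_id == test_pre) |
    (m$segment_kind == "interictal" & m$seq_id %in% test_int)
  list(train = which(!is_test), test = which(is_test))
}

#' Benchmark filter methods on synthetic subjects
#'
#' For every seed: generate a subject, hold out the last preictal sequence
#' and every third interictal sequence, estimate each method's filter bank on
#' the training clips, fit the KNN on the training window features, predict
#' the held-out clips and score the clip-level AUC.
#'
#' @param config A [synth_config()]; use a no-effect configuration for null
#'   calibration.
#' @param methods Character vector of filter methods.
#' @param seeds Integer vector of seeds (one subject realization per seed).
#' @param spec Window specification.
#' @param k KNN neighbour count.
#' @param tol,max_iter Power-iteration controls for the supervised filters
#'   (the benchmark default trades the last digits of eigenvector accuracy
#'   for speed; see the methods vignette).
#' @return Tibble of class `filter_benchmark`: one row per (method, seed)
#'   with the test AUC and split sizes.
#' @export
benchmark_filters <- function(config, methods = c("pbf", "ds"),
                              seeds = 1:20, spec = window_spec(),
                              k = 40L, tol = 1e-6, max_iter = 60L) {
  rows <- list()
  for (seed in seeds) {
    subj <- generate_subject(config, seed)
    split <- synth_split(subj$manifest)
    tensors <- lapply(subj$clips, function(cl) log_spectrum(sliding_windows(cl, spec)))
    kinds <- subj$manifest$segment_kind
    tr0 <- tensors[intersect(split$train, which(kinds == "interictal"))]
    tr1 <- tensors[intersect(split$train, which(kinds == "preictal"))]
    n_win <- dim(tensors[[1]]$values)[1L]
    train_labels <- rep(as.integer(kinds[split$train] == "preictal"),
                        each = n_win)
    test_labels <- as.integer(kinds[split$test] == "preictal")
    for (method in methods) {
      fw <- estimate_filter(tr0, tr1, method = method, tol = tol,
                            max_iter = max_iter)
      train_feats <- do.call(rbind, lapply(tensors[split$train],
                                           apply_filters, weights = fw))
      model <- knn_model(train_feats, train_labels, k = min(k, nrow(train_feats)))
      clip_prob <- vapply(split$test, function(i) {
        aggregate_windows(knn_posterior(model, apply_filters(tensors[[i]], fw)))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = method, seed = seed, auc = auc(clip_prob, test_labels),
        n_train_clips = length(split$train), n_test_clips = length(split$test),
        n_test_preictal = sum(test_labels)
      )
    }
    rm(tensors)
    gc(verbose = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("filter_benchmark", class(out))
  out
}

#' @exportS3Method generics::glance
glance.filter_benchmark <- function(x, ...) {
  x |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = stats::sd(.data$auc),
                     n_seeds = dplyr::n(), .groups = "drop")
}
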