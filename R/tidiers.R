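# broom-style accessors and ggplot2 autoplot methods for the fitted objects

#' @exportS3Method generics::tidy
tidy.filter_weights <- function(x, ...) {
  ranges <- x$band_ranges
  chan_slots <- length(x$weights)
  purrr::map_dfr(seq_len(chan_slots), function(ci) {
    purrr::map_dfr(seq_len(nrow(ranges)), function(bi) {
      bins <- band_bins(ranges[bi, ])
      u <- x$weights[[ci]][[bi]]
      reps <- length(u) / length(bins)  # joint scope: channels concatenated
      tibble::tibble(
        channel = if (x$scope == "joint")
          rep(seq_len(reps), each = length(bins)) else ci,
        band = ranges$band[bi],
        bin = rep(bins, times = reps),
        freq_hz = rep(bins, times = reps) * x$sampling_rate_hz / x$fft_length,
        weight = u
      )
    })
  })
}

#' @exportS3Method generics::glance
glance.filter_weights <- function(x, ...) {
  tibble::tibble(
    method = x$method, scope = x$scope,
    n_channels = x$n_channels, n_bands = nrow(x$band_ranges),
    sampling_rate_hz = x$sampling_rate_hz, fft_length = x$fft_length,
    converged_fraction = if (all(is.na(x$converged))) NA_real_
      else mean(x$converged, na.rm = TRUE),
    median_iterations = if (all(is.na(x$iterations))) NA_real_
      else stats::median(x$iterations, na.rm = TRUE)
  )
}

#' @exportS3Method generics::tidy
tidy.knn_model <- function(x, ...) {
  tibble::tibble(
    feature = colnames(x$x) %||% paste0("f", seq_len(x$p)),
    center = x$center, scale = x$scale
  )
}

#' @exportS3Method generics::glance
glance.knn_model <- function(x, ...) {
  tibble::tibble(n_train = nrow(x$x), n_preictal = sum(x$labels),
                 p = x$p, k = x$k, standardized = x$standardize)
}

#' Plot an ROC curve
#' @param object A [roc_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot filter weight profiles across frequency
#' @param object A [estimate_filter()] bank.
#' @param channels Channels to display (default: first 4).
#' @param ... Ignored.
#' @return A ggplot object faceted by band (free x scales) and channel.
#' @exportS3Method ggplot2::autoplot
autoplot.filter_weights <- function(object, channels = NULL, ...) {
  td <- tidy(object)
  channels <- channels %||% head(sort(unique(td$channel)), 4L)
  td <- dplyr::filter(td, .data$channel %in% channels)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$freq_hz, y = .data$weight)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#225ea8") +
    ggplot2::facet_grid(channel ~ band, scales = "free") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Filter weight",
                  title = sprintf("%s filter bank", toupper(object$method))) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic benchmark
#' @param object A [benchmark_filters()] table.
#' @param ... Ignored.
#' @return A ggplot object: per-seed AUCs and per-method means.
#' @exportS3Method ggplot2::autoplot
autoplot.filter_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = toupper(.data$method), y = .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, colour = "#225ea8") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          colour = "#e31a1c") +
    ggplot2::labs(x = "Filter", y = "Held-out clip AUC",
                  title = "Synthetic benchmark: clip-level AUC by filter") +
    ggplot2::theme_minimal()
}
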