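#' Distance-weighted K-nearest-neighbour model
#'
#' Stores the training window features together with per-feature
#' standardization statistics (mean/sd from the training data; constant
#' features get scale 1). Prediction uses Euclidean distances in the
#' standardized space and the exponential posterior of [knn_posterior()].
#'
#' @param features Numeric matrix `[N x p]` of training window features.
#' @param labels Binary vector of length `N` (1 = preictal, 0 = interictal).
#' @param k Number of neighbours; defaults to 40.
#' @param standardize Standardize features with training statistics before
#'   distances (default TRUE).
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(features, labels, k = 40L, standardize = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) abort("labels length must match rows")
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) abort("both classes must be present")
  k <- as.integer(k)
  if (k < 1L || k > nrow(features)) {
    abort(sprintf("K = %d must satisfy 1 <= K <= N = %d", k, nrow(features)))
  }
  if (standardize) {
    mu <- colMeans(features)
    s <- apply(features, 2L, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
  } else {
    mu <- rep(0, ncol(features))
    s <- rep(1, ncol(features))
  }
  xs <- sweep(sweep(features, 2L, mu, `-`), 2L, s, `/`)
  structure(
    list(x = xs, labels = labels, k = k, center = mu, scale = s,
         standardize = standardize, p = ncol(features)),
    class = "knn_model"
  )
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> N = %d windows (%d preictal), p = %d features, K = %d\n",
              nrow(x$x), sum(x$labels), x$p, x$k))
  invisible(x)
}

#' Exponential-distance KNN posterior
#'
#' For a query `x`, the `K` nearest training windows (squared Euclidean
#' distance in the standardized feature space; ties at the K-th distance
#' broken by stable training-row order) are weighted by
#' `exp(-||y - x||^2 / 2)` and the preictal posterior is the class-1 share of
#' the total weight. Weights are computed after subtracting the smallest
#' squared distance (a max-shift in log space), so the ratio is unchanged but
#' cannot underflow to 0/0.
#'
#' @param model A [knn_model()].
#' @param x Query feature vector of length `p`, or a `[m x p]` matrix of
#'   queries.
#' @return Posterior probability (vector of length `m`) in `[0, 1]`.
#' @export
knn_posterior <- function(model, x) {
  stopifnot(inherits(model, "knn_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != model$p) abort("query dimension mismatch")
  xs <- sweep(sweep(x, 2L, model$center, `-`), 2L, model$scale, `/`)
  tr <- model$x
  # squared distances [m x N]
  d2 <- outer(rowSums(xs^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(xs)), rowSums(tr^2)) - 2 * tcrossprod(xs, tr)
  d2[d2 < 0] <- 0
  apply(d2, 1L, function(row) {
    idx <- order(row)[seq_len(model$k)]  # stable: ties keep training order
    w <- exp(-(row[idx] - min(row[idx])) / 2)
    sum(w[model$labels[idx] == 1L]) / sum(w)
  })
}

#' Aggregate window posteriors into a clip probability
#'
#' One minus the geometric mean of the per-window complement probabilities:
#' `1 - (prod(1 - p_t))^(1/n)`. Computed in log space as
#' `1 - exp(mean(log1p(-p_t)))`; any window posterior of exactly 1 forces the
#' clip probability to 1.
#'
#' @param window_posteriors Numeric vector of per-window preictal posteriors
#'   in `[0, 1]`, length >= 1.
#' @return Clip-level preictal probability in `[0, 1]`.
#' @export
aggregate_windows <- function(window_posteriors) {
  p <- as.numeric(window_posteriors)
  if (length(p) == 0L) abort("empty posterior vector")
  if (any(p < 0 | p > 1 | is.na(p))) abort("posteriors must lie in [0, 1]")
  1 - exp(mean(log1p(-p)))
}

# sequence ids within (subject, kind): a new one-hour sequence starts
# wherever sequence_index == 1 (clips ordered by segment_index)
sequence_table <- function(manifest) {
  manifest |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id, .data$segment_kind) |>
    dplyr::arrange(.data$segment_index, .by_group = TRUE) |>
    dplyr::mutate(seq_id = cumsum(.data$sequence_index == 1L)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Leave-one-seizure-out fold plan
#'
#' One fold per preictal one-hour sequence (the seizure): that sequence is
#' the fold's validation unit, and the interictal sequences are distributed
#' across folds round-robin by ascending sequence id, so every fold's
#' validation set has both classes and no validation window ever appears in
#' its own fold's training set.
#'
#' @param manifest Clip manifest tibble (see [build_manifest()]).
#' @param subject Subject id to plan folds for.
#' @return Tibble with one row per (fold, sequence): columns `fold`,
#'   `segment_kind`, `seq_id`, `role` (`"validation"` or `"training"`).
#' @export
loso_folds <- function(manifest, subject) {
  m <- sequence_table(dplyr::filter(manifest, .data$subject_id == subject))
  seqs <- dplyr::distinct(m, .data$segment_kind, .data$seq_id)
  pre <- dplyr::filter(seqs, .data$segment_kind == "preictal") |>
    dplyr::arrange(.data$seq_id)
  inter <- dplyr::filter(seqs, .data$segment_kind == "interictal") |>
    dplyr::arrange(.data$seq_id)
  n_folds <- nrow(pre)
  if (n_folds < 2L) abort("leave-one-seizure-out needs at least 2 preictal sequences")
  val <- dplyr::bind_rows(
    dplyr::mutate(pre, fold = dplyr::row_number()),
    dplyr::mutate(inter, fold = ((dplyr::row_number() - 1L) %% n_folds) + 1L)
  )
  purrr::map_dfr(seq_len(n_folds), function(f) {
    v <- dplyr::filter(val, .data$fold == f)
    t <- dplyr::anti_join(seqs, v, by = c("segment_kind", "seq_id"))
    dplyr::bind_rows(
      dplyr::mutate(v[c("segment_kind", "seq_id")], fold = f, role = "validation"),
      dplyr::mutate(t, fold = f, role = "training")
    )
  }) |>
    dplyr::select("fold", "segment_kind", "seq_id", "role") |>
    dplyr::arrange(.data$fold, dplyr::desc(.data$role), .data$segment_kind,
                   .data$seq_id)
}

#' Predict preictal probabilities for clips
#'
#' Runs the full pipeline per clip: sliding Hamming windows, log-compressed
#' FFT spectra, band filtering with a trained filter bank, per-window KNN
#' posteriors, and geometric aggregation into one clip-level probability.
#'
#' @param clips An `ieeg_clip` or list of clips.
#' @param weights A trained [estimate_filter()] bank.
#' @param model A trained [knn_model()].
#' @param spec A [window_spec()].
#' @param spectrum,log_order Spectrum options, must match the settings the
#'   filter bank was trained with.
#' @return Tibble with one row per clip: `clip_name`, `n_windows`,
#'   `preictal_probability`, and `window_posteriors` (list column).
#' @export
predict_clips <- function(clips, weights, model, spec = window_spec(),
                          spectrum = NULL, log_order = NULL) {
  if (inherits(clips, "ieeg_clip")) clips <- list(clips)
  spectrum <- spectrum %||% weights$spectrum
  log_order <- log_order %||% weights$log_order
  rows <- purrr::map(clips, function(clip) {
    tens <- log_spectrum(sliding_windows(clip, spec), spectrum = spectrum,
                         log_order = log_order)
    feats <- apply_filters(tens, weights)
    post <- knn_posterior(model, feats)
    tibble::tibble(
      clip_name = clip_name(clip),
      n_windows = nrow(feats),
      preictal_probability = aggregate_windows(post),
      window_posteriors = list(post)
    )
  })
  dplyr::bind_rows(rows)
}
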