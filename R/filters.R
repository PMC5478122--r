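# Supervised per-band spectral filters.
#
# Conventions: class 0 = interictal (Z in the moment notation), class 1 =
# preictal (Y). All second-moment operators are applied matrix-free: the
# d x d matrices are never materialized, only products M %*% v through the
# stored class sample matrices.

#' Class-conditional moment accessors
#'
#' Holds the two class sample matrices together with their means and exposes
#' raw second-moment matrix-vector products `E[ZZ']v` and `E[YY']v` computed
#' as `(1/n) X' (X v)` — the d x d moment matrices are never formed.
#'
#' @param features0 Numeric matrix `[n0 x d]`, class 0 (interictal) window
#'   features.
#' @param features1 Numeric matrix `[n1 x d]`, class 1 (preictal) window
#'   features.
#' @return An object of class `moment_set` with fields `n0`, `n1`, `d`,
#'   `mean0`, `mean1` and moment product functions `m2_0(v)`, `m2_1(v)`.
#' @export
accumulate_moments <- function(features0, features1) {
  features0 <- as.matrix(features0)
  features1 <- as.matrix(features1)
  if (ncol(features0) != ncol(features1)) {
    abort("feature dimension mismatch between the two classes")
  }
  if (nrow(features0) < 2L || nrow(features1) < 2L) {
    abort("each class needs at least 2 samples")
  }
  structure(
    list(
      n0 = nrow(features0), n1 = nrow(features1), d = ncol(features0),
      mean0 = colMeans(features0), mean1 = colMeans(features1),
      x0 = features0, x1 = features1,
      m2_0 = function(v) drop(crossprod(features0, features0 %*% v)) / nrow(features0),
      m2_1 = function(v) drop(crossprod(features1, features1 %*% v)) / nrow(features1)
    ),
    class = "moment_set"
  )
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> d = %d, n0 = %d (interictal), n1 = %d (preictal)\n",
              x$d, x$n0, x$n1))
  invisible(x)
}

#' Pairing policy for the paired squared-difference (SqD) operator
#'
#' `independent_moments` (default) expands `E[(Z-Y)(Z-Y)']` under independent
#' pairing into raw moments — deterministic, no pairing noise. `sampled_pairs`
#' follows the streaming estimate: per sweep every preictal sample is paired
#' with an interictal sample drawn (seeded) with replacement, and the
#' operator is averaged over `sweeps` sweeps, reshuffled on every matrix
#' product.
#'
#' @param policy `"independent_moments"` or `"sampled_pairs"`.
#' @param seed Integer seed controlling the sampled pairings.
#' @param sweeps Sweeps averaged per operator application (sampled_pairs).
#' @return An object of class `pair_stream`.
#' @export
pair_stream <- function(policy = c("independent_moments", "sampled_pairs"),
                        seed = 1L, sweeps = 4L) {
  policy <- match.arg(policy)
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(list(policy = policy, seed = as.integer(seed),
                 sweeps = as.integer(sweeps), state = env),
            class = "pair_stream")
}

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Matrix-free operator product for a supervised filter objective
#'
#' Returns `M v` where `M` is the objective's matrix: `ds` ->
#' `E[ZZ'] - E[YY']`; `var` -> `E[ZZ'] - E[YY'] - E[Z]E[Z]' + E[Y]E[Y]'`
#' (the covariance difference); `tvm` ->
#' `E[ZZ'] - E[YY'] + (E[Y]-E[Z])E[Y]' + E[Y](E[Y]-E[Z])'`; `sqd` ->
#' `E[(Z-Y)(Z-Y)']` (independent-moment expansion or sampled pair sweeps
#' according to `pairs`).
#'
#' @param method One of `"var"`, `"tvm"`, `"ds"`, `"sqd"`.
#' @param moments A [accumulate_moments()] object.
#' @param v Numeric vector of length `moments$d`, nonzero.
#' @param pairs A [pair_stream()]; used by `method = "sqd"` only.
#' @return Numeric vector `M v`.
#' @export
filter_matvec <- function(method, moments, v, pairs = pair_stream()) {
  stopifnot(inherits(moments, "moment_set"))
  if (length(v) != moments$d) abort("v has wrong dimension")
  if (sqrt(sum(v^2)) == 0) abort("v must be nonzero")
  m <- moments
  switch(method,
    ds = m$m2_0(v) - m$m2_1(v),
    var = m$m2_0(v) - m$m2_1(v) - m$mean0 * sum(m$mean0 * v) +
      m$mean1 * sum(m$mean1 * v),
    tvm = m$m2_0(v) - m$m2_1(v) +
      (m$mean1 - m$mean0) * sum(m$mean1 * v) +
      m$mean1 * sum((m$mean1 - m$mean0) * v),
    sqd = {
      if (pairs$policy == "independent_moments") {
        m$m2_0(v) + m$m2_1(v) - m$mean0 * sum(m$mean1 * v) -
          m$mean1 * sum(m$mean0 * v)
      } else {
        pairs$state$calls <- pairs$state$calls + 1L
        call_id <- pairs$state$calls
        acc <- numeric(m$d)
        for (s in seq_len(pairs$sweeps)) {
          idx <- with_local_seed(
            pairs$seed + 7919L * ((call_id - 1L) * pairs$sweeps + s),
            sample.int(m$n0, m$n1, replace = TRUE)
          )
          d_mat <- m$x0[idx, , drop = FALSE] - m$x1
          acc <- acc + drop(crossprod(d_mat, d_mat %*% v)) / m$n1
        }
        acc / pairs$sweeps
      }
    },
    abort(sprintf("unknown method '%s'", method))
  )
}

#' Power iteration for a matrix-free symmetric operator
#'
#' Starts from the normalized all-ones vector and repeatedly applies the
#' operator, normalizing each iterate; stops when `1 - |u_k . u_(k-1)| < tol`
#' or after `max_iter` products. The convergence test uses the absolute
#' inner product, so iterates converging up to an alternating sign (negative
#' dominant eigenvalue) are detected as converged. The returned eigenvalue is
#' the Rayleigh quotient `u' M u`.
#'
#' By default the *dominant* (largest-magnitude) eigenpair is reported; for
#' the class-contrast objectives this is the direction of strongest class
#' difference regardless of its sign. `ensure = "algebraic"` instead re-runs
#' the iteration on the shifted operator `M + |lambda| I` whenever the
#' dominant eigenvalue is negative, reporting the algebraically largest
#' eigenpair.
#'
#' @param matvec Function `v -> M v` for a symmetric operator `M`.
#' @param d Dimension.
#' @param tol Convergence tolerance on `1 - |cos|` between iterates.
#' @param max_iter Maximum number of iterations.
#' @param ensure `"dominant"` (largest `|lambda|`) or `"algebraic"` (largest
#'   `lambda`).
#' @return List with `u` (unit vector, sign fixed so its largest-magnitude
#'   component is positive, first index on ties), `lambda` (Rayleigh
#'   quotient), `iterations`, `converged`.
#' @export
power_iteration <- function(matvec, d, tol = 1e-9, max_iter = 1000L,
                            ensure = c("dominant", "algebraic")) {
  ensure <- match.arg(ensure)
  stopifnot(d >= 1L, tol > 0)
  run <- function(mv) {
    u <- rep(1, d) / sqrt(d)
    converged <- FALSE
    iter <- 0L
    for (k in seq_len(max_iter)) {
      iter <- k
      v <- mv(u)
      nv <- sqrt(sum(v^2))
      if (nv == 0) abort("degenerate operator: matrix-vector product vanished")
      u_new <- v / nv
      if (1 - abs(sum(u_new * u)) < tol) {
        u <- u_new
        converged <- TRUE
        break
      }
      u <- u_new
    }
    lambda <- sum(u * mv(u))
    list(u = u, lambda = lambda, iterations = iter, converged = converged)
  }
  res <- run(matvec)
  if (ensure == "algebraic" && res$lambda < 0) {
    shift <- abs(res$lambda)
    res2 <- run(function(v) matvec(v) + shift * v)
    res2$lambda <- sum(res2$u * matvec(res2$u))
    res2$iterations <- res$iterations + res2$iterations
    res <- res2
  }
  i <- which.max(abs(res$u))
  if (res$u[i] < 0) res$u <- -res$u
  res
}

# stack the windows of one channel (or all channels, joint scope) restricted
# to a bin range, across a list of spectral tensors
stack_band_features <- function(tensors, channel, bins, joint = FALSE) {
  mats <- lapply(tensors, function(tn) {
    if (joint) {
      nch <- dim(tn$values)[2L]
      do.call(cbind, lapply(seq_len(nch), function(c) {
        m <- tn$values[, c, bins, drop = FALSE]
        dim(m) <- dim(m)[c(1L, 3L)]
        m
      }))
    } else {
      m <- tn$values[, channel, bins, drop = FALSE]
      dim(m) <- dim(m)[c(1L, 3L)]
      m
    }
  })
  do.call(rbind, mats)
}

as_tensor_list <- function(x) {
  if (inherits(x, "spectral_tensor")) list(x) else x
}

#' Estimate a per-band filter bank
#'
#' Estimates one weight vector per (channel, band) — or per band over the
#' concatenated channels with `scope = "joint"` — from labeled training
#' spectra. The window is the sample unit: every spectral window of every
#' training clip contributes one sample of its clip's class. Methods:
#'
#' * `pbf`: the conventional power-band filter, a uniform average
#'   (weights `1/m` over the band's `m` bins); unsupervised baseline.
#' * `dm`: difference of means, closed form
#'   `u = (E[Z]-E[Y]) / ||E[Z]-E[Y]||`.
#' * `var`, `tvm`, `ds`, `sqd`: unit eigenvector of the objective's matrix
#'   (variance difference, variance-mean trade-off, raw second-moment
#'   difference, paired squared difference), found by matrix-free
#'   [power_iteration()].
#'
#' @param spectra0 `spectral_tensor` or list of tensors for class 0
#'   (interictal) training clips.
#' @param spectra1 Same for class 1 (preictal).
#' @param method One of `"pbf"`, `"dm"`, `"var"`, `"tvm"`, `"ds"`, `"sqd"`.
#' @param bands Band definition tibble; defaults to [canonical_bands()].
#' @param scope `"per_channel"` (default; one filter per channel per band) or
#'   `"joint"` (one filter per band across all channels).
#' @param pairing A [pair_stream()] for `method = "sqd"`.
#' @param tol,max_iter Power-iteration controls.
#' @param ensure Eigenpair selection, see [power_iteration()].
#' @return An object of class `filter_weights`.
#' @export
estimate_filter <- function(spectra0, spectra1,
                            method = c("pbf", "dm", "var", "tvm", "ds", "sqd"),
                            bands = canonical_bands(),
                            scope = c("per_channel", "joint"),
                            pairing = pair_stream(),
                            tol = 1e-9, max_iter = 1000L,
                            ensure = c("dominant", "algebraic")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  ensure <- match.arg(ensure)
  t0 <- as_tensor_list(spectra0)
  t1 <- as_tensor_list(spectra1)
  ref <- t0[[1]]
  nch <- dim(ref$values)[2L]
  ranges <- band_bin_ranges(ref$sampling_rate_hz, ref$fft_length, bands)
  if (any(ranges$empty)) {
    abort(sprintf("empty band(s) at rate %g Hz: %s", ref$sampling_rate_hz,
                  paste(ranges$band[ranges$empty], collapse = ", ")))
  }
  nb <- nrow(ranges)
  chan_slots <- if (scope == "joint") 1L else nch
  weights <- vector("list", chan_slots)
  lambda <- matrix(NA_real_, chan_slots, nb)
  iterations <- matrix(NA_integer_, chan_slots, nb)
  converged <- matrix(NA, chan_slots, nb)
  band_names <- as.character(ranges$band)
  for (ci in seq_len(chan_slots)) {
    weights[[ci]] <- vector("list", nb)
    names(weights[[ci]]) <- band_names
    for (bi in seq_len(nb)) {
      bins <- band_bins(ranges[bi, ])
      m <- length(bins) * (if (scope == "joint") nch else 1L)
      if (method == "pbf") {
        weights[[ci]][[bi]] <- rep(1 / m, m)
        next
      }
      x0 <- stack_band_features(t0, ci, bins, joint = scope == "joint")
      x1 <- stack_band_features(t1, ci, bins, joint = scope == "joint")
      if (nrow(x0) < 2L || nrow(x1) < 2L) {
        abort("each class needs at least 2 training windows")
      }
      if (method == "dm") {
        u <- colMeans(x0) - colMeans(x1)
        nrm <- sqrt(sum(u^2))
        if (nrm == 0) abort("degenerate operator: class means coincide")
        weights[[ci]][[bi]] <- u / nrm
      } else {
        mom <- accumulate_moments(x0, x1)
        res <- power_iteration(
          function(v) filter_matvec(method, mom, v, pairs = pairing),
          d = m, tol = tol, max_iter = max_iter, ensure = ensure
        )
        weights[[ci]][[bi]] <- res$u
        lambda[ci, bi] <- res$lambda
        iterations[ci, bi] <- res$iterations
        converged[ci, bi] <- res$converged
      }
    }
  }
  structure(
    list(
      method = method, scope = scope,
      sampling_rate_hz = ref$sampling_rate_hz, fft_length = ref$fft_length,
      spectrum = ref$spectrum, log_order = ref$log_order,
      n_channels = nch, band_ranges = ranges,
      weights = weights, lambda = lambda, iterations = iterations,
      converged = converged
    ),
    class = "filter_weights"
  )
}

#' @export
print.filter_weights <- function(x, ...) {
  cat(sprintf(
    "<filter_weights> method %s (%s), %d channels x %d bands, fft %d @ %g Hz\n",
    toupper(x$method), x$scope, x$n_channels, nrow(x$band_ranges),
    x$fft_length, x$sampling_rate_hz
  ))
  if (!all(is.na(x$converged))) {
    cat(sprintf("  power iteration: %d/%d converged, median %g iterations\n",
                sum(x$converged, na.rm = TRUE), sum(!is.na(x$converged)),
                stats::median(x$iterations, na.rm = TRUE)))
  }
  invisible(x)
}

#' Apply a filter bank to a spectral tensor
#'
#' Produces the per-window feature matrix: feature `(w, c, b)` is the inner
#' product of the (channel `c`, band `b`) weight vector with the window's
#' spectral bins of that band. Columns are ordered channel-major,
#' band-minor (`ch1_delta, ch1_theta, ..., ch2_delta, ...`); with
#' `scope = "joint"` there is one column per band. For tensors built with
#' `log_order = "post"` the weighted sums are clamped to `> -1 + 1e-12` and
#' log1p-compressed here.
#'
#' @param spectra A `spectral_tensor`.
#' @param weights A [estimate_filter()] filter bank consistent with the
#'   tensor's sampling rate and FFT length.
#' @return Numeric matrix `[windows x features]` with named columns.
#' @export
apply_filters <- function(spectra, weights) {
  stopifnot(inherits(spectra, "spectral_tensor"),
            inherits(weights, "filter_weights"))
  if (spectra$fft_length != weights$fft_length ||
      spectra$sampling_rate_hz != weights$sampling_rate_hz) {
    abort("dimension mismatch: tensor and filter bank disagree on rate/FFT length")
  }
  nch <- dim(spectra$values)[2L]
  if (weights$scope == "per_channel" && nch != weights$n_channels) {
    abort("dimension mismatch: tensor channel count differs from filter bank")
  }
  ranges <- weights$band_ranges
  nb <- nrow(ranges)
  nw <- dim(spectra$values)[1L]
  joint <- weights$scope == "joint"
  chan_slots <- if (joint) 1L else nch
  out <- matrix(NA_real_, nw, chan_slots * nb)
  cols <- character(chan_slots * nb)
  k <- 0L
  for (ci in seq_len(chan_slots)) {
    for (bi in seq_len(nb)) {
      k <- k + 1L
      bins <- band_bins(ranges[bi, ])
      x <- stack_band_features(list(spectra), ci, bins, joint = joint)
      f <- drop(x %*% weights$weights[[ci]][[bi]])
      if (identical(spectra$log_order, "post")) {
        f <- log1p(pmax(f, -1 + 1e-12))
      }
      out[, k] <- f
      cols[k] <- if (joint) as.character(ranges$band[bi]) else {
        sprintf("ch%02d_%s", ci, ranges$band[bi])
      }
    }
  }
  colnames(out) <- cols
  out
}

#' Persist / load a filter bank as JSON
#'
#' @param weights A `filter_weights` object.
#' @param path JSON file path.
#' @return `read_filter_weights()` returns the `filter_weights` object.
#' @export
write_filter_weights <- function(weights, path) {
  stopifnot(inherits(weights, "filter_weights"))
  payload <- list(
    format = "seizecast-filter-weights-v1",
    method = weights$method, scope = weights$scope,
    sampling_rate_hz = weights$sampling_rate_hz,
    fft_length = weights$fft_length,
    spectrum = weights$spectrum, log_order = weights$log_order,
    n_channels = weights$n_channels,
    band_ranges = as.data.frame(
      dplyr::mutate(weights$band_ranges, band = as.character(.data$band))),
    weights = weights$weights,
    lambda = weights$lambda, iterations = weights$iterations,
    converged = weights$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_weights
#' @export
read_filter_weights <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  ranges <- dplyr::bind_rows(lapply(p$band_ranges, tibble::as_tibble))
  ranges$band <- factor(ranges$band, levels = ranges$band)
  ranges$first_bin <- as.integer(ranges$first_bin)
  ranges$last_bin <- as.integer(ranges$last_bin)
  ranges$n_bins <- as.integer(ranges$n_bins)
  chan_slots <- if (p$scope == "joint") 1L else p$n_channels
  weights <- lapply(seq_len(chan_slots), function(ci) {
    lapply(p$weights[[ci]], as.numeric)
  })
  as_mat <- function(rows, mode = "numeric") {
    m <- do.call(rbind, lapply(rows, function(r) {
      r[vapply(r, is.null, logical(1))] <- NA
      unlist(r) %||% rep(NA, nrow(ranges))
    }))
    if (is.null(m)) m <- matrix(NA, chan_slots, nrow(ranges))
    storage.mode(m) <- mode
    m
  }
  structure(
    list(
      method = p$method, scope = p$scope,
      sampling_rate_hz = p$sampling_rate_hz, fft_length = p$fft_length,
      spectrum = p$spectrum, log_order = p$log_order,
      n_channels = p$n_channels, band_ranges = ranges,
      weights = weights,
      lambda = as_mat(p$lambda),
      iterations = as_mat(p$iterations, "integer"),
      converged = as_mat(p$converged, "logical")
    ),
    class = "filter_weights"
  )
}
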