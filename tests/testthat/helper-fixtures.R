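# fixture builders shared across the test files

random_clip <- function(channels = 2L, rate = 400, duration = 2,
                        kind = "interictal", index = 1L, seq_index = 1L,
                        subject = "Sub_1") {
  ieeg_clip(
    data = matrix(rnorm(channels * round(rate * duration)), channels),
    sampling_rate_hz = rate, subject_id = subject, segment_kind = kind,
    segment_index = index, sequence_index = seq_index
  )
}

# quantize a matrix to float32 representable values (native dialect storage)
quantize_f32 <- function(x) {
  v <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  matrix(v, nrow(x), ncol(x))
}

# tiny spectral tensor wrapped around an explicit feature matrix, so filter
# estimation can be driven with arbitrary data: one band covers all d bins
tensor_from_matrix <- function(x, rate = 100, n_channels = 1L) {
  d <- ncol(x) / n_channels
  vals <- array(NA_real_, c(nrow(x), n_channels, d))
  for (c in seq_len(n_channels)) {
    vals[, c, ] <- x[, ((c - 1) * d + 1):(c * d), drop = FALSE]
  }
  structure(
    list(values = vals, freq_hz = seq_len(d) * rate / (2 * d),
         window_starts_sec = seq_len(nrow(x)) - 1, sampling_rate_hz = rate,
         fft_length = 2 * d, spectrum = "magnitude", log_order = "pre"),
    class = "spectral_tensor"
  )
}

# one band spanning every retained bin of tensor_from_matrix fixtures
all_bins_band <- function() {
  tibble::tibble(band = factor("all"), low_hz = 0, high_hz = Inf)
}

# dense matrices for the filter objectives, assembled directly from the
# definition (the oracle the matrix-free path is checked against)
dense_objective_matrix <- function(method, x0, x1) {
  m2 <- function(x) crossprod(x) / nrow(x)
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  switch(method,
    ds = m2(x0) - m2(x1),
    var = m2(x0) - m2(x1) - tcrossprod(mu0) + tcrossprod(mu1),
    tvm = m2(x0) - m2(x1) + tcrossprod(mu1 - mu0, mu1) +
      tcrossprod(mu1, mu1 - mu0),
    sqd = m2(x0) + m2(x1) - tcrossprod(mu0, mu1) - tcrossprod(mu1, mu0)
  )
}

# dominant (largest |eigenvalue|) eigenpair of a dense symmetric matrix
dense_dominant_eigen <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  i <- which.max(abs(e$values))
  list(u = e$vectors[, i], lambda = e$values[i])
}

random_two_class <- function(d, n0 = 60L, n1 = 40L) {
  shift <- rnorm(d, 0, 0.5)
  scale <- exp(rnorm(d, 0, 0.3))
  x0 <- matrix(rnorm(n0 * d), n0) %*% diag(scale, d)
  x1 <- sweep(matrix(rnorm(n1 * d, 0, 1.2), n1) %*% diag(scale, d), 2, shift, `+`)
  list(x0 = x0, x1 = x1)
}
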