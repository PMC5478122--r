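test_that("moment accessors reproduce hand-computed means and products", {
  m <- accumulate_moments(matrix(c(1, 3, 0, 0), 2), matrix(c(0, 0, 1, 3), 2))
  expect_equal(m$mean0, c(2, 0))
  expect_equal(m$mean1, c(0, 2))
  expect_equal(m$m2_0(c(1, 0)), c(5, 0))  # (1^2 + 3^2) / 2
  expect_error(accumulate_moments(matrix(1, 1, 2), matrix(1, 3, 2)),
               "at least 2 samples")
  expect_error(accumulate_moments(matrix(1, 2, 2), matrix(1, 2, 3)),
               "dimension mismatch")
})

test_that("matrix-free products equal densely assembled objective matrices", {
  # hand case: exact second moments diag(4,1) vs diag(1,2)
  x0 <- matrix(c(2, 2, -2, -2, 1, -1, 1, -1), 4)
  x1 <- matrix(c(1, 1, -1, -1, sqrt(2), -sqrt(2), sqrt(2), -sqrt(2)), 4)
  mm <- accumulate_moments(x0, x1)
  expect_equal(filter_matvec("ds", mm, c(1, 0)), c(3, 0))
  # dense-assembly oracle on random small data, all four operators
  withr::local_seed(21)
  for (i in 1:10) {
    d <- sample(2:12, 1)
    dat <- random_two_class(d, n0 = 15L, n1 = 9L)
    mom <- accumulate_moments(dat$x0, dat$x1)
    v <- rnorm(d)
    for (method in c("ds", "var", "tvm", "sqd")) {
      dense <- dense_objective_matrix(method, dat$x0, dat$x1)
      expect_equal(filter_matvec(method, mom, v), drop(dense %*% v),
                   tolerance = 1e-10)
    }
  }
  expect_error(filter_matvec("nope", mm, c(1, 0)), "unknown method")
  expect_error(filter_matvec("ds", mm, c(0, 0)), "nonzero")
})

test_that("sampled-pair SqD matches the rank-one hand computation on degenerate pairs", {
  # every admissible pairing has difference (3, 4): matvec of (1,0) must be
  # ((1,0).(3,4)) * (3,4) = (9, 12) for both pairing policies
  x0 <- matrix(rep(c(5, 6), each = 3), 3)
  x1 <- matrix(rep(c(2, 2), each = 3), 3)
  mm <- accumulate_moments(x0, x1)
  expect_equal(filter_matvec("sqd", mm, c(1, 0),
                             pair_stream("sampled_pairs", seed = 3)), c(9, 12))
  expect_equal(filter_matvec("sqd", mm, c(1, 0)), c(9, 12))
})

test_that("sampled-pair SqD agrees with independent moments on independent classes", {
  withr::local_seed(31)
  for (d in c(4L, 12L, 20L)) {
    dat <- random_two_class(d, n0 = 300L, n1 = 200L)
    t0 <- tensor_from_matrix(dat$x0)
    t1 <- tensor_from_matrix(dat$x1)
    f_ind <- estimate_filter(t0, t1, "sqd", bands = all_bins_band(),
                             pairing = pair_stream("independent_moments"))
    f_smp <- estimate_filter(t0, t1, "sqd", bands = all_bins_band(),
                             pairing = pair_stream("sampled_pairs", seed = 9,
                                                   sweeps = 8L),
                             tol = 1e-7, max_iter = 300L)
    cosine <- abs(sum(f_ind$weights[[1]][[1]] * f_smp$weights[[1]][[1]]))
    expect_gt(cosine, 0.99)
  }
})

test_that("sampled pairings are reproducible from the seed", {
  withr::local_seed(1)
  dat <- random_two_class(6L, 40L, 25L)
  mm <- accumulate_moments(dat$x0, dat$x1)
  v <- rnorm(6)
  a <- filter_matvec("sqd", mm, v, pair_stream("sampled_pairs", seed = 42))
  b <- filter_matvec("sqd", mm, v, pair_stream("sampled_pairs", seed = 42))
  c_ <- filter_matvec("sqd", mm, v, pair_stream("sampled_pairs", seed = 43))
  expect_identical(a, b)
  expect_false(identical(a, c_))
})

test_that("power iteration solves small diagonal problems exactly", {
  r <- power_iteration(function(v) c(3, 1) * v, 2)
  expect_equal(r$u, c(1, 0), tolerance = 1e-4)
  expect_equal(r$lambda, 3, tolerance = 1e-9)
  expect_true(r$converged)
  # dominant convention keeps the negative eigenvalue of largest magnitude
  r2 <- power_iteration(function(v) c(-5, 2) * v, 2)
  expect_equal(abs(r2$u), c(1, 0), tolerance = 1e-4)
  expect_equal(r2$lambda, -5, tolerance = 1e-9)
  # algebraic convention shifts and reports the largest eigenvalue
  r3 <- power_iteration(function(v) c(-5, 2) * v, 2, ensure = "algebraic")
  expect_equal(abs(r3$u), c(0, 1), tolerance = 1e-4)
  expect_equal(r3$lambda, 2, tolerance = 1e-9)
  # one-dimensional operator converges on the first iteration
  r4 <- power_iteration(function(v) 7 * v, 1)
  expect_identical(r4$iterations, 1L)
  expect_equal(r4$lambda, 7)
  expect_error(power_iteration(function(v) 0 * v, 3), "degenerate operator")
})

test_that("sign convention puts the largest-magnitude component positive", {
  withr::local_seed(4)
  for (i in 1:5) {
    dat <- random_two_class(8L)
    mom <- accumulate_moments(dat$x0, dat$x1)
    r <- power_iteration(function(v) filter_matvec("sqd", mom, v), 8L)
    expect_gte(r$u[which.max(abs(r$u))], 0)
  }
})

test_that("estimated eigenfilters match dense eigendecomposition (oracle)", {
  withr::local_seed(7)
  for (i in 1:25) {
    d <- sample(3:40, 1)
    dat <- random_two_class(d)
    t0 <- tensor_from_matrix(dat$x0)
    t1 <- tensor_from_matrix(dat$x1)
    for (method in c("ds", "var", "tvm", "sqd")) {
      fw <- estimate_filter(t0, t1, method, bands = all_bins_band())
      oracle <- dense_dominant_eigen(dense_objective_matrix(method, dat$x0,
                                                            dat$x1))
      u <- fw$weights[[1]][[1]]
      expect_gt(abs(sum(u * oracle$u)), 0.999)
      expect_lt(abs(fw$lambda[1, 1] - oracle$lambda) / abs(oracle$lambda),
                1e-6)
    }
  }
})

test_that("quadratic forms reproduce the variance and trade-off objectives", {
  withr::local_seed(8)
  for (i in 1:10) {
    d <- sample(2:15, 1)
    dat <- random_two_class(d, 25L, 18L)
    mom <- accumulate_moments(dat$x0, dat$x1)
    u <- rnorm(d); u <- u / sqrt(sum(u^2))
    proj0 <- drop(dat$x0 %*% u); proj1 <- drop(dat$x1 %*% u)
    var_n <- function(x) mean(x^2) - mean(x)^2  # population variance
    # VAR: u' S u == Var(pi(Z)) - Var(pi(Y)) on sample moments
    expect_equal(sum(u * filter_matvec("var", mom, u)),
                 var_n(proj0) - var_n(proj1), tolerance = 1e-10)
    # TVM: u' M u == (E[pi(Z) - pi(Y)])^2 + Var(pi(Z)) - Var(pi(Y))
    expect_equal(sum(u * filter_matvec("tvm", mom, u)),
                 (mean(proj0) - mean(proj1))^2 + var_n(proj0) - var_n(proj1),
                 tolerance = 1e-10)
  }
})

test_that("closed-form filters: PBF uniform and DM normalized mean difference", {
  withr::local_seed(9)
  x0 <- matrix(rnorm(40 * 6), 40)
  x1 <- matrix(rnorm(30 * 6), 30)
  t0 <- tensor_from_matrix(x0); t1 <- tensor_from_matrix(x1)
  pbf <- estimate_filter(t0, t1, "pbf", bands = all_bins_band())
  expect_equal(pbf$weights[[1]][[1]], rep(1 / 6, 6))
  dm <- estimate_filter(t0, t1, "dm", bands = all_bins_band())
  expected <- colMeans(x0) - colMeans(x1)
  expect_equal(dm$weights[[1]][[1]], expected / sqrt(sum(expected^2)))
  # frozen example: mean difference (0, 2, 0) gives u = (0, 1, 0)
  t0b <- tensor_from_matrix(matrix(rep(c(1, 2, 3), each = 4), 4) +
                              matrix(rnorm(12, 0, 1e-9), 4))
  t1b <- tensor_from_matrix(matrix(rep(c(1, 0, 3), each = 4), 4) +
                              matrix(rnorm(12, 0, 1e-9), 4))
  dmb <- estimate_filter(t0b, t1b, "dm", bands = all_bins_band())
  expect_equal(dmb$weights[[1]][[1]], c(0, 1, 0), tolerance = 1e-6)
})

test_that("the DM direction maximizes the mean-difference functional", {
  withr::local_seed(10)
  dat <- random_two_class(12L)
  t0 <- tensor_from_matrix(dat$x0); t1 <- tensor_from_matrix(dat$x1)
  dm <- estimate_filter(t0, t1, "dm", bands = all_bins_band())
  u <- dm$weights[[1]][[1]]
  diff <- colMeans(dat$x0) - colMeans(dat$x1)
  best <- sum(u * diff)
  rand <- matrix(rnorm(1000 * 12), 1000)
  rand <- rand / sqrt(rowSums(rand^2))
  expect_true(all(drop(rand %*% diff) <= best + 1e-12))
})

test_that("all filter objectives are scale equivariant", {
  withr::local_seed(12)
  dat <- random_two_class(9L)
  t0 <- tensor_from_matrix(dat$x0); t1 <- tensor_from_matrix(dat$x1)
  t0s <- tensor_from_matrix(dat$x0 * 37); t1s <- tensor_from_matrix(dat$x1 * 37)
  for (method in c("pbf", "dm", "var", "tvm", "ds", "sqd")) {
    a <- estimate_filter(t0, t1, method, bands = all_bins_band())
    b <- estimate_filter(t0s, t1s, method, bands = all_bins_band())
    expect_equal(a$weights[[1]][[1]], b$weights[[1]][[1]], tolerance = 1e-6)
  }
})

test_that("filter banks apply per channel and band with fixed column order", {
  # uniform average of an all-ones tensor is 1 everywhere
  ones <- structure(
    list(values = array(1, c(3, 2, 512)), freq_hz = seq_len(512) * 400 / 1024,
         window_starts_sec = 0:2, sampling_rate_hz = 400, fft_length = 1024,
         spectrum = "magnitude", log_order = "pre"),
    class = "spectral_tensor"
  )
  zeros <- ones; zeros$values[] <- 0
  fw <- estimate_filter(ones, zeros, "pbf")
  feats <- apply_filters(ones, fw)
  expect_equal(dim(feats), c(3L, 12L))
  expect_true(all(abs(feats - 1) < 1e-12))
  expect_identical(colnames(feats)[1:7],
                   c("ch01_delta", "ch01_theta", "ch01_alpha", "ch01_beta",
                     "ch01_low_gamma", "ch01_high_gamma", "ch02_delta"))
  expect_true(all(apply_filters(zeros, fw) == 0))
  # 16 channels x 6 bands -> 96 columns
  wide <- ones; wide$values <- array(1, c(1, 16, 512))
  fw16 <- estimate_filter(wide, zeros, "pbf")
  fw16$n_channels <- 16L
  expect_equal(ncol(apply_filters(wide, fw16)), 96L)
  # joint scope: one filter per band across channels
  fj <- estimate_filter(ones, zeros, "pbf", scope = "joint")
  expect_equal(ncol(apply_filters(ones, fj)), 6L)
  expect_equal(length(fj$weights[[1]][[1]]), 2L * fj$band_ranges$n_bins[1])
})

test_that("filter weights survive a JSON round trip", {
  withr::local_seed(14)
  dat <- random_two_class(10L)
  fw <- estimate_filter(tensor_from_matrix(dat$x0),
                        tensor_from_matrix(dat$x1), "ds",
                        bands = all_bins_band())
  path <- file.path(withr::local_tempdir(), "weights.json")
  write_filter_weights(fw, path)
  back <- read_filter_weights(path)
  expect_equal(back$weights, fw$weights)
  expect_equal(back$lambda, fw$lambda)
  expect_identical(back$method, fw$method)
  expect_equal(back$band_ranges$first_bin, fw$band_ranges$first_bin)
})
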