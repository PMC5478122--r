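# short-clip configuration shared by the generator tests: small enough for
# fast Monte-Carlo, long enough to resolve the 38-42 Hz plant
gen_cfg <- function(effects = tibble::tibble(low_hz = 38, high_hz = 42,
                                             factor = 4,
                                             variance_only = FALSE,
                                             channels = list(1:2)),
                    ...) {
  synth_config_small(clip_duration_sec = 10, n_interictal = 1L,
                     n_preictal = 1L, channels = 2L, effects = effects, ...)
}

clip_band_power <- function(clip, low, high, channel = 1L) {
  n <- ncol(clip$data)
  freq <- seq_len(n %/% 2) * clip$sampling_rate_hz / n
  sel <- which(freq >= low & freq < high)
  mean(Mod(stats::fft(clip$data[channel, ]))[sel + 1L]^2)
}

test_that("the generator is deterministic given config and seed", {
  cfg <- gen_cfg()
  a <- generate_subject(cfg, seed = 5)
  b <- generate_subject(cfg, seed = 5)
  c_ <- generate_subject(cfg, seed = 6)
  expect_identical(a$clips[[3]]$data, b$clips[[3]]$data)
  expect_identical(a$manifest, b$manifest)
  expect_false(identical(a$clips[[3]]$data, c_$clips[[3]]$data))
  # layout: 6 clips per sequence, sequence_index cycling 1..6
  expect_equal(a$manifest$sequence_index, rep(1:6, 2))
  expect_equal(unique(table(a$manifest$seq_id, a$manifest$segment_kind)), 6L)
})

test_that("a factor-4 plant yields a preictal/interictal power ratio near 4", {
  cfg <- gen_cfg()
  pre <- numeric(0); int <- numeric(0)
  for (seed in 7:31) {  # 25 subjects x 2 sequences = 50 clips per class
    subj <- generate_subject(cfg, seed)
    kinds <- subj$manifest$segment_kind
    pre <- c(pre, vapply(subj$clips[kinds == "preictal"][1:2],
                         clip_band_power, 0, low = 38, high = 42))
    int <- c(int, vapply(subj$clips[kinds == "interictal"][1:2],
                         clip_band_power, 0, low = 38, high = 42))
  }
  ratio <- mean(pre) / mean(int)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
})

test_that("a null configuration plants no band differences", {
  cfg <- gen_cfg(effects = default_effects(2L)[0, ])
  band_means <- function(clip) {
    vapply(seq_len(nrow(canonical_bands())), function(b) {
      clip_band_power(clip, canonical_bands()$low_hz[b],
                      canonical_bands()$high_hz[b])
    }, 0)
  }
  pre <- NULL; int <- NULL
  for (seed in 1:20) {
    subj <- generate_subject(cfg, seed)
    kinds <- subj$manifest$segment_kind
    pre <- rbind(pre, t(vapply(subj$clips[kinds == "preictal"], band_means,
                               numeric(6))))
    int <- rbind(int, t(vapply(subj$clips[kinds == "interictal"], band_means,
                               numeric(6))))
  }
  for (b in 1:6) {
    se <- sqrt(var(pre[, b]) / nrow(pre) + var(int[, b]) / nrow(int))
    expect_lt(abs(mean(pre[, b]) - mean(int[, b])), 3 * se)
  }
})

test_that("the realized mean periodogram converges to the target spectrum", {
  cfg <- synth_config_small(clip_duration_sec = 10, channels = 1L,
                            n_interictal = 17L, n_preictal = 17L,
                            effects = tibble::tibble(
                              low_hz = 30, high_hz = 40, factor = 3,
                              variance_only = FALSE, channels = list(1L)))
  subj <- generate_subject(cfg, seed = 2)   # 204 clips total
  kinds <- subj$manifest$segment_kind
  n <- ncol(subj$clips[[1]]$data)
  freq <- seq_len(n %/% 2) * cfg$sampling_rate_hz / n
  mean_pgram <- function(cls) {
    mats <- vapply(subj$clips[kinds == cls],
                   function(cl) Mod(stats::fft(cl$data[1, ]))[2:(n %/% 2 + 1)]^2,
                   numeric(n %/% 2))
    rowMeans(mats)
  }
  for (cls in c("interictal", "preictal")) {
    realized <- mean_pgram(cls)
    target <- synth_target_psd(cfg, freq, cls, 1L)
    ranges <- band_bin_ranges(cfg$sampling_rate_hz, n)
    for (b in which(!ranges$empty)) {
      bins <- ranges$first_bin[b]:ranges$last_bin[b]
      rel <- abs(mean(realized[bins]) - mean(target[bins])) / mean(target[bins])
      expect_lt(rel, 0.1)
    }
  }
})

test_that("variance-only effects change spread but not mean band power", {
  cfg <- gen_cfg(effects = tibble::tibble(low_hz = 38, high_hz = 42,
                                          factor = 4, variance_only = TRUE,
                                          channels = list(1L)),
                 clip_gain_sd = 0)
  pre <- numeric(0); int <- numeric(0)
  for (seed in 1:40) {
    subj <- generate_subject(cfg, seed)
    kinds <- subj$manifest$segment_kind
    pre <- c(pre, vapply(subj$clips[kinds == "preictal"], clip_band_power, 0,
                         low = 38, high = 42))
    int <- c(int, vapply(subj$clips[kinds == "interictal"], clip_band_power, 0,
                         low = 38, high = 42))
  }
  # means comparable, across-clip variance much larger under the effect
  expect_lt(abs(log(mean(pre) / mean(int))), 0.25)
  expect_gt(var(pre) / var(int), 3)
})

test_that("recovery score measures planted weight mass", {
  cfg <- gen_cfg()
  subj <- generate_subject(cfg, 1)
  ranges <- band_bin_ranges(400, 32768)
  lg <- ranges[ranges$band == "low_gamma", ]
  planted <- planted_bins(subj$truth, 32768, 1L, lg)
  expect_true(all(planted * 400 / 32768 >= 38))
  expect_true(all(planted * 400 / 32768 < 42))
  # a filter bank with all weight on planted bins scores 1; uniform scores k/m
  fake <- structure(
    list(method = "ds", scope = "per_channel", sampling_rate_hz = 400,
         fft_length = 32768, spectrum = "magnitude", log_order = "pre",
         n_channels = 1L, band_ranges = ranges,
         weights = list(setNames(vector("list", 6), as.character(ranges$band))),
         lambda = matrix(NA, 1, 6), iterations = matrix(NA, 1, 6),
         converged = matrix(NA, 1, 6)),
    class = "filter_weights"
  )
  bins <- lg$first_bin:lg$last_bin
  u_planted <- as.numeric(bins %in% planted)
  fake$weights[[1]][["low_gamma"]] <- u_planted / sqrt(sum(u_planted))
  expect_equal(recovery_score(fake, subj$truth, 1L, "low_gamma"), 1)
  fake$weights[[1]][["low_gamma"]] <- rep(1 / sqrt(length(bins)), length(bins))
  expect_equal(recovery_score(fake, subj$truth, 1L, "low_gamma"),
               length(planted) / length(bins))
  expect_error(recovery_score(fake, subj$truth, 1L, "delta"),
               "no planted bins")
})

test_that("label shuffling destroys filter recovery of the planted bins", {
  cfg <- synth_config_small(effects = tibble::tibble(
    low_hz = 38, high_hz = 42, factor = 4, variance_only = FALSE,
    channels = list(1:2)))
  subj <- generate_subject(cfg, 11)
  tens <- lapply(subj$clips, function(cl) log_spectrum(sliding_windows(cl)))
  kinds <- subj$manifest$segment_kind
  fw <- estimate_filter(tens[kinds == "interictal"], tens[kinds == "preictal"],
                        "ds", tol = 1e-6, max_iter = 100L)
  score <- recovery_score(fw, subj$truth, 1L, "low_gamma")
  # shuffled control: stratified permutation keeping true-class proportions
  # equal in both fake groups, so no supervision survives by imbalance
  n1 <- sum(kinds == "preictal")
  k1 <- round(n1 * n1 / length(tens))
  fake1 <- withr::with_seed(12, c(
    sample(which(kinds == "preictal"), k1),
    sample(which(kinds == "interictal"), n1 - k1)))
  fw_shuf <- estimate_filter(tens[-fake1], tens[fake1], "ds",
                             tol = 1e-6, max_iter = 100L)
  shuf <- recovery_score(fw_shuf, subj$truth, 1L, "low_gamma")
  lg <- fw$band_ranges[fw$band_ranges$band == "low_gamma", ]
  baseline <- length(planted_bins(subj$truth, fw$fft_length, 1L, lg)) /
    lg$n_bins
  expect_lt(shuf, 2 * baseline)
  expect_gt(score, 2 * shuf)  # supervision concentrates mass well above chance
})

test_that("single-method single-seed benchmark gives a one-row table", {
  cfg <- synth_config_small(clip_duration_sec = 60, channels = 2L,
                            n_interictal = 3L, n_preictal = 2L,
                            effects = tibble::tibble(
                              low_hz = 38, high_hz = 42, factor = 4,
                              variance_only = FALSE, channels = list(1:2)))
  bm <- benchmark_filters(cfg, methods = "pbf", seeds = 3, k = 10)
  expect_equal(nrow(bm), 1L)
  expect_identical(bm$method, "pbf")
  expect_gte(bm$auc, 0); expect_lte(bm$auc, 1)
  g <- glance(bm)
  expect_equal(g$n_seeds, 1L)
})
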