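#' Tie-corrected Mann-Whitney AUC
#'
#' Probability that a random positive scores above a random negative, with
#' ties credited 1/2. Equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores Numeric score vector (higher = more preictal).
#' @param labels Binary vector (1 = positive/preictal).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)  # midranks: ties get 0.5 credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @inheritParams auc
#' @return A tibble of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`, nondecreasing from (0, 0) to (1, 1), with the trapezoidal AUC in
#'   attribute `"auc"` (also via [glance()]).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- rev(!duplicated(rev(s)))  # last index of each tied score block
  tp <- cumsum(l)[keep]
  fp <- cumsum(1L - l)[keep]
  out <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
  trap <- sum(diff(out$fpr) * (head(out$tpr, -1) + tail(out$tpr, -1)) / 2)
  structure(out, auc = trap, class = c("roc_curve", class(out)))
}

#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_thresholds = nrow(x) - 1L)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d points)\n", attr(x, "auc"), nrow(x)))
  NextMethod()
}

# placement values: V10[i] = mean_j psi(x_i, y_j) over negatives, per positive
# (and V01 per negative), with psi = 1, 1/2, 0 for >, =, <
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(n0 <- neg)
  # midrank formulation (Sun & Xu): placements from ranks, O((m+n) log(m+n))
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos)
  r_neg <- rank(neg)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

#' DeLong paired test for the difference of two correlated AUCs
#'
#' Both scorers must score the same samples (same labels). The variance of
#' `auc_a - auc_b` is estimated from the empirical covariance of the
#' placement values (structural components) of the two scorers; the test
#' statistic is compared to a standard normal.
#'
#' @param scores_a,scores_b Score vectors of the two models on the same
#'   samples.
#' @param labels Shared binary labels (1 = positive).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return Object of class `auc_comparison`: list with `auc_a`, `auc_b`,
#'   `var_diff`, `z`, `p_value`, `alternative`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    pa <- delong_placements(scores_a, labels)
    res <- list(auc_a = pa$theta, auc_b = pa$theta, var_diff = 0, z = 0,
                p_value = 1, alternative = alternative)
    class(res) <- "auc_comparison"
    return(res)
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$theta - pb$theta
  if (var_diff <= 0) {
    if (abs(diff) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      abort("zero placement variance with unequal AUCs: DeLong test undefined")
    }
  } else {
    z <- diff / sqrt(var_diff)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE)
    )
  }
  res <- list(auc_a = pa$theta, auc_b = pb$theta, var_diff = var_diff, z = z,
              p_value = p, alternative = alternative)
  class(res) <- "auc_comparison"
  res
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "<auc_comparison> AUC_a = %.4f, AUC_b = %.4f, z = %.3f, p = %.3g (%s)\n",
    x$auc_a, x$auc_b, x$z, x$p_value, x$alternative
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.auc_comparison <- function(x, ...) {
  tibble::tibble(
    auc_a = x$auc_a, auc_b = x$auc_b, estimate = x$auc_a - x$auc_b,
    var_diff = x$var_diff, statistic = x$z, p_value = x$p_value,
    alternative = x$alternative
  )
}

#' Per-subject and pooled AUC report
#'
#' One AUC per subject plus a pooled AUC over the union of all subjects'
#' scores and labels (the contest-style pool). A subject whose labels are all
#' one class gets an `NA` per-subject AUC; its scores still enter the pool.
#'
#' @param predictions Tibble with columns `subject_id`, `score` and `label`
#'   (1 = preictal).
#' @return Tibble with columns `subject_id` (including `"pool"`), `auc`,
#'   `n_clips`, `n_preictal`.
#' @export
report_auc <- function(predictions) {
  stopifnot(all(c("subject_id", "score", "label") %in% names(predictions)))
  per <- predictions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      auc = if (dplyr::n_distinct(.data$label) < 2L) NA_real_
            else auc(.data$score, .data$label),
      n_clips = dplyr::n(),
      n_preictal = sum(.data$label == 1L),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$subject_id)
  pool <- tibble::tibble(
    subject_id = "pool",
    auc = auc(predictions$score, predictions$label),
    n_clips = nrow(predictions),
    n_preictal = sum(predictions$label == 1L)
  )
  dplyr::bind_rows(per, pool)
}
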