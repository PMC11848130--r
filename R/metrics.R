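#' ROC-AUC (Mann-Whitney probability)
#'
#' The probability that a random positive outranks a random negative, with
#' half credit for ties - computed from mid-ranks, so it equals the
#' normalized Mann-Whitney U statistic exactly.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc needs both classes present")
  r <- rank(scores)  # mid-ranks give ties half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC (average precision)
#'
#' Area under the precision-recall curve in the average-precision
#' formulation: the sum over descending score thresholds of precision times
#' the recall increment (step-wise interpolation, no trapezoid). Tied scores
#' are handled as a single threshold. Its baseline for random scores is the
#' outcome prevalence.
#'
#' @inheritParams roc_auc
#' @return Average precision in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  P <- sum(labels == 1L)
  if (P == 0L || P == length(labels))
    stop("pr_auc needs both classes present")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y)
  n <- seq_along(y)
  # last index of each tied block = a threshold
  thr <- which(s != c(s[-1], NA) | n == length(y))
  prec <- tp[thr] / n[thr]
  rec <- tp[thr] / P
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Confidence interval for a discrimination metric
#'
#' ROC-AUC: DeLong variance with a normal interval, clipped to \[0, 1\].
#' PR-AUC: stratified bootstrap percentile interval (positives and negatives
#' resampled separately, `B` resamples, fixed seed).
#'
#' @inheritParams roc_auc
#' @param metric `"roc"` or `"pr"`.
#' @param level Confidence level (default 0.95).
#' @param B Bootstrap resamples for the PR interval.
#' @param seed Bootstrap seed.
#' @return List: `estimate`, `lo`, `hi`, `level`, `method`.
#' @export
auc_ci <- function(scores, labels, metric = c("roc", "pr"), level = 0.95,
                   B = 2000L, seed = 1L) {
  metric <- match.arg(metric)
  labels <- as.integer(labels)
  if (metric == "roc") {
    est <- roc_auc(scores, labels)
    r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
    ci <- suppressWarnings(pROC::ci.auc(r, conf.level = level, method = "delong"))
    lo <- max(0, min(ci[1], est)); hi <- min(1, max(ci[3], est))
    list(estimate = est, lo = lo, hi = hi, level = level, method = "delong")
  } else {
    if (B < 100L) stop("bootstrap needs B >= 100")
    est <- pr_auc(scores, labels)
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    stat <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        repeat {
          i <- c(sample(pos, length(pos), replace = TRUE),
                 sample(neg, length(neg), replace = TRUE))
          if (length(unique(labels[i])) == 2L) break  # redraw degenerate
        }
        pr_auc(scores[i], labels[i])
      }, numeric(1))
    })
    a <- (1 - level) / 2
    q <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
    list(estimate = est, lo = min(q[1], est), hi = max(q[2], est),
         level = level, method = "bootstrap_percentile")
  }
}

#' Interpretation band of an AUC value
#'
#' Half-open clinical bands: \[0.9, 1\] excellent, \[0.8, 0.9) very good,
#' \[0.7, 0.8) good, \[0.6, 0.7) sufficient, \[0.5, 0.6) bad, below 0.5 the
#' test is not useful.
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @return Character label(s).
#' @export
classify_band <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0) || any(auc > 1))
    stop("auc must lie in [0, 1]")
  cut_lab <- function(a) {
    if (a >= 0.9) "excellent"
    else if (a >= 0.8) "very good"
    else if (a >= 0.7) "good"
    else if (a >= 0.6) "sufficient"
    else if (a >= 0.5) "bad"
    else "not useful"
  }
  vapply(auc, cut_lab, character(1))
}

#' Trial-retest reliability: ICC(2,1)
#'
#' Single-measure, absolute-agreement intraclass correlation from the
#' two-way random-effects ANOVA decomposition (participants x trials), with
#' the F-distribution confidence interval of McGraw & Wong.
#'
#' @param values Matrix (participants x trials) or data frame of repeated
#'   measurements; rows with any NA are dropped.
#' @param level Confidence level.
#' @return List: `icc`, `lo`, `hi`, `n`, `k`, `level`.
#' @export
icc <- function(values, level = 0.95) {
  m <- as.matrix(values)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("icc needs >= 2 trials for >= 2 participants")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  # McGraw & Wong (1996) CI for ICC(A,1)
  a <- (k * est) / (n * (1 - est)); b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  Fv <- MSR / MSE
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - level
  F_lo <- stats::qf(1 - alpha / 2, n - 1, v)
  F_hi <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - F_lo * MSE) /
    (F_lo * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (F_hi * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F_hi * MSR)
  list(icc = est, lo = max(-1, lo), hi = min(1, hi), n = n, k = k,
       level = level)
}
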