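# Threshold selection, operating-point metrics, ROC/AUC and bootstrap CIs
# for a scored cohort.  The positive-call convention is score >= threshold;
# candidate thresholds are midpoints between adjacent sorted unique scores
# plus +/- infinity.

check_cohort <- function(cohort) {
  need <- c("case_id", "score", "is_emergency")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(cohort$score))) stop("scores must be finite", call. = FALSE)
  invisible(cohort)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability with ties counted
#' one half, which equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param cohort data frame with `score` and logical `is_emergency`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(cohort) {
  check_cohort(cohort)
  y <- cohort$is_emergency
  if (all(y) || all(!y)) stop("both classes must be present", call. = FALSE)
  rk <- rank(cohort$score)       # midranks handle ties as 1/2
  n1 <- sum(y); n0 <- sum(!y)
  (sum(rk[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param cohort scored cohort.
#' @return data frame `threshold, sensitivity, specificity` over the full
#'   candidate-threshold set.
#' @export
roc_points <- function(cohort) {
  check_cohort(cohort)
  cand <- .threshold_candidates(cohort$score)
  do.call(rbind, lapply(cand, function(t) {
    m <- operating_metrics(cohort, t)
    data.frame(threshold = t, sensitivity = m$sensitivity,
               specificity = m$specificity)
  }))
}

.threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

#' Select an operating threshold on a tuning cohort
#'
#' `"youden"` maximizes sensitivity + specificity - 1 (ties resolved toward
#' the lowest threshold, i.e. higher sensitivity);
#' `"sensitivity_level"` returns the largest threshold whose tuning
#' sensitivity is at least `tau` (the high-sensitivity operating points use
#' tau = 0.95 and 1.00).
#'
#' @param tuning scored tuning cohort (both classes present).
#' @param policy `"youden"` or `"sensitivity_level"`.
#' @param tau required sensitivity for `"sensitivity_level"`.
#' @return the threshold (positive call: score >= threshold).
#' @export
select_threshold <- function(tuning, policy = c("youden", "sensitivity_level"),
                             tau = 0.95) {
  policy <- match.arg(policy)
  check_cohort(tuning)
  y <- tuning$is_emergency
  if (all(y) || all(!y)) stop("both classes must be present", call. = FALSE)
  cand <- .threshold_candidates(tuning$score)
  sens <- vapply(cand, function(t) mean(tuning$score[y] >= t), 0)
  spec <- vapply(cand, function(t) mean(tuning$score[!y] < t), 0)
  if (policy == "youden") {
    j <- sens + spec - 1
    cand[which.max(j)]          # first index = lowest threshold on ties
  } else {
    ok <- which(sens >= tau)
    if (!length(ok)) stop("sensitivity level ", tau, " is unattainable",
                          call. = FALSE)
    max(cand[ok])
  }
}

#' Operating-point metrics at a threshold
#'
#' @param cohort scored cohort.
#' @param threshold positive call when `score >= threshold`.
#' @return list with `sensitivity`, `specificity`, `accuracy`, counts, and
#'   explicit `false_negatives` / `false_positives` case-id vectors.
#' @export
operating_metrics <- function(cohort, threshold) {
  check_cohort(cohort)
  if (!is.finite(threshold) && !threshold %in% c(-Inf, Inf))
    stop("threshold must be numeric", call. = FALSE)
  pos <- cohort$score >= threshold
  y <- cohort$is_emergency
  tp <- sum(pos & y); fn <- sum(!pos & y)
  fp <- sum(pos & !y); tn <- sum(!pos & !y)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(y),
       tp = tp, fn = fn, fp = fp, tn = tn,
       false_negatives = cohort$case_id[!pos & y],
       false_positives = cohort$case_id[pos & !y])
}

#' Percentile bootstrap confidence interval
#'
#' Seeded case-resampling bootstrap (full scale: 10,000 iterations) with a
#' percentile 95% interval.  Resamples that leave the statistic undefined
#' because only one class is present are redrawn, up to a retry cap.
#'
#' @param cohort scored cohort (rows are resampled).
#' @param statistic function of a cohort returning a scalar.
#' @param iterations bootstrap iterations (default 10000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @param retry_cap redraw attempts per iteration for degenerate resamples.
#' @return list `point`, `lo`, `hi`, `iterations`.
#' @export
bootstrap_ci <- function(cohort, statistic, iterations = 10000L, seed = 1L,
                         conf = 0.95, retry_cap = 100L) {
  stopifnot(iterations >= 1)
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  point <- statistic(cohort)
  vals <- numeric(iterations)
  needs_both <- "is_emergency" %in% names(cohort)
  for (i in seq_len(iterations)) {
    for (tries in seq_len(retry_cap)) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- cohort[idx, , drop = FALSE]
      if (!needs_both || length(unique(res$is_emergency)) == 2 ||
          length(unique(cohort$is_emergency)) == 1) break
      if (tries == retry_cap)
        stop("degenerate bootstrap resamples exceeded the retry cap",
             call. = FALSE)
    }
    vals[i] <- statistic(res)
  }
  a <- (1 - conf) / 2
  qs <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  list(point = point, lo = qs[1], hi = qs[2], iterations = iterations)
}
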