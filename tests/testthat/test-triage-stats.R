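make_cohort <- function(scores, labels) {
  data.frame(case_id = sprintf("c%03d", seq_along(scores)),
             score = scores, is_emergency = as.logical(labels),
             stringsAsFactors = FALSE)
}

test_that("AUC equals pairwise concordance with ties counted one half", {
  expect_identical(roc_auc(make_cohort(c(1, 2, 10, 11), c(0, 0, 1, 1))), 1)
  set.seed(90)
  big <- make_cohort(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(roc_auc(big) - 0.5), 0.05)
  # O(n^2) oracle, with deliberate ties
  set.seed(91)
  for (rep in 1:3) {
    co <- make_cohort(round(rnorm(30), 1), rbinom(30, 1, 0.4))
    if (length(unique(co$is_emergency)) < 2) next
    pos <- co$score[co$is_emergency]; neg <- co$score[!co$is_emergency]
    conc <- 0
    for (p in pos) for (q in neg)
      conc <- conc + (p > q) + 0.5 * (p == q)
    expect_equal(roc_auc(co), conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(make_cohort(1:3, c(1, 1, 1))), "both classes")
  # invariance under strictly monotone transforms
  co <- make_cohort(rnorm(50), rbinom(50, 1, 0.3))
  expect_equal(roc_auc(co), roc_auc(transform(co, score = exp(score))))
})

test_that("threshold selection follows Youden and sensitivity policies", {
  co <- make_cohort(c(1, 2, 3, 4), c(0, 0, 1, 1))
  thr <- select_threshold(co, "youden")
  expect_gt(thr, 2); expect_lte(thr, 3)
  m <- operating_metrics(co, thr)
  expect_identical(m$sensitivity, 1)
  expect_identical(m$specificity, 1)
  # sensitivity_level(1.0): threshold at or below the lowest emergency score
  thr100 <- select_threshold(co, "sensitivity_level", tau = 1.0)
  expect_lte(thr100, 3)
  expect_identical(operating_metrics(co, thr100)$sensitivity, 1)
  expect_error(select_threshold(co, "sensitivity_level", tau = 1.1),
               "unattainable")
  # Youden equals an exhaustive scan over midpoints (brute-force oracle)
  set.seed(92)
  for (rep in 1:3) {
    co2 <- make_cohort(round(rnorm(50), 1), rbinom(50, 1, 0.3))
    if (length(unique(co2$is_emergency)) < 2) next
    u <- sort(unique(co2$score))
    cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
    j <- vapply(cand, function(t) {
      mm <- operating_metrics(co2, t)
      mm$sensitivity + mm$specificity - 1
    }, 0)
    got <- select_threshold(co2, "youden")
    expect_equal(max(j), {
      mg <- operating_metrics(co2, got)
      mg$sensitivity + mg$specificity - 1
    }, tolerance = 1e-12)
    # tie-break toward the lowest threshold
    expect_identical(got, cand[which.max(j)])
  }
})

test_that("operating metrics reproduce the screening-cohort arithmetic", {
  # 197 emergencies with 44 below threshold, 1598 non-emergencies with 305
  # above: the external ED screening cohort's confusion structure
  co <- make_cohort(c(rep(1, 153), rep(-1, 44), rep(1, 305), rep(-1, 1293)),
                    c(rep(1, 197), rep(0, 1598)))
  m <- operating_metrics(co, threshold = 0)
  expect_equal(m$sensitivity, 1 - 44 / 197)
  expect_equal(round(m$sensitivity, 2), 0.78)
  expect_identical(round(100 * m$fn / (m$tp + m$fn), 1), 22.3)  # FN rate
  expect_identical(round(100 * m$fp / (m$fp + m$tn), 1), 19.1)  # FP rate
  expect_identical(length(m$false_negatives), 44L)
  expect_identical(length(m$false_positives), 305L)
  # degenerate thresholds
  expect_identical(operating_metrics(co, -Inf)$sensitivity, 1)
  expect_identical(operating_metrics(co, -Inf)$specificity, 0)
  # hand-built 2x2 on a 10-case fixture
  co10 <- make_cohort(c(5, 4, 3, 2, 1, 5, 4, 3, 2, 1),
                      c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0))
  m10 <- operating_metrics(co10, 3.5)
  expect_identical(c(m10$tp, m10$fn, m10$fp, m10$tn), c(2L, 2L, 2L, 4L))
  expect_equal(m10$accuracy, 0.6)
})

test_that("the bootstrap is seeded, degenerate-safe, and calibrated", {
  co <- make_cohort(rnorm(30), rbinom(30, 1, 0.5))
  const <- function(d) 42
  ci <- bootstrap_ci(co, const, iterations = 50, seed = 1)
  expect_identical(c(ci$point, ci$lo, ci$hi), c(42, 42, 42))
  a <- bootstrap_ci(co, function(d) mean(d$score), iterations = 200, seed = 9)
  b <- bootstrap_ci(co, function(d) mean(d$score), iterations = 200, seed = 9)
  expect_identical(a, b)
  # coverage of the 95% percentile interval for a N(0,1) mean, n = 200
  set.seed(1234)
  hits <- 0L
  for (rep in 1:200) {
    d <- data.frame(case_id = as.character(1:200), score = rnorm(200))
    ci <- bootstrap_ci(d, function(x) mean(x$score), iterations = 400,
                       seed = rep)
    if (ci$lo <= 0 && ci$hi >= 0) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.93)
})
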