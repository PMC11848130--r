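test_that("roc_auc equals the Mann-Whitney pair count with ties half-credit", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(1, 8), c(1, 1, 0, 0, 0, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), sample(1:2, 1))  # coarse grid forces ties
    expect_equal(roc_auc(s, y), bruteforce_auc(s, y))
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  set.seed(5)
  y <- rbinom(60, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("roc_auc invariances hold", {
  set.seed(32)
  y <- rbinom(40, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(40)
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)
  expect_equal(roc_auc(exp(3 * s), y), roc_auc(s, y))
})

test_that("pr_auc matches enumerated average precision", {
  expect_equal(pr_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(pr_auc(c(4, 3, 2, 1), c(0, 1, 0, 0)), 0.5)
  # all rankings of n <= 8 with <= 3 positives, distinct scores
  for (n in 3:8) {
    for (npos in 1:min(3, n - 1)) {
      for (pos_set in utils::combn(n, npos, simplify = FALSE)) {
        lab <- integer(n); lab[pos_set] <- 1L
        s <- seq(n, 1)  # descending scores, rank i has score n - i + 1
        expect_equal(pr_auc(s, lab), enumerated_ap(lab))
      }
    }
  }
})

test_that("pr_auc respects its prevalence baselines", {
  set.seed(33)
  # large-sample random scores: mean AP near prevalence
  ap <- replicate(40, {
    y <- rbinom(400, 1, 0.25); y[1:2] <- c(0, 1)
    pr_auc(runif(400), y)
  })
  expect_lt(abs(mean(ap) - 0.25), 0.02)
  # any ranking with a positive first has AP above prevalence
  y <- c(1, 0, 0, 1, 0, 0, 0, 0)
  expect_gt(pr_auc(8:1, y), mean(y))
  # reversed perfect ranking scores below prevalence
  y2 <- c(rep(0, 6), rep(1, 2))
  expect_lt(pr_auc(8:1, y2), mean(y2))
})

test_that("confidence intervals bracket the estimate and clip at 1", {
  y <- c(rep(1, 40), rep(0, 160))
  s <- c(runif(40, 0.6, 1), runif(160, 0, 0.4))
  ci <- auc_ci(s, y, "roc")
  expect_equal(ci$estimate, 1.0)
  expect_equal(ci$hi, 1.0)
  expect_true(ci$lo <= ci$estimate)
  set.seed(34)
  y2 <- rbinom(80, 1, 0.3); y2[1:2] <- c(0, 1)
  s2 <- rnorm(80) + 0.8 * y2
  for (m in c("roc", "pr")) {
    ci2 <- auc_ci(s2, y2, m, B = 300)
    expect_true(ci2$lo <= ci2$estimate && ci2$estimate <= ci2$hi)
  }
  expect_error(auc_ci(s2, y2, "pr", B = 10), "B >= 100")
})

test_that("DeLong intervals achieve near-nominal coverage on binormal scores", {
  # AUC 0.8 <=> mean separation sqrt(2) * qnorm(0.8) under unit normals
  delta <- sqrt(2) * qnorm(0.8)
  set.seed(35)
  hits <- replicate(500, {
    y <- rbinom(100, 1, 0.3)
    if (length(unique(y)) < 2) return(NA)
    s <- rnorm(100) + delta * y
    ci <- auc_ci(s, y, "roc")
    ci$lo <= 0.8 && 0.8 <= ci$hi
  })
  cov <- mean(hits, na.rm = TRUE)
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.98)
})

test_that("AUC bands follow the half-open clinical convention", {
  expect_identical(classify_band(0.909), "excellent")
  expect_identical(classify_band(0.670), "sufficient")
  expect_identical(classify_band(0.85), "very good")
  expect_identical(classify_band(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.499)),
                   c("excellent", "very good", "good", "sufficient", "bad",
                     "not useful"))
  expect_error(classify_band(1.2), "\\[0, 1\\]")
})

test_that("ICC(2,1) behaves at its extremes and recovers a known value", {
  # perfect agreement across trials, heterogeneous participants
  m <- cbind(1:20, 1:20, 1:20)
  expect_equal(icc(m)$icc, 1.0, tolerance = 1e-9)
  # no between-participant signal
  set.seed(36)
  m2 <- matrix(rnorm(300), 100, 3)
  expect_lt(abs(icc(m2)$icc), 0.1)
  # two-way model tuned for ICC 0.6: var_p / (var_p + var_e) with var_p = 1.5
  m3 <- outer(rnorm(100, 0, sqrt(1.5)), rep(1, 3)) + matrix(rnorm(300), 100, 3)
  r <- icc(m3)
  expect_lt(abs(r$icc - 0.6), 0.08)
  expect_true(r$lo < r$icc && r$icc < r$hi)
  expect_error(icc(matrix(1, 1, 3)), ">= 2")
})
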