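test_that("univariate screening is direction-agnostic with named ranking", {
  set.seed(41)
  y <- rep(c(1, 0), c(10, 30))
  x <- data.frame(perfect = y + 0,
                  weak_pos = rnorm(40) + 0.1 * y,
                  strong_neg = rnorm(40) - 2 * y,   # low values mark fallers
                  constant = rep(1, 40))
  scr <- univariate_screen(x, y, k = 10)
  expect_identical(scr$feature[1], "perfect")
  expect_equal(scr$auc[1], 1.0)
  # a feature with AUC 0.44 outranks one with AUC 0.52: 0.56 > 0.52
  expect_lt(scr$auc[scr$feature == "strong_neg"], 0.5)
  expect_identical(scr$feature[2], "strong_neg")
  expect_identical(scr$feature[4], "constant")
  expect_equal(scr$auc[scr$feature == "constant"], 0.5)
  # k larger than the feature count returns everything
  expect_identical(nrow(scr), 4L)
})

test_that("NearMiss keeps the negatives nearest the positive class", {
  # toy 2-D set with a brute-force oracle, 2 positives, ratio 1:2
  x <- rbind(c(0, 0), c(1, 0),               # positives
             c(0.2, 0.1), c(5, 5), c(0.9, -0.1), c(4, -4),
             c(0.5, 0.4), c(10, 0), c(0.1, -0.3), c(-6, 2))
  y <- c(1, 1, rep(0, 8))
  keep <- nearmiss_undersample(x, y, ratio_neg = 2, n_neighbors = 2)
  # oracle: standardized mean distance to both positives
  mu <- colMeans(x); sd <- apply(x, 2, sd)
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  d <- sapply(3:10, function(i)
    mean(sqrt(rowSums(sweep(xs[1:2, , drop = FALSE], 2, xs[i, ])^2))))
  oracle <- sort(c(1L, 2L, (3:10)[order(d)][1:4]))
  expect_identical(as.integer(keep), oracle)

  # already at the requested ratio: nothing removed, no warning
  y2 <- c(1, 1, rep(0, 8))
  expect_silent(keep2 <- nearmiss_undersample(x, y2, ratio_neg = 4))
  expect_identical(as.integer(keep2), 1:10)
  # 1:1 with equal classes: unchanged
  x3 <- matrix(rnorm(12), 6, 2); y3 <- rep(c(1, 0), each = 3)
  expect_identical(as.integer(nearmiss_undersample(x3, y3, ratio_neg = 1)), 1:6)
})

test_that("stratified group k-fold balances positives and keeps groups whole", {
  # 10 groups, 2 positive, k = 2: each fold gets exactly one positive group
  y <- rep(c(1, 1, rep(0, 8)), each = 3)
  g <- rep(sprintf("g%02d", 1:10), each = 3)
  for (seed in 0:5) {
    f <- stratified_group_kfold(y, g, k = 2, seed = seed)
    byg <- tapply(f, g, unique)
    expect_true(all(lengths(byg) == 1L))  # group atomicity
    posg <- tapply(y, g, max)
    expect_identical(as.integer(table(unlist(byg)[posg == 1])), c(1L, 1L))
  }
  # fewer positive groups than folds is allowed but warned about
  expect_warning(f1 <- stratified_group_kfold(y, g, k = 3, seed = 42),
                 "fewer positive groups")
  f2 <- suppressWarnings(stratified_group_kfold(y, g, k = 3, seed = 42))
  expect_identical(f1, f2)  # determinism under the same seed
  expect_error(stratified_group_kfold(c(0, 1), c("a", "a"), k = 2),
               "participant-level")
})

test_that("logistic fits match closed forms and survive separation", {
  # intercept-only: 1 positive, 3 negatives
  m <- fit_logistic(matrix(0, 4, 1), c(1, 0, 0, 0))
  expect_equal(unname(m$coef[1]), log(1 / 3), tolerance = 1e-6)
  # single binary predictor: unstandardized slope = log odds ratio
  x <- matrix(rep(c(1, 0), c(20, 20)))
  y <- c(rep(1, 12), rep(0, 8), rep(1, 5), rep(0, 15))
  a <- 12; b <- 5; cc <- 8; d <- 15
  m2 <- fit_logistic(x, y)
  slope_raw <- unname(m2$coef[2] / m2$scale)
  expect_equal(slope_raw, log(a * d / (b * cc)), tolerance = 1e-6)
  expect_false(m2$penalized)
  # perfectly separated data: penalized refit with finite coefficients
  xs <- matrix(c(1:5, 11:15))
  ys <- rep(c(0, 1), c(5, 5))
  m3 <- fit_logistic(xs, ys)
  expect_true(m3$penalized)
  expect_true(all(is.finite(m3$coef)))
  expect_error(fit_logistic(x, rep(1, 40)), "single-class")
})

test_that("logistic fit agrees with glm on ordinary data", {
  set.seed(43)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, plogis(X %*% c(0.8, -0.5, 0)))
  m <- fit_logistic(X, y)
  g <- glm(y ~ scale(X), family = binomial)
  expect_equal(unname(m$coef), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(predict(m, X)[1:5]),
               unname(fitted(g)[1:5]), tolerance = 1e-7)
})

test_that("cross-validation artifacts are training-fold-only (no leakage)", {
  d <- simulate_feature_cohort(n = 60, prevalence = 0.2, seed = 44)
  fn <- sprintf("f%02d", 1:10)
  # on this small cohort some training folds cannot reach the full 1:4
  # ratio, which NearMiss warns about; the canary concerns the artifacts
  run1 <- suppressWarnings(cv_run(d[fn], d$fall_history, d$participant_id,
                                  fn[1:3], k = 3, seed = 0))
  # perturb each fold's held-out rows, keeping training rows untouched
  for (f in 1:3) {
    d2 <- d
    test_rows <- which(run1$folds == f)
    d2[test_rows, fn] <- d2[test_rows, fn] + 100
    run2 <- suppressWarnings(cv_run(d2[fn], d2$fall_history,
                                    d2$participant_id, fn[1:3], k = 3, seed = 0))
    expect_identical(run2$artifacts[[f]], run1$artifacts[[f]])
  }
})

test_that("the combination search explores all combinations and reports a winner", {
  d <- simulate_feature_cohort(n = 60, prevalence = 0.2, d = 1.2, seed = 45)
  fn <- sprintf("f%02d", 1:5)
  rep <- search_combinations(d[fn], d$fall_history, d$participant_id, fn,
                             sizes = 3:5, folds = c(3, 4), seeds = 0)
  expect_equal(rep$config$n_combinations,
               choose(5, 3) + choose(5, 4) + choose(5, 5))
  expect_identical(nrow(rep$table), rep$config$n_combinations)
  expect_true(length(rep$winner) %in% 3:5)
  expect_s3_class(rep$final_model, "tristep_logistic")
  # table is sorted by mean PR-AUC with the tie-break ordering
  expect_true(all(diff(rep$table$mean_pr) <= 1e-12))
  expect_error(search_combinations(d[fn], d$fall_history, d$participant_id,
                                   fn[1:2]), "at least 3")
})

test_that("external evaluation returns banded metrics with intervals", {
  set.seed(46)
  d <- simulate_feature_cohort(n = 80, prevalence = 0.25, d = 1.5, seed = 46)
  fn <- sprintf("f%02d", 1:10)
  model <- fit_logistic(d[fn[1:3]], d$fall_history)
  ev <- evaluate_external(model, d[fn], d$fall_history, B = 200)
  expect_true(ev$roc$lo <= ev$roc$estimate && ev$roc$estimate <= ev$roc$hi)
  expect_true(ev$pr$lo <= ev$pr$estimate && ev$pr$estimate <= ev$pr$hi)
  expect_true(ev$roc$band %in% c("excellent", "very good", "good",
                                 "sufficient", "bad", "not useful"))
  # a model scoring positives uniformly above negatives is perfect
  y <- rep(c(1, 0), c(5, 15))
  mm <- structure(list(features = "z", coef = c(0, 0.2), center = 0, scale = 1,
                       penalized = FALSE), class = "tristep_logistic")
  ev2 <- evaluate_external(mm, data.frame(z = 20:1), y, B = 200)
  expect_equal(ev2$roc$estimate, 1.0)
  expect_equal(ev2$pr$estimate, 1.0)
  expect_error(evaluate_external(mm, data.frame(z = 1:4), rep(0, 4)),
               "single class")
})
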