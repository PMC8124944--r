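test_that("ROC/AUC matches brute-force pair counting", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_error(roc_auc(1:3, rep(TRUE, 3)), "both classes")
  set.seed(14)
  for (i in 1:30) {
    n <- sample(10:100, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    s <- round(rnorm(n), 1)
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }
  # AUC is invariant under strictly monotone transforms of the scores
  y <- rep(c(TRUE, FALSE), each = 20)
  s <- rnorm(40, mean = y)
  expect_equal(roc_auc(exp(s), y)$auc, roc_auc(s, y)$auc, tolerance = 1e-12)
})

test_that("the ROC sweep is monotone in the cutoff", {
  set.seed(15)
  y <- rep(c(TRUE, FALSE), each = 30)
  s <- rnorm(60, mean = 0.8 * y)
  curve <- roc_auc(s, y)$curve   # thresholds in decreasing order
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_true(all(diff(curve$specificity) <= 0))
})

test_that("cutoff selection works on enumerable toys", {
  # separable case: target specificity 1 puts the cutoff between classes
  y <- c(TRUE, TRUE, FALSE, FALSE)
  s <- c(0.9, 0.8, 0.3, 0.2)
  cc <- choose_cutoff(s, y, "high_specificity", 1.0)
  expect_gt(cc$cutoff, 0.3); expect_lt(cc$cutoff, 0.8)
  expect_equal(cc$sensitivity, 1.0)
  # hand-enumerated threshold sweep
  s2 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  y2 <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  # midpoints: .15 .25 .35 .45 .55; spec = 1/3, 2/3, 2/3, 1, 1
  cs <- choose_cutoff(s2, y2, "high_specificity", 0.9)
  expect_equal(cs$cutoff, 0.45)
  expect_equal(cs$sensitivity, 2 / 3)
  # sens = 1, 1, 2/3, 2/3, 1/3 -> largest midpoint with sens >= 0.8 is .25,
  # where controls .1, .2 of 3 fall below: spec = 2/3
  ch <- choose_cutoff(s2, y2, "high_sensitivity", 0.8)
  expect_equal(ch$cutoff, 0.25)
  expect_equal(ch$specificity, 2 / 3)
  # the top score belonging to a control makes specificity 1 unreachable
  expect_error(choose_cutoff(c(0.2, 0.5, 0.9), c(TRUE, TRUE, FALSE),
                             "high_specificity", 0.9),
               "best attainable")
})

test_that("confusion metrics follow the arithmetic and Bayes identity", {
  # TP=3 FN=1 TN=4 FP=2
  s <- c(1, 1, 1, 0,   1, 1, 0, 0, 0, 0)
  y <- rep(c(TRUE, FALSE), c(4, 6))
  rep <- confusion_metrics(s, y, cutoff = 0.5)
  expect_equal(unname(rep$counts), c(3, 2, 4, 1))
  m <- setNames(rep$metrics$estimate, rep$metrics$metric)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 2 / 3)
  expect_equal(unname(m["ppv"]), 0.6)
  expect_equal(unname(m["npv"]), 0.8)
  # Bayes identity with observed prevalence
  prev <- mean(y)
  ppv <- m["sensitivity"] * prev /
    (m["sensitivity"] * prev + (1 - m["specificity"]) * (1 - prev))
  expect_equal(unname(m["ppv"]), unname(ppv), tolerance = 1e-12)
  expect_true(all(rep$metrics$lower <= rep$metrics$estimate + 1e-12))
  expect_true(all(rep$metrics$upper >= rep$metrics$estimate - 1e-12))
  # cutoff below all scores: everything called positive
  lo <- confusion_metrics(s, y, cutoff = -1)
  mlo <- setNames(lo$metrics$estimate, lo$metrics$metric)
  expect_equal(unname(mlo["sensitivity"]), 1)
  expect_equal(unname(mlo["specificity"]), 0)
  expect_false(lo$metrics$defined[lo$metrics$metric == "npv"])
})

test_that("Wilson intervals behave like binomial intervals should", {
  ci <- wilson_ci(8, 10)
  expect_equal(unname(ci["estimate"]), 0.8)
  expect_true(ci["lower"] < 0.8 && ci["upper"] > 0.8)
  expect_true(ci["lower"] >= 0 && ci["upper"] <= 1)
  # large n: approaches the Wald interval
  big <- wilson_ci(800, 1000)
  wald <- 0.8 + c(-1, 1) * qnorm(0.975) * sqrt(0.8 * 0.2 / 1000)
  expect_equal(unname(big["lower"]), wald[1], tolerance = 2e-3)
  expect_equal(unname(big["upper"]), wald[2], tolerance = 2e-3)
  expect_true(all(is.na(wilson_ci(0, 0))))
})

test_that("the trend statistic matches pair-sum enumeration", {
  x <- c(1, 2,  2, 3,  4)
  g <- c(1, 1,  2, 2,  3)
  # AB pairs: 2>1, 3>1, 2==2 (half), 3>2 = 3.5; AC: 2; BC: 2 -> 7.5
  expect_equal(brute_jt(x, g), 7.5)
  tr <- trend_by_group(x, g, n_perm = 200, seed = 1)
  expect_equal(tr$statistic, 7.5)
  set.seed(16)
  for (i in 1:10) {
    n <- 18
    g2 <- sample(1:3, n, replace = TRUE)
    if (length(unique(g2)) < 2) next
    x2 <- round(rnorm(n), 1)
    expect_equal(trend_by_group(x2, g2, n_perm = 50, seed = 2)$statistic,
                 brute_jt(x2, g2))
  }
})

test_that("the permutation trend test is calibrated and powered", {
  set.seed(17)
  # null: identical group distributions -> p roughly uniform
  ps <- replicate(120, {
    g <- rep(1:3, each = 12)
    trend_by_group(rnorm(36), g, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps), 0.40); expect_lt(mean(ps), 0.60)
  expect_gt(mean(ps < 0.5), 0.35); expect_lt(mean(ps < 0.5), 0.65)
  # power: +0.5 shift per ordinal level
  g <- rep(1:3, each = 30)
  x <- rnorm(90, mean = 0.5 * g, sd = 0.5)
  tr <- trend_by_group(x, g, n_perm = 2000, seed = 3)
  expect_gt(tr$z, 0)
  expect_lt(tr$p_value, 0.01)
  # missing group values are excluded and counted
  g2 <- c(g, NA, NA)
  x2 <- c(x, 5, 5)
  expect_equal(trend_by_group(x2, g2, n_perm = 50, seed = 4)$n_missing, 2)
  expect_error(trend_by_group(1:5, rep(1, 5), n_perm = 10), "2 non-empty")
})

test_that("frozen evaluation is idempotent and control-set semantics hold", {
  set.seed(18)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X[y, 1] <- X[y, 1] + 1.5
  pm <- panel_model(c("a", "b"), c(2, 0.1), 0, colMeans(X[, 1:2]),
                    apply(X[, 1:2], 2, sd))
  ev <- evaluate_frozen(pm, X, y)
  # resubstitution AUC reproduces exactly on re-evaluation
  ev2 <- evaluate_frozen(pm, X, y)
  expect_identical(ev$auc, ev2$auc)
  expect_identical(ev$scores, ev2$scores)
  # adding easy controls (all scoring below every case) cannot lower the AUC
  lows <- matrix(rnorm(20 * 3, -6), 20, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  Xplus <- rbind(X, lows)
  yplus <- c(y, rep(FALSE, 20))
  evp <- evaluate_frozen(pm, Xplus, yplus)
  expect_gte(evp$auc, ev$auc)
  # unreachable operating targets surface as messages, not errors
  expect_true(is.list(ev$cutoffs$high_specificity))
})
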