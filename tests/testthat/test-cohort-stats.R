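test_that("SYNTAX grouping partitions the score line at 22/23 and 32/33", {
  expect_equal(as.character(syntax_group(c(0, 22, 23, 32, 33, 50))),
               c("low", "low", "medium", "medium", "high", "high"))
  # fractional scores round half-up before grouping
  expect_equal(as.character(syntax_group(c(22.4, 22.5, 32.5))),
               c("low", "medium", "high"))
  expect_error(syntax_group(-1), "non-negative")
  # every non-negative integer lands in exactly one group
  g <- syntax_group(0:60)
  expect_false(any(is.na(g)))
  expect_equal(as.vector(table(g)), c(23, 10, 28))
})

test_that("vessel filter applies strict inclusion on both criteria", {
  vessels <- tibble::tibble(
    diameter = c(1.5, 2.0, 2.0, 3.1, 1.2),
    stenosis = c(60, 50, 80, 55, 90)
  )
  kept <- vessel_filter(vessels)
  # boundary diameters and stenoses are excluded; order preserved
  expect_equal(kept$diameter, c(2.0, 3.1))
  expect_equal(kept$stenosis, c(80, 55))
  expect_error(vessel_filter(tibble::tibble(diameter = -1, stenosis = 50)), "positive")
})

test_that("Pearson correlation matches textbook formulas", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 7.1, 6.0, 8.3)
  expect_equal(pearson_r(x, x)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)

  set.seed(14)
  a <- rnorm(50)
  b <- 0.5 * a + rnorm(50)
  res <- pearson_r(a, b)
  # hand computation: r, t statistic, Fisher z interval
  n <- 50
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = n - 2)
  z <- atanh(r_hand)
  ci_hand <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  expect_equal(res$estimate, r_hand)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p.value, p_hand)
  expect_equal(c(res$conf.low, res$conf.high), ci_hand, tolerance = 1e-10)

  expect_error(pearson_r(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_r(1:3, 1:3), "n >= 4")
})

test_that("Pearson correlation transforms correctly under affine maps", {
  set.seed(15)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40)
  r0 <- pearson_r(x, y)$estimate
  expect_equal(pearson_r(2 * x + 7, y)$estimate, r0)
  expect_equal(pearson_r(x, -3 * y + 1)$estimate, -r0)
})

test_that("one-way ANOVA reproduces the sum-of-squares decomposition", {
  # equal group means: between-group SS = 0, F = 0
  res0 <- anova_oneway(c(1, 2, 3, 0, 2, 4), rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0)

  # two groups: F equals the squared equal-variance t statistic
  set.seed(16)
  v <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  f2 <- anova_oneway(v, g)$statistic
  t2 <- t.test(v ~ g, var.equal = TRUE)$statistic^2
  expect_equal(f2, unname(t2))

  # three groups vs hand decomposition
  set.seed(17)
  vals <- c(rnorm(8, 0), rnorm(9, 0.5), rnorm(7, 1))
  grp <- rep(c("x", "y", "z"), c(8, 9, 7))
  res <- anova_oneway(vals, grp)
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / (24 - 3))
  expect_equal(res$statistic, f_hand)
  expect_equal(res$p.value, pf(f_hand, 2, 21, lower.tail = FALSE))

  expect_error(anova_oneway(rep(5, 6), rep(c("a", "b"), 3)), "identical")
  expect_error(anova_oneway(1:4, rep("a", 4)), "2 groups")
})

test_that("chi-square matches expected-count hand computation and scaling", {
  # a table equal to its independence expectation
  ind <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(chi_square(ind)$statistic, 0)

  tb <- matrix(c(10, 20, 20, 10), 2, 2)
  res <- chi_square(tb)
  # hand computation via expected counts (all margins 30, total 60)
  expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  chi_hand <- sum((tb - expected)^2 / expected)
  expect_equal(res$statistic, chi_hand)
  expect_equal(res$df, 1)
  # scaling all counts by k scales the statistic by k
  expect_equal(chi_square(3 * tb)$statistic, 3 * chi_hand)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("diagnostic metrics count the confusion table correctly", {
  # predictions defining the truth: perfect classification
  ffr <- c(0.6, 0.7, 0.85, 0.95)
  truth <- ffr <= 0.8
  perfect <- diagnostic_metrics(ffr, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # degenerate all-positive classifier
  allpos <- diagnostic_metrics(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)

  # seeded predictions vs direct count arithmetic
  set.seed(18)
  pred <- runif(200, 0.5, 1)
  tr <- runif(200) < 0.4
  dm <- diagnostic_metrics(pred, tr, cutoff = 0.8)
  pos <- pred <= 0.8
  expect_equal(dm$tp, sum(pos & tr))
  expect_equal(dm$fn, sum(!pos & tr))
  expect_equal(dm$accuracy, (sum(pos & tr) + sum(!pos & !tr)) / 200)
  expect_error(diagnostic_metrics(numeric(0), logical(0)), "empty")
})

test_that("trapezoidal AUC equals Mann-Whitney concordance", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)

  # chance level at large n
  set.seed(19)
  sc <- rnorm(4000)
  lb <- runif(4000) < 0.5
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.03)

  # n = 20 with ties: exhaustive pairwise concordance oracle
  set.seed(20)
  scores <- sample(1:8, 20, replace = TRUE)
  labels <- c(rep(TRUE, 9), rep(FALSE, 11))
  res <- roc_auc(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  expect_equal(res$auc, conc / (length(pos) * length(neg)))

  # cross-check against an established ROC implementation
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
    direction = "<", quiet = TRUE
  )))
  expect_equal(res$auc, proc_auc)

  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("low-FFR direction reverses the ROC orientation", {
  ffr <- c(0.5, 0.6, 0.7, 0.9, 0.95, 1.0)
  ischemic <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(ffr, ischemic, direction = "<")$auc, 1)
  expect_equal(roc_auc(ffr, ischemic, direction = ">")$auc, 0)
})

test_that("group event comparison flags degeneracy and finds real contrasts", {
  coh0 <- simulate_cohort(n = 60, event_prob = c(0, 0, 0), seed = 3)
  res0 <- group_event_rates(coh0)
  expect_true(res0$degenerate)
  expect_true(all(res0$rates$rate == 0))
  expect_null(res0$overall)

  coh <- simulate_cohort(n = 3000, event_prob = c(0.1, 0.1, 0.4), seed = 4)
  res <- group_event_rates(coh)
  expect_lt(res$overall$p.value, 0.05)
  hl <- res$pairwise[res$pairwise$group1 == "low" & res$pairwise$group2 == "high", ]
  expect_lt(hl$p.value, 0.05)
  # rates are plain count arithmetic
  expect_equal(res$rates$rate, res$rates$events / res$rates$n)
  # Bonferroni never lowers a p-value
  resb <- group_event_rates(coh, adjust = "bonferroni")
  expect_true(all(resb$pairwise$p.value >= res$pairwise$p.value - 1e-15))
})
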