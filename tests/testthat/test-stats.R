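test_that("ROC/AUC worked examples", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  # 3 of 4 discordant-free pairs by hand
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  # all-tied scores are uninformative under the 0.5 tie convention
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  # curve endpoints and monotonicity
  r <- roc_auc(c(3, 1, 4, 2, 5), c(0, 0, 1, 0, 1))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("AUC equals the Mann-Whitney statistic, with and without ties", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    scores <- if (i %% 2 == 0) sample(1:6, n, replace = TRUE)  # heavy ties
              else rnorm(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_identical(roc_auc(scores, labels)$auc,
                     mann_whitney_auc(scores, labels))
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(23)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(0, 1)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, base)
  expect_equal(roc_auc(scores^3 + 5 * scores, labels)$auc, base)
})

test_that("accuracy-optimal threshold scans candidates correctly", {
  r <- best_threshold_by_accuracy(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$threshold, 2.5)
  expect_equal(r$ratio, 1.0)
  r2 <- best_threshold_by_accuracy(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$ratio, 0.75)
  expect_equal(r2$threshold, 1.5)  # tie broken toward the smaller value
  # majority-class bound always attainable at an extreme threshold
  set.seed(29)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    s <- rnorm(n)
    l <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    majority <- max(sum(l), n - sum(l)) / n
    expect_gte(best_threshold_by_accuracy(s, l)$ratio, majority)
  }
})

test_that("Pearson correlation worked examples and permutation p", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1.0)
  expect_error(pearson_r(c(1, 2, 3), c(2, 2, 2)), "variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")

  # p-value agrees with a permutation test within Monte-Carlo error
  set.seed(41)
  x <- rnorm(9)
  y <- 0.6 * x + rnorm(9)
  res <- pearson_r(x, y)
  r_obs <- abs(res$r)
  perm <- replicate(1e4, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= r_obs)
  se <- sqrt(p_perm * (1 - p_perm) / 1e4)
  expect_lt(abs(res$p - p_perm), 4 * se + 0.02)
})

test_that("Mood's median test matches the hand-worked 2x2 chi-square", {
  m <- moods_median_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$grand_median, 3.5)
  expect_identical(unname(m$table),
                   rbind(c(0L, 3L), c(3L, 0L)))
  expect_equal(m$chi2, 6.0)
  expect_equal(m$p, 0.0143, tolerance = 1e-2)
  # symmetry
  expect_equal(moods_median_test(c(4, 5, 6), c(1, 2, 3))$chi2, 6.0)
  m0 <- moods_median_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(m0$chi2, 0)
  expect_error(moods_median_test(c(1, 1), c(1, 1)), "degenerate")
  expect_error(moods_median_test(numeric(0), c(1, 2)), "non-empty")
})
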