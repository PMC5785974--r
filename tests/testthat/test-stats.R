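# exhaustive pairwise AUC oracle: P(pos > neg) + 0.5 P(pos = neg)
auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

test_that("AUC equals the exhaustive pairwise statistic", {
  expect_equal(roc_auc(c(3, 5), c(1, 4))$auc, 0.75)
  x <- c(1, 2, 3, 4)
  expect_equal(roc_auc(x, x)$auc, 0.5)
  expect_equal(roc_auc(5:8, 1:4)$auc, 1.0)
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")

  set.seed(12)
  for (i in 1:25) {
    np <- sample(1:200, 1); nn <- sample(1:200, 1)
    # coarse rounding forces plenty of ties
    pos <- round(rnorm(np, 0.3), sample(0:1, 1))
    neg <- round(rnorm(nn), sample(0:1, 1))
    expect_equal(roc_auc(pos, neg)$auc, auc_oracle(pos, neg))
  }
})

test_that("the ROC curve runs monotonically from (0,0) to (1,1)", {
  set.seed(13)
  r <- roc_auc(rnorm(80, 1), rnorm(120))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(14)
  pos <- rnorm(150, 0.8); neg <- rnorm(100)
  ours <- roc_auc(pos, neg)$auc
  ref <- suppressMessages(pROC::auc(
    response = c(rep(1, 150), rep(0, 100)), predictor = c(pos, neg),
    direction = "<", levels = c(0, 1)))
  expect_equal(ours, as.numeric(ref))
})

test_that("MCV captures the linearly explained share of variability", {
  set.seed(15)
  m <- rlnorm(3000, 0, 0.4)
  expect_equal(mcv(2 * m, m)$mcv, 100, tolerance = 1e-8)

  x <- rlnorm(1e5, 5, 0.3)
  m2 <- rlnorm(1e5, 0, 0.4)
  expect_lt(abs(mcv(x, m2)$mcv), 1)   # independent: no linear trend

  # exact construction with in-sample R^2 = 0.75 gives MCV = 50 exactly
  mm <- rlnorm(1e4, 0, 0.4)
  eps <- rnorm(1e4)
  eps <- residuals(lm(eps ~ mm))
  eps <- eps / sd(eps) * sd(2 * mm) / sqrt(3)
  prot <- 10 + 2 * mm + eps
  r <- mcv(prot, mm)
  expect_equal(r$r_squared, 0.75, tolerance = 1e-10)
  expect_equal(r$mcv, 50, tolerance = 1e-8)

  expect_error(mcv(rep(3, 10), 1:10), "variance")
  expect_error(mcv(1:3, 1:2), "match")
})

test_that("MCV is invariant under affine changes of the mito axis", {
  set.seed(16)
  m <- rlnorm(2000, 0, 0.4)
  x <- 3 * m + rnorm(2000, 0, 0.5) + 10
  base <- mcv(x, m)$mcv
  expect_equal(mcv(x, 5 * m)$mcv, base)
  expect_equal(mcv(x, m + 100)$mcv, base)
})

test_that("dispersion measures match hand arithmetic and scale out", {
  v <- 1:8
  d <- dispersion(v, reps = 200, seed = 1)
  expect_equal(d$cv, sd(v) / mean(v))
  # type-7 quartiles of 1..8: Q1 = 2.75, Q3 = 6.25
  expect_equal(d$iqr_over_mean, (6.25 - 2.75) / 4.5)
  d10 <- dispersion(10 * v, reps = 200, seed = 1)
  expect_equal(d10$cv, d$cv)
  expect_equal(d10$iqr_over_mean, d$iqr_over_mean)

  dc <- dispersion(rep(4, 10), reps = 200, seed = 1)
  expect_equal(dc$cv, 0)
  expect_equal(dc$iqr_over_mean, 0)
  expect_error(dispersion(c(1, 2, 3)), "at least 4")
  expect_error(dispersion(c(-5, -6, -7, -8)), "positive")
})

test_that("Spearman correlation is the rank Pearson with mid-ranks", {
  expect_equal(spearman_rho(1:10, exp(1:10)), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3)), 0.5)
  x <- c(1, 1, 2, 3); y <- c(2, 1, 1, 3)
  expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:3), "equal length")
})

test_that("bootstrap intervals are seeded, honest about drops, and calibrated", {
  v <- rnorm(50)
  ci1 <- bootstrap_ci(mean, v, reps = 500, seed = 9)
  ci2 <- bootstrap_ci(mean, v, reps = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_error(bootstrap_ci(mean, v, reps = 50), "at least 100")

  cc <- bootstrap_ci(mean, rep(2, 30), reps = 200, seed = 1)
  expect_equal(unname(cc[1]), unname(cc[2]))

  # resamples where the statistic is undefined are dropped and counted
  stat <- function(x) if (min(x) == 1) NA_real_ else mean(x)
  ci3 <- bootstrap_ci(stat, c(1, 5, 6, 7), reps = 200, seed = 2)
  expect_gt(attr(ci3, "dropped"), 0)

  # coverage of the 95% interval for a Normal mean (scaled-down simulation)
  set.seed(17)
  hits <- vapply(1:150, function(i) {
    x <- rnorm(100)
    ci <- bootstrap_ci(mean, x, reps = 400, seed = i)
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  expect_gt(mean(hits), 0.89)
  expect_lt(mean(hits), 0.99)
})
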