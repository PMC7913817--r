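test_that("signed-rank test matches exhaustive sign enumeration for small n", {
  w <- wilcoxon_signed_rank(c(1, -2, 3))
  expect_equal(w$w_minus, 2)
  expect_equal(w$w_plus, 4)
  expect_equal(w$p, 0.75)
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    d <- sample(seq(0.5, 30, by = 0.5), n) * sample(c(-1, 1), n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p, wilcox_enum_p(d),
                 label = paste("enumeration, draw", rep))
  }
})

test_that("signed-rank test is symmetric under sign flip and degenerate on all zeros", {
  d <- c(3.5, -1, 7, -2, 0.5, 4)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_signed_rank(-d)$p)
  z <- wilcoxon_signed_rank(rep(0, 6))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
})

test_that("signed-rank type-I error is near nominal for 17 matched pairs", {
  set.seed(77)
  rej <- vapply(1:2000, function(i)
    wilcoxon_signed_rank(rnorm(17))$p < 0.05, logical(1))
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("Spearman correlation equals Pearson on mid-ranks and is monotone-invariant", {
  expect_equal(spearman_cor(1:10, 1:10)$r, 1)
  expect_equal(spearman_cor(1:10, 10:1)$r, -1)
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$r, 0.8)
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  expect_equal(spearman_cor(x, y)$r, cor(rank(x), rank(y)))
  expect_equal(spearman_cor(exp(x), y)$r, spearman_cor(x, y)$r)
  expect_equal(spearman_cor(x, y^3 + 10)$r, spearman_cor(x, exp(y))$r)
  expect_false(spearman_cor(rep(1, 5), 1:5)$defined)
})

test_that("AUC equals brute-force pair counting, including ties", {
  r <- roc_auc(c(160, 150, 140), c(130, 145, 120), "lower")
  expect_equal(r$auc, 8 / 9)
  set.seed(11)
  for (rep in 1:1000) {
    n0 <- sample(2:8, 1); n1 <- sample(2:8, 1)
    ctrl <- sample(1:6, n0, replace = TRUE)   # coarse grid forces ties
    case <- sample(1:6, n1, replace = TRUE)
    o <- sample(c("lower", "higher"), 1)
    expect_equal(roc_auc(ctrl, case, o)$auc, auc_brute(ctrl, case, o))
  }
})

test_that("AUC complement law and extremes hold", {
  set.seed(3)
  ctrl <- rnorm(9); case <- rnorm(7)
  a1 <- roc_auc(ctrl, case, "lower")$auc
  a2 <- roc_auc(ctrl, case, "higher")$auc
  expect_equal(a1 + a2, 1)
  expect_equal(roc_auc(case, ctrl, "higher")$auc, a1)   # swapped groups
  expect_equal(roc_auc(c(10, 11, 12), c(1, 2, 3), "lower")$auc, 1.0)
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("AUC agrees with an independent ROC implementation", {
  library(pROC)
  set.seed(21)
  for (rep in 1:10) {
    ctrl <- rnorm(15, 160, 25); case <- rnorm(12, 130, 30)
    mine <- roc_auc(ctrl, case, "lower")$auc
    ref <- as.numeric(pROC::auc(
      pROC::roc(response = rep(0:1, c(15, 12)), predictor = c(ctrl, case),
                direction = ">", quiet = TRUE)))
    expect_equal(mine, ref)
  }
})

test_that("Hanley-McNeil standard error matches its closed form at AUC one-half", {
  # at A = 0.5 the formula reduces to SE^2 = (n0 + n1 + 1) / (12 n0 n1)
  r <- roc_auc(c(1, 4), c(2, 3), "higher")
  expect_equal(r$auc, 0.5)
  expect_equal(r$se^2, 5 / 48)
  expect_equal(r$p, 1)
})

test_that("odds ratio per SD decrease recovers a known logistic signal", {
  set.seed(9)
  cover <- vapply(1:200, function(i) {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(-x))    # log-odds 1 per SD decrease
    o <- or_per_sd(x, y)$or
    o > 2.3 && o < 3.2
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("odds ratio is null for independent predictors and reparameterization-invariant", {
  set.seed(13)
  x <- rnorm(4000); y <- rbinom(4000, 1, 0.4)
  o <- or_per_sd(x, y)
  expect_lt(abs(log(o$or)), 3 * o$se)
  expect_gt(o$p, 0.001)
  # flipping the predictor sign flips the coefficient but the same scaling
  # SD keeps |log OR| identical
  o2 <- or_per_sd(-x, y)
  expect_equal(o2$or, 1 / o$or, tolerance = 1e-8)
  sep <- or_per_sd(c(1:5, 11:15), rep(0:1, each = 5))
  expect_true(sep$separation)
  expect_identical(sep$ci, c(0, Inf))
})

test_that("forward stepwise enters a lone strong predictor and nothing else", {
  set.seed(31)
  x <- rnorm(400)
  y <- rbinom(400, 1, plogis(-1.2 * x))
  noise <- rnorm(400)
  sw <- stepwise_logistic(data.frame(signal = x, noise = noise), y)
  expect_identical(sw$entered, "signal")
  expect_true(all(sw$entry_p < 0.05))
  expect_true(all(sw$entered %in% c("signal", "noise")))
})

test_that("pure-noise candidates enter at about the nominal rate", {
  set.seed(47)
  entered <- vapply(1:200, function(i) {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(-x))
    nz <- rnorm(1000)
    sw <- stepwise_logistic(data.frame(signal = x, noise = nz), y)
    "noise" %in% sw$entered
  }, logical(1))
  expect_lte(mean(entered), 0.10)
})

test_that("near-collinear equally informative candidates yield a single entry", {
  set.seed(59)
  x1 <- rnorm(300)
  x2 <- 0.99 * x1 + sqrt(1 - 0.99^2) * rnorm(300)
  y <- rbinom(300, 1, plogis(-(x1 + x2) / 2))
  sw <- stepwise_logistic(data.frame(a = x1, b = x2), y)
  expect_identical(length(sw$entered), 1L)
  expect_true(all(sw$entry_p < 0.05))
})

test_that("an empty stepwise model is a valid result", {
  set.seed(61)
  sw <- stepwise_logistic(data.frame(a = rnorm(80), b = rnorm(80)),
                          rbinom(80, 1, 0.5))
  expect_length(sw$entered, 0)
  expect_identical(nrow(sw$summary), 0L)
})
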