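test_that("cohort sample moments converge to the group parameters", {
  p <- cohort_params(n_per_group = 10000L)
  co <- generate_cohort(p, seed = 11)
  tab <- p$params
  n <- 10000
  for (grp in 0:1) {
    sub <- co[co$group == grp, ]
    mcol <- if (grp == 0) "control_mean" else "case_mean"
    scol <- if (grp == 0) "control_sd" else "case_sd"
    for (v in vertebral_levels()) {
      i <- match(v, tab$variable)
      expect_lt(abs(mean(sub[[v]]) - tab[[mcol]][i]), 4 * tab[[scol]][i] / sqrt(n))
    }
    # VAT/SAT are zero-truncated; compare against truncated-normal moments
    for (v in c("VAT", "SAT")) {
      i <- match(v, tab$variable)
      mu <- tab[[mcol]][i]; s <- tab[[scol]][i]
      mu_trunc <- mu + s * dnorm(mu / s) / pnorm(mu / s)
      expect_lt(abs(mean(sub[[v]]) - mu_trunc), 4 * s / sqrt(n))
    }
  }
  # the Th7 group means reproduce the published 166.3 / 128.4 within 1%
  expect_lt(abs(mean(co$Th7[co$group == 0]) / 166.3 - 1), 0.01)
  expect_lt(abs(mean(co$Th7[co$group == 1]) / 128.4 - 1), 0.01)
})

test_that("cohort structure: perfect 1:1 matching, non-negative fat, recomputable ratio", {
  co <- generate_cohort(cohort_params(n_per_group = 40L), seed = 5)
  ctrl <- co[co$group == 0, ]; case <- co[co$group == 1, ]
  expect_setequal(ctrl$pair_id, case$pair_id)
  expect_false(any(duplicated(ctrl$pair_id)))
  expect_true(all(co$VAT >= 0) && all(co$SAT >= 0))
  expect_equal(co$VATSAT[co$SAT > 0], (co$VAT / co$SAT)[co$SAT > 0])
  expect_equal(co$L1L3, rowMeans(co[, c("L1", "L2", "L3")]))
  expect_identical(generate_cohort(cohort_params(), seed = 9),
                   generate_cohort(cohort_params(), seed = 9))
})

test_that("identical group distributions give chance-level discrimination at large n", {
  tab <- table1_parameters()
  tab$case_mean <- tab$control_mean
  tab$case_sd <- tab$control_sd
  co <- generate_cohort(cohort_params(params = tab, n_per_group = 5000L), seed = 2)
  a <- roc_auc(co$Th9[co$group == 0], co$Th9[co$group == 1], "lower")
  expect_lt(abs(a$auc - 0.5), 0.02)
})

test_that("exchangeable latent correlation propagates to Spearman as the Gaussian copula predicts", {
  p <- cohort_params(rho = 0.8, n_per_group = 5000L)
  co <- generate_cohort(p, seed = 4)
  expected <- 6 / pi * asin(0.8 / 2)
  for (pair in list(c("Th5", "Th11"), c("Th7", "L2"), c("L1", "L5"))) {
    r <- spearman_cor(co[[pair[1]]][co$group == 0],
                      co[[pair[2]]][co$group == 0])$r
    expect_lt(abs(r - expected), 0.05)
  }
})

test_that("prevalent-fracture injection produces missing BMD cells, not zeros", {
  co <- generate_cohort(cohort_params(n_prevalent = 5L), seed = 8)
  bmd <- as.matrix(co[, vertebral_levels()])
  expect_identical(sum(is.na(bmd[co$group == 1, ])), 5L)
  expect_identical(sum(is.na(bmd[co$group == 0, ])), 0L)
  expect_false(any(bmd == 0, na.rm = TRUE))
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(n_per_group = 0L), "positive")
  expect_error(cohort_params(rho = 1), "rho")
  bad <- table1_parameters(); bad$control_sd[1] <- 0
  expect_error(cohort_params(params = bad), "SD")
})
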