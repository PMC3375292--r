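test_that("well-separated classes classify perfectly, null data at chance", {
  set.seed(301)
  # two classes 10 SD apart
  x <- rbind(matrix(rnorm(50 * 3), 50, 3),
             matrix(rnorm(50 * 3, mean = 10), 50, 3))
  g <- rep(c("a", "b"), each = 50)
  fit <- lda_fit(x, g)
  expect_equal(fit$overall_loo_pct, 100)
  expect_lt(fit$wilks_lambda, 0.05)
  # 4 shuffled classes of 50: LOO within the binomial 99% CI around 25%
  set.seed(302)
  xn <- matrix(rnorm(200 * 8), 200, 8)
  gn <- sample(rep(letters[1:4], each = 50))
  fitn <- lda_fit(xn, gn)
  ci <- qnorm(0.995) * sqrt(0.25 * 0.75 / 200) * 100
  expect_lt(abs(fitn$overall_loo_pct - 25), ci + 3)  # LOO pessimism margin
  expect_lte(fitn$overall_loo_pct, fitn$overall_training_pct + 5)
})

test_that("Wilks' lambda is 1 when class means are equal by construction", {
  set.seed(303)
  base <- matrix(rnorm(40 * 3), 40, 3)
  # duplicating the data across classes makes every class mean identical
  x <- rbind(base, base)
  g <- rep(c("a", "b"), each = 40)
  fit <- lda_fit(x, g)
  expect_equal(fit$wilks_lambda, 1, tolerance = 1e-10)
  expect_equal(fit$chi_sq, 0, tolerance = 1e-8)
})

test_that("the chi-square approximation uses Bartlett's correction", {
  set.seed(304)
  x <- matrix(rnorm(90 * 4), 90, 4)
  x[31:60, 1] <- x[31:60, 1] + 1
  g <- rep(c("a", "b", "c"), each = 30)
  fit <- lda_fit(x, g)
  W <- matrix(0, 4, 4)
  for (k in c("a", "b", "c")) {
    xi <- scale(x[g == k, ], scale = FALSE)
    W <- W + crossprod(xi)
  }
  lam <- det(W) / det(crossprod(scale(x, scale = FALSE)))
  expect_equal(fit$wilks_lambda, lam, tolerance = 1e-10)
  expect_equal(fit$chi_sq, -(90 - 1 - (4 + 3) / 2) * log(lam),
               tolerance = 1e-10)
  expect_identical(fit$df, 4L * 2L)
  expect_identical(ncol(fit$scaling), 2L)   # min(p, g-1)
})

test_that("degenerate inputs are rejected with useful errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(lda_fit(x, rep("a", 10)), "2 classes")
  expect_error(lda_fit(x, c(rep("a", 9), "b")), "single note")
  expect_error(lda_fit(matrix(rnorm(12), 4, 3), c("a", "a", "b", "b")),
               "variables")
})

test_that("structure matrix ranks the informative variable first", {
  set.seed(305)
  g <- rep(c("a", "b"), each = 60)
  x <- cbind(sig = ifelse(g == "a", 0, 3) + rnorm(120),
             n1 = rnorm(120), n2 = rnorm(120), n3 = rnorm(120))
  fit <- lda_fit(x, g)
  sm <- structure_matrix(fit, x, g, top = 4)
  expect_identical(sm$top$variable[1], "sig")
  expect_true(all(abs(sm$correlations) <= 1))
  # a pure-noise variable has near-zero loading
  expect_lt(abs(sm$correlations["n1", 1]), 0.3)
})

test_that("group-rate comparison and outlier test follow their formulas", {
  wild <- c(88, 98, 94, 84); captive <- c(63, 82, 65, 37)
  cmp <- compare_group_rates(wild, captive)
  expect_equal(round(cmp$t, 3), 2.987)
  expect_equal(cmp$df, 6)
  expect_equal(round(cmp$p_value, 3), 0.024)
  # symmetry: swapping groups negates t, keeps p
  rev <- compare_group_rates(captive, wild)
  expect_equal(rev$t, -cmp$t)
  expect_equal(rev$p_value, cmp$p_value)
  # identical groups: t = 0, p = 1
  same <- compare_group_rates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_group_rates(c(1, 1), c(1, 1)), "variance")

  # outlier test: candidate at the mean gives 0; brute-force oracle on a
  # symmetric set
  r <- c(10, 20, 30)
  expect_equal(outlier_chisq(r, 20)$chi_sq, 0)
  expect_equal(outlier_chisq(r, 20)$p_value, 1)
  a <- 5; rs <- c(-a, 0, a)
  brute <- (a - sum(rs) / 3)^2 / (sum((rs - mean(rs))^2) / 2)
  got <- outlier_chisq(rs, a)
  expect_equal(got$chi_sq, brute)
  expect_equal(got$p_value, pchisq(brute, 1, lower.tail = FALSE))
  expect_error(outlier_chisq(rs, 99), "candidate")
})

test_that("Holm correction reproduces the step-down ladder", {
  one <- holm_correction(0.03, alpha = 0.05)
  expect_true(one$reject)
  expect_equal(one$threshold, 0.05)
  lad <- holm_correction(c(0.04, 0.001), alpha = 0.05)
  expect_equal(lad$threshold, c(0.05, 0.025))
  expect_true(all(lad$reject))
  none <- holm_correction(rep(1, 5))
  expect_false(any(none$reject))
  expect_error(holm_correction(c(0.5, 1.2)), "0, 1")
})

test_that("chance rates match equal-probability assignment", {
  expect_equal(chance_rate(4), 25)
  expect_equal(round(chance_rate(18)), 6)
})
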