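test_that("perfect agreement gives ICC 1 with zero SEM", {
  Y <- cbind(seq(10, 19), seq(10, 19))
  fit <- icc(Y)
  expect_identical(fit$icc, 1)
  expect_identical(c(fit$ci_low, fit$ci_high), c(1, 1))
  expect_equal(sem(Y, fit$icc), 0)
})

test_that("both ICC forms match the brute-force ANOVA oracle", {
  # fixed 6 x 2 toy table
  Y <- cbind(c(9, 11, 13, 10, 14, 12), c(9.5, 10.5, 13.5, 10, 14.5, 11.5))
  for (model in c("two_way_random_absolute_single",
                  "two_way_mixed_consistency_single")) {
    expect_equal(icc(Y, model)$icc, oracle_icc(Y, model), tolerance = 1e-10)
  }
  # randomized small designs
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(3:8, 1); k <- sample(2:3, 1)
    Y <- random_ratings_matrix(n, k)
    for (model in c("two_way_random_absolute_single",
                    "two_way_mixed_consistency_single")) {
      expect_equal(icc(Y, model)$icc, oracle_icc(Y, model),
                   tolerance = 1e-10)
    }
  }
})

test_that("long-format tables are validated and matched to the matrix path", {
  r <- simulate_ratings(12, 3, 0.3, 0.6, 8, 3, seed = 2)
  Y <- matrix(r$value, 8, 3)
  expect_equal(icc(r)$icc, icc(Y)$icc, tolerance = 1e-12)
  expect_error(icc(r[-1, ]), "incomplete")
  expect_error(icc(r[r$rater_id == "R1", ]), "at least 2")
  expect_error(icc(matrix(5, 4, 2)), "zero total variance")
})

test_that("qualitative bands follow the published cut-points and are monotone", {
  expect_equal(classify_icc(c(0, 0.78, 0.93)), c("poor", "good", "very_good"))
  expect_equal(classify_icc(c(0.3, 0.5, -0.4, 1)),
               c("fair", "moderate", "poor", "very_good"))
  # half-open midpoint boundaries: every value gets exactly one band
  expect_equal(classify_icc(c(0.205, 0.405, 0.605, 0.805)),
               c("fair", "moderate", "good", "very_good"))
  expect_error(classify_icc(1.2), "exceed")
  set.seed(13)
  x <- sort(runif(50, -0.5, 1))
  bands <- match(classify_icc(x),
                 c("poor", "fair", "moderate", "good", "very_good"))
  expect_true(all(diff(bands) >= 0))
})

test_that("SEM and MDC follow their closed forms", {
  Y <- cbind(c(1, 5, 9, 13), c(2, 6, 10, 14))
  expect_equal(sem(Y, 0.75), sd(as.vector(Y)) * 0.5)
  expect_equal(sem(Y, 1), 0)
  expect_error(sem(Y, 1.2), "\\[-1, 1\\]")
  # ANOVA-error SEM recovers the generating error SD
  r <- simulate_ratings(12, 3, 0, 1, 1000, 2, seed = 4)
  expect_lt(abs(sem(r, method = "anova_error") - 1), 0.05)

  expect_equal(mdc(0), 0)
  expect_equal(round(mdc(1.74), 2), 2.46)
  expect_equal(round(mdc(0.55), 2), 0.78)
  expect_equal(mdc(2, z = qnorm(0.975)), qnorm(0.975) * sqrt(2) * 2)
  expect_error(mdc(-1), "non-negative")
  set.seed(9)
  x <- runif(20, 0.01, 10)
  expect_equal(mdc(x) / x, rep(sqrt(2), 20))
})

test_that("ICC estimates recover the generating variance ratio", {
  for (rho in c(0.5, 0.8, 0.95)) {
    ss <- sqrt(rho / (1 - rho))
    r <- simulate_ratings(12, ss, 0, 1, 2000, 2, seed = 11)
    expect_lt(abs(icc(r)$icc - rho), 0.02)
    expect_equal(attr(r, "true_icc"), rho)
  }
  # with a rater effect the single realized contrast does not average out,
  # but the estimate is unbiased across independent rater draws
  est <- vapply(1:150, function(s)
    icc(simulate_ratings(12, 3, 0.5, 0.5, 150, 2, seed = s))$icc, numeric(1))
  expect_lt(abs(mean(est) - 9 / (9 + 0.25 + 0.25)), 0.015)
})

test_that("95% CIs cover the true ICC near nominally", {
  hits <- 0L
  for (i in 1:300) {
    f <- icc(simulate_ratings(12, 2, 0, 1, 30, 2, seed = 10000 + i))
    if (f$ci_low <= 0.8 && f$ci_high >= 0.8) hits <- hits + 1L
  }
  expect_gt(hits / 300, 0.90)
  expect_lt(hits / 300, 0.99)
})

test_that("concurrent validity mirrors the two-rater ICC contract", {
  a <- stats::setNames(c(10, 12, 14, 16, 11, 13, 15, 17, 12, 18),
                       paste0("S", 1:10))
  expect_equal(concurrent_validity(a, a)$icc, 1)

  # fixed offset of one SD: absolute agreement penalised, consistency not
  b <- a + sd(a)
  abs_fit <- concurrent_validity(a, b)
  con_fit <- concurrent_validity(a, b, model = "two_way_mixed_consistency_single")
  expect_lt(abs_fit$icc, con_fit$icc)
  expect_equal(abs_fit$icc, oracle_icc(cbind(a, b)), tolerance = 1e-10)
  expect_equal(con_fit$icc,
               oracle_icc(cbind(a, b), "two_way_mixed_consistency_single"),
               tolerance = 1e-10)

  # independent noise: near-zero agreement
  set.seed(21)
  x <- stats::setNames(rnorm(50, 12, 2), paste0("S", 1:50))
  y <- stats::setNames(rnorm(50, 12, 2), paste0("S", 1:50))
  expect_lt(abs(concurrent_validity(x, y)$icc), 0.3)

  expect_error(concurrent_validity(a, a[1:5]), "different subject sets")
})

test_that("sample size for an ICC study is sane and sufficiently powered", {
  n <- sample_size_icc(rho0 = 0.75, rho1 = 0.95, alpha = 0.05,
                       power = 0.80, k = 2)
  expect_true(n %in% c(10L, 11L))

  # Monte-Carlo power oracle at the returned n: one-sided test rejects when
  # the lower one-sided 95% bound exceeds rho0
  ss <- sqrt(0.95 / 0.05)
  rejections <- vapply(1:400, function(s) {
    f <- icc(simulate_ratings(12, ss, 0, 1, n, 2, seed = 20000 + s),
             conf_level = 0.90)
    f$ci_low > 0.75
  }, logical(1))
  expect_gt(mean(rejections), 0.80 - 3 * sqrt(0.8 * 0.2 / 400))

  # monotonicity: shrinking effect gap or tightening alpha/power raises n
  expect_gt(sample_size_icc(0.90, 0.95), n)
  expect_gt(sample_size_icc(0.75, 0.95, alpha = 0.01, power = 0.95), n)
  expect_error(sample_size_icc(0.95, 0.75), "rho0 < rho1")
})
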