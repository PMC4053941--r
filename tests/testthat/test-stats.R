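# Cohort statistics: one-tailed chi-squared, two-sample KS, stringency.

test_that("a null table gives statistic 0 and one-tailed p = 0.5", {
  r <- chi2_shell_test(c(10, 5, 9, 8, 8), c(20, 10, 18, 16, 16))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)
  expect_identical(r$direction, "none")
  expect_identical(r$stringency, "ns")
})

test_that("the chi-squared statistic matches the closed form", {
  # a=30, b=15 (test shell1/internal), c=10, d=25
  ct <- c(30, 0, 5, 5, 5); cc <- c(10, 0, 10, 10, 5)
  r <- chi2_shell_test(ct, cc)
  expect_equal(r$statistic, oracle_chi2_stat(30, 15, 10, 25),
               tolerance = 1e-12)
  expect_equal(r$statistic, 80 * (30 * 25 - 15 * 10)^2 / (45 * 35 * 40 * 40),
               tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE) / 2)
  expect_identical(r$direction, "peripheral_gain")
  # swapping cohorts flips direction, keeps the statistic
  rs <- chi2_shell_test(cc, ct)
  expect_equal(rs$statistic, r$statistic)
  expect_identical(rs$direction, "peripheral_loss")
  expect_equal(rs$p_value, 1 - pchisq(r$statistic, 1, lower.tail = FALSE) / 2)
})

test_that("chi-squared agrees with stats::chisq.test on random tables", {
  set.seed(99)
  for (i in 1:200) {
    a <- sample(1:40, 4)
    r <- chi2_shell_test(c(a[1], 0, a[2], 0, 0), c(a[3], 0, a[4], 0, 0),
                         two_sided = TRUE)
    ref <- suppressWarnings(
      chisq.test(matrix(a, 2, byrow = TRUE), correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("degenerate tables and bad counts are rejected", {
  expect_error(chi2_shell_test(c(0, 0, 0, 0, 0), c(1, 0, 1, 0, 0)),
               "degenerate")
  expect_error(chi2_shell_test(c(5, 0, 0, 0, 0), c(5, 0, 0, 0, 0)),
               "degenerate")   # internal margin zero
  expect_error(chi2_shell_test(c(1, 2), c(1, 2)), "K >= 5")
  expect_error(chi2_shell_test(c(1.5, 0, 1, 1, 1), c(1, 0, 1, 1, 1)),
               "integer")
})

test_that("KS separated samples give D = 1 and exact p = 0.1", {
  r <- ks_peripheral_test(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 2 / choose(6, 3))
  expect_identical(r$method, "exact")
  expect_identical(r$direction, "peripheral_loss")
})

test_that("identical samples give D = 0 and p = 1", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  r <- ks_peripheral_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("exact KS p matches the exhaustive permutation oracle", {
  set.seed(13)
  for (n1 in c(3, 5, 7)) for (n2 in c(4, 6)) {
    x <- runif(n1); y <- runif(n2) + 0.2
    r <- ks_peripheral_test(x, y)
    expect_identical(r$method, "exact")
    expect_equal(r$p_value, oracle_ks_perm_p(x, y), tolerance = 1e-12)
  }
})

test_that("asymptotic KS p agrees with stats::ks.test at larger n", {
  set.seed(14)
  x <- rnorm(80); y <- rnorm(90, 0.3)
  r <- ks_peripheral_test(x, y)
  ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("profiles are accepted directly and tiny cohorts rejected", {
  m <- disc_mask(40, 101)
  p <- erode_shells_2d(m, 5)
  profs <- lapply(c(0.5, 1, 2), function(a)
    shell_intensity_profile_2d(p, ifelse(p$labels == 1L, a, 0.1)))
  ctrl <- lapply(c(1, 1.5, 2.5), function(a)
    shell_intensity_profile_2d(p, ifelse(p$labels == 5L, a, 0.1)))
  r <- ks_peripheral_test(profs, ctrl)
  expect_identical(r$direction, "peripheral_gain")
  expect_error(ks_peripheral_test(c(1, 2), c(1, 2, 3)),
               "insufficient cells")
})

test_that("stringency classes follow the 0.01/0.05 thresholds strictly", {
  expect_identical(classify_stringency(0.002), "high")
  expect_identical(classify_stringency(0.03), "low")
  expect_identical(classify_stringency(0.05), "ns")   # boundary is strict
  expect_identical(classify_stringency(0.01), "low")
  expect_error(classify_stringency(1.2), "\\[0, 1\\]")
  expect_error(classify_stringency(-0.1), "\\[0, 1\\]")
})

test_that("replicate summaries use the n-1 standard deviation", {
  r <- replicate_summary(c(50, 60, 70))
  expect_equal(r$mean, 60)
  expect_equal(r$sd, 10)
  expect_equal(replicate_summary(c(20, 22))$sd, sqrt(2))
  expect_equal(replicate_summary(c(5, 5, 5))$sd, 0)
  expect_error(replicate_summary(7), "at least 2")
})
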