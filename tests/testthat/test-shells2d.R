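# Equal-area quantile partition of the midplane and per-shell scoring.

test_that("disc shells have analytic equal-area boundaries", {
  R <- 100
  m <- disc_mask(R, 221)
  p <- erode_shells_2d(m, 5)
  ctr <- 111
  r <- sqrt((row(m) - ctr)^2 + (col(m) - ctr)^2)
  # shell-1/shell-2 boundary at R*sqrt(0.8) (20% of a disc's area lies
  # outside that radius)
  b12 <- R * sqrt(0.8)
  expect_lt(abs(max(r[p$labels == 2]) - b12), 1)
  expect_lt(abs(min(r[p$labels == 1]) - b12), 1)
  # innermost boundary at R*sqrt(0.2)
  b45 <- R * sqrt(0.2)
  expect_lt(abs(max(r[p$labels == 5]) - b45), 1)
})

test_that("K = 1 partition is the mask itself", {
  m <- random_blob_mask(9, size = 101, r0 = 35)
  p <- erode_shells_2d(m, 1)
  expect_identical(p$labels == 1L, m)
})

test_that("partition labels equal the brute-force distance-sort oracle", {
  for (seed in c(4, 8, 15)) {
    m <- random_blob_mask(seed, size = 121, r0 = 45)
    p <- erode_shells_2d(m, 5)
    expect_identical(p$labels, oracle_partition_labels(m, 5))
  }
})

test_that("partitions are nested, near-equal and cover the mask exactly", {
  for (seed in 21:26) {
    m <- random_blob_mask(seed)
    p <- erode_shells_2d(m, 5)
    A <- sum(m)
    # exact cover
    expect_identical(p$labels > 0L, m)
    expect_equal(sum(p$shell_sizes), A)
    # discretization imbalance below K
    expect_lt(max(p$shell_sizes) - min(p$shell_sizes), 5)
    # nesting: shells are distance-ordered bands
    d <- p$distance
    for (k in 1:4)
      expect_lte(max(d[p$labels == k]), min(d[p$labels == k + 1L]))
  }
})

test_that("too-small masks are rejected", {
  m <- matrix(FALSE, 30, 30)
  m[10:15, 10:15] <- TRUE   # 36 px < 25 * 5
  expect_error(erode_shells_2d(m, 5), "too small")
})

test_that("spot shell assignment matches analytic disc area fractions", {
  R <- 100
  m <- disc_mask(R, 221)
  p <- erode_shells_2d(m, 5)
  ctr0 <- 110   # 0-based centre
  mk_spot <- function(x, y) {
    structure(list(x = x, y = y, z = 0, peak = 1, shell = NA_integer_,
                   cell_id = NA), class = "spot_record")
  }
  # centre of the disc: distance maximum, innermost shell
  expect_identical(assign_spot_shell(p, mk_spot(ctr0, ctr0))$shell, 5L)
  # radius 90: outer area fraction 1 - 0.9^2 = 0.19 < 0.20, shell 1
  expect_identical(assign_spot_shell(p, mk_spot(ctr0 + 90, ctr0))$shell, 1L)
  # radius 60: outer fraction 0.64, cumulative band (0.6, 0.8], shell 4
  expect_identical(assign_spot_shell(p, mk_spot(ctr0, ctr0 - 60))$shell, 4L)
  # outside the mask
  expect_error(assign_spot_shell(p, mk_spot(1, 1)), "outside mask")
})

test_that("shell histograms count and normalize correctly", {
  h <- shell_spot_histogram(rep(1L, 50), 5)
  expect_equal(h$percent, c(100, 0, 0, 0, 0))
  expect_equal(sum(h$counts), 50)
  coh <- simulate_spot_cohort(sim_config(seed = 61), 5000)
  h2 <- shell_spot_histogram(coh$true_shell, 5)
  expect_true(all(abs(h2$percent - 20) < 1.7))
  expect_equal(sum(h2$percent), 100)
  expect_error(shell_spot_histogram(integer(0), 5), "no cells")
})

test_that("intensity profiles fraction signal by shell", {
  m <- disc_mask(60, 141)
  p <- erode_shells_2d(m, 5)
  # uniform signal over the mask: equal areas give 0.2 per shell
  prof <- shell_intensity_profile_2d(p, ifelse(m, 1, 0))
  expect_equal(prof$fractions, p$shell_sizes / sum(p$shell_sizes))
  expect_true(all(abs(prof$fractions - 0.2) < 1e-3))
  expect_equal(sum(prof$fractions), 1, tolerance = 1e-9)
  expect_equal(prof$peripheral_sum, sum(prof$fractions[1:2]))
  expect_equal(prof$internal_sum, sum(prof$fractions[4:5]))
  # signal confined to shell 1
  sig <- ifelse(p$labels == 1L, 2.5, 0)
  expect_equal(shell_intensity_profile_2d(p, sig)$fractions,
               c(1, 0, 0, 0, 0))
  # background subtraction and thresholding zero out the rest
  sig2 <- ifelse(p$labels == 1L, 2.5, 0.4) + 0.1
  prof2 <- shell_intensity_profile_2d(p, sig2, threshold = 0.5,
                                      background = 0.1)
  expect_equal(prof2$fractions, c(1, 0, 0, 0, 0))
  expect_error(shell_intensity_profile_2d(p, matrix(0, 141, 141)),
               "no signal")
})

test_that("counterstain profile reflects a rim enhancement as 2/6", {
  m <- disc_mask(60, 141)
  p <- erode_shells_2d(m, 5)
  dapi <- ifelse(p$labels == 1L, 2, ifelse(m, 1, 0))
  prof <- dapi_shell_profile(p, dapi)
  s <- p$shell_sizes
  expect_equal(prof$fractions[1], 2 * s[1] / (2 * s[1] + sum(s[2:5])))
  expect_equal(prof$fractions[1], 1 / 3, tolerance = 1e-3)
  expect_error(dapi_shell_profile(p, matrix(0, 141, 141)), "no signal")
})
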