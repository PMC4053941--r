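# Equal-volume 3D partition, territory binarization and the
# sequential-subtraction identity.

test_that("ball shells have the analytic equal-volume boundary", {
  R <- 20
  v <- ball_mask(R, 49)
  p <- erode_shells_3d(v, 6, voxel_dims = c(1, 1, 1))
  ctr <- 25
  g2 <- (seq_len(49) - ctr)^2
  r <- sqrt(outer(outer(g2, g2, "+"), g2, "+"))
  b12 <- R * (5 / 6)^(1 / 3)       # 0.9410 R
  expect_lt(abs(max(r[p$labels == 2]) - b12), 1)
  expect_lt(abs(min(r[p$labels == 1]) - b12), 1)
})

test_that("anisotropic partitions match the brute-force oracle", {
  v <- random_blob_volume(31, dims = c(40L, 40L, 14L))
  p <- erode_shells_3d(v, 6, voxel_dims = c(1, 1, 2))
  expect_identical(p$labels, oracle_partition_labels(v, 6, c(1, 1, 2)))
  # calibration flows through from the nuclear mask (0.2/0.1 = ratio 2)
  nm <- structure(list(mask = v, pixel_size_xy = 0.1, z_step = 0.2),
                  class = "nuclear_mask")
  p2 <- erode_shells_3d(nm, 6)
  expect_identical(p2$labels, p$labels)
  # disabling anisotropy changes the partition of a flat volume
  p3 <- erode_shells_3d(v, 6, voxel_dims = c(1, 1, 2), anisotropic = FALSE)
  expect_false(identical(p3$labels, p$labels))
})

test_that("K = 1 returns the mask and small volumes are rejected", {
  v <- ball_mask(10, 25)
  expect_identical(erode_shells_3d(v, 1, voxel_dims = c(1, 1, 1))$labels == 1L,
                   v)
  small <- array(FALSE, c(16, 16, 8)); small[4:12, 4:12, 3:6] <- TRUE
  expect_error(erode_shells_3d(small, 6, voxel_dims = c(1, 1, 1)),
               "too small")
})

test_that("equal-volume property holds on random volumes", {
  for (seed in c(51, 52, 53)) {
    v <- random_blob_volume(seed)
    p <- erode_shells_3d(v, 6, voxel_dims = c(1, 1, 2))
    expect_lt(max(abs(p$shell_sizes - sum(v) / 6)) / (sum(v) / 6), 0.02)
  }
})

test_that("territory binarization removes speckle but keeps the body", {
  cfg <- sim_config(seed = 71, noise = list(gaussian_sd = 0,
                                            poisson_scale = 0))
  s <- simulate_territory_3d(cfg, 1)
  nm <- segment_nucleus(s$stack)
  # noiseless: binary equals the generating region exactly
  terr <- binarize_territory(s$stack, nm, threshold = 0.3)
  expect_identical(terr$mask, s$territory & nm$mask)
  # add five isolated 3-voxel speckles inside the nucleus
  vol <- get_channel(s$stack, "territory")
  free <- which(nm$mask & !s$territory & vol < 0.1)
  set.seed(1)
  for (lin in sample(free, 5)) {
    ijk <- arrayInd(lin, dim(vol))
    vol[ijk[1], ijk[2], ijk[3]] <- 0.9
    if (ijk[1] > 1) vol[ijk[1] - 1, ijk[2], ijk[3]] <- 0.9
    if (ijk[2] > 1) vol[ijk[1], ijk[2] - 1, ijk[3]] <- 0.9
  }
  cleaned <- binarize_territory(vol, nm, threshold = 0.3,
                                min_component_size = 10)
  expect_identical(cleaned$mask, s$territory & nm$mask)
  # threshold above the maximum leaves nothing
  expect_error(binarize_territory(vol, nm, threshold = 2), "no territory")
})

test_that("sequential subtraction equals direct per-shell summation", {
  cfg <- sim_config(seed = 72,
                    territory = list(radial_bias = 2, area_fraction = 0.12))
  for (i in 1:3) {
    s <- simulate_territory_3d(cfg, i)
    nm <- segment_nucleus(s$stack)
    p <- erode_shells_3d(nm, 6)
    terr <- binarize_territory(s$stack, nm, threshold = 0.3)
    prof <- unique_shell_fractions_3d(p, terr)
    direct <- vapply(1:6, function(k)
      sum(terr$mask & p$labels == k) / sum(terr$mask), numeric(1))
    expect_equal(prof$fractions, direct, tolerance = 1e-9)
    expect_equal(sum(prof$fractions), 1, tolerance = 1e-9)
    expect_equal(prof$peripheral_sum + sum(prof$fractions[3:4]) +
                   prof$internal_sum, 1, tolerance = 1e-9)
  }
})

test_that("a whole-nucleus territory spreads ~1/6 per unique shell", {
  cfg <- sim_config(seed = 73,
                    territory = list(radial_bias = 0, area_fraction = 0.999),
                    noise = list(gaussian_sd = 0, poisson_scale = 0))
  s <- simulate_territory_3d(cfg, 1)
  nm <- segment_nucleus(s$stack)
  p <- erode_shells_3d(nm, 6)
  terr <- binarize_territory(s$stack, nm, threshold = 0.3)
  prof <- unique_shell_fractions_3d(p, terr)
  expect_true(all(abs(prof$fractions - 1 / 6) < 0.005))
})

test_that("territory confined to outer shells registers only there", {
  v <- ball_mask(16, 41)
  p <- erode_shells_3d(v, 6, voxel_dims = c(1, 1, 1))
  tm <- array(p$labels %in% 1:2, dim(p$labels))
  terr <- structure(list(mask = tm, threshold = 0, min_component_size = 1L),
                    class = "binary_territory")
  prof <- unique_shell_fractions_3d(p, terr)
  s <- p$shell_sizes
  expect_equal(prof$fractions,
               c(s[1], s[2], 0, 0, 0, 0) / (s[1] + s[2]),
               tolerance = 1e-12)
})

test_that("2D and 3D analyses recapitulate the same peripheral ordering", {
  run_arm <- function(bias, seed, n = 8) {
    cfg <- sim_config(seed = seed,
                      territory = list(radial_bias = bias,
                                       area_fraction = 0.1))
    t(vapply(seq_len(n), function(i) {
      s <- simulate_territory_3d(cfg, i)
      nm <- segment_nucleus(s$stack)
      p3 <- unique_shell_fractions_3d(
        erode_shells_3d(nm, 6),
        binarize_territory(s$stack, nm, threshold = 0.3))
      mz <- select_midplane(nm)
      plane <- get_channel(s$stack, "territory")[, , mz + 1]
      p2 <- shell_intensity_profile_2d(erode_shells_2d(nm, 5), plane,
                                       threshold = 0.3)
      c(p2$peripheral_sum, p3$peripheral_sum)
    }, numeric(2)))
  }
  biased <- run_arm(3, 81)
  control <- run_arm(0, 82)
  # both views order the cohorts the same way ...
  expect_gt(mean(biased[, 1]), mean(control[, 1]))
  expect_gt(mean(biased[, 2]), mean(control[, 2]))
  # ... and within each cell the two views are positively associated
  all2d <- c(biased[, 1], control[, 1])
  all3d <- c(biased[, 2], control[, 2])
  expect_gt(cor(all2d, all3d), 0.5)
})
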