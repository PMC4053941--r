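#' Simulation configuration
#'
#' Parameters of the synthetic-image generator that stands in for the
#' microscopy data: nuclei are smooth, slightly irregular elliptical blobs
#' with weaker-intensity nucleolar regions; tagged loci are point-like
#' Gaussian spots placed with a configurable radial bias; chromosome
#' territories are connected regions occupying a set fraction of the
#' nuclear volume at a configurable radial position. Defaults emulate the
#' empirical regimes of the assay: a uniform-in-area baseline puts roughly
#' 20 percent of loci in each of five shells, and peripherally enriched
#' conditions put 50-60 percent in shell 1.
#'
#' @param n_cells cells per condition (default 50, the per-condition sample
#'   size of the 2D locus screen).
#' @param n_shells_2d,n_shells_3d shell counts (defaults 5 and 6).
#' @param nucleus list: `semi_axes` (x, y) in px of the midplane ellipse,
#'   `roughness` (relative amplitude of low-frequency boundary
#'   perturbation).
#' @param img_size 2D image size `(y, x)` in px.
#' @param spot list: `placement` (`"uniform_area"` or `"shell_mixture"`),
#'   `shell1_prob` (mixture weight of the outermost equal-area band),
#'   `sigma` (Gaussian spot s.d., px), `amplitude` (peak intensity).
#' @param territory list: `radial_bias` (0 = uniformly placed centre;
#'   positive pushes the territory centre toward the periphery, negative
#'   toward the centre; the centre's midplane area-rank is drawn from
#'   `Beta(exp(-bias), exp(bias))`), `area_fraction` (fraction of nuclear
#'   volume occupied, in (0,1)), `intensity` (paint level),
#'   `z_compression` (z-weight of the growth metric in (0,1]; values < 1
#'   make territories columnar, spanning the nuclear height as chromosome
#'   territories do in flattened nuclei).
#' @param nucleoli list: `count`, `radius` (px), `intensity_dip` (fractional
#'   intensity reduction inside a nucleolus).
#' @param noise list: `gaussian_sd` (read noise s.d. on the [0,1] scale),
#'   `poisson_scale` (full-scale photon count for shot noise; 0 disables).
#' @param dims_3d z-stack size `(z, y, x)` in voxels (at least 16 x 64 x
#'   64).
#' @param nucleus_3d list: `semi_axes_um` (x, y, z) physical semi-axes of
#'   the 3D nucleus in micrometres.
#' @param pixel_size_xy,z_step calibration in micrometres (defaults 0.1 and
#'   0.2, matching 0.2 um acquisition steps).
#' @param seed integer master seed; per-cell substreams are derived from it
#'   so identical config + seed reproduces identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 50L,
                       n_shells_2d = 5L,
                       n_shells_3d = 6L,
                       nucleus = list(),
                       img_size = c(128L, 128L),
                       spot = list(),
                       territory = list(),
                       nucleoli = list(),
                       noise = list(),
                       dims_3d = c(20L, 80L, 80L),
                       nucleus_3d = list(),
                       pixel_size_xy = 0.1,
                       z_step = 0.2,
                       seed = 1L) {
  defaults <- function(given, def) utils::modifyList(def, as.list(given))
  cfg <- list(
    n_cells = as.integer(n_cells),
    n_shells_2d = as.integer(n_shells_2d),
    n_shells_3d = as.integer(n_shells_3d),
    nucleus = defaults(nucleus, list(semi_axes = c(45, 35),
                                     roughness = 0.05)),
    img_size = as.integer(img_size),
    spot = defaults(spot, list(placement = "uniform_area",
                               shell1_prob = 0.2, sigma = 1.5,
                               amplitude = 0.8)),
    territory = defaults(territory, list(radial_bias = 0,
                                         area_fraction = 0.1,
                                         intensity = 0.75,
                                         z_compression = 0.35)),
    nucleoli = defaults(nucleoli, list(count = 2L, radius = 6,
                                       intensity_dip = 0.5)),
    noise = defaults(noise, list(gaussian_sd = 0.01, poisson_scale = 200)),
    dims_3d = as.integer(dims_3d),
    nucleus_3d = defaults(nucleus_3d,
                          list(semi_axes_um = c(3.0, 2.4, 1.6))),
    pixel_size_xy = pixel_size_xy,
    z_step = z_step,
    seed = as.integer(seed))
  with(cfg, {
    if (n_cells < 1L) stop("n_cells must be >= 1")
    if (n_shells_2d < 1L || n_shells_3d < 1L) stop("shell counts must be >= 1")
    if (any(nucleus$semi_axes <= 0) || any(img_size < 16L))
      stop("geometric parameters must be positive (image at least 16 px)")
    if (!spot$placement %in% c("uniform_area", "shell_mixture"))
      stop("spot placement must be 'uniform_area' or 'shell_mixture'")
    if (spot$shell1_prob < 0 || spot$shell1_prob > 1)
      stop("shell1_prob must lie in [0, 1]")
    if (spot$sigma <= 0 || spot$amplitude <= 0)
      stop("spot sigma/amplitude must be positive")
    if (territory$area_fraction <= 0 || territory$area_fraction >= 1)
      stop("territory area_fraction must lie in (0, 1)")
    if (territory$z_compression <= 0 || territory$z_compression > 1)
      stop("territory z_compression must lie in (0, 1]")
    if (nucleoli$count < 0 || nucleoli$radius <= 0 ||
        nucleoli$intensity_dip < 0 || nucleoli$intensity_dip > 1)
      stop("invalid nucleoli parameters")
    if (noise$gaussian_sd < 0 || noise$poisson_scale < 0)
      stop("noise parameters must be non-negative")
    if (dims_3d[1] < 16L || dims_3d[2] < 64L || dims_3d[3] < 64L)
      stop("3D stack must be at least 16 x 64 x 64 voxels")
    if (any(nucleus_3d$semi_axes_um <= 0))
      stop("3D semi-axes must be positive")
    if (pixel_size_xy <= 0 || z_step <= 0)
      stop("calibration must be positive")
  })
  structure(cfg, class = "sim_config")
}

# Irregular-ellipse midplane mask: radius scaled by a low-frequency
# harmonic perturbation so equal-area partitioning is exercised on
# non-circular shapes while the unperturbed case stays analytic.
blob_mask_2d <- function(img_size, semi_axes, roughness) {
  eps <- if (roughness > 0) roughness * runif(3, 0.5, 1) else numeric(3)
  phi <- runif(3, 0, 2 * pi)
  cy <- (img_size[1] + 1) / 2
  cx <- (img_size[2] + 1) / 2
  y <- matrix(seq_len(img_size[1]) - cy, img_size[1], img_size[2])
  x <- matrix(seq_len(img_size[2]) - cx, img_size[1], img_size[2],
              byrow = TRUE)
  u <- x / semi_axes[1]
  v <- y / semi_axes[2]
  th <- atan2(v, u)
  rho <- 1
  for (m in 1:3) rho <- rho + eps[m] * cos((m + 1) * th + phi[m])
  mask <- (u^2 + v^2) <= rho^2
  list(mask = mask, eps = eps, phi = phi)
}

# Index (into `which(mask)` raster order) of the pixel at area-rank u:
# the fraction of nuclear area strictly outside the pixel's distance
# contour is ~u. Rank 0 = boundary, rank 1 = distance maximum.
pixels_at_area_rank <- function(mask, u, spacing = c(1, 1)) {
  dist <- distance_transform(mask, spacing)
  idx <- which(mask)
  A <- length(idx)
  ord <- order(dist[idx], seq_len(A))
  pos <- pmin(A, 1L + floor(u * A))
  idx[ord[pos]]
}

#' Pixel coordinates of mask locations at given area-ranks
#'
#' Maps area-ranks `u` in \\[0,1\\] (fraction of the nuclear area outside
#' the point's interior-distance contour: 0 = at the boundary, 1 = at the
#' distance maximum) to 0-based `(x, y)` pixel coordinates of a 2D mask.
#' Uniform `u` gives positions uniform over the nuclear area, and the
#' quantile shell partition discretizes exactly this rank, so ground truth
#' expressed as `u` makes shell-recovery tests exact.
#'
#' @param mask logical `(y, x)` mask.
#' @param u numeric vector of ranks in \\[0,1\\].
#' @return matrix with columns `x`, `y` (0-based pixel centres).
#' @export
spot_positions_at_rank <- function(mask, u) {
  stopifnot(all(u >= 0 & u <= 1))
  lin <- pixels_at_area_rank(mask, u)
  ij <- arrayInd(lin, dim(mask))
  cbind(x = ij[, 2] - 1L, y = ij[, 1] - 1L)
}

# Draw one area-rank according to the configured placement model.
draw_spot_rank <- function(spot, K) {
  if (spot$placement == "uniform_area" ) return(runif(1))
  if (runif(1) < spot$shell1_prob) runif(1, 0, 1 / K) else runif(1)
}

apply_noise <- function(img, noise) {
  if (noise$poisson_scale > 0)
    img <- rpois(length(img), img * noise$poisson_scale) /
      noise$poisson_scale
  if (noise$gaussian_sd > 0)
    img <- img + rnorm(length(img), 0, noise$gaussian_sd)
  img
}

quantize16 <- function(img, d) {
  img <- pmin(pmax(img, 0), 1)
  array(round(img * 65535) / 65535, d)
}

#' Simulate one 2D nucleus with a tagged-locus spot
#'
#' Generates a two-channel midplane image (DNA counterstain with nucleolar
#' intensity dips; one Gaussian spot) together with ground truth. The spot
#' is placed at an area-rank `u`: `"uniform_area"` draws `u ~ U(0,1)`
#' (uniform over the nuclear area); `"shell_mixture"` places the spot in
#' the outermost `1/K` area band with probability `shell1_prob` and
#' uniformly over the whole area otherwise, so the marginal shell-1
#' probability is `p + (1 - p)/K`.
#'
#' @param config a [sim_config()].
#' @param cell_id integer cell identifier (also selects the per-cell random
#'   substream).
#' @return list with `stack` (an [image_stack]), `truth` (one ground-truth
#'   record: `cell_id`, `u`, `true_shell`, `spot_x`, `spot_y`, `area`,
#'   `semi_major`, `semi_minor`), and `mask` (the noiseless generating
#'   mask).
#' @export
simulate_nucleus_2d <- function(config, cell_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sa <- config$nucleus$semi_axes
  if (3 * config$spot$sigma >= min(sa))
    stop("spot larger than nucleus")
  with_seed(cell_seed(config$seed, cell_id), {
    b <- blob_mask_2d(config$img_size, sa, config$nucleus$roughness)
    mask <- b$mask
    A <- sum(mask)
    K <- config$n_shells_2d
    u <- draw_spot_rank(config$spot, K)
    lin <- pixels_at_area_rank(mask, u)
    ij <- arrayInd(lin, dim(mask))
    part <- shell_partition_core(mask, K, c(1, 1))
    true_shell <- part$labels[lin]
    dapi <- nucleolar_dapi_2d(mask, config)
    spotch <- gaussian_spot_2d(dim(mask), x0 = ij[2] - 1, y0 = ij[1] - 1,
                               sigma = config$spot$sigma,
                               amp = config$spot$amplitude)
    dapi <- quantize16(apply_noise(dapi, config$noise), dim(mask))
    spotch <- quantize16(apply_noise(spotch, config$noise), dim(mask))
    stack <- image_stack(list(dapi, spotch), c("nuclear_stain", "spot"),
                         config$pixel_size_xy, config$z_step)
    truth <- data.frame(cell_id = as.integer(cell_id), u = u,
                        true_shell = as.integer(true_shell),
                        spot_x = ij[2] - 1, spot_y = ij[1] - 1,
                        area = A, semi_major = max(sa), semi_minor = min(sa))
    list(stack = stack, truth = truth, mask = mask)
  })
}

nucleolar_dapi_2d <- function(mask, config) {
  dapi <- ifelse(mask, 0.7, 0.02)
  nuc <- config$nucleoli
  if (nuc$count > 0) {
    d <- dim(mask)
    ij <- which(mask, arr.ind = TRUE)
    dist <- distance_transform(mask)
    interior <- dist[mask] > nuc$radius + 1
    cand <- which(interior)
    if (length(cand) > 0) {
      pick <- ij[sample(cand, min(nuc$count, length(cand))), , drop = FALSE]
      y <- matrix(seq_len(d[1]), d[1], d[2])
      x <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
      for (r in seq_len(nrow(pick))) {
        inside <- (y - pick[r, 1])^2 + (x - pick[r, 2])^2 <= nuc$radius^2
        dapi[inside & mask] <- dapi[inside & mask] * (1 - nuc$intensity_dip)
      }
    }
  }
  dapi
}

gaussian_spot_2d <- function(d, x0, y0, sigma, amp) {
  y <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  x <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  amp * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2))
}

#' Simulate one 3D nucleus with a chromosome territory
#'
#' Generates a two-channel z-stack: an ellipsoidal (optionally rough in
#' xy) nucleus with nucleolar dips, and a connected territory occupying
#' `area_fraction` of the nuclear volume. The territory is the set of
#' nuclear voxels nearest - in a z-compressed physical metric, so the
#' region is columnar like a chromosome territory in a flattened nucleus -
#' to a centre placed at the nuclear midplane whose lateral area-rank is
#' drawn from `Beta(exp(-radial_bias), exp(radial_bias))`: bias 0 places
#' centres uniformly over the midplane area, positive bias pushes
#' territories toward the periphery, negative toward the nuclear centre.
#'
#' @inheritParams simulate_nucleus_2d
#' @return list with `stack` (an [image_stack] with `nuclear_stain` and
#'   `territory` channels), `truth` (centre rank and coordinates, achieved
#'   volume fraction, true per-shell fractions `f1..fK` of the noiseless
#'   territory under the true partition), `mask` (nucleus), and
#'   `territory` (the noiseless territory voxel mask).
#' @export
simulate_territory_3d <- function(config, cell_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  frac <- config$territory$area_fraction
  if (frac >= 1) stop("territory area_fraction must be < 1")
  with_seed(cell_seed(config$seed, cell_id) + 1e6, {
    d <- config$dims_3d                       # (z, y, x)
    px <- config$pixel_size_xy
    sp <- c(px, px, config$z_step)            # (y, x, z) calibration
    spz <- c(config$z_step, px, px)           # spacing in (z, y, x) order
    mask <- blob_mask_3d(d, config$nucleus_3d$semi_axes_um, sp,
                         config$nucleus$roughness)
    V <- sum(mask)
    K <- config$n_shells_3d
    part <- shell_partition_core(mask, K, spz)
    # Territory centre: lateral (midplane) position at a biased area-rank.
    # In flattened nuclei radial position is a lateral property - a centre
    # drawn by 3D distance rank would land mostly on the top/bottom
    # surfaces - so the bias acts on the midplane area-rank and the
    # territory grows as a z-elongated column, like chromosome territories
    # spanning the nuclear height.
    b <- config$territory$radial_bias
    v <- runif(1)
    u_c <- qbeta(v, exp(-b), exp(b))
    mid <- which.max(apply(mask, 1, sum))
    mask2d <- mask[mid, , ]                     # (y, x)
    lin2d <- pixels_at_area_rank(mask2d, u_c)
    yx <- arrayInd(lin2d, dim(mask2d))
    cc <- c(mid, yx[1], yx[2])                  # (z, y, x)
    # nearest ceil(frac * V) nuclear voxels in the z-compressed metric
    zc <- config$territory$z_compression
    idx <- which(mask)
    ij <- which(mask, arr.ind = TRUE)
    dd <- ((ij[, 1] - cc[1]) * spz[1] * zc)^2 +
          ((ij[, 2] - cc[2]) * spz[2])^2 +
          ((ij[, 3] - cc[3]) * spz[3])^2
    ntv <- min(V, as.integer(ceiling(frac * V)))
    sel <- order(dd, seq_along(dd))[seq_len(ntv)]
    terr <- array(FALSE, dim(mask))
    terr[idx[sel]] <- TRUE
    true_frac <- vapply(seq_len(K),
                        function(k) sum(terr & part$labels == k) / ntv,
                        numeric(1))
    dapi <- nucleolar_dapi_3d(mask, config, spz)
    paint <- ifelse(terr, config$territory$intensity, 0.02)
    dapi <- quantize16(apply_noise(dapi, config$noise), dim(mask))
    paint <- quantize16(apply_noise(paint, config$noise), dim(mask))
    # channels stored (y, x, z)
    stack <- image_stack(list(aperm(dapi, c(2, 3, 1)),
                              aperm(paint, c(2, 3, 1))),
                         c("nuclear_stain", "territory"),
                         config$pixel_size_xy, config$z_step)
    truth <- data.frame(cell_id = as.integer(cell_id), centre_rank = u_c,
                        centre_x = cc[3] - 1, centre_y = cc[2] - 1,
                        centre_z = cc[1] - 1,
                        volume = V, territory_voxels = ntv,
                        achieved_fraction = ntv / V)
    for (k in seq_len(K)) truth[[paste0("f", k)]] <- true_frac[k]
    list(stack = stack, truth = truth,
         mask = aperm(mask, c(2, 3, 1)),
         territory = aperm(terr, c(2, 3, 1)))
  })
}

# Ellipsoid mask over a (z, y, x) grid with the 2D angular roughness
# applied to the xy radius at every slice (keeps the shape z-symmetric).
blob_mask_3d <- function(dims_zyx, semi_axes_um, spacing_yxz, roughness) {
  eps <- if (roughness > 0) roughness * runif(3, 0.5, 1) else numeric(3)
  phi <- runif(3, 0, 2 * pi)
  cz <- (dims_zyx[1] + 1) / 2
  cy <- (dims_zyx[2] + 1) / 2
  cx <- (dims_zyx[3] + 1) / 2
  zc <- (seq_len(dims_zyx[1]) - cz) * spacing_yxz[3]
  yc <- (seq_len(dims_zyx[2]) - cy) * spacing_yxz[1]
  xc <- (seq_len(dims_zyx[3]) - cx) * spacing_yxz[2]
  ax <- semi_axes_um[1]; ay <- semi_axes_um[2]; az <- semi_axes_um[3]
  mask <- array(FALSE, dims_zyx)
  for (zi in seq_along(zc)) {
    u <- matrix(xc / ax, length(yc), length(xc), byrow = TRUE)
    v <- matrix(yc / ay, length(yc), length(xc))
    th <- atan2(v, u)
    rho <- 1
    for (m in 1:3) rho <- rho + eps[m] * cos((m + 1) * th + phi[m])
    mask[zi, , ] <- (u^2 + v^2) <= pmax(rho^2 - (zc[zi] / az)^2, 0)
  }
  mask
}

# spz is the voxel spacing in (z, y, x) order, matching the mask layout.
nucleolar_dapi_3d <- function(mask, config, spz) {
  dapi <- ifelse(mask, 0.7, 0.02)
  nuc <- config$nucleoli
  if (nuc$count > 0) {
    dist <- distance_transform(mask, spz)
    r_um <- nuc$radius * config$pixel_size_xy
    cand <- which(mask & dist > r_um + max(spz))
    if (length(cand) > 0) {
      picks <- arrayInd(sample(cand, min(nuc$count, length(cand))),
                        dim(mask))
      ij <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
      for (r in seq_len(nrow(picks))) {
        dd <- ((ij[, 1] - picks[r, 1]) * spz[1])^2 +
              ((ij[, 2] - picks[r, 2]) * spz[2])^2 +
              ((ij[, 3] - picks[r, 3]) * spz[3])^2
        inside <- array(dd <= r_um^2, dim(mask)) & mask
        dapi[inside] <- dapi[inside] * (1 - nuc$intensity_dip)
      }
    }
  }
  dapi
}

#' Fast spot-placement cohort on a shared nucleus geometry
#'
#' Draws `n` independent spot placements on a single simulated nucleus and
#' returns their ground-truth shells, for calibration and power studies
#' where per-cell nuclear shape variation is irrelevant. The per-spot
#' area-ranks follow the configured placement model.
#'
#' @param config a [sim_config()].
#' @param n number of spots (cells).
#' @param mask optional logical mask to place spots on (defaults to a
#'   freshly simulated noiseless nucleus mask).
#' @return data.frame with `cell_id`, `u`, `true_shell`, `spot_x`,
#'   `spot_y`; the mask used is attached as attribute `"mask"`.
#' @export
simulate_spot_cohort <- function(config, n = config$n_cells, mask = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(cell_seed(config$seed, 0L) + 5e5, {
    if (is.null(mask)) {
      mask <- blob_mask_2d(config$img_size, config$nucleus$semi_axes,
                           config$nucleus$roughness)$mask
    }
    K <- config$n_shells_2d
    u <- vapply(seq_len(n), function(i) draw_spot_rank(config$spot, K),
                numeric(1))
    lin <- pixels_at_area_rank(mask, u)
    part <- shell_partition_core(mask, K, c(1, 1))
    ij <- arrayInd(lin, dim(mask))
    out <- data.frame(cell_id = seq_len(n), u = u,
                      true_shell = as.integer(part$labels[lin]),
                      spot_x = ij[, 2] - 1L, spot_y = ij[, 1] - 1L)
    attr(out, "mask") <- mask
    out
  })
}

#' Write a synthetic fixture set to disk
#'
#' One multi-channel 16-bit TIFF per cell (channel 0 = nuclear stain,
#' channel 1 = signal; pages channel-major), a ground-truth manifest CSV,
#' and the generating configuration as YAML. Intensities are quantized to
#' the 16-bit grid before writing, so the files round-trip losslessly
#' through [read_fixture_set()].
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param mode `"spots2d"` (default) or `"paint3d"`.
#' @return path to the manifest CSV, invisibly.
#' @export
write_fixture_set <- function(config, out_dir,
                              mode = c("spots2d", "paint3d")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    sim <- if (mode == "spots2d") simulate_nucleus_2d(config, i)
           else simulate_territory_3d(config, i)
    f <- file.path(out_dir, sprintf("cell_%04d.tif", i))
    write_image_stack(sim$stack, f)
    row <- sim$truth
    row$file <- basename(f)
    row$n_z <- dim(sim$stack$data)[3]
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  cfg <- unclass(config)
  cfg$mode <- mode
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(manifest_path)
}

#' Read back a fixture set written by [write_fixture_set()]
#'
#' @param dir fixture directory.
#' @return list with `config` (a `sim_config`), `manifest` (data.frame),
#'   and `stacks` (list of [image_stack]s in manifest order).
#' @export
read_fixture_set <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  mode <- cfg$mode
  cfg$mode <- NULL
  config <- do.call(sim_config, cfg)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  roles <- if (identical(mode, "paint3d")) c("nuclear_stain", "territory")
           else c("nuclear_stain", "spot")
  stacks <- lapply(seq_len(nrow(manifest)), function(i)
    read_image_stack(file.path(dir, manifest$file[i]), roles,
                     n_z = manifest$n_z[i],
                     pixel_size_xy = config$pixel_size_xy,
                     z_step = config$z_step))
  list(config = config, manifest = manifest, stacks = stacks, mode = mode)
}
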