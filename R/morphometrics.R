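#' Nuclear midplane morphometrics
#'
#' Size and shape descriptors used to check that a treatment does not act
#' indirectly through gross nuclear deformation: midplane area, the longest
#' distance across the midplane (maximum Feret diameter, i.e. the maximum
#' pairwise distance between boundary pixel centres) and the shortest
#' width (minimum Feret diameter, scanned over rotations in 1 degree
#' steps).
#'
#' @param mask logical `(y, x)` midplane mask or a `nuclear_mask`.
#' @param pixel_size_xy pixel size in micrometres (taken from a
#'   `nuclear_mask` when available).
#' @param angle_step rotation step in degrees for the minimum Feret scan.
#' @return list with `area` (um^2), `longest` (um), `shortest` (um).
#' @export
nucleus_morphometrics <- function(mask, pixel_size_xy = NULL,
                                  angle_step = 1) {
  if (inherits(mask, "nuclear_mask")) {
    if (is.null(pixel_size_xy)) pixel_size_xy <- mask$pixel_size_xy
    mask <- midplane_mask(mask)
  }
  if (is.null(pixel_size_xy)) pixel_size_xy <- 1
  stopifnot(is.logical(mask), length(dim(mask)) == 2L)
  A <- sum(mask)
  if (A == 0L) stop("empty mask")
  bnd <- boundary_pixels(mask)
  # convex hull suffices for both Feret extremes
  hull <- bnd[grDevices::chull(bnd[, 1], bnd[, 2]), , drop = FALSE]
  n <- nrow(hull)
  longest <- if (n == 1L) 0 else {
    dd <- as.matrix(stats::dist(hull))
    max(dd)
  }
  th <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  proj <- outer(hull[, 1], cos(th)) + outer(hull[, 2], sin(th))
  widths <- apply(proj, 2, function(p) max(p) - min(p))
  # extents are centre-to-centre distances between boundary pixels
  list(area = A * pixel_size_xy^2,
       longest = longest * pixel_size_xy,
       shortest = min(widths) * pixel_size_xy)
}

# (x, y) 0-based centre coordinates of mask pixels with a 4-neighbour
# outside the mask (or on the array border).
boundary_pixels <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
        pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  ij <- which(core & !nb, arr.ind = TRUE)
  cbind(x = ij[, 2] - 1, y = ij[, 1] - 1)
}
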