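#' Multi-channel image stack
#'
#' Container for a single-cell fluorescence image: one or more channels over
#' a common `(y, x, z)` grid (z-extent 1 for a 2D midplane image). Each
#' channel carries a role: `"nuclear_stain"` (DNA counterstain used for
#' segmentation), `"spot"` (a point-like tagged locus) or `"territory"`
#' (an extended chromosome paint).
#'
#' @param channels list of numeric arrays, each `(y, x)` or `(y, x, z)`,
#'   identical dimensions, non-negative intensities.
#' @param channel_roles character vector, one role per channel; at least one
#'   `"nuclear_stain"` required.
#' @param pixel_size_xy lateral pixel size in micrometres.
#' @param z_step axial step between z-slices in micrometres.
#' @return an object of class `image_stack` with fields `data`
#'   (`(y, x, z, channel)` array), `channel_roles`, `pixel_size_xy`,
#'   `z_step`.
#' @export
image_stack <- function(channels, channel_roles,
                        pixel_size_xy = 0.1, z_step = 0.2) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("channels must be a non-empty list of arrays")
  dims <- lapply(channels, function(ch) {
    d <- dim(ch)
    if (is.null(d) || !(length(d) %in% c(2L, 3L)))
      stop("each channel must be a 2-d or 3-d array")
    if (length(d) == 2L) c(d, 1L) else d
  })
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all channels must share dimensions")
  if (any(d0[1:2] < 16L)) stop("spatial extents must be at least 16 px")
  if (length(channel_roles) != length(channels))
    stop("one role per channel required")
  roles <- as.character(channel_roles)
  ok <- roles %in% c("nuclear_stain", "spot", "territory")
  if (!all(ok))
    stop("unknown channel role(s): ", paste(roles[!ok], collapse = ", "))
  if (!"nuclear_stain" %in% roles)
    stop("at least one channel must have role 'nuclear_stain'")
  if (pixel_size_xy <= 0 || z_step <= 0)
    stop("pixel_size_xy and z_step must be positive")
  data <- array(0, c(d0, length(channels)))
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    if (any(ch < 0)) stop("intensities must be non-negative")
    data[, , , i] <- ch
  }
  structure(
    list(data = data, channel_roles = roles,
         pixel_size_xy = pixel_size_xy, z_step = z_step),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d px, %d z-slice(s), channels [%s]\n",
              d[2], d[1], d[3], paste(x$channel_roles, collapse = ", ")))
  cat(sprintf("  pixel %.3g um, z-step %.3g um\n",
              x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' Extract one channel of an image stack by role
#'
#' @param stack an [image_stack].
#' @param role channel role to extract; the first matching channel is
#'   returned.
#' @return numeric `(y, x, z)` array (z-extent 1 for 2D images).
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(role, stack$channel_roles)
  if (is.na(i)) stop(sprintf("no channel with role '%s'", role))
  ch <- stack$data[, , , i, drop = FALSE]
  dim(ch) <- dim(stack$data)[1:3]
  ch
}

#' Physical voxel spacing of a stack in `(y, x, z)` order
#' @param stack an [image_stack] or any object with `pixel_size_xy`/`z_step`.
#' @return numeric length-3 vector of micrometre spacings.
#' @export
voxel_spacing <- function(stack) {
  c(stack$pixel_size_xy, stack$pixel_size_xy, stack$z_step)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are ordered channel-major: all z-slices of channel 1, then all
#' z-slices of channel 2, and so on. Intensities must lie in `[0, 1]` and
#' are stored as 16-bit samples, so values quantized to the 16-bit grid
#' (`k / 65535`) round-trip exactly.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (max(stack$data) > 1 + 1e-12)
    stop("intensities must be within [0, 1] for 16-bit TIFF export")
  pages <- vector("list", d[3] * d[4])
  k <- 0L
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- stack$data[, , z, ch]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF file path.
#' @param channel_roles roles of the stored channels, in storage order.
#' @param n_z number of z-slices per channel (total pages must equal
#'   `n_z * length(channel_roles)`).
#' @param pixel_size_xy,z_step physical calibration to attach.
#' @return an [image_stack].
#' @export
read_image_stack <- function(path, channel_roles, n_z = NULL,
                             pixel_size_xy = 0.1, z_step = 0.2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channel_roles)
  if (is.null(n_z)) n_z <- length(pages) / nc
  if (n_z != round(n_z) || length(pages) != n_z * nc)
    stop("page count does not match channel_roles/n_z")
  n_z <- as.integer(n_z)
  channels <- vector("list", nc)
  for (ch in seq_len(nc)) {
    vol <- array(0, c(dim(pages[[1]]), n_z))
    for (z in seq_len(n_z)) vol[, , z] <- pages[[(ch - 1L) * n_z + z]]
    channels[[ch]] <- vol
  }
  image_stack(channels, channel_roles, pixel_size_xy, z_step)
}
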