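#' Interior Euclidean distance transform
#'
#' Distance from every foreground pixel/voxel to the nearest background
#' location, in physical units. The array border counts as background, so a
#' mask touching the image edge is treated as cut there. Computed exactly by
#' separable lower-envelope passes; anisotropic voxels (e.g. confocal z-steps
#' coarser than the xy pixel pitch) are handled through `spacing`.
#'
#' @param mask logical matrix `(y, x)` or 3-d array `(y, x, z)`; `TRUE` =
#'   foreground.
#' @param spacing numeric vector of per-axis sample spacings in the same
#'   order as `dim(mask)` (i.e. `(y, x)` or `(y, x, z)`). Defaults to 1 per
#'   axis (pixel units).
#' @return numeric array of `dim(mask)`: 0 on background, the Euclidean
#'   distance to the nearest background elsewhere.
#' @examples
#' m <- matrix(FALSE, 21, 21); m[6:16, 6:16] <- TRUE
#' d <- distance_transform(m)
#' d[11, 11] # centre of an 11x11 square: 5.5 px to the outside
#' @export
distance_transform <- function(mask, spacing = rep(1, length(dim(mask)))) {
  dm <- dim(mask)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)))
    stop("mask must be a 2-d matrix or 3-d array")
  if (length(spacing) != length(dm) || any(spacing <= 0))
    stop("spacing must be positive, one value per mask dimension")
  storage.mode(mask) <- "logical"
  # pad with one background layer so the border acts as background
  pd <- dm + 2L
  padded <- array(FALSE, pd)
  if (length(dm) == 2L) padded[2:(dm[1] + 1L), 2:(dm[2] + 1L)] <- mask
  else padded[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- mask
  d2 <- .edt_sq_cpp(as.logical(padded), as.integer(pd), as.numeric(spacing))
  dim(d2) <- pd
  d <- if (length(dm) == 2L) d2[2:(dm[1] + 1L), 2:(dm[2] + 1L)]
       else d2[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)]
  dim(d) <- dm
  sqrt(d)
}
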