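#' Segment the nucleus from the DNA counterstain channel
#'
#' Each z-slice is thresholded automatically (Otsu on the slice rescaled to
#' its own intensity range, so segmentation is invariant to overall
#' intensity scaling), the largest connected foreground component across the
#' volume is kept, and holes are filled slice-wise so weakly stained
#' interior regions such as nucleoli are not excluded from the nuclear area.
#'
#' @param stack an [image_stack] with a `nuclear_stain` channel.
#' @param threshold optional manual threshold (absolute intensity) applied
#'   to every slice instead of the automatic one.
#' @return an object of class `nuclear_mask`: list with `mask` (logical
#'   `(y, x, z)` array), `pixel_size_xy`, `z_step`, and the per-slice
#'   thresholds used (`thresholds`).
#' @export
segment_nucleus <- function(stack, threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  vol <- get_channel(stack, "nuclear_stain")
  d <- dim(vol)
  fg <- array(FALSE, d)
  thr_used <- rep(NA_real_, d[3])
  for (z in seq_len(d[3])) {
    plane <- vol[, , z]
    mx <- max(plane)
    if (mx <= 0) next
    if (mx - min(plane) < 1e-9) next  # contrast-free slice: no nucleus
    if (is.null(threshold)) {
      thr <- EBImage::otsu(EBImage::Image(plane / mx), range = c(0, 1)) * mx
    } else thr <- threshold
    thr_used[z] <- thr
    fg[, , z] <- plane > thr
  }
  if (!any(fg)) stop("no nucleus detected")
  lab <- label_components_3d(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- lab == keep
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    if (any(sl)) mask[, , z] <- EBImage::fillHull(sl) > 0
  }
  structure(
    list(mask = mask, pixel_size_xy = stack$pixel_size_xy,
         z_step = stack$z_step, thresholds = thr_used),
    class = "nuclear_mask")
}

#' @export
print.nuclear_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("nuclear_mask: %d x %d px, %d z-slice(s), %d fg voxels\n",
              d[2], d[1], d[3], sum(x$mask)))
  invisible(x)
}

# Label connected components of a (y, x, z) logical array: 8-connectivity
# in-plane (EBImage::bwlabel), face adjacency between consecutive slices,
# merged with union-find.
label_components_3d <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  offset <- 0L
  nlab <- integer(d[3])
  for (z in seq_len(d[3])) {
    if (any(fg[, , z])) {
      l <- EBImage::bwlabel(fg[, , z])
      nlab[z] <- max(l)
      lz <- as.integer(l)
      lz[lz > 0L] <- lz[lz > 0L] + offset
      lab[, , z] <- lz
      offset <- offset + nlab[z]
    }
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (d[3] > 1L) for (z in seq_len(d[3] - 1L)) {
    a <- lab[, , z]; b <- lab[, , z + 1L]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relabel[lab[pos]]
  lab
}

#' Select the nuclear midplane
#'
#' The midplane is the z-slice at which the nuclear cross-section is widest
#' (maximum foreground area); ties are broken towards the lower index.
#'
#' @param mask a `nuclear_mask`.
#' @return 0-based z-index of the midplane slice.
#' @export
select_midplane <- function(mask) {
  stopifnot(inherits(mask, "nuclear_mask"))
  areas <- apply(mask$mask, 3, sum)
  if (all(areas == 0)) stop("empty mask")
  which.max(areas) - 1L
}

#' Extract the midplane slice of a nuclear mask
#' @param mask a `nuclear_mask`.
#' @param z 0-based z-index; defaults to [select_midplane()].
#' @return logical `(y, x)` matrix.
#' @export
midplane_mask <- function(mask, z = select_midplane(mask)) {
  mask$mask[, , z + 1L]
}

#' Detect the tagged-locus spot in a cell
#'
#' The spot channel is thresholded automatically (Otsu) inside the nuclear
#' mask; among the above-threshold connected components the one with the
#' highest peak intensity is taken (one integrated array per cell), and its
#' intensity-weighted centroid is returned in 0-based pixel-centre
#' coordinates.
#'
#' @param stack an [image_stack] with a `spot` channel.
#' @param mask the cell's `nuclear_mask`.
#' @param threshold optional manual absolute threshold.
#' @return an object of class `spot_record`: list with `x`, `y`, `z`
#'   (0-based, pixel-centre), `peak`, `shell` (`NA` until assigned),
#'   `cell_id` (`NA` until set by the caller).
#' @export
detect_spot <- function(stack, mask, threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "nuclear_mask"))
  vol <- get_channel(stack, "spot")
  mx <- max(vol)
  if (mx <= 0) stop("no spot")
  thr <- if (is.null(threshold))
    EBImage::otsu(EBImage::Image(vol / mx), range = c(0, 1)) * mx
  else threshold
  fg <- vol > thr & mask$mask
  if (!any(fg)) stop("no spot")
  lab <- label_components_3d(fg)
  ncomp <- max(lab)
  peaks <- vapply(seq_len(ncomp), function(i) max(vol[lab == i]), numeric(1))
  best <- which.max(peaks)
  idx <- which(lab == best)
  d <- dim(vol)
  coord <- arrayInd(idx, d)
  w <- vol[idx]
  structure(
    list(cell_id = NA_integer_,
         x = sum(w * (coord[, 2] - 1)) / sum(w),
         y = sum(w * (coord[, 1] - 1)) / sum(w),
         z = sum(w * (coord[, 3] - 1)) / sum(w),
         peak = peaks[best], threshold = thr, shell = NA_integer_),
    class = "spot_record")
}

#' @export
print.spot_record <- function(x, ...) {
  cat(sprintf(
    "spot_record: centre (%.2f, %.2f, %.2f), peak %.3g, shell %s\n",
    x$x, x$y, x$z, x$peak,
    ifelse(is.na(x$shell), "unassigned", x$shell)))
  invisible(x)
}

#' Midplane gate for 2D spot scoring
#'
#' Cells are scored in 2D only when the spot lies at (or within
#' `tol_slices` of) the nuclear midplane, which avoids axial-position errors
#' for loci near the top or bottom of the nucleus.
#'
#' @param spot a `spot_record`.
#' @param midplane_z 0-based midplane z-index.
#' @param tol_slices tolerance in slices (default 1; `Inf` disables the
#'   gate).
#' @return `TRUE` if the cell passes the gate.
#' @export
midplane_gate <- function(spot, midplane_z, tol_slices = 1) {
  stopifnot(inherits(spot, "spot_record"))
  abs(spot$z - midplane_z) <= tol_slices
}
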