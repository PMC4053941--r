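# Geometric fixtures and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the package's own distance
# transform and partition code paths.

disc_mask <- function(R, size = 2L * R + 21L) {
  ctr <- (size + 1) / 2
  m <- matrix(FALSE, size, size)
  (row(m) - ctr)^2 + (col(m) - ctr)^2 <= R^2
}

ellipse_mask <- function(a, b, size = 2L * max(a, b) + 21L) {
  ctr <- (size + 1) / 2
  m <- matrix(FALSE, size, size)
  ((col(m) - ctr) / a)^2 + ((row(m) - ctr) / b)^2 <= 1
}

ball_mask <- function(R, size = 2L * R + 9L) {
  ctr <- (size + 1) / 2
  g2 <- (seq_len(size) - ctr)^2
  arr <- outer(outer(g2, g2, "+"), g2, "+")
  array(arr <= R^2, rep(size, 3L))
}

# irregular but smooth 2D blob: ellipse radius modulated by low-frequency
# harmonics (independent reimplementation, not the package generator)
random_blob_mask <- function(seed, size = 141L, r0 = 58, ecc = 0.8,
                             rough = 0.12) {
  set.seed(seed)
  ctr <- (size + 1) / 2
  a <- r0
  b <- r0 * runif(1, ecc, 1)
  eps <- rough * runif(3, 0.3, 1)
  phi <- runif(3, 0, 2 * pi)
  m <- matrix(FALSE, size, size)
  u <- (col(m) - ctr) / a
  v <- (row(m) - ctr) / b
  th <- atan2(v, u)
  rho <- 1 + eps[1] * cos(2 * th + phi[1]) + eps[2] * cos(3 * th + phi[2]) +
    eps[3] * cos(4 * th + phi[3])
  u^2 + v^2 <= rho^2
}

random_blob_volume <- function(seed, dims = c(44L, 44L, 16L), rough = 0.1) {
  set.seed(seed)
  a <- dims[2] * 0.40; b <- dims[1] * 0.40; cz <- dims[3] * 0.42
  eps <- rough * runif(3, 0.3, 1)
  phi <- runif(3, 0, 2 * pi)
  ctr <- (dims + 1) / 2
  vol <- array(FALSE, dims)
  m <- matrix(0, dims[1], dims[2])
  u <- (col(m) - ctr[2]) / a
  v <- (row(m) - ctr[1]) / b
  th <- atan2(v, u)
  rho <- 1 + eps[1] * cos(2 * th + phi[1]) + eps[2] * cos(3 * th + phi[2]) +
    eps[3] * cos(4 * th + phi[3])
  for (z in seq_len(dims[3])) {
    zz <- ((z - ctr[3]) / cz)^2
    vol[, , z] <- u^2 + v^2 <= pmax(rho^2 - zz, 0)
  }
  vol
}

# shift a logical array by `by` along `axis`, padding with FALSE
shift_logical <- function(x, axis, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[matrix_index(dst, d)] <- x[matrix_index(src, d)]
  out
}
matrix_index <- function(idx, d) {
  # build a logical index array selecting the hyper-rectangle
  sel <- array(FALSE, d)
  if (length(d) == 2L) sel[idx[[1]], idx[[2]]] <- TRUE
  else sel[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  sel
}

# Exact brute-force squared EDT: distance of each foreground voxel to the
# nearest background voxel (array border counts as background). Exploits
# the fact that the nearest background voxel is always box-adjacent to the
# foreground, so only interface voxels need scanning.
oracle_edt_sq <- function(mask, spacing = rep(1, length(dim(mask)))) {
  d <- dim(mask)
  nd <- length(d)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  if (nd == 2L) pm[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  else pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  dil <- pm
  for (ax in seq_len(nd))
    dil <- dil | shift_logical(dil, ax, 1L) | shift_logical(dil, ax, -1L)
  interface <- dil & !pm
  B <- which(interface, arr.ind = TRUE)
  Fg <- which(pm, arr.ind = TRUE)
  out <- array(0, pd)
  fgidx <- which(pm)
  chunk <- max(1L, floor(4e6 / nrow(B)))
  for (s in seq(1L, nrow(Fg), by = chunk)) {
    e <- min(nrow(Fg), s + chunk - 1L)
    acc <- 0
    for (k in seq_len(nd)) {
      dk <- outer(Fg[s:e, k], B[, k], "-") * spacing[k]
      acc <- acc + dk * dk
    }
    mins <- acc[cbind(seq_len(nrow(acc)),
                      max.col(-acc, ties.method = "first"))]
    out[fgidx[s:e]] <- mins
  }
  if (nd == 2L) out[2:(d[1] + 1L), 2:(d[2] + 1L)]
  else out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

# Brute-force distance-sort quantile partition: sort all in-mask squared
# distances ascending (ties by raster order) and split into K blocks of
# ceiling(A/K) (last block takes the remainder).
oracle_partition_labels <- function(mask, K,
                                    spacing = rep(1, length(dim(mask)))) {
  sp <- spacing / min(spacing)
  d2 <- oracle_edt_sq(mask, sp)
  idx <- which(mask)
  A <- length(idx)
  ord <- order(d2[idx], seq_len(A))
  s <- as.integer(ceiling(A / K))
  sizes <- c(rep(s, K - 1L), A - (K - 1L) * s)
  labels <- array(0L, dim(mask))
  labels[idx[ord]] <- rep.int(seq_len(K), sizes)
  labels
}

# Exhaustive two-sample KS permutation oracle: over all label assignments,
# the fraction with D >= observed D.
oracle_ks_perm_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  Dobs <- oracle_ks_D(x, y)
  combs <- utils::combn(n1 + n2, n1)
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    xi <- pool[combs[, j]]
    yi <- pool[-combs[, j]]
    if (oracle_ks_D(xi, yi) >= Dobs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combs)
}
oracle_ks_D <- function(x, y) {
  pts <- sort(c(x, y))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# closed-form 2x2 chi-squared
oracle_chi2_stat <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  N * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}
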