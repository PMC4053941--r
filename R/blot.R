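#' Band-intensity table for tissue western blots
#'
#' Integrated band intensities (equal-size box per band) for a set of
#' proteins across tissues, used to quantify tissue restriction of
#' expression.
#'
#' @param intensities numeric matrix, proteins in rows, tissues in
#'   columns; non-negative, at least one protein and two tissues.
#' @param proteins,tissues optional row/column names.
#' @return a `band_table` (the matrix with validated dimnames).
#' @export
band_table <- function(intensities, proteins = rownames(intensities),
                       tissues = colnames(intensities)) {
  m <- as.matrix(intensities)
  if (nrow(m) < 1L || ncol(m) < 2L)
    stop("need at least 1 protein and 2 tissues")
  if (any(m < 0)) stop("intensities must be non-negative")
  if (is.null(proteins)) proteins <- paste0("protein", seq_len(nrow(m)))
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(ncol(m)))
  dimnames(m) <- list(proteins, tissues)
  class(m) <- c("band_table", class(m))
  m
}

#' Read a band-intensity CSV (first column protein, header tissues)
#' @param path CSV file path.
#' @param background optional name of a per-lane background column to
#'   subtract (clipped at zero) and drop.
#' @return a `band_table`.
#' @export
read_band_table <- function(path, background = NULL) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.null(background)) {
    if (!background %in% colnames(m)) stop("background column not found")
    m <- pmax(m - m[, background], 0)
    m <- m[, setdiff(colnames(m), background), drop = FALSE]
  }
  band_table(m)
}

#' Per-tissue percentage of summed band signal
#'
#' For each protein the intensities are summed over all tissues and each
#' tissue's signal expressed as a percentage of that sum, so a protein
#' expressed evenly across 11 tissues scores ~9% everywhere while a
#' liver-restricted one concentrates most of its signal in the liver lane.
#'
#' @param table a [band_table()] (or plain matrix).
#' @return matrix of percentages, rows summing to 100. Full precision is
#'   retained; round to integers for display.
#' @export
tissue_percentages <- function(table) {
  m <- unclass(as.matrix(table))
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("all-zero protein row")
  sweep(m, 1, rs, "/") * 100
}

#' Fold-ratio of expression between two tissues
#'
#' @param percent_row named numeric vector (one row of
#'   [tissue_percentages()]).
#' @param tissue_a,tissue_b tissue names or indices; the result is
#'   `percent[a] / percent[b]`.
#' @return fold change (dimensionless).
#' @export
tissue_fold_ratio <- function(percent_row, tissue_a, tissue_b) {
  a <- percent_row[[tissue_a]]
  b <- percent_row[[tissue_b]]
  if (is.na(a) || is.na(b)) stop("unknown tissue")
  if (b <= 0) stop("undefined fold")
  a / b
}
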