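#' Stringency classification of a p-value
#'
#' The screen reports raw p-values against two fixed thresholds:
#' `"high"` stringency for p < 0.01 (rendered `**`), `"low"` for
#' 0.01 <= p < 0.05 (`*`), `"ns"` otherwise. No multiple-testing
#' correction is applied.
#'
#' @param p p-value in \\[0, 1\\].
#' @return one of `"high"`, `"low"`, `"ns"`.
#' @export
classify_stringency <- function(p) {
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]")
  if (p < 0.01) "high" else if (p < 0.05) "low" else "ns"
}

test_result <- function(test, statistic, p, direction, n, extra = list()) {
  structure(
    c(list(test = test, statistic = statistic, p_value = p,
           stringency = classify_stringency(p), direction = direction,
           n = n), extra),
    class = "nucshell_test")
}

#' @export
print.nucshell_test <- function(x, ...) {
  star <- switch(x$stringency, high = "**", low = "*", "")
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s (%s, %s)\n",
              x$test, x$statistic, x$p_value, star, x$stringency,
              x$direction))
  invisible(x)
}

#' One-tailed chi-squared test on peripheral vs internal locus counts
#'
#' Compares the number of tagged loci in the outermost shell (shell 1)
#' against the combined internal shells (3+4+5) between a test condition
#' and a control, as a 2x2 contingency table; shell 2 is excluded by
#' definition. The statistic is the 1-df chi-squared without continuity
#' correction; the one-tailed p-value halves the upper tail when the test
#' cohort's shell-1 proportion exceeds the control's and is its complement
#' otherwise (so an exactly null table gives p = 0.5).
#'
#' @param counts_test,counts_control non-negative integer per-shell counts
#'   (length K >= 5, shell 1 first).
#' @param two_sided report the conventional two-sided p instead.
#' @param correct apply the Yates continuity correction.
#' @return a `nucshell_test` with fields `statistic`, `p_value`,
#'   `stringency`, `direction` (`"peripheral_gain"` when the test cohort is
#'   more peripheral), `n`, and the underlying `table`.
#' @export
chi2_shell_test <- function(counts_test, counts_control,
                            two_sided = FALSE, correct = FALSE) {
  check_counts <- function(x) {
    if (length(x) < 5L || any(x < 0) || any(x != round(x)))
      stop("per-shell counts must be non-negative integers, K >= 5")
  }
  check_counts(counts_test); check_counts(counts_control)
  a <- counts_test[1L];    b <- sum(counts_test[3:5])
  c_ <- counts_control[1L]; d <- sum(counts_control[3:5])
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(c("shell1", "shells3to5"),
                                c("test", "control")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table")
  N <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - N / 2)
  stat <- N * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  p_test <- a / (a + b)
  p_ctrl <- c_ / (c_ + d)
  tail <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (two_sided) {
    p <- tail
  } else {
    p <- if (p_test > p_ctrl) tail / 2 else 1 - tail / 2
  }
  direction <- if (p_test > p_ctrl) "peripheral_gain"
               else if (p_test < p_ctrl) "peripheral_loss" else "none"
  test_result("chi2_shell", stat, p, direction,
              n = c(test = sum(counts_test), control = sum(counts_control)),
              extra = list(table = tab, two_sided = two_sided))
}

#' Two-sample Kolmogorov-Smirnov test on peripheral intensity fractions
#'
#' Territories span several shells, so conditions are compared on the
#' distribution of per-cell peripheral fractions (signal in shells 1+2).
#' D is the supremum distance between the two empirical CDFs. For small
#' tie-free cohorts (`min(n1, n2) <= exact_max`) the p-value is exact,
#' computed by counting lattice paths that keep the ECDF difference below
#' the observed D; otherwise the asymptotic Kolmogorov distribution is
#' used with effective size `n1 n2 / (n1 + n2)`.
#'
#' @param profiles_test,profiles_control numeric vectors of per-cell
#'   peripheral fractions, or lists of `shell_profile`s (their
#'   `peripheral_sum` is used).
#' @param exact_max largest `min(n1, n2)` for which the exact p is used
#'   (default 10).
#' @return a `nucshell_test`; `direction` is `"peripheral_gain"` when the
#'   test cohort's mean peripheral fraction exceeds the control's.
#' @export
ks_peripheral_test <- function(profiles_test, profiles_control,
                               exact_max = 10L) {
  as_vals <- function(x) {
    if (is.list(x) && length(x) && inherits(x[[1]], "shell_profile"))
      vapply(x, function(p) p$peripheral_sum, numeric(1))
    else as.numeric(x)
  }
  x <- as_vals(profiles_test)
  y <- as_vals(profiles_control)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3L || n2 < 3L) stop("insufficient cells")
  D <- ks_statistic(x, y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (D == 0) {
    p <- 1
    method <- "degenerate"
  } else if (min(n1, n2) <= exact_max && !ties) {
    p <- ks_exact_p(D, n1, n2)
    method <- "exact"
  } else {
    if (ties && min(n1, n2) <= exact_max)
      warning("ties present; using asymptotic p-value")
    n_eff <- n1 * n2 / (n1 + n2)
    p <- ks_asymptotic_p(sqrt(n_eff) * D)
    method <- "asymptotic"
  }
  direction <- if (mean(x) > mean(y)) "peripheral_gain"
               else if (mean(x) < mean(y)) "peripheral_loss" else "none"
  test_result("ks_peripheral", D, p, direction,
              n = c(test = n1, control = n2),
              extra = list(method = method))
}

# sup |ECDF1 - ECDF2| evaluated over the pooled sample points.
ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  e1 <- vapply(pts, function(t) mean(x <= t), numeric(1))
  e2 <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(e1 - e2))
}

# Exact two-sample KS p-value for tie-free data: the fraction of the
# choose(n1+n2, n1) equally likely orderings whose ECDF difference ever
# reaches D. Counted by the standard lattice-path recursion: paths from
# (0,0) to (n1,n2) with all intermediate |i/n1 - j/n2| < D realize D_perm
# < D, so p = 1 - (#such paths)/choose(n1+n2, n1).
ks_exact_p <- function(D, n1, n2, tol = 1e-9) {
  u <- matrix(0, n1 + 1L, n2 + 1L)
  inside <- function(i, j) abs(i / n1 - j / n2) < D - tol
  u[1, 1] <- 1
  for (i in 0:n1) for (j in 0:n2) {
    if (i == 0L && j == 0L) next
    if (!inside(i, j) && !(i == n1 && j == n2)) { u[i + 1L, j + 1L] <- 0; next }
    acc <- 0
    if (i > 0L) acc <- acc + u[i, j + 1L]
    if (j > 0L) acc <- acc + u[i + 1L, j]
    u[i + 1L, j + 1L] <- acc
  }
  1 - u[n1 + 1L, n2 + 1L] / choose(n1 + n2, n1)
}

# Asymptotic Kolmogorov survival function Q(lambda).
ks_asymptotic_p <- function(lambda, terms = 100L) {
  if (lambda < 1e-8) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Mean and standard deviation across replicate experiments
#'
#' Cohort summaries are reported as the mean of per-experiment means with
#' the sample (n-1) standard deviation between them (the error bars of the
#' replicate analyses).
#'
#' @param per_experiment_means numeric vector of per-experiment means
#'   (length >= 2).
#' @return list with `mean` and `sd`.
#' @export
replicate_summary <- function(per_experiment_means) {
  x <- as.numeric(per_experiment_means)
  if (length(x) < 2L) stop("need at least 2 experiment means")
  list(mean = mean(x), sd = sd(x))
}
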