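# Sample entropy baseline and gait preprocessing.

#' Sample entropy of a scalar series
#'
#' Counts pairs of delayed templates of length `m` (and `m + 1`) whose
#' Chebyshev distance is at most `delta`, self-matches excluded, and returns
#' `-log(A / B)` where `B` and `A` are the match counts at lengths `m` and
#' `m + 1`. Both counts run over the same template start indices
#' `1 .. N - m * tau`, so every `(m + 1)`-match is also an `m`-match and the
#' value is nonnegative. When no `(m + 1)`-templates match (`A = 0`) the value
#' is `Inf`, reported explicitly.
#'
#' @param series numeric vector.
#' @param m template length (positive integer, default 2).
#' @param tau delay between template samples (default 1, the classical form).
#' @param delta match tolerance; defaults to `delta_factor * sd(series)`.
#' @param delta_factor multiplier on the per-series standard deviation
#'   (`n - 1` denominator) used when `delta` is not given. Default 0.2.
#' @param normalize if `TRUE`, z-normalize the series first (then `sd = 1`).
#' @return Object of class `sampen`: list with `value` (finite `>= 0` or
#'   `Inf`), match counts `A` and `B`, and the `delta` used.
#' @examples
#' sample_entropy(rep(1, 30), m = 2, delta = 0.1)$value  # 0: fully regular
#' @export
sample_entropy <- function(series, m = 2L, tau = 1L, delta = NULL,
                           delta_factor = 0.2, normalize = FALSE) {
  assert_series(series)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L) stop("template length m must be >= 1", call. = FALSE)
  if (tau < 1L) stop("delay tau must be >= 1", call. = FALSE)
  if (normalize) {
    s <- stats::sd(series)
    series <- if (s > 0) (series - mean(series)) / s else series - mean(series)
  }
  if (is.null(delta)) {
    if (delta_factor <= 0) stop("delta_factor must be > 0", call. = FALSE)
    delta <- delta_factor * stats::sd(series)
  }
  if (!is.finite(delta) || delta <= 0)
    stop("match tolerance delta must be > 0 ",
         "(constant series need an explicit delta)", call. = FALSE)
  n <- length(series)
  nt <- n - m * tau                    # number of (m+1)-templates
  if (nt < 2L)
    stop(sprintf("series too short for SampEn with (m = %d, tau = %d): need N >= %d",
                 m, tau, m * tau + 2L), call. = FALSE)
  # Chebyshev distances between m-templates over the shared start indices
  D <- matrix(0, nt, nt)
  for (j in 0:(m - 1L)) {
    v <- series[seq_len(nt) + j * tau]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  up <- upper.tri(D)
  B <- sum(D[up] <= delta)
  v <- series[seq_len(nt) + m * tau]   # extend templates by one delayed sample
  D1 <- pmax(D, abs(outer(v, v, "-")))
  A <- sum(D1[up] <= delta)
  value <- if (A == 0L) Inf else -log(A / B)
  structure(list(value = value, A = A, B = B, delta = delta, m = m, tau = tau),
            class = "sampen")
}

#' @export
print.sampen <- function(x, ...) {
  cat(sprintf("SampEn(m = %d, tau = %d, delta = %.4g) = %s  [A = %d, B = %d]\n",
              x$m, x$tau, x$delta,
              if (is.finite(x$value)) sprintf("%.4f", x$value) else "inf",
              x$A, x$B))
  invisible(x)
}

#' Third-order one-dimensional median filter
#'
#' Replaces each sample by the median of the centered window of three,
#' treating the signal as zero beyond the endpoints. Length is preserved.
#'
#' @param series numeric vector.
#' @return Filtered numeric vector of the same length.
#' @examples
#' median_filter3(c(1, 5, 2, 8, 3))  # 1 2 5 3 3
#' @export
median_filter3 <- function(series) {
  assert_series(series)
  n <- length(series)
  p <- c(0, series, 0)
  a <- p[seq_len(n)]; b <- p[seq_len(n) + 1L]; cc <- p[seq_len(n) + 2L]
  # median of three without sorting
  pmax(pmin(a, b), pmin(cc, pmax(a, b)))
}

#' Preprocess a raw gait swing-interval series
#'
#' Median-filters the full record ([median_filter3()]) and truncates to the
#' first 120 samples, the shortest record length in the gait database, so all
#' subjects are analyzed at a common length.
#'
#' @param series numeric vector with at least `keep` samples.
#' @param keep number of samples to keep (default 120).
#' @param id optional record identifier used in error messages.
#' @return Numeric vector of length `keep`.
#' @export
preprocess_gait <- function(series, keep = 120L, id = NULL) {
  assert_series(series)
  keep <- as.integer(keep)
  if (length(series) < keep)
    stop(sprintf("gait record%s has %d samples; %d required",
                 if (is.null(id)) "" else paste0(" '", id, "'"),
                 length(series), keep), call. = FALSE)
  median_filter3(series)[seq_len(keep)]
}
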