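# Phase-space reconstruction, fuzzy c-means partitioning and fuzzy
# recurrence plots.

assert_series <- function(series) {
  if (!is.numeric(series) || length(series) < 1L)
    stop("series must be a numeric vector of length >= 1", call. = FALSE)
  if (!all(is.finite(series)))
    stop("series contains non-finite values", call. = FALSE)
  invisible(series)
}

#' Time-delay embedding of a scalar series
#'
#' Reconstructs a phase-space trajectory from a scalar time series by stacking
#' delayed copies: row i is `(t[i], t[i + tau], ..., t[i + (m - 1) * tau])`.
#' The number of reconstructed state vectors is `M = N - (m - 1) * tau`.
#'
#' @param series numeric vector, the scalar time series.
#' @param m embedding dimension (positive integer).
#' @param tau time delay in samples (positive integer).
#' @return An `M x m` numeric matrix of phase-space vectors.
#' @examples
#' embed_series(1:5, m = 2, tau = 1)
#' @export
embed_series <- function(series, m, tau = 1L) {
  assert_series(series)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L) stop("embedding dimension m must be >= 1", call. = FALSE)
  if (tau < 1L) stop("time delay tau must be >= 1", call. = FALSE)
  n <- length(series)
  n_min <- (m - 1L) * tau + 1L
  if (n < n_min)
    stop(sprintf("series too short for (m = %d, tau = %d): need N >= %d, got %d",
                 m, tau, n_min, n), call. = FALSE)
  M <- n - (m - 1L) * tau
  X <- vapply(seq_len(m), function(j) series[seq_len(M) + (j - 1L) * tau],
              numeric(M))
  matrix(X, nrow = M, ncol = m)
}

#' Fuzzy c-means partition of a phase-space set
#'
#' Standard fuzzy c-means by alternating optimization: membership-weighted
#' centers and inverse-distance membership updates with Euclidean distances.
#' Initialization draws the membership matrix from a uniform simplex under
#' `seed`; iteration stops when the largest absolute membership change falls
#' below `tol` or after `max_iter` sweeps.
#'
#' @param X numeric matrix (`M x m`), rows are phase-space vectors.
#' @param c number of clusters, `1 <= c <= nrow(X)`.
#' @param fuzzifier fuzziness exponent, `> 1` (default 2).
#' @param tol convergence threshold on `max(abs(U - U_old))`.
#' @param max_iter iteration cap.
#' @param seed integer seed for the membership initialization.
#' @return An object of class `fuzzy_partition`: list with `U` (`M x c`
#'   memberships, rows sum to 1), `V` (`c x m` centers), `c`, `converged`,
#'   `iterations` and `objective_trace` (non-increasing).
#' @export
fcm_partition <- function(X, c, fuzzifier = 2, tol = 1e-5, max_iter = 300L,
                          seed = 1L) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  M <- nrow(X)
  c <- as.integer(c)
  if (c < 1L) stop("cluster count c must be >= 1", call. = FALSE)
  if (c > M) stop(sprintf("cluster count c = %d exceeds number of points M = %d",
                          c, M), call. = FALSE)
  if (fuzzifier <= 1) stop("fuzzifier must be > 1", call. = FALSE)

  if (c == 1L) {
    U <- matrix(1, M, 1L)
    V <- matrix(colMeans(X), 1L, ncol(X))
    return(structure(list(U = U, V = V, c = 1L, converged = TRUE,
                          iterations = 0L, objective_trace = numeric(0)),
                     class = "fuzzy_partition"))
  }

  set.seed(seed)
  # uniform (Dirichlet(1,...,1)) rows via normalized exponentials
  U <- matrix(-log(stats::runif(M * c)), M, c)
  U <- U / rowSums(U)

  expo <- 2 / (fuzzifier - 1)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  V <- NULL
  repeat {
    it <- it + 1L
    Uf <- U^fuzzifier
    V <- crossprod(Uf, X) / colSums(Uf)           # c x m centers
    # squared Euclidean distances, M x c
    d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(V) +
      outer(rep(1, M), rowSums(V^2))
    d2[d2 < 0] <- 0
    zero <- d2 < .Machine$double.eps
    U_new <- 1 / ((d2 + .Machine$double.xmin)^(expo / 2) *
                    rowSums((d2 + .Machine$double.xmin)^(-expo / 2)))
    hit <- rowSums(zero) > 0
    if (any(hit)) {                                # crisp on coincident centers
      U_new[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    trace <- c(trace, sum(U_new^fuzzifier * d2))
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  Uf <- U^fuzzifier
  V <- crossprod(Uf, X) / colSums(Uf)
  if (c > 1L && min(stats::dist(V)) < 1e-8)
    warning("fuzzy c-means converged with coincident cluster centers; ",
            "memberships are uniform across them", call. = FALSE)
  structure(list(U = U, V = V, c = c, converged = converged, iterations = it,
                 objective_trace = trace),
            class = "fuzzy_partition")
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("Fuzzy c-means partition: %d points, %d clusters, %s after %d iterations\n",
              nrow(x$U), x$c,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Fuzzy recurrence plot from a membership matrix
#'
#' Composes cluster memberships into a fuzzy recurrence relation by the
#' max-min rule: `R[i, k] = max_j min(U[i, j], U[k, j])`. The relation is
#' symmetric by construction and the diagonal is forced to 1 (reflexivity).
#'
#' @param U an `M x c` membership matrix with entries in `[0, 1]`, or a
#'   `fuzzy_partition`.
#' @return An `M x M` symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
frp_from_partition <- function(U) {
  if (inherits(U, "fuzzy_partition")) U <- U$U
  if (!is.matrix(U)) U <- matrix(U, ncol = 1L)
  if (any(U < -1e-12) || any(U > 1 + 1e-12))
    stop("membership grades must lie in [0, 1]", call. = FALSE)
  U <- pmin(pmax(U, 0), 1)
  M <- nrow(U)
  R <- matrix(0, M, M)
  for (j in seq_len(ncol(U))) {
    A <- matrix(U[, j], M, M)          # A[i, k] = U[i, j]
    R <- pmax(R, pmin(A, t(A)))        # min(U[i,j], U[k,j]), symmetric
  }
  diag(R) <- 1
  R
}

#' Build a fuzzy recurrence plot from a scalar series
#'
#' Convenience composition of [embed_series()], [fcm_partition()] and
#' [frp_from_partition()].
#'
#' @inheritParams embed_series
#' @inheritParams fcm_partition
#' @return An `M x M` fuzzy recurrence matrix, `M = N - (m - 1) * tau`, with
#'   the converged `fuzzy_partition` attached as attribute `"partition"`.
#' @export
build_frp <- function(series, m = 4L, tau = 1L, c = 3L, fuzzifier = 2,
                      tol = 1e-5, max_iter = 300L, seed = 1L) {
  X <- embed_series(series, m = m, tau = tau)
  part <- fcm_partition(X, c = c, fuzzifier = fuzzifier, tol = tol,
                        max_iter = max_iter, seed = seed)
  R <- frp_from_partition(part)
  attr(R, "partition") <- part
  R
}
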