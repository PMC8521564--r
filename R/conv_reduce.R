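# Iterated convolution + ReLU + max pooling of a fuzzy recurrence plot down
# to a small matrix, and its largest eigenvalue.

#' Default sharpening kernel
#'
#' The 3x3 sharpening kernel applied at every reduction step. Its entries sum
#' to 1, so constant regions are preserved in the interior; it is symmetric,
#' so cross-correlation and convolution coincide.
#'
#' @return A 3x3 numeric matrix `[[0,-1,0],[-1,5,-1],[0,-1,0]]`.
#' @export
sharpen_kernel <- function() {
  matrix(c(0, -1, 0,
           -1, 5, -1,
           0, -1, 0), nrow = 3L, byrow = TRUE)
}

#' Same-size 2-D convolution
#'
#' Applies a 3x3 kernel to a square matrix so the output has the same side
#' length as the input. Values outside the matrix are taken from the nearest
#' edge (`"replicate"`, the default) or set to zero (`"zero"`). Replication
#' makes the unit-sum sharpening kernel leave constant matrices unchanged
#' everywhere, so repeated application cannot inflate a bounded recurrence
#' matrix through its borders; zero padding amplifies corners by up to the
#' center weight per pass. The operator is implemented as cross-correlation;
#' for the symmetric default kernel this equals convolution.
#'
#' @param A square numeric matrix.
#' @param w 3x3 kernel (default [sharpen_kernel()]).
#' @param padding `"replicate"` (default) or `"zero"`.
#' @return Matrix of the same dimensions as `A`.
#' @export
convolve_same <- function(A, w = sharpen_kernel(),
                          padding = c("replicate", "zero")) {
  padding <- match.arg(padding)
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix", call. = FALSE)
  if (!is.matrix(w) || any(dim(w) != 3L))
    stop("kernel w must be 3x3", call. = FALSE)
  s <- nrow(A)
  P <- matrix(0, s + 2L, s + 2L)
  P[2:(s + 1L), 2:(s + 1L)] <- A
  if (padding == "replicate") {
    P[1L, 2:(s + 1L)] <- A[1L, ]
    P[s + 2L, 2:(s + 1L)] <- A[s, ]
    P[2:(s + 1L), 1L] <- A[, 1L]
    P[2:(s + 1L), s + 2L] <- A[, s]
    P[1L, 1L] <- A[1L, 1L]; P[1L, s + 2L] <- A[1L, s]
    P[s + 2L, 1L] <- A[s, 1L]; P[s + 2L, s + 2L] <- A[s, s]
  }
  out <- matrix(0, s, s)
  for (a in 1:3) for (b in 1:3) {
    if (w[a, b] != 0)
      out <- out + w[a, b] * P[a:(a + s - 1L), b:(b + s - 1L)]
  }
  out
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`; shape preserved.
#'
#' @param A numeric matrix or vector.
#' @return `A` with negative entries replaced by 0.
#' @export
relu <- function(A) {
  A[A < 0] <- 0
  A
}

#' Max pooling of a square matrix
#'
#' Partitions rows and columns into windows of edge `window` advanced by
#' `stride` and takes the maximum over each window. In `"ceil"` mode partial
#' windows at the trailing edge are kept, so the output side is
#' `ceiling(side / stride)` when `window == stride`; `"floor"` mode drops
#' partial windows.
#'
#' @param A square numeric matrix.
#' @param window pooling window edge length (positive integer).
#' @param stride step between windows (positive integer).
#' @param mode `"ceil"` (keep partial edge windows, default) or `"floor"`.
#' @return The pooled square matrix.
#' @export
max_pool <- function(A, window = 2L, stride = 2L, mode = c("ceil", "floor")) {
  mode <- match.arg(mode)
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix", call. = FALSE)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 1L) stop("pooling window must be >= 1", call. = FALSE)
  if (stride < 1L) stop("pooling stride must be >= 1", call. = FALSE)
  s <- nrow(A)
  starts <- seq.int(1L, s, by = stride)
  if (mode == "floor") starts <- starts[starts + window - 1L <= s]
  if (length(starts) == 0L)
    stop("no complete pooling window fits the matrix in floor mode",
         call. = FALSE)
  pool_rows <- function(B) {
    out <- matrix(-Inf, length(starts), ncol(B))
    for (off in 0:(window - 1L)) {
      rows <- starts + off
      ok <- rows <= s
      if (!any(ok)) break
      out[ok, ] <- pmax(out[ok, , drop = FALSE], B[rows[ok], , drop = FALSE])
    }
    out
  }
  t(pool_rows(t(pool_rows(A))))
}

#' Reduce a fuzzy recurrence plot to an n x n convolved matrix
#'
#' Repeats convolution with `kernel`, rectification and max pooling while the
#' current side length exceeds `n`, exactly in that order, recording the side
#' length after every pooling step. With the default window-2/stride-2
#' ceil-mode pooling each iteration maps side `s` to `ceiling(s / 2)`, which
#' reaches `n = 2` exactly from any starting side.
#'
#' @param R square numeric matrix (a fuzzy recurrence plot).
#' @param n target side length (default 2).
#' @param kernel convolution kernel (default [sharpen_kernel()]).
#' @param padding convolution border handling (see [convolve_same()]).
#' @inheritParams max_pool
#' @return List of class `cfrp`: `matrix` (the final `n x n` rectified
#'   matrix) and `size_trajectory` (side lengths from input to output).
#' @export
reduce_to_cfrp <- function(R, n = 2L, kernel = sharpen_kernel(),
                           window = 2L, stride = 2L, mode = "ceil",
                           padding = "replicate") {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop("R must be a square matrix", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("target size n must be >= 1", call. = FALSE)
  s <- nrow(R)
  if (s < n)
    stop(sprintf("matrix side %d is smaller than target n = %d", s, n),
         call. = FALSE)
  sizes <- s
  A <- R
  while (nrow(A) > n) {
    A <- max_pool(relu(convolve_same(A, kernel, padding = padding)),
                  window = window, stride = stride, mode = mode)
    if (nrow(A) >= sizes[length(sizes)])
      stop("pooling configuration does not shrink the matrix; ",
           "reduction would not terminate", call. = FALSE)
    sizes <- c(sizes, nrow(A))
  }
  if (nrow(A) != n)
    stop(sprintf("pooling overshot the target: reached side %d, wanted %d",
                 nrow(A), n), call. = FALSE)
  structure(list(matrix = A, size_trajectory = sizes), class = "cfrp")
}

#' @export
print.cfrp <- function(x, ...) {
  cat(sprintf("Convolved FRP %dx%d; size trajectory: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$size_trajectory, collapse = " -> ")))
  print(x$matrix)
  invisible(x)
}

#' Largest eigenvalue of a convolved recurrence matrix
#'
#' Returns the algebraically largest eigenvalue of a symmetric matrix.
#' Asymmetry beyond `tol` signals a convention bug upstream and raises an
#' error rather than silently taking moduli.
#'
#' @param C square numeric matrix or a `cfrp`.
#' @param tol symmetry tolerance (max absolute difference, default 1e-9).
#' @return List with `lambda_max` and `final_matrix`.
#' @export
largest_eigenvalue <- function(C, tol = 1e-9) {
  mat <- if (inherits(C, "cfrp")) C$matrix else C
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("C must be a square matrix", call. = FALSE)
  if (max(abs(mat - t(mat))) > tol)
    stop("matrix is not symmetric within tolerance; ",
         "check the reduction conventions", call. = FALSE)
  lam <- eigen((mat + t(mat)) / 2, symmetric = TRUE, only.values = TRUE)$values[1]
  list(lambda_max = lam, final_matrix = mat)
}

#' Recurrence eigenvalue of a scalar time series
#'
#' End-to-end statistic: embed the series, fit a fuzzy c-means partition,
#' compose the fuzzy recurrence plot, reduce it by iterated
#' convolution/ReLU/max pooling to `n x n`, and return the largest
#' eigenvalue of the result. Deterministic for a fixed `seed`.
#'
#' @inheritParams build_frp
#' @inheritParams reduce_to_cfrp
#' @return Object of class `recur_eig`: list with `lambda_max`,
#'   `final_matrix`, `size_trajectory` and `config` (parameter echo).
#' @examples
#' s <- sin(2 * pi * 0.02 * seq_len(200))
#' recurrence_eigenvalue(s, m = 4, tau = 1, c = 3, n = 2, seed = 1)$lambda_max
#' @export
recurrence_eigenvalue <- function(series, m = 4L, tau = 1L, c = 3L, n = 2L,
                                  fuzzifier = 2, tol = 1e-5, max_iter = 300L,
                                  seed = 1L, kernel = sharpen_kernel(),
                                  window = 2L, stride = 2L, mode = "ceil",
                                  padding = "replicate") {
  R <- build_frp(series, m = m, tau = tau, c = c, fuzzifier = fuzzifier,
                 tol = tol, max_iter = max_iter, seed = seed)
  red <- reduce_to_cfrp(R, n = n, kernel = kernel, window = window,
                        stride = stride, mode = mode, padding = padding)
  eig <- largest_eigenvalue(red)
  structure(list(lambda_max = eig$lambda_max,
                 final_matrix = red$matrix,
                 size_trajectory = red$size_trajectory,
                 config = list(m = m, tau = tau, c = c, n = n,
                               fuzzifier = fuzzifier, tol = tol,
                               max_iter = max_iter, seed = seed,
                               window = window, stride = stride, mode = mode,
                               padding = padding)),
            class = "recur_eig")
}

#' @export
print.recur_eig <- function(x, ...) {
  cat(sprintf("Recurrence eigenvalue: lambda_max = %.6f\n", x$lambda_max))
  cat(sprintf("  size trajectory: %s\n",
              paste(x$size_trajectory, collapse = " -> ")))
  invisible(x)
}
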