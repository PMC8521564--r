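# Independent brute-force oracles and fixture builders shared by the tests.
# Each oracle restates the defining formula as a naive loop, independent of
# the vectorized implementations it checks.

oracle_maxmin <- function(U) {
  M <- nrow(U)
  R <- matrix(0, M, M)
  for (i in seq_len(M)) for (k in seq_len(M)) {
    best <- 0
    for (j in seq_len(ncol(U))) best <- max(best, min(U[i, j], U[k, j]))
    R[i, k] <- best
  }
  diag(R) <- 1
  R
}

oracle_conv <- function(A, w, padding = "replicate") {
  s <- nrow(A)
  at <- function(i, k) {
    if (padding == "zero") {
      if (i < 1 || i > s || k < 1 || k > s) 0 else A[i, k]
    } else {
      A[min(max(i, 1), s), min(max(k, 1), s)]
    }
  }
  out <- matrix(0, s, s)
  for (i in seq_len(s)) for (k in seq_len(s)) {
    acc <- 0
    for (a in -1:1) for (b in -1:1)
      acc <- acc + w[a + 2, b + 2] * at(i + a, k + b)
    out[i, k] <- acc
  }
  out
}

oracle_pool <- function(A, window, stride, mode = "ceil") {
  s <- nrow(A)
  starts <- seq(1, s, by = stride)
  if (mode == "floor") starts <- starts[starts + window - 1 <= s]
  Q <- length(starts)
  out <- matrix(0, Q, Q)
  for (q in seq_len(Q)) for (r in seq_len(Q)) {
    rows <- starts[q]:min(starts[q] + window - 1, s)
    cols <- starts[r]:min(starts[r] + window - 1, s)
    out[q, r] <- max(A[rows, cols])
  }
  out
}

oracle_sampen <- function(x, m, tau, delta) {
  nt <- length(x) - m * tau
  tmpl <- function(i, len) x[i + (0:(len - 1)) * tau]
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    if (max(abs(tmpl(i, m) - tmpl(j, m))) <= delta) B <- B + 1L
    if (max(abs(tmpl(i, m + 1) - tmpl(j, m + 1))) <= delta) A <- A + 1L
  }
  list(A = A, B = B, value = if (A == 0L) Inf else -log(A / B))
}

# Naive UPGMA: returns merge heights and the member-label sets formed, using
# the arithmetic mean over all original-pair distances at every step.
oracle_upgma <- function(D, labels = rownames(D)) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  groups <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, bestd / 2)
    groups <- c(groups, list(sort(labels[merged])))
  }
  list(heights = heights, groups = groups)
}

# Member-label sets formed by each merge of an upgma_tree (hclust encoding).
tree_groups <- function(tree) {
  out <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    members <- unlist(lapply(tree$merge[k, ], function(v)
      if (v < 0) -v else out[[v]]))
    out[[k]] <- members
  }
  lapply(out, function(idx) sort(tree$labels[idx]))
}

random_membership <- function(M, c) {
  U <- matrix(stats::runif(M * c), M, c)
  U / rowSums(U)
}

random_symmetric <- function(s) {
  A <- matrix(stats::rnorm(s * s), s, s)
  (A + t(A)) / 2
}

gait_summaries <- function(group) {
  mom <- cohort_moments("gait_eigenvalue")
  g <- mom[mom$group == group, ]
  lapply(seq_len(nrow(g)), function(i)
    summary_from_moments(g$mean[i], g$sd[i], g$n[i], g$label[i]))
}
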