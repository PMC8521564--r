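# Cohort summaries (mean, SD, one-sample t p-value, t-based CIs) and UPGMA
# dendrograms over cohort distances.

make_summary <- function(mean, sd, n, label) {
  se <- sd / sqrt(n)
  degenerate <- sd == 0
  if (degenerate) {
    p <- if (mean == 0) NA_real_ else 0
  } else {
    p <- 2 * stats::pt(-abs(mean / se), df = n - 1)
  }
  ci <- function(level) {
    half <- if (degenerate) 0 else stats::qt((1 + level) / 2, df = n - 1) * se
    c(lower = mean - half, upper = mean + half)
  }
  structure(list(label = label, n = n, mean = mean, sd = sd,
                 p_value = p, ci95 = ci(0.95), ci99 = ci(0.99),
                 degenerate = degenerate),
            class = "cohort_summary")
}

#' Summarize a cohort of complexity values
#'
#' Mean, standard deviation (`n - 1` denominator), two-sided one-sample
#' Student-t p-value against a zero mean, and t-based 95%/99% confidence
#' intervals `mean +/- t_{n-1,(1+level)/2} * sd / sqrt(n)`.
#'
#' @param values numeric vector of per-series statistics (all finite; an
#'   infinite sample-entropy sentinel is rejected with an error).
#' @param label cohort label.
#' @return Object of class `cohort_summary`: list with `label`, `n`, `mean`,
#'   `sd`, `p_value`, `ci95`, `ci99` and a `degenerate` flag (`sd == 0`).
#' @export
summarize_cohort <- function(values, label = "cohort") {
  if (length(values) < 2L)
    stop("cohort needs at least 2 values", call. = FALSE)
  if (any(is.infinite(values)))
    stop(sprintf("cohort '%s' contains infinite values; ", label),
         "infinite sample entropies cannot be averaged (increase m)",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("cohort values must be finite", call. = FALSE)
  make_summary(mean(values), stats::sd(values), length(values), label)
}

#' Cohort summary from printed moments
#'
#' Applies the same p-value and confidence-interval formulas as
#' [summarize_cohort()] to already-computed moments, so published
#' mean/SD/n rows can be checked without the raw data.
#'
#' @param mean cohort mean.
#' @param sd cohort standard deviation (`n - 1` denominator), `>= 0`.
#' @param n cohort size, `>= 2`.
#' @param label cohort label.
#' @return A `cohort_summary` (see [summarize_cohort()]).
#' @examples
#' summary_from_moments(5.48, 0.8322, 109, "N2")
#' @export
summary_from_moments <- function(mean, sd, n, label = "cohort") {
  if (!is.finite(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (!is.finite(mean)) stop("mean must be finite", call. = FALSE)
  make_summary(mean, sd, as.integer(n), label)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean = %.4f +/- %.4f, p = %.4e\n",
              x$label, x$n, x$mean, x$sd, x$p_value))
  cat(sprintf("  95%% CI (%.4f, %.4f); 99%% CI (%.4f, %.4f)%s\n",
              x$ci95[1], x$ci95[2], x$ci99[1], x$ci99[2],
              if (x$degenerate) "  [degenerate: sd = 0]" else ""))
  invisible(x)
}

#' Convert cohort summaries to a data frame
#'
#' One row per summary, in the column order mean, SD, p-value, 95% CI,
#' 99% CI.
#'
#' @param summaries a `cohort_summary` or list of them.
#' @return A data.frame.
#' @export
summaries_to_df <- function(summaries) {
  if (inherits(summaries, "cohort_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(label = s$label, n = s$n, mean = s$mean, sd = s$sd,
               p_value = s$p_value,
               ci95_lower = s$ci95[[1]], ci95_upper = s$ci95[[2]],
               ci99_lower = s$ci99[[1]], ci99_upper = s$ci99[[2]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Pairwise distance matrix between cohorts
#'
#' Default metric: absolute difference of cohort means.
#'
#' @param summaries list of `cohort_summary` objects with distinct labels.
#' @return Symmetric matrix with zero diagonal, dimnames = labels.
#' @export
cohort_distance_matrix <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least 2 cohorts", call. = FALSE)
  labels <- vapply(summaries, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate cohort labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  means <- vapply(summaries, function(s) s$mean, numeric(1))
  D <- abs(outer(means, means, "-"))
  dimnames(D) <- list(labels, labels)
  D
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: repeatedly merge the
#' closest pair of clusters, with inter-cluster distance the arithmetic mean
#' of all member-pair distances; each merge sits at half its distance, so the
#' tree is ultrametric. Implemented via average-linkage
#' [stats::hclust()] and converted to an `ape` phylogeny for newick export.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param labels leaf labels (default `rownames(D)`).
#' @return Object of class `upgma_tree`: list with `labels`, `merge`
#'   (hclust-style merge matrix), `heights` (merge heights, = distance / 2,
#'   non-decreasing), `phylo` (an [ape::as.phylo()] tree) and `newick`.
#' @examples
#' D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' upgma(D)$newick
#' @export
upgma <- function(D, labels = rownames(D)) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12 || any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric and nonnegative with a zero diagonal",
         call. = FALSE)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)   # branch lengths from heights / 2: ultrametric
  structure(list(labels = labels, merge = hc$merge, heights = hc$height / 2,
                 phylo = phy, newick = ape::write.tree(phy)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", x$newick, "\n")
  invisible(x)
}

#' Labels of the first (lowest) UPGMA merge
#'
#' @param tree an `upgma_tree`.
#' @return Character vector of the leaf labels joined at the lowest merge, or
#'   `NULL` if the lowest merge is not between two singletons.
#' @export
first_merge_labels <- function(tree) {
  m <- tree$merge[1, ]
  if (any(m > 0)) return(NULL)
  tree$labels[-m]
}
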