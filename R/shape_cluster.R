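#' Composite-angle distance between two normalized P'(r') functions
#'
#' For each sampled bin, the shared component is `min(a_i, b_i)` and the
#' unique component is `max(a_i, b_i) - min(a_i, b_i)`.  Summing the
#' per-bin (shared, unique) vectors gives a 2-D vector whose angle with
#' the shared axis, scaled from `[0, pi/2]` to `[0, 1]`, is the
#' distance: identical functions give 0, functions with disjoint support
#' give 1.  Grids of unequal length are zero-padded, so differing
#' `dmax / Rg` extents contribute unique mass and are penalized.
#'
#' The distance is symmetric with a zero diagonal; the triangle
#' inequality is not asserted.
#'
#' @param a,b [normalize_pr] results (unit-sum vectors on the step-1/4
#'   grid).
#' @return A single distance in `[0, 1]`.
#' @export
composite_angle_distance <- function(a, b) {
  pa <- if (inherits(a, "normalized_pr")) a$p_prime else as.numeric(a)
  pb <- if (inherits(b, "normalized_pr")) b$p_prime else as.numeric(b)
  n <- max(length(pa), length(pb))
  pa <- c(pa, rep(0, n - length(pa)))
  pb <- c(pb, rep(0, n - length(pb)))
  shared <- sum(pmin(pa, pb))
  unique_ <- sum(pmax(pa, pb) - pmin(pa, pb))
  if (shared == 0 && unique_ == 0) return(0)
  atan2(unique_, shared) / (pi / 2)
}

#' Pairwise composite-angle distance matrix
#'
#' @param prs List of [normalize_pr] results.
#' @param labels Optional labels; defaults to each element's `label`.
#' @return Object of class `pr_distance_matrix` wrapping a symmetric
#'   matrix with zero diagonal and entries in `[0, 1]`.
#' @export
pr_distance_matrix <- function(prs, labels = NULL) {
  stopifnot(is.list(prs), length(prs) >= 2L)
  n <- length(prs)
  if (is.null(labels)) {
    labels <- vapply(seq_len(n), function(i) {
      l <- prs[[i]]$label
      if (is.null(l) || !nzchar(l)) sprintf("curve%02d", i) else l
    }, character(1))
  }
  labels <- make.unique(as.character(labels))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- composite_angle_distance(prs[[i]], prs[[j]])
    }
  }
  structure(list(labels = labels, d = d), class = "pr_distance_matrix")
}

#' @export
print.pr_distance_matrix <- function(x, ...) {
  cat(sprintf("<pr_distance_matrix> %d curves, distances in [%.3f, %.3f]\n",
              length(x$labels), min(x$d), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Hierarchical shape clustering from a distance matrix
#'
#' Agglomerative clustering (complete linkage by default, matching R's
#' `hclust` default; average linkage available) on the composite-angle
#' distances, with a flat cut at `k` clusters.  Deterministic for a
#' given input order.
#'
#' @param dm A [pr_distance_matrix] (or a plain symmetric matrix).
#' @param k Number of clusters, `2 <= k <= n`.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return Object of class `shape_clusters`: `tree` (an `hclust`),
#'   `assignment` (named integer vector), `k`, `linkage`.
#' @export
cluster_shapes <- function(dm, k, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(dm, "pr_distance_matrix")) dm$d else as.matrix(dm)
  n <- nrow(d)
  k <- as.integer(k)
  if (k < 2L || k > n) {
    stop(sprintf("k must be between 2 and %d", n), call. = FALSE)
  }
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  assignment <- stats::cutree(tree, k = k)
  structure(list(tree = tree, assignment = assignment, k = k,
                 linkage = linkage),
            class = "shape_clusters")
}

#' @export
print.shape_clusters <- function(x, ...) {
  cat(sprintf("<shape_clusters> k = %d (%s linkage); sizes: %s\n",
              x$k, x$linkage,
              paste(table(x$assignment), collapse = ", ")))
  invisible(x)
}
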