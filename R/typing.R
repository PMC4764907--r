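# Enterotype-style community typing: square-root Jensen-Shannon distance,
# PAM clustering, Calinski-Harabasz k-selection, silhouette, PCA biplot
# coordinates.

#' Relative abundance profiles
#'
#' Per-sample relative abundances against the whole-community denominator
#' (each sample's total reads), optionally restricted to a subset of OTUs.
#' Profiles of a subset are deliberately *not* renormalized over the
#' subset: rows of a subset matrix sum to at most 1.
#'
#' @param table An [otu_table].
#' @param otu_subset Optional character vector of OTU ids.
#' @return A numeric matrix of fractions (samples x OTUs).
#' @export
relative_abundance <- function(table, otu_subset = NULL) {
  totals <- rowSums(table)
  if (any(totals == 0)) {
    stop("zero-total sample: ",
      paste(rownames(table)[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  rel <- unclass(table) / totals
  if (!is.null(otu_subset)) {
    missing <- setdiff(otu_subset, colnames(rel))
    if (length(missing) > 0) {
      stop("OTUs not in table: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    rel <- rel[, otu_subset, drop = FALSE]
  }
  rel
}

#' Square-root Jensen-Shannon distance matrix
#'
#' For each pair of samples, zeros are replaced by `pseudocount`, rows are
#' renormalized to sum 1, and the distance is
#' `sqrt(0.5 * KLD(p, m) + 0.5 * KLD(q, m))` with `m = (p + q) / 2` and
#' natural-log Kullback-Leibler divergence. The square root of the
#' Jensen-Shannon divergence is a metric, bounded by `sqrt(log(2))`.
#'
#' @param profiles Numeric matrix of abundance profiles (samples x OTUs),
#'   e.g. from [relative_abundance()].
#' @param pseudocount Positive zero-replacement value (default 1e-6).
#' @return A symmetric distance matrix with sample dimnames.
#' @export
jsd_distance <- function(profiles, pseudocount = 1e-6) {
  stopifnot(pseudocount > 0)
  p <- as.matrix(profiles)
  if (any(p < 0)) stop("negative abundances", call. = FALSE)
  p[p == 0] <- pseudocount
  p <- p / rowSums(p)
  d <- .jsd_matrix_cpp(p)
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  d
}

#' Partitioning around medoids (PAM) clustering
#'
#' Deterministic k-medoids on a precomputed distance matrix: greedy BUILD
#' seeding followed by steepest-descent SWAP, with ties broken toward the
#' lowest sample index. No random restarts are used, so the result is a
#' pure function of the distance matrix.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of clusters, `2 <= k < n` (k = 1 is allowed for
#'   completeness).
#' @param seed Ignored (the algorithm is deterministic); retained so all
#'   stochastic-looking stages share one calling convention.
#' @return List with `medoids` (indices), `medoid_ids`, `labels` (integer
#'   vector in `1..k`, named by sample), `total_deviation`.
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) {
    stop(sprintf("k = %d must be smaller than n = %d", k, n), call. = FALSE)
  }
  res <- .pam_cpp(d, as.integer(k))
  labels <- as.integer(res$labels)
  names(labels) <- rownames(d)
  list(
    medoids = as.integer(res$medoids),
    medoid_ids = rownames(d)[res$medoids],
    labels = labels,
    total_deviation = res$total_deviation
  )
}

# Medoid of each cluster under squared distances (used by the CH index):
# the member minimizing the within-cluster sum of squared distances, ties
# to the lowest index.
cluster_medoids_sq <- function(d2, labels) {
  vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(colSums(d2[idx, idx, drop = FALSE]))]
  }, integer(1))
}

#' Calinski-Harabasz index for a clustering of a distance matrix
#'
#' Medoid-based variant for arbitrary dissimilarities:
#' `CH = (B / (k - 1)) / (W / (n - k))` with
#' `W = sum_c sum_{i in c} d(i, medoid_c)^2` and
#' `B = sum_c n_c * d(medoid_c, medoid_global)^2`, where medoids minimize
#' within-group sums of squared distances and the global medoid minimizes
#' the total sum of squared distances. Returns `Inf` when `W = 0`
#' (duplicated points).
#'
#' @param d Symmetric distance matrix.
#' @param labels Cluster labels (any type; `k >= 2` non-empty clusters).
#' @return The CH score (larger = better separated).
#' @export
calinski_harabasz <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2) stop("CH index requires at least 2 clusters", call. = FALSE)
  d2 <- d^2
  med <- cluster_medoids_sq(d2, labels)
  global_med <- which.min(colSums(d2))
  W <- 0
  B <- 0
  for (cl in seq_len(k)) {
    idx <- which(labels == cl)
    W <- W + sum(d2[idx, med[cl]])
    B <- B + length(idx) * d2[med[cl], global_med]
  }
  if (W == 0) {
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Mean silhouette width
#'
#' `s(i) = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean distance
#' to the sample's own cluster (excluding itself) and `b_i` the smallest
#' mean distance to another cluster; members of singleton clusters score 0
#' by convention.
#'
#' @param d Symmetric distance matrix.
#' @param labels Cluster labels (`k >= 2`).
#' @return Mean of the per-sample widths, in `[-1, 1]`. The per-sample
#'   values are attached as attribute `"widths"`.
#' @export
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2) stop("silhouette requires at least 2 clusters", call. = FALSE)
  n <- nrow(d)
  s <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[own] == 1) {
      s[i] <- 0
      next
    }
    a <- sum(d[i, labels == own]) / (sizes[own] - 1)
    b <- min(vapply(
      setdiff(seq_len(k), own),
      function(cl) mean(d[i, labels == cl]), numeric(1)
    ))
    s[i] <- (b - a) / max(a, b)
  }
  structure(mean(s), widths = s)
}

#' Select the number of community types
#'
#' Runs [pam_cluster()] for every `k` in `k_range`, scores each partition
#' with [calinski_harabasz()], and keeps the `k` maximizing the CH index
#' (ties go to the smaller `k`). The chosen partition's mean silhouette
#' width is reported as a cluster-quality diagnostic.
#'
#' @param d Symmetric distance matrix (e.g. from [jsd_distance()]).
#' @param k_range Candidate cluster numbers within `[2, n - 1]`.
#' @param seed Ignored (deterministic); see [pam_cluster()].
#' @return A `community_typing` object: `k`, `labels`, `medoid_ids`,
#'   `ch_by_k`, `mean_silhouette`, `silhouette_widths`, `total_deviation`.
#' @export
choose_k <- function(d, k_range = 2:10, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  k_range <- as.integer(k_range)
  stopifnot(all(k_range >= 2), all(k_range < n))
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  ch <- vapply(
    seq_along(k_range),
    function(i) calinski_harabasz(d, fits[[i]]$labels), numeric(1)
  )
  names(ch) <- as.character(k_range)
  best <- which.max(ch) # first maximum = smallest k on ties
  fit <- fits[[best]]
  sil <- mean_silhouette(d, fit$labels)
  structure(
    list(
      k = k_range[best],
      labels = fit$labels,
      medoid_ids = fit$medoid_ids,
      ch_by_k = ch,
      mean_silhouette = as.numeric(sil),
      silhouette_widths = attr(sil, "widths"),
      total_deviation = fit$total_deviation
    ),
    class = "community_typing"
  )
}

#' @export
print.community_typing <- function(x, ...) {
  cat(sprintf(
    "Community typing: k = %d (CH-selected), mean silhouette %.3f\n",
    x$k, x$mean_silhouette
  ))
  cat("  type sizes:", paste(table(x$labels), collapse = ", "), "\n")
  cat(
    "  CH by k:",
    paste(sprintf("%s=%.1f", names(x$ch_by_k), x$ch_by_k), collapse = " "),
    "\n"
  )
  invisible(x)
}

#' PCA biplot coordinates of abundance profiles
#'
#' Principal component analysis of the column-standardized profiles
#' (centering and unit-variance scaling, i.e. eigendecomposition of the
#' correlation matrix). The sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param profiles Numeric matrix (samples x OTUs) with at least 2 rows
#'   and columns and no zero-variance column.
#' @return A `typing_pca` object: `scores` (samples x components),
#'   `loadings` (OTUs x components, orthonormal), `pct_variance`
#'   (sums to 100).
#' @export
pca_biplot <- function(profiles) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) >= 2, ncol(profiles) >= 2)
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance OTU column: ",
      paste(colnames(profiles)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  fit <- stats::prcomp(profiles, center = TRUE, scale. = TRUE)
  loadings <- fit$rotation
  scores <- fit$x
  for (j in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = scores, loadings = loadings, pct_variance = pct),
    class = "typing_pca"
  )
}

#' @export
print.typing_pca <- function(x, ...) {
  cat(sprintf(
    "PCA of %d profiles x %d OTUs; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$scores), nrow(x$loadings),
    x$pct_variance[1], x$pct_variance[2]
  ))
  invisible(x)
}

#' Plot community types on the first two principal components
#'
#' @param x A `community_typing` object.
#' @param pca A `typing_pca` object over the same samples (from
#'   [pca_biplot()]).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.community_typing <- function(x, pca, ...) {
  stopifnot(inherits(pca, "typing_pca"))
  plot(pca$scores[, 1], pca$scores[, 2],
    col = x$labels, pch = 16,
    xlab = sprintf("PC1 (%.1f%%)", pca$pct_variance[1]),
    ylab = sprintf("PC2 (%.1f%%)", pca$pct_variance[2]),
    ...
  )
  invisible(x)
}
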