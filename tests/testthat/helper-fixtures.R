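# Shared fixtures and independent oracles for the test suite.

# Random small OTU table.
random_otu_table <- function(n_samples, n_otus, max_count = 50) {
  m <- matrix(
    sample.int(max_count + 1, n_samples * n_otus, replace = TRUE) - 1L,
    n_samples, n_otus,
    dimnames = list(
      sprintf("S%02d", seq_len(n_samples)),
      sprintf("OTU_%03d", seq_len(n_otus))
    )
  )
  otu_table(m)
}

# Independent Faith's-PD oracle: union of edges on each root-to-leaf path,
# found with ape::nodepath, summed once. Root-inclusive by construction.
brute_force_pd <- function(tree, present_tips) {
  if (length(present_tips) == 0) {
    return(0)
  }
  root <- length(tree$tip.label) + 1L
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  used <- character(0)
  for (tip in present_tips) {
    path <- ape::nodepath(tree, root, match(tip, tree$tip.label))
    for (i in seq_len(length(path) - 1)) {
      used <- union(used, paste(path[i], path[i + 1]))
    }
  }
  sum(tree$edge.length[match(used, edge_key)])
}

# Exhaustive k-medoids minimum total deviation.
exhaustive_kmedoids <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  min(apply(combs, 2, function(m) {
    sum(apply(d[, m, drop = FALSE], 1, min))
  }))
}

# Brute-force silhouette widths, computed point by point from definitions.
brute_force_silhouette <- function(d, labels) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) {
      return(0)
    }
    a <- mean(d[i, mates])
    b <- min(vapply(
      setdiff(unique(labels), own),
      function(cl) mean(d[i, labels == cl]), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Majority-vote mapping from PAM labels to planted type labels; returns the
# per-sample planted-type prediction implied by the clustering.
map_labels_to_truth <- function(labels, truth) {
  truth <- truth[names(labels)]
  mapped <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- labels == cl
    tab <- table(truth[idx])
    mapped[idx] <- names(tab)[which.max(tab)]
  }
  names(mapped) <- names(labels)
  mapped
}

# Small simulation settings for fast tests: few OTUs, shallow depths.
tiny_params <- function(...) {
  simulation_params(
    n_samples = 60, n_block_i = 5, n_block_ii = 4, n_core_other = 10,
    n_rare = 30, depth_log_mean = log(2000), depth_log_sd = 0.1, ...
  )
}
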