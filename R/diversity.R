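# Rarefaction and per-sample alpha diversity.

#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric draw)
#' so all samples are compared at a common sequencing depth. The draw is
#' generated by sequential conditional hypergeometric sampling, which is
#' exact and O(number of OTUs).
#'
#' @param row Non-negative integer count vector.
#' @param depth Target depth; must not exceed `sum(row)`.
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return An integer vector of the same length summing to `depth`.
#' @export
rarefy_counts <- function(row, depth, seed = NULL) {
  stopifnot(all(row >= 0), depth >= 0)
  total <- sum(row)
  if (total < depth) {
    stop(sprintf(
      "sample has %d reads, fewer than rarefaction depth %d",
      total, depth
    ), call. = FALSE)
  }
  if (total == depth) {
    return(as.integer(row))
  }
  with_seed(seed, {
    out <- integer(length(row))
    k <- depth
    remaining <- total
    for (i in seq_along(row)) {
      if (k == 0L) break
      ni <- row[i]
      if (ni == 0L) next
      remaining <- remaining - ni
      take <- stats::rhyper(1, ni, remaining, k)
      out[i] <- take
      k <- k - take
    }
    out
  })
}

#' Rarefy every sample of an OTU table
#'
#' Each sample is subsampled once to `depth` reads with a per-sample seed
#' derived deterministically from the global seed and the sample id, so
#' results do not depend on sample order. Samples with fewer than `depth`
#' reads are excluded (not rarefied) and reported in the `"excluded"`
#' attribute.
#'
#' @param table An [otu_table].
#' @param depth Rarefaction depth.
#' @param seed Global integer seed.
#' @return An [otu_table] of the retained samples with attribute
#'   `"excluded"` (character vector of dropped sample ids).
#' @export
rarefy_table <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table)
  keep <- totals >= depth
  out <- matrix(0L, sum(keep), ncol(table),
    dimnames = list(rownames(table)[keep], colnames(table))
  )
  for (id in rownames(out)) {
    out[id, ] <- rarefy_counts(table[id, ], depth, derive_seed(seed, id))
  }
  res <- otu_table(out)
  attr(res, "excluded") <- rownames(table)[!keep]
  res
}

#' Number of observed OTUs in a sample
#'
#' @param row Count vector.
#' @return Count of entries greater than zero.
#' @export
observed_otus <- function(row) {
  sum(row > 0)
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over relative abundances, with zero-count
#' terms contributing 0.
#'
#' @param row Count (or proportion) vector with positive total.
#' @return Diversity in nats.
#' @export
shannon_index <- function(row) {
  total <- sum(row)
  if (total <= 0) {
    stop("cannot compute Shannon index of an empty sample", call. = FALSE)
  }
  p <- row[row > 0] / total
  -sum(p * log(p))
}

#' Faith's phylogenetic diversity of a sample
#'
#' The sum of branch lengths of the minimal subtree connecting every OTU
#' observed in the sample. By default the subtree includes the path up to
#' the tree root (the convention of `picante::pd`); set
#' `include_root = FALSE` to span only the most recent common ancestor of
#' the observed OTUs.
#'
#' @param row Named count vector (names are OTU ids), or a logical/numeric
#'   presence vector.
#' @param tree A rooted [ape::phylo] tree whose leaves include every OTU
#'   with a positive count.
#' @param include_root Include the root path (default `TRUE`).
#' @return PD in branch-length units.
#' @export
faith_pd <- function(row, tree, include_root = TRUE) {
  present <- names(row)[row > 0]
  if (is.null(names(row))) {
    stop("`row` must be named by OTU id", call. = FALSE)
  }
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0) {
    stop("OTUs absent from the tree: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(present) == 0) {
    return(0)
  }
  tip_idx <- match(present, tree$tip.label)
  pd <- pd_from_tips(tree, tip_idx)
  if (!include_root && length(present) >= 1) {
    pd <- pd - root_to_mrca_length(tree, tip_idx)
  }
  pd
}

# PD (root-inclusive) for a set of tip indices: sum of lengths of edges
# whose child subtree contains at least one present tip.
pd_from_tips <- function(tree, tip_idx) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  present <- logical(n_node)
  present[tip_idx] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    if (present[po$edge[i, 2]]) present[po$edge[i, 1]] <- TRUE
  }
  sum(po$edge.length[present[po$edge[, 2]]])
}

root_to_mrca_length <- function(tree, tip_idx) {
  if (length(tip_idx) == 1) {
    mrca <- tip_idx
  } else {
    mrca <- ape::getMRCA(tree, tip_idx)
  }
  root <- length(tree$tip.label) + 1L
  if (mrca == root) {
    return(0)
  }
  path <- ape::nodepath(tree, root, mrca)
  len <- 0
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  for (i in seq_len(length(path) - 1)) {
    e <- match(paste(path[i], path[i + 1]), edge_key)
    len <- len + tree$edge.length[e]
  }
  len
}

#' Faith's PD for every sample of a table
#'
#' Vectorized over samples via a tip-by-edge incidence matrix; equivalent
#' to calling [faith_pd()] per row.
#'
#' @param table An [otu_table] (or count matrix with OTU colnames).
#' @param tree A rooted [ape::phylo] tree.
#' @param include_root Include the root path (default `TRUE`).
#' @return A named numeric vector of PD values.
#' @export
faith_pd_table <- function(table, tree, include_root = TRUE) {
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing) > 0) {
    stop("OTUs absent from the tree: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  inc <- edge_tip_matrix(tree)[colnames(table), , drop = FALSE]
  presence <- (unclass(table) > 0) * 1
  edge_hit <- presence %*% inc > 0
  pd <- as.numeric(edge_hit %*% tree$edge.length)
  names(pd) <- rownames(table)
  if (!include_root) {
    for (id in rownames(table)) {
      tip_idx <- match(
        colnames(table)[table[id, ] > 0],
        tree$tip.label
      )
      if (length(tip_idx) > 0) {
        pd[id] <- pd[id] - root_to_mrca_length(tree, tip_idx)
      }
    }
  }
  pd
}

#' Expected rarefaction curve for one sample
#'
#' The expected number of observed OTUs at each depth under sampling
#' without replacement has the closed form
#' `E[S(d)] = sum_i (1 - choose(N - n_i, d) / choose(N, d))`; the analytic
#' curve is returned always, and a seeded Monte-Carlo mean over `reps`
#' rarefactions is added when `reps > 0`.
#'
#' @param row Count vector.
#' @param depths Integer depths, each at most `sum(row)`.
#' @param reps Monte-Carlo replicates per depth (0 = analytic only).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return A data.frame with columns `depth`, `expected_otus` and (when
#'   `reps > 0`) `mc_mean_otus`.
#' @export
rarefaction_curve <- function(row, depths, reps = 0, seed = NULL) {
  total <- sum(row)
  stopifnot(all(depths >= 0), all(depths <= total))
  expected <- vapply(depths, function(d) {
    # lchoose for numerical stability at survey-scale read counts
    sum(1 - exp(lchoose(total - row, d) - lchoose(total, d)))
  }, numeric(1))
  out <- data.frame(depth = as.integer(depths), expected_otus = expected)
  if (reps > 0) {
    out$mc_mean_otus <- with_seed(seed, vapply(depths, function(d) {
      mean(vapply(
        seq_len(reps),
        function(i) observed_otus(rarefy_counts(row, d)), numeric(1)
      ))
    }, numeric(1)))
  }
  out
}

#' Per-sample alpha-diversity profiles
#'
#' Computes raw read counts, observed OTUs, Shannon index and Faith's PD
#' for every sample, after rarefaction to a common depth. Samples below
#' the rarefaction depth are excluded and reported via the `"excluded"`
#' attribute.
#'
#' @param table An [otu_table] of raw counts.
#' @param tree A rooted [ape::phylo] tree covering the table's OTUs.
#' @param depth Rarefaction depth.
#' @param seed Integer seed for rarefaction.
#' @param pd_on_rarefied Compute PD on the rarefied (default) or raw
#'   counts.
#' @return A data.frame with columns `sample_id`, `n_reads_raw`,
#'   `observed_otus`, `shannon`, `pd`.
#' @export
diversity_profiles <- function(table, tree, depth = 5000, seed = 1L,
                               pd_on_rarefied = TRUE) {
  rare <- rarefy_table(table, depth, seed)
  ids <- rownames(rare)
  pd_input <- if (pd_on_rarefied) rare else table[ids, , drop = FALSE]
  out <- data.frame(
    sample_id = ids,
    n_reads_raw = as.integer(rowSums(table)[ids]),
    observed_otus = as.integer(apply(rare, 1, observed_otus)),
    shannon = apply(rare, 1, shannon_index),
    pd = faith_pd_table(pd_input, tree),
    row.names = ids,
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- attr(rare, "excluded")
  attr(out, "rarefied_table") <- rare
  out
}
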