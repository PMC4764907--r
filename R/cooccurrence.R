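# Pairwise-correlation co-occurrence network over predominant-core OTUs.

#' Pairwise Pearson correlations between OTU abundance profiles
#'
#' Sample Pearson coefficient per OTU pair with a two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param profiles Numeric matrix (samples x OTUs), `n >= 3` samples,
#'   no constant column.
#' @return A data.frame with one row per unordered pair: `otu_a`,
#'   `otu_b`, `r`, `p_raw`.
#' @export
pairwise_pearson <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant OTU column: ",
      paste(colnames(profiles)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  r <- stats::cor(profiles)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[pairs]
  # clamp for the boundary case |r| = 1 (p -> 0)
  tstat <- rv * sqrt(n - 2) / sqrt(pmax(1 - rv^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.nan(tstat) | is.infinite(tstat)] <- 0
  data.frame(
    otu_a = colnames(profiles)[pairs[, 1]],
    otu_b = colnames(profiles)[pairs[, 2]],
    r = rv,
    p_raw = p,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), returned in
#' input order. Wraps [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Build a co-occurrence network
#'
#' Edges connect OTU pairs with a positive Pearson correlation whose
#' BH-adjusted p-value falls below `edge_alpha`; cohabiting groups are the
#' connected components (of size >= 2) of the thresholded graph. The
#' adjustment is over all tested pairs.
#'
#' @param profiles Numeric matrix (samples x OTUs) of relative abundances.
#' @param edge_alpha Adjusted-p cutoff, default `1e-12`.
#' @return A `cooccurrence_network` object: `nodes`, `edges` (data.frame
#'   `otu_a`, `otu_b`, `r`, `p_raw`, `p_adj`), `groups` (list of character
#'   vectors), `edge_alpha`.
#' @export
build_network <- function(profiles, edge_alpha = 1e-12) {
  stopifnot(edge_alpha >= 0, edge_alpha < 1)
  tests <- pairwise_pearson(profiles)
  tests$p_adj <- bh_adjust(tests$p_raw)
  edges <- tests[tests$r > 0 & tests$p_adj < edge_alpha, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(colnames(profiles))
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("otu_a", "otu_b")],
      directed = FALSE, vertices = nodes
    )
    comp <- igraph::components(g)
    groups <- split(names(comp$membership), comp$membership)
    groups <- unname(groups[vapply(groups, length, integer(1)) >= 2])
    groups <- lapply(groups, sort)
    groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  } else {
    groups <- list()
  }
  structure(
    list(
      nodes = nodes, edges = edges, groups = groups,
      edge_alpha = edge_alpha, all_pairs = tests
    ),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "Co-occurrence network: %d OTUs, %d edges (r > 0, adjusted p < %g), %d cohabiting group(s)\n",
    length(x$nodes), nrow(x$edges), x$edge_alpha, length(x$groups)
  ))
  for (i in seq_along(x$groups)) {
    cat(sprintf(
      "  group %d (%d OTUs): %s\n", i, length(x$groups[[i]]),
      paste(x$groups[[i]], collapse = ", ")
    ))
  }
  invisible(x)
}
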