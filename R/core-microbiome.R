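# Diversity-quintile stratification and core / predominant-core OTU
# identification.

#' Stratify samples into phylogenetic-diversity quantile groups
#'
#' Rank-based split into `n_groups` nearly equal groups ordered by PD
#' (Q1 = lowest). Ties in PD are broken by sample id so the assignment is
#' reproducible; when `n` is not divisible by `n_groups` the lower groups
#' take the extra samples. Boundaries are reported as the minimum PD of
#' each upper group, matching the half-open interval convention
#' `cut_{q} <= PD < cut_{q+1}`.
#'
#' @param pd Named numeric vector of per-sample PD values.
#' @param n_groups Number of strata (default 5, i.e. quintiles).
#' @return A `pd_quintiles` object: list with `labels` (named factor
#'   `Q1..Qn` in input-sample order) and `boundaries` (`n_groups - 1`
#'   cut values).
#' @export
assign_pd_quintiles <- function(pd, n_groups = 5) {
  if (is.null(names(pd))) {
    stop("`pd` must be named by sample id", call. = FALSE)
  }
  n <- length(pd)
  if (n < n_groups) {
    stop(sprintf(
      "cannot form %d groups from %d samples", n_groups, n
    ), call. = FALSE)
  }
  ord <- order(pd, names(pd))
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  grp <- rep(seq_len(n_groups), times = sizes)
  labels <- factor(paste0("Q", grp), levels = paste0("Q", seq_len(n_groups)))
  out_labels <- labels[order(ord)] # back to input order
  names(out_labels) <- names(pd)
  sorted_pd <- pd[ord]
  starts <- cumsum(sizes)
  boundaries <- sorted_pd[starts[-n_groups] + 1L]
  names(boundaries) <- paste0("Q", 2:n_groups)
  structure(
    list(labels = out_labels, boundaries = boundaries),
    class = "pd_quintiles"
  )
}

#' @export
print.pd_quintiles <- function(x, ...) {
  cat(sprintf(
    "PD stratification: %d samples in %d groups (sizes %s)\n",
    length(x$labels), nlevels(x$labels),
    paste(table(x$labels), collapse = ", ")
  ))
  cat("  boundaries:", paste(format(x$boundaries, digits = 4),
    collapse = ", "
  ), "\n")
  invisible(x)
}

quintile_samples <- function(quintiles, level) {
  names(quintiles$labels)[quintiles$labels == level]
}

#' Per-OTU detection prevalence
#'
#' Fraction of samples (optionally restricted to a subset) in which each
#' OTU is detected with at least one read.
#'
#' @param table An [otu_table] (typically rarefied).
#' @param sample_subset Optional character vector of sample ids.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
otu_prevalence <- function(table, sample_subset = NULL) {
  m <- unclass(table)
  if (!is.null(sample_subset)) {
    if (length(sample_subset) == 0) {
      stop("empty sample subset", call. = FALSE)
    }
    missing <- setdiff(sample_subset, rownames(m))
    if (length(missing) > 0) {
      stop("samples not in table: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    m <- m[sample_subset, , drop = FALSE]
  }
  colMeans(m > 0)
}

#' Identify core OTUs
#'
#' Core OTUs are detected in at least `threshold` of all samples and, by
#' default, in at least `threshold` of the samples of every diversity
#' quintile separately (`rule = "every_quintile"`). The weaker rule
#' `"overall_and_q1"` requires only overall and lowest-quintile
#' prevalence. The two coincide when detection rates rise with the
#' diversity stratum.
#'
#' @param table An [otu_table] (typically rarefied).
#' @param quintiles A `pd_quintiles` object from [assign_pd_quintiles()].
#' @param threshold Prevalence threshold in (0, 1); default 0.75.
#' @param rule Core definition; see Details.
#' @return Character vector of core OTU ids (in table column order).
#' @export
identify_core_otus <- function(table, quintiles, threshold = 0.75,
                               rule = c("every_quintile", "overall_and_q1")) {
  rule <- match.arg(rule)
  stopifnot(threshold > 0, threshold <= 1)
  overall <- otu_prevalence(table)
  ok <- overall >= threshold
  levels_needed <- if (rule == "every_quintile") {
    levels(quintiles$labels)
  } else {
    levels(quintiles$labels)[1]
  }
  for (q in levels_needed) {
    ok <- ok & otu_prevalence(table, quintile_samples(quintiles, q)) >=
      threshold
  }
  colnames(table)[ok]
}

#' Newly shared OTUs per ascending diversity quintile
#'
#' For each quintile above the first, the OTUs that reach the prevalence
#' threshold within that quintile but are neither core nor already added
#' at a lower quintile. Mirrors the expanding shared sets displayed per
#' stratum in prevalence heatmaps.
#'
#' @param table An [otu_table] (typically rarefied).
#' @param quintiles A `pd_quintiles` object.
#' @param core Character vector of core OTU ids (computed with the same
#'   threshold).
#' @param threshold Prevalence threshold; default 0.75.
#' @return Named list `Q2..Qn` of character vectors, pairwise disjoint and
#'   disjoint from `core`.
#' @export
shared_otus_by_quintile <- function(table, quintiles, core,
                                    threshold = 0.75) {
  qs <- levels(quintiles$labels)[-1]
  seen <- core
  out <- list()
  for (q in qs) {
    prev <- otu_prevalence(table, quintile_samples(quintiles, q))
    added <- setdiff(colnames(table)[prev >= threshold], seen)
    out[[q]] <- added
    seen <- c(seen, added)
  }
  out
}

#' Select predominant-core OTUs
#'
#' Core OTUs whose mean per-sample relative abundance (whole-community
#' denominator) across the lowest-quintile samples reaches
#' `abundance_threshold` (default 1%). These dominant shared taxa are the
#' input to community typing.
#'
#' @param table An [otu_table] (typically rarefied).
#' @param core Character vector of core OTU ids.
#' @param quintiles A `pd_quintiles` object.
#' @param abundance_threshold Fraction; default 0.01.
#' @return Character vector of predominant-core OTU ids.
#' @export
select_predominant_core <- function(table, core, quintiles,
                                    abundance_threshold = 0.01) {
  q1 <- quintile_samples(quintiles, levels(quintiles$labels)[1])
  if (length(q1) == 0) {
    stop("lowest quintile is empty", call. = FALSE)
  }
  rel <- relative_abundance(table[q1, , drop = FALSE])
  mean_rel <- colMeans(rel[, core, drop = FALSE])
  core[mean_rel >= abundance_threshold]
}

#' Fraction of each microbiome accounted for by a set of OTUs
#'
#' @param table An [otu_table].
#' @param core Character vector of OTU ids.
#' @return Named numeric vector: per sample, core reads / total reads.
#' @export
core_fraction <- function(table, core) {
  totals <- rowSums(table)
  if (any(totals == 0)) {
    stop("zero-total sample: ",
      paste(rownames(table)[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  if (length(core) == 0) {
    return(stats::setNames(rep(0, nrow(table)), rownames(table)))
  }
  rowSums(table[, core, drop = FALSE]) / totals
}
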