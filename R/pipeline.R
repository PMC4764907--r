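# End-to-end driver: exclusions, rarefaction, diversity, stratification,
# core identification, community typing, co-occurrence network,
# association tables.

#' Run the full stratification pipeline
#'
#' Executes the analysis end to end on a count table, tree and metadata:
#' sample exclusions (antibiotics users, samples under the rarefaction
#' depth), rarefaction, alpha diversity (observed OTUs, Shannon, Faith's
#' PD), PD quintile stratification, core / quintile-shared /
#' predominant-core OTU identification, Jensen-Shannon + PAM community
#' typing with Calinski-Harabasz k-selection, PCA biplot coordinates, the
#' co-occurrence network, and the bivariate and multivariate association
#' tables (standardized linear regression of PD; crude and adjusted
#' Poisson prevalence-ratio models of community type, both restricted to
#' dentate individuals). The result is a pure function of the inputs and
#' `cfg$rng_seed`.
#'
#' @param table An [otu_table] of raw counts.
#' @param tree A rooted [ape::phylo] tree whose leaves cover the table's
#'   OTUs.
#' @param meta A [sample_metadata] table covering the table's samples
#'   (extra samples are ignored; missing ones are dropped with a warning).
#' @param cfg An [analysis_config].
#' @return A `salitype_pipeline` list; see the vignette for the bundle's
#'   components.
#' @export
run_pipeline <- function(table, tree, meta, cfg = analysis_config()) {
  stopifnot(inherits(table, "otu_table"), inherits(cfg, "analysis_config"))
  missing_leaves <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_leaves) > 0) {
    stop("tree is missing OTUs: ", paste(missing_leaves, collapse = ", "),
      call. = FALSE
    )
  }
  exclusions <- data.frame(
    sample_id = character(0), reason = character(0),
    stringsAsFactors = FALSE
  )
  note_exclusion <- function(ids, reason) {
    if (length(ids) > 0) {
      exclusions <<- rbind(exclusions, data.frame(
        sample_id = ids, reason = reason, stringsAsFactors = FALSE
      ))
    }
  }

  absent_meta <- setdiff(rownames(table), meta$sample_id)
  if (length(absent_meta) > 0) {
    warning(
      length(absent_meta),
      " sample(s) missing from metadata were dropped"
    )
    note_exclusion(absent_meta, "missing_metadata")
  }
  keep <- intersect(rownames(table), meta$sample_id)
  abx <- keep[meta[keep, "antibiotics_use"] %in% TRUE]
  note_exclusion(abx, "antibiotics_use")
  keep <- setdiff(keep, abx)
  if (length(keep) < 2) {
    stop("fewer than 2 samples remain after exclusions", call. = FALSE)
  }
  table <- otu_table(unclass(table)[keep, , drop = FALSE])

  # diversity (includes rarefaction; under-depth samples drop out here)
  div <- diversity_profiles(table, tree,
    depth = cfg$rarefaction_depth,
    seed = cfg$rng_seed, pd_on_rarefied = cfg$pd_on_rarefied
  )
  note_exclusion(attr(div, "excluded"), "below_rarefaction_depth")
  rare <- attr(div, "rarefied_table")
  if (nrow(rare) < cfg$n_quintiles) {
    stop("too few samples after exclusions to form ", cfg$n_quintiles,
      " diversity strata",
      call. = FALSE
    )
  }

  pd <- stats::setNames(div$pd, div$sample_id)
  quintiles <- assign_pd_quintiles(pd, cfg$n_quintiles)
  core <- identify_core_otus(rare, quintiles, cfg$prevalence_threshold,
    rule = cfg$core_rule
  )
  shared <- shared_otus_by_quintile(rare, quintiles, core,
    cfg$prevalence_threshold
  )
  predominant <- select_predominant_core(rare, core, quintiles,
    cfg$abundance_threshold
  )
  core_frac <- core_fraction(rare, core)

  if (length(predominant) < 2) {
    stop("fewer than 2 predominant-core OTUs; cannot type communities",
      call. = FALSE
    )
  }
  profiles <- relative_abundance(rare, predominant)
  d <- jsd_distance(profiles, cfg$jsd_pseudocount)
  typing <- choose_k(d, cfg$k_range)
  pca <- pca_biplot(profiles)
  network <- build_network(profiles, cfg$edge_alpha)

  meta_kept <- meta[rownames(rare), , drop = FALSE]
  associations <- association_tables(
    div, typing, meta_kept, cfg, note_exclusion
  )

  structure(
    list(
      config = cfg,
      n_otus_total = ncol(table),
      exclusions = exclusions,
      diversity = div,
      quintiles = quintiles,
      core = list(
        core_otus = core,
        shared_by_quintile = shared,
        predominant_core = predominant,
        core_fraction = core_frac
      ),
      profiles = profiles,
      typing = typing,
      pca = pca,
      network = network,
      associations = associations
    ),
    class = "salitype_pipeline"
  )
}

# Bivariate tables (PD vs covariates; type I vs type II) and the two
# multivariate models. `note` logs regression-stage exclusions.
association_tables <- function(div, typing, meta, cfg, note) {
  meta$pd <- div[meta$sample_id, "pd"]
  meta$type <- typing$labels[meta$sample_id]
  # PAM's own label order is kept: without taxonomy there is no intrinsic
  # way to decide which cluster to call "type I"
  meta$smoking_current <- meta$smoking == "current"

  continuous <- c(
    "age", "bmi", "n_teeth", "pct_dft", "mean_ppd", "pct_bop",
    "plaque_index"
  )
  binary <- c("sex", "has_decayed_teeth", "smoking_current")

  # PD bivariate screen
  pd_rows <- list()
  for (v in continuous) {
    ok <- !is.na(meta[[v]])
    pd_rows[[v]] <- pearson_cor_test(meta$pd[ok], meta[[v]][ok])
  }
  for (v in binary) {
    g <- meta[[v]]
    if (is.factor(g)) g <- g == levels(g)[1]
    ok <- !is.na(g)
    pd_rows[[v]] <- student_t_test(
      meta$pd[ok & g], meta$pd[ok & !g]
    )
  }
  pd_bivariate <- data.frame(
    variable = names(pd_rows),
    test = vapply(pd_rows, function(x) x$test_name, character(1)),
    effect = vapply(pd_rows, function(x) x$effect, numeric(1)),
    p_value = vapply(pd_rows, function(x) x$p_value, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  # type I vs type II bivariate table (t-test / Fisher)
  is_type1 <- meta$type == 1
  type_rows <- list()
  for (v in continuous) {
    ok <- !is.na(meta[[v]])
    type_rows[[v]] <- student_t_test(
      meta[[v]][ok & is_type1], meta[[v]][ok & !is_type1]
    )
  }
  for (v in binary) {
    g <- meta[[v]]
    if (is.factor(g)) g <- g == levels(g)[1]
    tab <- table(factor(is_type1, c(TRUE, FALSE)), factor(g, c(TRUE, FALSE)))
    type_rows[[v]] <- fishers_exact(
      tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]
    )
  }
  type_bivariate <- data.frame(
    variable = names(type_rows),
    test = vapply(type_rows, function(x) x$test_name, character(1)),
    type_I = vapply(
      type_rows,
      function(x) unname(x$group_summaries["A"]), character(1)
    ),
    type_II = vapply(
      type_rows,
      function(x) unname(x$group_summaries["B"]), character(1)
    ),
    p_value = vapply(type_rows, function(x) x$p_value, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  # regression population: dentate samples with complete periodontal data
  few_teeth <- meta$sample_id[meta$n_teeth < cfg$dentate_min_teeth]
  note(few_teeth, sprintf(
    "fewer_than_%d_teeth (regression models only)", cfg$dentate_min_teeth
  ))
  covars <- c(
    "age", "sex", "bmi", "n_teeth", "has_decayed_teeth", "pct_dft",
    "mean_ppd", "pct_bop", "plaque_index", "smoking_current"
  )
  sub <- meta[meta$n_teeth >= cfg$dentate_min_teeth, , drop = FALSE]
  incomplete <- sub$sample_id[!stats::complete.cases(sub[covars])]
  note(incomplete, "missing_periodontal_data (regression models only)")
  sub <- sub[stats::complete.cases(sub[covars]), , drop = FALSE]
  sub$sex <- sub$sex == "male" # male vs female contrast

  pd_model <- linear_regression_standardized(sub$pd, sub[covars])
  # sex excluded from the adjusted type model (no bivariate association is
  # expected for it; mirrors the published model specification)
  type_model <- poisson_prevalence_model(
    sub$type == 1, sub[setdiff(covars, "sex")]
  )

  list(
    pd_bivariate = pd_bivariate,
    type_bivariate = type_bivariate,
    pd_model = pd_model,
    type_model = type_model,
    regression_n = nrow(sub)
  )
}

#' @export
print.salitype_pipeline <- function(x, ...) {
  div <- x$diversity
  cat("Salivary microbiome stratification pipeline\n")
  full_excl <- x$exclusions$sample_id[
    !grepl("regression models only", x$exclusions$reason)
  ]
  cat(sprintf(
    "  samples analyzed: %d (%d excluded)\n",
    nrow(div), length(unique(full_excl))
  ))
  cat(sprintf(
    "  PD range: %.2f-%.2f; quintile boundaries %s\n",
    min(div$pd), max(div$pd),
    paste(format(x$quintiles$boundaries, digits = 4), collapse = ", ")
  ))
  cat(sprintf(
    "  core OTUs: %d (of %d), predominant core: %d\n",
    length(x$core$core_otus), x$n_otus_total,
    length(x$core$predominant_core)
  ))
  cat(sprintf(
    "  core fraction: %.1f ± %.1f %%\n",
    100 * mean(x$core$core_fraction), 100 * stats::sd(x$core$core_fraction)
  ))
  print(x$typing)
  print(x$network)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.salitype_pipeline <- function(object, ...) {
  print(object)
  cat("\nPD regression (standardized betas):\n")
  print(object$associations$pd_model)
  cat("\nCommunity-type prevalence-ratio model:\n")
  print(object$associations$type_model)
  invisible(object)
}

#' Write pipeline results to a directory
#'
#' Emits per-stage TSV tables (diversity profiles, quintile assignment,
#' core list with prevalence and predominant flags, quintile-shared sets,
#' typing labels with silhouette widths, CH-by-k curve, PCA scores and
#' loadings, network edge list and groups, association tables, exclusion
#' log) plus a `summary.json`.
#'
#' @param result A `salitype_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "salitype_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  tsv(result$diversity, "diversity.tsv")
  tsv(data.frame(
    sample_id = names(result$quintiles$labels),
    quintile = as.character(result$quintiles$labels)
  ), "quintiles.tsv")

  rare_prev <- otu_prevalence(attr(result$diversity, "rarefied_table"))
  core <- result$core$core_otus
  tsv(data.frame(
    otu_id = core,
    overall_prevalence = rare_prev[core],
    predominant = core %in% result$core$predominant_core
  ), "core_otus.tsv")
  shared <- result$core$shared_by_quintile
  tsv(data.frame(
    quintile = rep(names(shared), lengths(shared)),
    otu_id = unlist(shared, use.names = FALSE)
  ), "shared_by_quintile.tsv")
  tsv(data.frame(
    sample_id = names(result$core$core_fraction),
    core_fraction = result$core$core_fraction
  ), "core_fraction.tsv")

  tsv(data.frame(
    sample_id = names(result$typing$labels),
    type = result$typing$labels,
    silhouette = result$typing$silhouette_widths
  ), "typing_labels.tsv")
  tsv(data.frame(
    k = as.integer(names(result$typing$ch_by_k)),
    ch = result$typing$ch_by_k
  ), "ch_by_k.tsv")
  tsv(data.frame(
    sample_id = rownames(result$pca$scores),
    result$pca$scores[, 1:2]
  ), "pca_scores.tsv")
  tsv(data.frame(
    otu_id = rownames(result$pca$loadings),
    result$pca$loadings[, 1:2]
  ), "pca_loadings.tsv")

  tsv(result$network$edges, "network_edges.tsv")
  tsv(data.frame(
    group = rep(seq_along(result$network$groups),
      lengths(result$network$groups)
    ),
    otu_id = unlist(result$network$groups, use.names = FALSE)
  ), "network_groups.tsv")

  assoc <- result$associations
  tsv(assoc$pd_bivariate, "pd_bivariate.tsv")
  tsv(assoc$type_bivariate, "type_bivariate.tsv")
  tsv(data.frame(
    term = names(assoc$pd_model$beta),
    std_beta = assoc$pd_model$beta,
    p_value = assoc$pd_model$p_value
  ), "pd_regression.tsv")
  tsv(assoc$type_model$table, "type_regression.tsv")
  tsv(result$exclusions, "exclusions.tsv")

  jsonlite::write_json(
    list(
      n_samples = nrow(result$diversity),
      n_core = length(result$core$core_otus),
      n_predominant_core = length(result$core$predominant_core),
      mean_core_fraction = mean(result$core$core_fraction),
      k = result$typing$k,
      mean_silhouette = result$typing$mean_silhouette,
      pct_variance_pc1 = result$pca$pct_variance[1],
      pct_variance_pc2 = result$pca$pct_variance[2],
      n_network_edges = nrow(result$network$edges),
      n_cohabiting_groups = length(result$network$groups),
      adj_r_squared = assoc$pd_model$adj_r_squared,
      regression_n = assoc$regression_n
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
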