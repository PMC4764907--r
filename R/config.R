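#' Analysis configuration
#'
#' Collects the tunable constants of the pipeline. Defaults reproduce the
#' published protocol: rarefaction to 5,000 reads per sample, a 75%
#' prevalence threshold for core OTUs, a 1% mean-relative-abundance
#' threshold (in the lowest diversity quintile) for predominant-core OTUs,
#' quintile (5-group) stratification, Jensen-Shannon pseudocount 1e-6,
#' cluster numbers 2-10 scored by the Calinski-Harabasz index, a 1e-12
#' adjusted-p cutoff for co-occurrence edges, and restriction of the
#' regression models to dentate individuals with at least 9 teeth.
#'
#' @param rarefaction_depth Reads per sample after rarefaction.
#' @param prevalence_threshold Fraction of samples an OTU must be detected
#'   in to count as core.
#' @param abundance_threshold Mean relative abundance (fraction) an OTU
#'   must reach in the lowest quintile to count as predominant core.
#' @param n_quintiles Number of diversity strata.
#' @param jsd_pseudocount Zero-replacement fraction inside the JSD.
#' @param k_range Candidate cluster numbers for community typing.
#' @param edge_alpha Adjusted-p cutoff for network edges.
#' @param dentate_min_teeth Minimum tooth count for the regression models.
#' @param core_rule `"every_quintile"` (core = prevalent overall and in
#'   every quintile) or `"overall_and_q1"` (overall and lowest quintile
#'   only).
#' @param pd_on_rarefied Compute Faith's PD on rarefied counts (default)
#'   or on the raw table.
#' @param rng_seed Integer seed governing every random step.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(rarefaction_depth = 5000,
                            prevalence_threshold = 0.75,
                            abundance_threshold = 0.01,
                            n_quintiles = 5,
                            jsd_pseudocount = 1e-6,
                            k_range = 2:10,
                            edge_alpha = 1e-12,
                            dentate_min_teeth = 9,
                            core_rule = c("every_quintile", "overall_and_q1"),
                            pd_on_rarefied = TRUE,
                            rng_seed = 1L) {
  core_rule <- match.arg(core_rule)
  cfg <- list(
    rarefaction_depth = as.integer(rarefaction_depth),
    prevalence_threshold = prevalence_threshold,
    abundance_threshold = abundance_threshold,
    n_quintiles = as.integer(n_quintiles),
    jsd_pseudocount = jsd_pseudocount,
    k_range = as.integer(k_range),
    edge_alpha = edge_alpha,
    dentate_min_teeth = as.integer(dentate_min_teeth),
    core_rule = core_rule,
    pd_on_rarefied = isTRUE(pd_on_rarefied),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$rarefaction_depth > 0,
    cfg$prevalence_threshold > 0, cfg$prevalence_threshold < 1,
    cfg$abundance_threshold > 0, cfg$abundance_threshold < 1,
    cfg$jsd_pseudocount > 0, cfg$jsd_pseudocount < 1,
    cfg$edge_alpha > 0, cfg$edge_alpha < 1,
    cfg$n_quintiles >= 2,
    min(cfg$k_range) >= 2
  )
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [analysis_config()] defaults.
#'
#' @param path Path to a YAML file whose keys mirror [analysis_config()]
#'   arguments.
#' @return An `analysis_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf(
      "  %-21s %s\n", nm,
      paste(format(x[[nm]]), collapse = " ")
    ))
  }
  invisible(x)
}
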