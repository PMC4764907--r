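# Ground-truth simulator: a two-community-type Dirichlet-multinomial
# population with a planted core/rare prevalence hierarchy and
# covariate-linked diversity, mirroring the structure the analysis stages
# are designed to detect.

#' Simulation parameters
#'
#' Defaults emulate a population-scale salivary 16S survey: 500 samples
#' over 300 OTUs, of which 22 are predominant-core (split into two
#' cohabiting blocks of 13 and 9 that define community types I and II),
#' 50 further core OTUs at 95% inclusion prevalence, and 228 rare OTUs at
#' 20% baseline inclusion. A sample's own block's base abundances are
#' multiplied by `block_contrast` (3). Compositions are drawn from a
#' Dirichlet with a single concentration scalar and counts from a
#' multinomial at a lognormal read depth centered on 14,000 reads.
#' Rare-OTU inclusion is tied to oral-condition covariates
#' (`diversity_link`: more teeth, more plaque, deeper pockets, more
#' bleeding and current smoking all raise diversity) and type-I
#' membership is tied to age, BMI, caries experience and smoking
#' (`metadata_link`), reproducing the direction of the published
#' association tables.
#'
#' @param n_samples Number of samples.
#' @param n_block_i,n_block_ii Predominant-core OTUs in cohabiting blocks
#'   I and II.
#' @param n_core_other Non-predominant core OTUs.
#' @param n_rare Rare OTUs.
#' @param type_probability Baseline probability of community type I.
#' @param dirichlet_concentration Dirichlet concentration scalar (larger =
#'   less compositional noise within a type).
#' @param block_contrast Multiplier applied to a sample's own block's base
#'   abundances.
#' @param core_prevalence Per-sample inclusion probability of
#'   non-predominant core OTUs.
#' @param rare_prevalence Baseline inclusion probability of rare OTUs.
#' @param predominant_weight,core_other_weight,rare_weight Unnormalized
#'   base abundance per OTU of each tier.
#' @param depth_log_mean,depth_log_sd Lognormal read-depth parameters;
#'   defaults give depths near 14,000 with essentially no mass below
#'   5,000.
#' @param diversity_link Named coefficients (logit scale, standardized
#'   covariates) shifting rare-OTU inclusion.
#' @param metadata_link Named coefficients (logit scale) shifting type-I
#'   membership.
#' @param prob_antibiotics Probability a sample is an antibiotics user.
#' @param prob_missing_periodontal Probability the periodontal fields are
#'   recorded as missing.
#' @param seed Default seed used by [simulate_dataset()].
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_samples = 500,
                              n_block_i = 13,
                              n_block_ii = 9,
                              n_core_other = 50,
                              n_rare = 228,
                              type_probability = 0.5,
                              dirichlet_concentration = 500,
                              block_contrast = 3,
                              core_prevalence = 0.95,
                              rare_prevalence = 0.2,
                              predominant_weight = 0.025,
                              core_other_weight = 0.008,
                              rare_weight = 0.003,
                              depth_log_mean = log(14000),
                              depth_log_sd = 0.2,
                              diversity_link = c(
                                n_teeth = 0.3, plaque_index = 0.3,
                                mean_ppd = 0.3, pct_bop = 0.3,
                                smoking_current = 0.5
                              ),
                              metadata_link = c(
                                age = 0.4, bmi = 0.4, pct_dft = 0.4,
                                smoking_current = 0.8
                              ),
                              prob_antibiotics = 0.002,
                              prob_missing_periodontal = 0.001,
                              seed = 1L) {
  p <- list(
    n_samples = as.integer(n_samples),
    n_block_i = as.integer(n_block_i),
    n_block_ii = as.integer(n_block_ii),
    n_core_other = as.integer(n_core_other),
    n_rare = as.integer(n_rare),
    type_probability = type_probability,
    dirichlet_concentration = dirichlet_concentration,
    block_contrast = block_contrast,
    core_prevalence = core_prevalence,
    rare_prevalence = rare_prevalence,
    predominant_weight = predominant_weight,
    core_other_weight = core_other_weight,
    rare_weight = rare_weight,
    depth_log_mean = depth_log_mean,
    depth_log_sd = depth_log_sd,
    diversity_link = diversity_link,
    metadata_link = metadata_link,
    prob_antibiotics = prob_antibiotics,
    prob_missing_periodontal = prob_missing_periodontal,
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_samples >= 1,
    p$n_block_i + p$n_block_ii >= 1,
    p$type_probability > 0, p$type_probability < 1,
    p$dirichlet_concentration > 0,
    p$block_contrast >= 1,
    p$core_prevalence > 0, p$core_prevalence <= 1,
    p$rare_prevalence >= 0, p$rare_prevalence <= 1,
    p$predominant_weight > 0
  )
  structure(p, class = "simulation_params")
}

# OTU id layout and tier membership implied by the parameters.
otu_layout <- function(params) {
  n <- params$n_block_i + params$n_block_ii + params$n_core_other +
    params$n_rare
  ids <- sprintf("OTU_%03d", seq_len(n))
  tier <- rep(
    c("block_I", "block_II", "core_other", "rare"),
    c(
      params$n_block_i, params$n_block_ii, params$n_core_other,
      params$n_rare
    )
  )
  list(ids = ids, tier = tier, n = n)
}

# Per-type base weight vectors (unnormalized; normalization happens over
# each sample's included set).
base_weights <- function(params) {
  layout <- otu_layout(params)
  w <- numeric(layout$n)
  w[layout$tier %in% c("block_I", "block_II")] <- params$predominant_weight
  w[layout$tier == "core_other"] <- params$core_other_weight
  w[layout$tier == "rare"] <- params$rare_weight
  w_i <- w
  w_i[layout$tier == "block_I"] <-
    w_i[layout$tier == "block_I"] * params$block_contrast
  w_ii <- w
  w_ii[layout$tier == "block_II"] <-
    w_ii[layout$tier == "block_II"] * params$block_contrast
  list(
    type_I = stats::setNames(w_i, layout$ids),
    type_II = stats::setNames(w_ii, layout$ids)
  )
}

#' Simulate a random phylogeny for the OTU pool
#'
#' Yule (pure-birth) topology with independent exponential(1) branch
#' lengths, leaves labeled `OTU_001..OTU_n`; stands in for a 16S gene
#' tree.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return A rooted [ape::phylo] tree.
#' @export
simulate_tree <- function(n_leaves, seed = 1L) {
  stopifnot(n_leaves >= 2)
  with_seed(seed, {
    tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1)
    tr$tip.label <- sprintf("OTU_%03d", seq_len(n_leaves))
    tr
  })
}

# z-scores against the generator's own location/scale constants, so link
# coefficients are per-SD effects.
covariate_z <- function(meta_raw) {
  list(
    age = (meta_raw$age - 63) / 11,
    bmi = (meta_raw$bmi - 23.2) / 3.4,
    n_teeth = (meta_raw$n_teeth - 21.6) / 8,
    pct_dft = (meta_raw$pct_dft - 63) / 23,
    mean_ppd = (meta_raw$mean_ppd - 1.84) / 0.63,
    pct_bop = (meta_raw$pct_bop - 18.6) / 20,
    plaque_index = (meta_raw$plaque_index - 0.68) / 0.6,
    smoking_current = as.numeric(meta_raw$smoking == "current") - 0.15
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw raw covariates for n samples (before any missingness masking).
draw_metadata_raw <- function(n) {
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = clamp(stats::rnorm(n, 63, 11), 40, 95),
    sex = ifelse(stats::runif(n) < 0.56, "female", "male"),
    bmi = clamp(stats::rnorm(n, 23.2, 3.4), 14, 45),
    n_teeth = as.integer(clamp(round(stats::rnorm(n, 21.6, 8)), 0, 28)),
    has_decayed_teeth = stats::runif(n) < 0.3,
    pct_dft = clamp(stats::rnorm(n, 63, 23), 0, 100),
    mean_ppd = clamp(stats::rnorm(n, 1.84, 0.63), 0.5, 10),
    pct_bop = clamp(stats::rnorm(n, 18.6, 20), 0, 100),
    plaque_index = clamp(stats::rnorm(n, 0.68, 0.6), 0, 3),
    smoking = sample(c("never", "past", "current"), n,
      replace = TRUE, prob = c(0.60, 0.25, 0.15)
    ),
    stringsAsFactors = FALSE
  )
}

# Linear predictor from named link coefficients and the z-score list.
link_shift <- function(link, z, i) {
  s <- 0
  for (nm in names(link)) s <- s + link[[nm]] * z[[nm]][i]
  s
}

#' Simulate one sample's count vector
#'
#' Given the sample's community type and covariates: (1) the base
#' composition is the predominant-core means with the sample's own block
#' multiplied by `block_contrast`; (2) each non-predominant core OTU is
#' included with probability `core_prevalence` and each rare OTU with a
#' probability shifted from `rare_prevalence` on the logit scale by
#' `diversity_link`; (3) a composition is drawn from
#' `Dirichlet(concentration * base)` restricted to the included set; (4)
#' counts are multinomial at a lognormal depth.
#'
#' @param params A [simulation_params] object.
#' @param sample_index Sample number (used in error messages).
#' @param type Community type, `"I"` or `"II"`.
#' @param rare_logit_shift Shift added to `qlogis(rare_prevalence)`.
#' @param seed Optional seed (draws from the current stream when `NULL`,
#'   as [simulate_dataset()] does).
#' @return A list with `counts` (named integer vector), `included`
#'   (logical vector), `depth`.
#' @export
simulate_sample <- function(params, sample_index = 1L, type = c("I", "II"),
                            rare_logit_shift = 0, seed = NULL) {
  type <- match.arg(type)
  layout <- otu_layout(params)
  w <- base_weights(params)[[if (type == "I") "type_I" else "type_II"]]
  with_seed(seed, {
    p_rare <- stats::plogis(
      stats::qlogis(max(params$rare_prevalence, 1e-12)) + rare_logit_shift
    )
    if (params$rare_prevalence == 0) p_rare <- 0
    for (attempt in 1:10) {
      included <- layout$tier %in% c("block_I", "block_II") |
        (layout$tier == "core_other" &
          stats::runif(layout$n) < params$core_prevalence) |
        (layout$tier == "rare" & stats::runif(layout$n) < p_rare)
      if (any(included)) break
      if (attempt == 10) {
        stop("sample ", sample_index,
          ": could not draw a non-empty OTU set",
          call. = FALSE
        )
      }
    }
    base <- w * included
    base <- base / sum(base)
    shape <- params$dirichlet_concentration * base[included]
    g <- stats::rgamma(length(shape), shape = shape, rate = 1)
    if (sum(g) == 0) g[which.max(shape)] <- 1 # numerically degenerate draw
    comp <- numeric(layout$n)
    comp[included] <- g / sum(g)
    depth <- max(1L, as.integer(round(stats::rlnorm(
      1, params$depth_log_mean, params$depth_log_sd
    ))))
    counts <- as.integer(stats::rmultinom(1, depth, comp))
    names(counts) <- layout$ids
    list(counts = counts, included = included, depth = depth)
  })
}

#' Simulate a complete ground-truth dataset
#'
#' Draws covariates, assigns community types via `metadata_link`,
#' generates every sample with [simulate_sample()] (rare-OTU inclusion
#' shifted by `diversity_link`), and builds a Yule phylogeny over the OTU
#' pool. The returned truth records everything the analysis stages try to
#' recover.
#'
#' @param params A [simulation_params] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A `salitype_simulation` list: `table` ([otu_table]), `tree`
#'   ([ape::phylo]), `metadata` ([sample_metadata]), `truth` (list with
#'   `type` per sample, `included` matrix, `tier` per OTU, `base_weights`,
#'   `params`).
#' @export
simulate_dataset <- function(params = simulation_params(),
                             seed = params$seed) {
  layout <- otu_layout(params)
  n <- params$n_samples
  with_seed(seed, {
    meta_raw <- draw_metadata_raw(n)
    z <- covariate_z(meta_raw)
    type_shift <- vapply(
      seq_len(n), function(i) link_shift(params$metadata_link, z, i),
      numeric(1)
    )
    p_type <- stats::plogis(
      stats::qlogis(params$type_probability) + type_shift
    )
    type <- ifelse(stats::runif(n) < p_type, "I", "II")
    rare_shift <- vapply(
      seq_len(n), function(i) link_shift(params$diversity_link, z, i),
      numeric(1)
    )
    counts <- matrix(0L, n, layout$n,
      dimnames = list(meta_raw$sample_id, layout$ids)
    )
    included <- matrix(FALSE, n, layout$n,
      dimnames = dimnames(counts)
    )
    for (i in seq_len(n)) {
      s <- simulate_sample(params, i,
        type = type[i],
        rare_logit_shift = rare_shift[i]
      )
      counts[i, ] <- s$counts
      included[i, ] <- s$included
    }
    meta_raw$antibiotics_use <- stats::runif(n) < params$prob_antibiotics
    miss <- stats::runif(n) < params$prob_missing_periodontal
    meta_raw[miss, periodontal_columns] <- NA
    metadata <- sample_metadata(meta_raw)
    tree <- simulate_tree(max(layout$n, 2), derive_seed(seed, "tree"))
    structure(
      list(
        table = otu_table(counts),
        tree = tree,
        metadata = metadata,
        truth = list(
          type = stats::setNames(type, meta_raw$sample_id),
          included = included,
          tier = stats::setNames(layout$tier, layout$ids),
          base_weights = base_weights(params),
          type_probability = p_type,
          params = params
        )
      ),
      class = "salitype_simulation"
    )
  })
}

#' @export
print.salitype_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d samples x %d OTUs (type I fraction %.2f)\n",
    nrow(x$table), ncol(x$table), mean(x$truth$type == "I")
  ))
  invisible(x)
}
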