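---
title: "Methods: diversity stratification and community typing of salivary microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity stratification and community typing of salivary microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salitype)
```

## The analysis and its assumptions

Population-scale 16S rRNA surveys of saliva show two complementary axes
of between-person variation: *how many* lineages a person carries
(alpha diversity, dominated by minority taxa), and *in what proportions*
the universally shared dominant taxa occur (community types). `salitype`
implements both axes as one pipeline over a sample-by-OTU count table, a
rooted OTU phylogeny, and clinical covariates.

The pipeline assumes counts are comparable only after rarefaction to a
common depth, that detection ("present") means at least one read in the
rarefied table, and that the tree's branch lengths are meaningful
divergence units. It makes no distributional assumption about the
abundance profiles themselves: typing is distance-based
(Jensen–Shannon), and the only parametric models are the two regression
layers at the end.

### Alpha diversity

Rarefaction is an exact multivariate-hypergeometric draw (sequential
conditional hypergeometric sampling), once per sample, with the
per-sample seed derived deterministically from the global seed and the
sample id — so results are independent of sample order and reproducible
bit-for-bit. `rarefaction_curve()` exists separately and returns the
analytic expectation
$E[S(d)] = \sum_i \left(1 - \binom{N - n_i}{d}\big/\binom{N}{d}\right)$,
optionally with Monte-Carlo means.

Faith's PD is the sum of branch lengths of the minimal subtree
connecting the sample's OTUs *and the root*. The root-inclusive
convention is the default because it matches the standard `picante::pd`
behavior (tested against it); `include_root = FALSE` gives the
MRCA-spanning variant. Diversity (including PD) is computed on the
rarefied table by default — whether to use raw counts for PD is
genuinely open, so a flag (`pd_on_rarefied`) exposes the alternative;
rarefied is the default because all detection-based statistics downstream
use the rarefied table and consistency trumps the marginal information
loss.

### Quintiles and the core microbiome

Samples are rank-split into `n_quintiles = 5` near-equal groups ordered
by PD; ties break by sample id, extra samples go to the lower groups,
and boundaries are reported as the minimum PD of each upper group (the
half-open display convention `cut ≤ PD < cut'`). Two published phrasings
of the core rule differ subtly — prevalent overall *and in every
quintile*, versus overall *and in the lowest quintile* only. Both are
implemented (`core_rule`); the stricter every-quintile rule is the
default since it is the description attached to the main result, and the
two coincide whenever detection rates rise with the diversity stratum.
The predominant core applies the ≥ 1% mean-relative-abundance filter
within Q1, the least diverse stratum, where shared taxa dominate most.

### Community typing

Distances are $\sqrt{\mathrm{JSD}(p, q)}$ with natural-log KLD,
computed after replacing zeros with a pseudocount (default $10^{-6}$)
and renormalizing each profile *inside* the distance computation. The
profiles handed to the metric are relative to the whole community, not
renormalized over the 22-OTU subset: the pseudocount protocol performs
the renormalization anyway, and keeping whole-community values preserves
the interpretation of the PCA loadings. The square root makes the
divergence a metric (bounded by $\sqrt{\ln 2}$), which PAM and the
silhouette assume.

PAM is implemented as greedy BUILD followed by steepest-descent SWAP,
with all ties broken toward the lowest sample index — fully
deterministic, no random restarts (the `seed` argument exists only for
calling-convention symmetry). Like any deterministic local search, it
can stop at a non-global optimum; on unstructured random instances this
happens for roughly 8% of tiny problems (the reference `cluster::pam`
behaves identically there), while on separated data it reliably attains
the optimum. Tests assert the attainable properties: never better than
the exhaustive optimum, exhaustive-optimal on separated instances,
agreement with `cluster::pam`.

The number of types maximizes the Calinski–Harabasz index in its
distance-matrix variant: centrotypes are medoids under *squared*
distances, $W$ sums squared distances to cluster medoids and $B$ sums
size-weighted squared medoid-to-global-medoid distances, with
$\mathrm{CH} = (B/(k-1))/(W/(n-k))$; `Inf` is returned when $W = 0$.
Ties in the CH curve go to the smaller $k$. The silhouette is computed
on the JSD scale (not squared); this is a judgment call — the squared
scale would shrink widths — and the JSD scale is the default because the
clustering itself optimizes unsquared deviations. Singleton clusters
score 0 by convention. PCA standardizes columns (correlation-matrix
eigendecomposition) and fixes each component's sign so its
largest-magnitude loading is positive.

### Co-occurrence network

Plain Pearson correlation on raw relative abundances (deliberately no
CLR or logit transform; transformed profiles can simply be passed in
instead), $p$ from the
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ statistic, Benjamini–Hochberg adjustment
over all $\binom{22}{2} = 231$ pairs at survey scale, and edges for
$r > 0$ with adjusted $p$ below `edge_alpha` ($10^{-12}$ by default).
Cohabiting groups are connected components with at least two members —
the simplest rule consistent with displaying groups as connected
clusters; no community-detection algorithm is imposed.

### Association layer

"Student's *t*" is the pooled-variance test (Welch by flag);
Fisher's exact test uses the probability-based two-sided rule (sum of
conditional-hypergeometric probabilities no larger than the observed
table's). The PD model is OLS on z-scored response and predictors, so
coefficients are standardized β; binary predictors are standardized too
by default (flag `standardize_binary`), matching an all-standardized
coefficient table. The community-type model is a modified Poisson
regression — Poisson-family GLM with log link on the 0/1 type indicator,
IRLS to relative deviance change below $10^{-8}$, at most 100
iterations — whose exponentiated coefficients are *prevalence ratios*
(the field sometimes prints them as "odds ratios"; the package says
ratio). Model-based standard errors are the default, sandwich SEs by
flag; both regressions are restricted to dentate samples
(`dentate_min_teeth = 9`) with complete periodontal data, and sex is
omitted from the adjusted type model, reproducing the published model
specification. Whether edentulous individuals belong in the *typing*
population is open; the default keeps all samples for typing and
restricts only the regressions, since typing needs no dental covariates.

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates the structure the pipeline is designed to
detect, with every choice fixed up front:

* **Scale.** 500 samples, 300 OTUs, lognormal read depth centered on
  14,000 (sd 0.2 on the log scale), echoing per-sample depths of
  population surveys while staying desk-sized. All recovery experiments
  in the test suite run at this scale over 100 seeds (50 for the
  negative control); the vignette's numbers and the acceptance script
  use the same defaults.
* **Tiers.** 22 predominant-core OTUs split into cohabiting blocks of 13
  and 9; 50 further core OTUs included per sample with probability 0.95;
  228 rare OTUs at baseline inclusion 0.2. Base weights are equal within
  tiers (0.025 / 0.008 / 0.003), chosen so the realized tier shares
  match survey experience: the predominant core carries roughly
  two-thirds of each microbiome and the full core roughly 90%.
* **Types.** A sample's own block's weights are multiplied by
  `block_contrast = 3` and the composition is drawn from a Dirichlet
  with concentration 500 times the normalized base. The concentration is
  deliberately on the low-dispersion side: it keeps per-sample inclusion
  essentially equal to detection (a core OTU included in a sample is
  seen in its reads with probability ≈ 0.996 at depth 5,000), so the
  planted prevalence tiers are what the detection-based core rules see.
  The cost is realism in cluster sharpness — simulated typings separate
  almost perfectly (silhouette ≈ 0.66), whereas real salivary profiles
  are nearly continuous (published mean silhouette 0.19). Passing the
  recovery tests therefore demonstrates correctness of the machinery,
  not that real data yield clean types.
* **Links.** Rare-OTU inclusion (hence PD) rises with teeth, plaque,
  pocket depth, bleeding and current smoking (logit coefficients 0.3,
  smoking 0.5, per SD); type-I membership rises with age, BMI, caries
  experience and smoking (0.4, smoking 0.8). Directions mirror the
  published association tables; magnitudes were fixed a priori so that
  sign recovery at n = 500 has comfortable power (planted standardized
  effects are several times their standard errors).
* **Not modeled.** Phylogenetic correlation of abundances (the tree is
  an independent Yule tree with exponential branch lengths, so PD is in
  arbitrary units); taxon-specific dispersion (one concentration
  scalar); ranked within-tier abundance distributions; longitudinal
  structure; sequencing artifacts. Consequently the simulator cannot
  probe compositional-correlation biases of the Pearson network or the
  behavior of CH selection on continuous (untyped) variation beyond the
  `block_contrast = 1` negative control.

## Numerical choices

Zero replacement in the JSD uses the pseudocount before renormalization;
rarefaction uses `rhyper` sequentially (exact, O(#OTUs)); expected
rarefaction curves use `lchoose` to avoid overflow at survey-scale read
counts. Degenerate cases are explicit: empty samples error in
`shannon_index` and `relative_abundance`; a zero within-cluster sum of
squares returns an `Inf` CH sentinel; zero-variance columns error in PCA
and the correlation tests; a two-sample *t* on two constant equal groups
returns *p* = 1 (unequal, *p* = 0); Poisson fits that fail to converge
or receive a constant outcome error rather than returning estimates.
PAM label numbering is arbitrary — recovery metrics (Rand index,
majority-vote orientation) are label-permutation invariant, and ratio
directions in the type model should be interpreted only after orienting
labels against an external reference.

## Worked sizes and limitations

A full default pipeline (500 samples × 300 OTUs, k = 2…10) runs in
under a second after simulation; the complete 100-seed recovery
experiment takes about two minutes. Known limitations: the core rules
are prevalence-threshold rules, sensitive to depth through detection;
PAM is a local search (see above); the Poisson prevalence-ratio model
with model-based SEs is mildly conservative compared to sandwich SEs;
and the simulator's cleanliness means silhouette and CH values on
simulated data should not be compared numerically with values from real
surveys.
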