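# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions never
#' disturb the caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a character id (polynomial rolling hash).
# Used to derive per-sample seeds from (global seed, sample id).
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (v in utf8ToInt(x)) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

# Per-sample seed from a global seed and a sample id; stays below 2^31.
derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + string_hash(id)) %%
    2147483647)
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two labelings agree (both together or
#' both apart). Used to score recovery of planted community types; 1 means
#' identical partitions up to label permutation.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

# Format "mean +/- sd" summaries used in group tables.
mean_sd_label <- function(x, digits = 2) {
  sprintf(
    "%s ± %s",
    format(round(mean(x), digits), nsmall = digits),
    format(round(stats::sd(x), digits), nsmall = digits)
  )
}
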