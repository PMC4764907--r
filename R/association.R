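# Bivariate tests and multivariate models linking diversity and community
# type to oral-health covariates.

bivariate_result <- function(test_name, statistic, p_value, effect,
                             group_summaries = NULL) {
  structure(
    list(
      test_name = test_name, statistic = statistic, p_value = p_value,
      effect = effect, group_summaries = group_summaries
    ),
    class = "bivariate_test"
  )
}

#' @export
print.bivariate_test <- function(x, ...) {
  cat(sprintf(
    "%s: statistic = %.4g, p = %.3g, effect = %.4g\n",
    x$test_name, x$statistic, x$p_value, x$effect
  ))
  invisible(x)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical equal-variance t-test on `n_A + n_B - 2` degrees of freedom
#' (Welch's correction available via `var_equal = FALSE`). Degenerate
#' zero-variance inputs return p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A `bivariate_test` with effect = mean difference `x - y` and
#'   per-group mean/sd summaries.
#' @export
student_t_test <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(bivariate_result(
      "student_t",
      statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      p_value = if (same) 1 else 0,
      effect = mean(x) - mean(y),
      group_summaries = c(A = mean_sd_label(x), B = mean_sd_label(y))
    ))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  bivariate_result(
    if (var_equal) "student_t" else "welch_t",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    effect = mean(x) - mean(y),
    group_summaries = c(A = mean_sd_label(x), B = mean_sd_label(y))
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by full enumeration of the conditional
#' hypergeometric distribution with both margins fixed: the sum of the
#' probabilities of all tables no more probable than the observed one
#' (the probability-based two-sided rule). The effect is the sample odds
#' ratio `(a * d) / (b * c)`.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups,
#'   columns = outcome: table `rbind(c(a, b), c(c, d))`.
#' @return A `bivariate_test` with effect = sample odds ratio.
#' @export
fishers_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  col2 <- b + d
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    stop("empty margin in 2x2 table", call. = FALSE)
  }
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- stats::dhyper(support, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  bivariate_result(
    "fisher_exact",
    statistic = p_obs, p_value = p, effect = or,
    group_summaries = c(
      A = sprintf("%d/%d (%.1f%%)", a, row1, 100 * a / row1),
      B = sprintf("%d/%d (%.1f%%)", c, row2, 100 * c / row2)
    )
  )
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return A `bivariate_test` with effect = r.
#' @export
pearson_cor_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input to correlation test", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  bivariate_result(
    "pearson_cor",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    effect = unname(ht$estimate)
  )
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares on the z-scored response and z-scored
#' predictors, so each coefficient is a standardized beta (change in
#' response SDs per predictor SD). Binary/dummy predictors are z-scored
#' too by default, matching an all-standardized coefficient table; set
#' `standardize_binary = FALSE` to leave two-valued columns on their raw
#' scale.
#'
#' @param response Numeric vector.
#' @param covariates data.frame of numeric/logical/factor predictors
#'   (factors are expanded to treatment dummies first).
#' @param standardize_binary Standardize two-valued columns (default
#'   `TRUE`).
#' @return A `std_lm` object: `beta` (standardized), `p_value`,
#'   `r_squared`, `adj_r_squared`, `n`, and the underlying `fit`.
#' @export
linear_regression_standardized <- function(response, covariates,
                                           standardize_binary = TRUE) {
  stopifnot(nrow(covariates) == length(response))
  X <- expand_design(covariates)
  n <- length(response)
  if (n <= ncol(X) + 1) {
    stop("more model terms than samples allow", call. = FALSE)
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop("rank-deficient design; collinear terms: ",
      paste(colnames(X)[dropped], collapse = ", "),
      call. = FALSE
    )
  }
  z <- function(v) (v - mean(v)) / stats::sd(v)
  Xs <- X
  for (j in seq_len(ncol(X))) {
    two_valued <- length(unique(X[, j])) == 2
    if (standardize_binary || !two_valued) Xs[, j] <- z(X[, j])
  }
  dat <- data.frame(.y = z(response), Xs, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  coefs <- sm$coefficients[-1, , drop = FALSE]
  structure(
    list(
      beta = stats::setNames(coefs[, 1], rownames(coefs)),
      p_value = stats::setNames(coefs[, 4], rownames(coefs)),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      n = n,
      fit = fit
    ),
    class = "std_lm"
  )
}

#' @export
print.std_lm <- function(x, ...) {
  cat(sprintf(
    "Standardized multiple regression (n = %d, adjusted R^2 = %.2f)\n",
    x$n, x$adj_r_squared
  ))
  print(data.frame(
    std_beta = round(x$beta, 3),
    p_value = signif(x$p_value, 2)
  ))
  invisible(x)
}

# Expand a covariate data.frame to a numeric design matrix: logicals to
# 0/1, factors to treatment dummies, numerics as-is.
expand_design <- function(covariates) {
  covariates <- as.data.frame(covariates)
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.logical(v)) {
      cols[[nm]] <- as.numeric(v)
    } else if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      for (lev in levels(v)[-1]) {
        cols[[paste0(nm, "_", lev)]] <- as.numeric(v == lev)
      }
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(covariates)
  X
}

#' Modified Poisson regression for a binary outcome (prevalence ratios)
#'
#' Generalized linear model with Poisson family and log link fitted to a
#' 0/1 outcome by iteratively reweighted least squares; the exponentiated
#' coefficients are prevalence ratios. Model-based 95% confidence
#' intervals `exp(coef +/- 1.96 * SE)` are reported by default; sandwich
#' (robust) standard errors, the usual companion of the modified Poisson
#' estimator, are available with `robust = TRUE`. Crude (single-covariate)
#' ratios are fitted alongside the adjusted model.
#'
#' @param outcome 0/1 (or logical) vector.
#' @param covariates data.frame of predictors (see
#'   [linear_regression_standardized()] for type handling).
#' @param robust Use sandwich standard errors (requires the sandwich
#'   package).
#' @return A `prevalence_model` object with a `table` data.frame (`term`,
#'   `crude_ratio`, `crude_lo`, `crude_hi`, `adj_ratio`, `adj_lo`,
#'   `adj_hi`, `adj_p`), the adjusted `fit`, and `n`.
#' @export
poisson_prevalence_model <- function(outcome, covariates, robust = FALSE) {
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)), nrow(covariates) == length(outcome))
  if (all(outcome == 0) || all(outcome == 1)) {
    stop("degenerate outcome: no variation between the two types",
      call. = FALSE
    )
  }
  X <- expand_design(covariates)
  zero_var <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(zero_var)) {
    stop("zero-variance term(s): ",
      paste(colnames(X)[zero_var], collapse = ", "),
      call. = FALSE
    )
  }
  fit_one <- function(Xsub) {
    dat <- data.frame(.y = outcome, Xsub, check.names = FALSE)
    fit <- stats::glm(.y ~ .,
      data = dat, family = stats::poisson(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    )
    if (!fit$converged) {
      stop("Poisson fit did not converge within 100 IRLS iterations",
        call. = FALSE
      )
    }
    fit
  }
  fit <- fit_one(X)
  se <- if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      stop("robust = TRUE requires the 'sandwich' package", call. = FALSE)
    }
    sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))
  } else {
    sqrt(diag(stats::vcov(fit)))
  }
  co <- stats::coef(fit)
  zstat <- co / se
  pvals <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  terms <- names(co)[-1]
  crude <- t(vapply(colnames(X), function(nm) {
    f <- fit_one(X[, nm, drop = FALSE])
    cc <- stats::coef(f)[2]
    ss <- sqrt(stats::vcov(f)[2, 2])
    c(exp(cc), exp(cc - 1.96 * ss), exp(cc + 1.96 * ss))
  }, numeric(3)))
  tab <- data.frame(
    term = terms,
    crude_ratio = crude[, 1], crude_lo = crude[, 2], crude_hi = crude[, 3],
    adj_ratio = exp(co[-1]),
    adj_lo = exp(co[-1] - 1.96 * se[-1]),
    adj_hi = exp(co[-1] + 1.96 * se[-1]),
    adj_p = pvals[-1],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, fit = fit, n = length(outcome), robust = robust),
    class = "prevalence_model"
  )
}

#' @export
print.prevalence_model <- function(x, ...) {
  cat(sprintf(
    "Poisson prevalence-ratio model (n = %d, %s SEs)\n", x$n,
    if (x$robust) "sandwich" else "model-based"
  ))
  tab <- x$table
  out <- data.frame(
    term = tab$term,
    crude = sprintf(
      "%.2f (%.2f-%.2f)", tab$crude_ratio, tab$crude_lo, tab$crude_hi
    ),
    adjusted = sprintf(
      "%.2f (%.2f-%.2f)", tab$adj_ratio, tab$adj_lo, tab$adj_hi
    ),
    p = signif(tab$adj_p, 2)
  )
  print(out, row.names = FALSE)
  invisible(x)
}
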