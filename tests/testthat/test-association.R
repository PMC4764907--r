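test_that("pooled t-test matches the hand formula and handles degenerate input", {
  r <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand evaluation for (1,2,3) vs (4,5,6): pooled sd = 1, se = sqrt(2/3)
  r <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  t_hand <- (2 - 5) / (1 * sqrt(1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$p_value, 2 * stats::pt(abs(t_hand), 4, lower.tail = FALSE))
  expect_equal(r$effect, -3)

  # order invariance up to the sign of t
  r2 <- student_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)

  # zero-variance sentinel cases
  expect_equal(student_t_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(student_t_test(c(2, 2), c(3, 3))$p_value, 0)
})

test_that("Fisher's exact test equals the enumeration oracle and fisher.test", {
  r <- fishers_exact(5, 5, 3, 3) # identical proportions
  expect_equal(r$p_value, 1)

  # (3,0,0,3): 4 possible tables with both margins (3,3); enumerate by hand
  r <- fishers_exact(3, 0, 0, 3)
  probs <- choose(3, 0:3) * choose(3, 3 - (0:3)) / choose(6, 3)
  p_obs <- probs[4]
  expect_equal(r$p_value, sum(probs[probs <= p_obs]))
  expect_equal(r$p_value, 2 / 20)

  # transposition invariance
  expect_equal(
    fishers_exact(7, 2, 3, 8)$p_value,
    fishers_exact(7, 3, 2, 8)$p_value
  )
  expect_error(fishers_exact(0, 0, 2, 3), "empty margin")

  set.seed(23)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(8:30, 1), rep(0.25, 4)))
    if (any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
      any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) {
      next
    }
    mine <- fishers_exact(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("standardized betas equal the raw-coefficient scaling identity", {
  set.seed(17)
  n <- 80
  covars <- data.frame(
    x1 = rnorm(n), x2 = rnorm(n), flag = rnorm(n) > 0
  )
  y <- 1 + 0.5 * covars$x1 - 0.3 * covars$x2 +
    0.8 * covars$flag + rnorm(n)
  fit <- linear_regression_standardized(y, covars)
  raw <- stats::lm(
    y ~ x1 + x2 + flag,
    data = transform(covars, flag = as.numeric(flag))
  )
  for (term in c("x1", "x2", "flag")) {
    x <- as.numeric(covars[[term]])
    expect_equal(
      unname(fit$beta[term]),
      unname(stats::coef(raw)[term]) * stats::sd(x) / stats::sd(y),
      tolerance = 1e-10
    )
  }
  expect_equal(fit$adj_r_squared, summary(raw)$adj.r.squared)
  # permuting covariate order changes nothing
  fit2 <- linear_regression_standardized(y, covars[, c(3, 1, 2)])
  expect_equal(fit2$beta[names(fit$beta)], fit$beta)

  # y = x exactly (perfect fit warning from summary.lm is expected)
  fit3 <- suppressWarnings(
    linear_regression_standardized(1:10, data.frame(x = 1:10))
  )
  expect_equal(unname(fit3$beta), 1)
  expect_equal(fit3$adj_r_squared, 1)

  # collinear design is reported
  expect_error(
    linear_regression_standardized(y, transform(covars, x3 = x1 * 2)),
    "collinear"
  )
})

test_that("standardized-coefficient recovery on simulated designs", {
  set.seed(29)
  hits <- 0
  n_rep <- 40
  for (i in 1:n_rep) {
    n <- 2000
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    y <- 0.3 * x1 - 0.2 * x2 + rnorm(n, sd = sqrt(1 - 0.3^2 - 0.2^2))
    fit <- linear_regression_standardized(y, data.frame(x1, x2))
    se <- sqrt(1 / n) # approximate SE of a standardized beta
    if (abs(fit$beta["x1"] - 0.3) < 2 * se && abs(fit$beta["x2"] + 0.2) < 2 * se) {
      hits <- hits + 1
    }
  }
  # each coefficient lands within 2 SE ~95% of the time; jointly ~90%
  expect_gte(hits, n_rep * 0.8)
})

test_that("Poisson prevalence ratios reduce to the closed-form rate ratio", {
  set.seed(41)
  for (i in 1:10) {
    n <- 400
    x <- rbinom(n, 1, 0.5)
    p <- ifelse(x == 1, 0.66, 0.4546)
    y <- rbinom(n, 1, p)
    if (length(unique(y[x == 1])) < 2 || length(unique(y[x == 0])) < 2) next
    fit <- poisson_prevalence_model(y, data.frame(x = x))
    ratio_closed <- mean(y[x == 1]) / mean(y[x == 0])
    expect_equal(fit$table$adj_ratio, ratio_closed, tolerance = 1e-6)
    expect_equal(fit$table$crude_ratio, ratio_closed, tolerance = 1e-6)
    expect_true(fit$table$adj_lo <= fit$table$adj_ratio)
    expect_true(fit$table$adj_hi >= fit$table$adj_ratio)
  }
  expect_error(
    poisson_prevalence_model(rep(0, 10), data.frame(x = rnorm(10))),
    "degenerate"
  )
  expect_error(
    poisson_prevalence_model(
      rbinom(10, 1, 0.5), data.frame(x = rep(2, 10))
    ),
    "zero-variance"
  )
})

test_that("Poisson CI covers the null for an unrelated covariate", {
  set.seed(61)
  cover <- 0
  n_rep <- 100
  for (i in 1:n_rep) {
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    fit <- poisson_prevalence_model(y, data.frame(x = x))
    if (fit$table$adj_lo <= 1 && fit$table$adj_hi >= 1) cover <- cover + 1
  }
  expect_gte(cover, 88)
  expect_lte(cover, 100)
})

test_that("robust (sandwich) intervals are available and non-degenerate", {
  skip_if_not_installed("sandwich")
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(0.3 * x))
  fit <- poisson_prevalence_model(y, data.frame(x = x), robust = TRUE)
  expect_true(fit$table$adj_lo < fit$table$adj_ratio)
  expect_true(fit$table$adj_hi > fit$table$adj_ratio)
})
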