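test_that("relative abundances use the whole-community denominator", {
  tab <- random_otu_table(4, 5)
  rel <- relative_abundance(tab)
  expect_equal(unname(rowSums(rel)), rep(1, 4))
  brute <- unclass(tab) / rowSums(unclass(tab))
  expect_equal(rel, brute)
  sub <- relative_abundance(tab, colnames(tab)[1:2])
  expect_equal(sub, brute[, 1:2]) # not renormalized over the subset
  m <- matrix(c(5L, 5L), 1, dimnames = list("S1", c("a", "b")))
  expect_equal(relative_abundance(otu_table(m))[1, "a"], 0.5)
})

test_that("square-root JSD matches closed forms and hand evaluation", {
  p <- rbind(a = c(0.2, 0.8), b = c(0.2, 0.8))
  d <- jsd_distance(p)
  expect_equal(d["a", "b"], 0)

  # disjoint distributions approach sqrt(log 2) as the pseudocount vanishes
  p <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(jsd_distance(p, 1e-12)["a", "b"], sqrt(log(2)),
    tolerance = 1e-6
  )

  # hand evaluation of both KLD terms for (0.5,0.5) vs (0.9,0.1)
  pq <- rbind(a = c(0.5, 0.5), b = c(0.9, 0.1))
  m <- c(0.7, 0.3)
  kl1 <- 0.5 * log(0.5 / 0.7) + 0.5 * log(0.5 / 0.3)
  kl2 <- 0.9 * log(0.9 / 0.7) + 0.1 * log(0.1 / 0.3)
  expect_equal(jsd_distance(pq, 1e-9)["a", "b"],
    sqrt(0.5 * kl1 + 0.5 * kl2),
    tolerance = 1e-6
  )
})

test_that("sqrt-JSD behaves as a metric on random profiles", {
  set.seed(12)
  for (rep in 1:20) {
    p <- matrix(rgamma(4 * 6, 0.7), 4)
    p <- p / rowSums(p)
    rownames(p) <- paste0("s", 1:4)
    d <- jsd_distance(p)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_true(all(d <= sqrt(log(2)) + 1e-9))
    for (i in 1:4) {
      for (j in 1:4) {
        for (k in 1:4) {
          expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
        }
      }
    }
  }
})

test_that("PAM separates well-separated pairs and never beats the exhaustive optimum", {
  d <- as.matrix(stats::dist(c(0, 0.1, 10, 10.1)))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit <- pam_cluster(d, 2)
  expect_equal(unname(fit$labels[1]), unname(fit$labels[2]))
  expect_equal(unname(fit$labels[3]), unname(fit$labels[4]))
  expect_false(fit$labels[1] == fit$labels[3])
  expect_error(pam_cluster(d, 4), "must be smaller")

  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    p <- matrix(rgamma(n * 4, 1), n)
    p <- p / rowSums(p)
    rownames(p) <- paste0("s", 1:n)
    d <- jsd_distance(p)
    fit <- pam_cluster(d, k)
    # recomputed deviation matches the reported one
    expect_equal(
      fit$total_deviation,
      sum(d[cbind(seq_len(n), fit$medoids[fit$labels])]),
      tolerance = 1e-12
    )
    # local search can never beat the global optimum
    expect_gte(fit$total_deviation, exhaustive_kmedoids(d, k) - 1e-9)
    # every medoid belongs to its own cluster
    expect_equal(unname(fit$labels[fit$medoids]), seq_len(k))
  }
})

test_that("PAM attains the exhaustive optimum on separated instances and matches cluster::pam overall", {
  skip_if_not_installed("cluster")
  set.seed(78)
  agree <- 0
  n_inst <- 60
  for (i in 1:n_inst) {
    n <- sample(6:8, 1)
    k <- 2
    centers <- c(rep(0, ceiling(n / 2)), rep(5, floor(n / 2)))
    x <- centers + rnorm(n, sd = 0.2)
    d <- as.matrix(stats::dist(x))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    fit <- pam_cluster(d, k)
    expect_equal(fit$total_deviation, exhaustive_kmedoids(d, k),
      tolerance = 1e-9
    )
    cp <- cluster::pam(stats::as.dist(d), k, diss = TRUE)
    cp_dev <- sum(apply(d[, cp$id.med, drop = FALSE], 1, min))
    if (abs(cp_dev - fit$total_deviation) < 1e-9) agree <- agree + 1
  }
  expect_equal(agree, n_inst)
})

test_that("Calinski-Harabasz follows the medoid-variant formula", {
  # two clusters of duplicated points: W = 0 -> infinity sentinel
  d <- matrix(0, 4, 4)
  d[1:2, 3:4] <- 1
  d[3:4, 1:2] <- 1
  expect_equal(calinski_harabasz(d, c(1, 1, 2, 2)), Inf)
  expect_error(calinski_harabasz(d, rep(1, 4)), "at least 2")

  # hand-computed 5-point instance on the line: points 0, 1, 2, 10, 11
  x <- c(0, 1, 2, 10, 11)
  d <- as.matrix(stats::dist(x))
  labels <- c(1, 1, 1, 2, 2)
  # medoid of {0,1,2} is 1 (sumsq 2); medoid of {10,11} is 10 (sumsq 1)
  W <- (1 + 0 + 1) + (0 + 1)
  # global medoid minimizes total sumsq: candidates give 2 -> 1+4+64+81=...
  sumsq <- sapply(seq_along(x), function(i) sum((x - x[i])^2))
  g <- x[which.min(sumsq)]
  B <- 3 * (1 - g)^2 + 2 * (10 - g)^2
  ch_hand <- (B / (2 - 1)) / (W / (5 - 2))
  expect_equal(calinski_harabasz(d, labels), ch_hand)

  # the planted labeling dominates random labelings on separated data
  set.seed(90)
  x <- c(rnorm(6, 0, 0.1), rnorm(6, 8, 0.1))
  d <- as.matrix(stats::dist(x))
  planted <- rep(1:2, each = 6)
  ch_planted <- calinski_harabasz(d, planted)
  for (i in 1:100) {
    rnd <- sample(planted)
    if (all(rnd == planted) || all(rnd == 3 - planted)) next
    expect_lt(calinski_harabasz(d, rnd), ch_planted)
  }
})

test_that("silhouette widths match the per-point definition", {
  # two infinitely separated tight clusters -> mean silhouette ~ 1
  x <- c(0, 1e-6, 2e-6, 1e9, 1e9 + 1)
  d <- as.matrix(stats::dist(x))
  s <- mean_silhouette(d, c(1, 1, 1, 2, 2))
  expect_gt(as.numeric(s), 0.999999)

  # singleton contributes 0
  d <- as.matrix(stats::dist(c(0, 0.5, 4)))
  s <- mean_silhouette(d, c(1, 1, 2))
  expect_equal(attr(s, "widths")[3], 0)

  set.seed(55)
  for (i in 1:20) {
    n <- 6
    x <- matrix(rnorm(n * 2), n)
    d <- as.matrix(stats::dist(x))
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- labels[1] %% 3 + 1
    s <- mean_silhouette(d, labels)
    expect_equal(
      unname(attr(s, "widths")), brute_force_silhouette(d, labels),
      tolerance = 1e-12
    )
    expect_gte(as.numeric(s), -1)
    expect_lte(as.numeric(s), 1)
  }
})

test_that("silhouette agrees with cluster::silhouette when no singletons", {
  skip_if_not_installed("cluster")
  set.seed(56)
  for (i in 1:10) {
    x <- matrix(rnorm(16), 8)
    d <- as.matrix(stats::dist(x))
    labels <- rep(1:2, each = 4)
    s <- mean_silhouette(d, labels)
    ref <- cluster::silhouette(labels, dmatrix = d)
    expect_equal(as.numeric(s), mean(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("choose_k maximizes CH with smaller-k tie-breaking", {
  sim <- simulate_dataset(simulation_params(n_samples = 120), seed = 2)
  rare <- rarefy_table(sim$table, 5000, seed = 2)
  pred <- names(sim$truth$tier)[sim$truth$tier %in% c("block_I", "block_II")]
  prof <- relative_abundance(rare, pred)
  d <- jsd_distance(prof)
  ty <- choose_k(d, 2:6)
  expect_equal(ty$k, 2L)
  expect_equal(unname(ty$ch_by_k["2"]), max(ty$ch_by_k))
  expect_gte(rand_index(ty$labels, sim$truth$type[names(ty$labels)]), 0.9)

  ty2 <- choose_k(d, 2L)
  expect_equal(ty2$k, 2L)
  expect_length(ty2$ch_by_k, 1)
})

test_that("PCA biplot coordinates reproduce the correlation eigendecomposition", {
  set.seed(31)
  x <- matrix(rnorm(5 * 3), 5, dimnames = list(paste0("s", 1:5), paste0("o", 1:3)))
  res <- pca_biplot(x)
  eig <- eigen(stats::cor(x))
  expect_equal(unname(res$pct_variance),
    100 * eig$values / sum(eig$values),
    tolerance = 1e-10
  )
  expect_equal(sum(res$pct_variance), 100)
  # loadings orthonormal, equal to eigenvectors up to sign
  expect_equal(unname(t(res$loadings) %*% res$loadings), diag(3),
    tolerance = 1e-10
  )
  for (j in 1:3) {
    expect_equal(abs(unname(res$loadings[, j])), abs(eig$vectors[, j]),
      tolerance = 1e-8
    )
    # sign convention: largest-magnitude loading positive
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  # scores are the standardized data projected on the loadings
  z <- scale(x)
  expect_equal(unname(res$scores), unname(z %*% res$loadings),
    tolerance = 1e-10
  )

  # two perfectly correlated columns: PC1 explains everything
  y <- cbind(a = 1:6, b = (1:6) * 2)
  res2 <- pca_biplot(y)
  expect_equal(res2$pct_variance[1], 100)
  expect_error(pca_biplot(cbind(a = rep(1, 4), b = 1:4)), "zero-variance")
})
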