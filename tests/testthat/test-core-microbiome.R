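test_that("quantile stratification splits ranks into near-equal ordered groups", {
  pd <- stats::setNames(1:10, sprintf("S%02d", 1:10))
  q <- assign_pd_quintiles(pd, 5)
  expect_equal(
    unname(split(names(pd), q$labels)),
    list(
      c("S01", "S02"), c("S03", "S04"), c("S05", "S06"),
      c("S07", "S08"), c("S09", "S10")
    )
  )
  expect_equal(unname(q$boundaries), c(3, 5, 7, 9))

  # all ties: filled in sample-id order, sizes differ by at most one
  pd <- stats::setNames(rep(2.5, 7), sprintf("S%02d", 7:1))
  q <- assign_pd_quintiles(pd, 3)
  expect_equal(as.vector(table(q$labels)), c(3, 2, 2))
  expect_equal(unname(q$labels[order(names(q$labels))]), factor(
    c("Q1", "Q1", "Q1", "Q2", "Q2", "Q3", "Q3"),
    levels = c("Q1", "Q2", "Q3")
  ))

  expect_error(assign_pd_quintiles(stats::setNames(1, "a"), 5), "cannot form")

  set.seed(19)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    pd <- stats::setNames(round(runif(n), 2), sprintf("S%03d", 1:n))
    q <- assign_pd_quintiles(pd, 5)
    sizes <- as.vector(table(q$labels))
    expect_true(all(sizes %in% c(floor(n / 5), ceiling(n / 5))))
    # PD-sorted: every Q_j value <= every Q_{j+1} value
    maxes <- tapply(pd, q$labels, max)
    mins <- tapply(pd, q$labels, min)
    expect_true(all(maxes[-5] <= mins[-1]))
    # boundary lies between its groups
    expect_true(all(q$boundaries >= maxes[-5] & q$boundaries <= mins[-1]))
  }
})

test_that("prevalence is the brute-force detection fraction", {
  m <- matrix(c(1L, 0L, 3L, 2L, 0L, 0L, 5L, 1L),
    nrow = 4,
    dimnames = list(paste0("S", 1:4), c("a", "b"))
  )
  tab <- otu_table(m)
  expect_equal(otu_prevalence(tab), c(a = 0.75, b = 0.5))
  expect_error(otu_prevalence(tab, character(0)), "empty")
  set.seed(3)
  for (i in 1:10) {
    tab <- random_otu_table(6, 8, max_count = 2)
    brute <- apply(unclass(tab), 2, function(col) mean(col >= 1))
    expect_equal(otu_prevalence(tab), brute)
  }
})

test_that("core identification recovers planted prevalence tiers", {
  params <- simulation_params(n_samples = 500)
  sim <- simulate_dataset(params, seed = 11)
  rare <- rarefy_table(sim$table, 5000, seed = 11)
  pd <- faith_pd_table(rare, sim$tree)
  q <- assign_pd_quintiles(pd, 5)
  core <- identify_core_otus(rare, q, 0.75)
  planted <- names(sim$truth$tier)[sim$truth$tier != "rare"]
  expect_setequal(core, planted)

  # threshold 1 with a structural zero per OTU gives an empty core
  m <- diag(0L, 4)
  m[lower.tri(m) | upper.tri(m)] <- 5L
  dimnames(m) <- list(paste0("S", 1:4), paste0("o", 1:4))
  tab <- otu_table(m)
  pd2 <- stats::setNames(1:4, rownames(m))
  q2 <- assign_pd_quintiles(pd2, 2)
  expect_length(identify_core_otus(tab, q2, 0.999999), 0)

  # monotone in the threshold
  prev_core <- identify_core_otus(rare, q, 0.5)
  expect_true(all(core %in% prev_core))
  expect_true(
    length(identify_core_otus(rare, q, 0.9)) <= length(core)
  )
  # the weaker overall+Q1 rule can only enlarge the core
  weak <- identify_core_otus(rare, q, 0.75, rule = "overall_and_q1")
  expect_true(all(core %in% weak))
})

test_that("quintile-added shared sets are disjoint, core-free and correctly placed", {
  # constructed fixture: an OTU present in 80% of Q3 samples, absent
  # elsewhere, must appear exactly in the Q3 added set
  set.seed(42)
  n <- 50
  pd <- stats::setNames(seq_len(n), sprintf("S%03d", 1:n))
  q <- assign_pd_quintiles(pd, 5)
  m <- matrix(0L, n, 3, dimnames = list(names(pd), c("core1", "q3otu", "rare1")))
  m[, "core1"] <- 10L
  q3 <- names(q$labels)[q$labels == "Q3"]
  m[sample(q3, 8), "q3otu"] <- 4L
  m[sample(rownames(m), 5), "rare1"] <- 2L
  tab <- otu_table(m)
  core <- identify_core_otus(tab, q, 0.75)
  expect_equal(core, "core1")
  shared <- shared_otus_by_quintile(tab, q, core, 0.75)
  expect_equal(shared$Q3, "q3otu")
  expect_equal(
    unlist(shared[c("Q2", "Q4", "Q5")], use.names = FALSE),
    character(0)
  )

  # property: disjoint cover on simulated data
  sim <- simulate_dataset(tiny_params(), seed = 5)
  rare <- rarefy_table(sim$table, 1000, seed = 5)
  pd <- faith_pd_table(rare, sim$tree)
  qq <- assign_pd_quintiles(pd, 5)
  core <- identify_core_otus(rare, qq, 0.6)
  sh <- shared_otus_by_quintile(rare, qq, core, 0.6)
  all_sets <- c(list(core), unname(sh))
  pooled <- unlist(all_sets)
  expect_equal(anyDuplicated(pooled), 0L)
  for (lev in names(sh)) {
    prev <- otu_prevalence(rare, names(qq$labels)[qq$labels == lev])
    # every added OTU reaches the threshold in its quintile
    expect_true(all(prev[sh[[lev]]] >= 0.6))
  }
})

test_that("predominant-core selection applies the Q1 mean-abundance rule", {
  n <- 20
  pd <- stats::setNames(seq_len(n), sprintf("S%03d", 1:n))
  q <- assign_pd_quintiles(pd, 5)
  m <- matrix(0L, n, 3,
    dimnames = list(names(pd), c("big", "small", "mid"))
  )
  m[, "big"] <- 200L # 2% of each sample would need totals; build explicitly
  m[, "small"] <- 5L
  m[, "mid"] <- 795L
  tab <- otu_table(m) # every sample: big 20%, small 0.5%, mid 79.5%
  core <- c("big", "small", "mid")
  sel <- select_predominant_core(tab, core, q, 0.01)
  expect_setequal(sel, c("big", "mid"))

  sim <- simulate_dataset(simulation_params(n_samples = 500), seed = 11)
  rare <- rarefy_table(sim$table, 5000, seed = 11)
  pdv <- faith_pd_table(rare, sim$tree)
  qq <- assign_pd_quintiles(pdv, 5)
  core <- identify_core_otus(rare, qq, 0.75)
  sel <- select_predominant_core(rare, core, qq, 0.01)
  planted <- names(sim$truth$tier)[
    sim$truth$tier %in% c("block_I", "block_II")
  ]
  expect_setequal(sel, planted)
})

test_that("core fraction sums reads over the core per sample", {
  tab <- random_otu_table(5, 6)
  expect_equal(
    unname(core_fraction(tab, colnames(tab))), rep(1, 5)
  )
  expect_equal(unname(core_fraction(tab, character(0))), rep(0, 5))
  brute <- rowSums(unclass(tab)[, c(1, 3)]) / rowSums(unclass(tab))
  expect_equal(core_fraction(tab, colnames(tab)[c(1, 3)]), brute)
})
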