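test_that("topology sampler produces exchangeable labelled histories", {
  expect_error(sample_topology(1), ">= 2")

  # n = 2: the single topology, every branch with the right leaf set
  set.seed(1)
  t2 <- sample_topology(2)
  expect_identical(t2$parent, c(3L, 3L, NA))
  expect_identical(t2$k_merge, c(2L, 2L, 1L))

  # n = 3: the three labelled topologies (identified by the first-merging
  # cherry) are uniform by exchangeability of the uniform pair merge
  set.seed(2)
  cherries <- replicate(6000, {
    topo <- sample_topology(3)
    paste(which(topo$leafset[4, ]), collapse = "")
  })
  freq <- table(cherries) / length(cherries)
  expect_setequal(names(freq), c("12", "13", "23"))
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 6000)))
})

test_that("interval sampler enforces the stem fraction and coalescent rates", {
  set.seed(3)
  tt <- sample_intervals(6, 0.7)
  expect_length(tt, 6)
  expect_equal(tt[1] / sum(tt), 0.7, tolerance = 1e-12)

  # alpha = 1/2 means the stem equals the whole coalescent phase
  tt2 <- sample_intervals(10, 0.5)
  expect_equal(tt2[1], sum(tt2[-1]))

  # E[T_k] = 2 / (k (k - 1)): check k = 2 and k = 5 by Monte Carlo
  set.seed(4)
  draws <- replicate(4000, sample_intervals(5, 0.5))
  for (k in c(2, 5)) {
    mu <- 2 / (k * (k - 1))
    se <- mu / sqrt(ncol(draws))  # exponential: sd = mean
    expect_equal(mean(draws[k, ]), mu, tolerance = 4 * se / mu)
  }

  expect_error(sample_intervals(5, 1), "strictly between")
  expect_error(sample_intervals(5, 0), "strictly between")
})

test_that("mutation pair placement respects ancestry structure", {
  set.seed(5)
  for (i in 1:200) {
    g <- sample_genealogy(sample(2:8, 1), runif(1, 0.1, 0.9))
    pr <- place_mutation_pair(g)
    geno <- pr$genotypes
    if (pr$relation == "forward") {
      # descendant carriers are a subset of ancestor carriers
      expect_false(any(geno[, "x"] == 0 & geno[, "y"] == 1))
    } else if (pr$relation == "backward") {
      expect_false(any(geno[, "x"] == 1 & geno[, "y"] == 0))
    } else {
      expect_false(any(geno[, "x"] == 1 & geno[, "y"] == 1))
    }
    # both mutations on the stem can never be independent
    if (all(pr$branches == 2 * g$n - 1))
      expect_true(pr$relation %in% c("forward", "backward"))
  }
})

test_that("prior estimate matches the n = 2 closed form", {
  # with two leaves, T_1 = c T_2 for c = alpha/(1-alpha), so each mutation
  # lands on a specific leaf branch with probability 1/(c+2) regardless of
  # T_2, and Pr(independent) = 2/(c+2)^2 exactly
  for (alpha in c(0.3, 0.5, 0.8)) {
    cc <- alpha / (1 - alpha)
    p_true <- 2 / (cc + 2)^2
    n_pairs <- 200 * 500
    p <- estimate_priors(coalescent_config(2, alpha, b_tree = 200,
                                           b_mut = 500, seed = 101))
    se <- sqrt(p_true * (1 - p_true) / n_pairs)
    expect_lt(abs(p$order_prior[["independent"]] - p_true), 3 * se)
  }
})

test_that("prior tables are normalized with exact structural zeros", {
  p <- estimate_priors(coalescent_config(7, 0.6, b_tree = 100, b_mut = 500,
                                         seed = 8))
  expect_equal(sum(p$order_prior), 1, tolerance = 1e-12)
  expect_identical(p$order_prior[["forward"]], p$order_prior[["backward"]])
  expect_equal(unname(rowSums(p$cond_genotype)), rep(1, 3), tolerance = 1e-12)
  expect_identical(p$cond_genotype["forward", "01"], 0)
  expect_identical(p$cond_genotype["backward", "10"], 0)
  expect_identical(p$cond_genotype["independent", "11"], 0)
  # pooled same-lineage draws make backward the transpose of forward
  expect_identical(unname(p$cond_genotype["backward", c("00", "01", "10", "11")]),
                   unname(p$cond_genotype["forward", c("00", "10", "01", "11")]))
})

test_that("prior estimation is reproducible for a fixed seed", {
  cfg <- coalescent_config(12, 0.4, b_tree = 50, b_mut = 300, seed = 99)
  p1 <- estimate_priors(cfg)
  p2 <- estimate_priors(cfg)
  expect_identical(p1$order_prior, p2$order_prior)
  expect_identical(p1$cond_genotype, p2$cond_genotype)
})

test_that("independence prior decreases as the stem fraction grows", {
  pg <- prior_grid(10, c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99),
                   b_tree = 300, b_mut = 2000, seed = 12)
  p_ind <- vapply(pg, function(p) p$order_prior[["independent"]], numeric(1))
  expect_true(all(diff(p_ind) < 0))
  # near alpha = 1 the stem dominates: directed priors approach 1/2
  expect_gt(pg[[6]]$order_prior[["forward"]], 0.45)
})

test_that("compiled tallies agree with the R-level placement sampler", {
  # estimate Pr(independent) and Pr((1,1) | forward) two ways at n = 5
  n <- 5; alpha <- 0.5
  p_cpp <- estimate_priors(coalescent_config(n, alpha, b_tree = 300,
                                             b_mut = 300, seed = 21))
  set.seed(22)
  draws <- replicate(6000, {
    g <- sample_genealogy(n, alpha)
    pr <- place_mutation_pair(g)
    c(ind = pr$relation == "independent",
      f11 = if (pr$relation != "independent")
        mean(pr$genotypes[, 1] & pr$genotypes[, 2]) else NA_real_)
  })
  p_ind_r <- mean(draws["ind", ])
  se <- sqrt(p_ind_r * (1 - p_ind_r) / ncol(draws))
  expect_lt(abs(p_cpp$order_prior[["independent"]] - p_ind_r), 5 * se)
  f11_r <- mean(draws["f11", ], na.rm = TRUE)
  expect_equal(f11_r, p_cpp$cond_genotype["forward", "11"], tolerance = 0.1)
})

test_that("seeded prior tables are cached and identical on re-request", {
  cfg <- coalescent_config(6, 0.55, b_tree = 20, b_mut = 100, seed = 1234)
  p1 <- estimate_priors(cfg)
  p2 <- estimate_priors(cfg)
  expect_identical(p1$mc_counts, p2$mc_counts)
})
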