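test_that("relation cell probabilities honor structural zeros and normalize", {
  prior <- fixed_prior()
  e0 <- error_rates(0, 0)
  # without an error channel, a carried descendant implies a carried ancestor
  expect_equal(relation_cell_prob(c(0, 1), "forward", prior, e0), 0)
  expect_equal(relation_cell_prob(c(1, 1), "independent", prior, e0), 0)

  for (rel in c("forward", "backward", "independent")) {
    tot <- sum(vapply(0:8, function(k)
      relation_cell_prob(c(k %% 3, k %/% 3), rel, prior, error_rates()),
      numeric(1)))
    expect_equal(tot, 1)
  }
})

test_that("pair log-likelihood sums per-cell terms and flags impossibilities", {
  prior <- fixed_prior()
  e <- error_rates()
  m <- toy_two_site()
  ll1 <- pair_loglik(m, "x", "y", "independent", prior, e)
  # duplicating every sample doubles the log-likelihood
  m2 <- genotype_matrix(cbind(unclass(m), unclass(m)),
                        sample_ids = paste0("s", 1:14))
  expect_equal(pair_loglik(m2, "x", "y", "independent", prior, e), 2 * ll1)

  # the toy data contain (0,1) cells, incompatible with x ancestral to y
  # when no errors can explain them
  expect_identical(pair_loglik(m, "x", "y", "forward", prior,
                               error_rates(0, 0)), -Inf)

  single <- genotype_matrix(rbind(x = 0L, y = 0L))
  expect_equal(pair_loglik(single, "x", "y", "forward", prior, e),
               log(relation_cell_prob(c(0, 0), "forward", prior, e)))

  allmiss <- genotype_matrix(rbind(x = c(0L, NA), y = c(NA, 1L)))
  expect_error(pair_loglik(allmiss, "x", "y", "forward", prior, e),
               "no cell has both sites observed")
})

test_that("likelihoods match the brute-force enumeration oracle", {
  prior <- fixed_prior(p_same = 0.25, fwd = c(0.1, 0.35, 0, 0.55),
                       ind = c(0.3, 0.5, 0.2, 0))
  set.seed(31)
  for (i in 1:10) {
    e <- if (i %% 2) error_rates(0, 0) else error_rates(0.05, 0.4, 0.01)
    m <- random_genotype_matrix(2, 3, missing_rate = 0.1)
    rownames(m) <- c("x", "y")
    for (rel in c("forward", "backward", "independent")) {
      direct <- tryCatch(pair_loglik(m, "x", "y", rel, prior, e),
                         error = function(err) NULL)
      if (is.null(direct)) next
      oracle <- brute_force_loglik(m, "x", "y", rel, prior, e)
      if (is.infinite(direct)) expect_identical(oracle, -Inf)
      else expect_equal(direct, oracle, tolerance = 1e-10)
    }
  }
})

test_that("the toy example is classified as y ancestral to x", {
  prior <- estimate_priors(coalescent_config(7, 0.5, b_tree = 200,
                                             b_mut = 1000, seed = 51))
  row <- pair_posterior(toy_two_site(), "x", "y", prior, error_rates())
  expect_identical(row$map_relation, "backward")
  expect_gt(row$p_backward, row$p_forward)
  expect_gt(row$p_backward, row$p_independent)
  expect_equal(row$p_forward + row$p_backward + row$p_independent, 1)
})

test_that("disjoint carriers classify as independent under zero errors", {
  m <- genotype_matrix(rbind(x = c(1L, 1L, 0L, 0L, 0L),
                             y = c(0L, 0L, 1L, 1L, 0L)))
  row <- pair_posterior(m, "x", "y", fixed_prior(), error_rates(0, 0))
  expect_identical(row$map_relation, "independent")
  expect_equal(row$p_independent, 1)
})

test_that("classify_pairs covers all pairs with antisymmetric posteriors", {
  set.seed(61)
  m <- random_genotype_matrix(6, 15, missing_rate = 0.25)
  prior <- fixed_prior()
  pm <- classify_pairs(m, prior, error_rates())
  expect_identical(nrow(pm), as.integer(choose(6, 2)))
  ok <- !pm$unclassifiable
  expect_equal(pm$p_forward[ok] + pm$p_backward[ok] + pm$p_independent[ok],
               rep(1, sum(ok)))

  # a pair read in the reverse orientation swaps forward and backward
  both <- orient_pairs(pm)
  expect_identical(nrow(both), 2L * nrow(pm))
  for (r in which(ok)[1:5]) {
    fwd <- pm[r, ]
    rev_row <- both[both$site_x == fwd$site_y & both$site_y == fwd$site_x, ]
    expect_equal(rev_row$p_backward, fwd$p_forward)
    expect_equal(rev_row$p_independent, fwd$p_independent)
    expect_identical(rev_row$n_used, fwd$n_used)
  }

  # reversing the matrix row order gives the mirrored classification
  m_rev <- m[rev(seq_len(nrow(m))), ]
  pm_rev <- classify_pairs(m_rev, prior, error_rates())
  a <- pm[pm$site_x == "g1" & pm$site_y == "g2", ]
  b <- pm_rev[pm_rev$site_x == "g2" & pm_rev$site_y == "g1", ]
  expect_equal(b$p_forward, a$p_backward)
  expect_equal(b$loglik_forward, a$loglik_backward)
})

test_that("posteriors are invariant to sample order", {
  set.seed(62)
  m <- random_genotype_matrix(4, 12, missing_rate = 0.2)
  prior <- fixed_prior()
  pm1 <- classify_pairs(m, prior, error_rates())
  pm2 <- classify_pairs(m[, sample(ncol(m))], prior, error_rates())
  expect_equal(pm1$p_forward, pm2$p_forward)
  expect_equal(pm1$p_independent, pm2$p_independent)
})

test_that("pairs with no joint observation are flagged, not guessed", {
  m <- genotype_matrix(rbind(a = c(1L, NA, 0L), b = c(NA, 1L, NA),
                             c = c(0L, 1L, 1L)))
  pm <- classify_pairs(m, fixed_prior(), error_rates())
  ab <- pm[pm$site_x == "a" & pm$site_y == "b", ]
  expect_true(ab$unclassifiable)
  expect_identical(ab$n_used, 0L)
  expect_error(classify_pairs(m, fixed_prior(), error_rates(),
                              on_empty = "error"),
               "no cell has both sites observed")
})

test_that("a 2-site matrix yields exactly one pair", {
  m <- genotype_matrix(rbind(x = c(0L, 1L), y = c(1L, 1L)))
  pm <- classify_pairs(m, fixed_prior(), error_rates())
  expect_identical(nrow(pm), 1L)
})
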