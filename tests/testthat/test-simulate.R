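test_that("zero error and zero missingness give clean perfect-phylogeny data", {
  sim <- simulate_genotypes(12, 8, alpha = 0.5, e = error_rates(0, 0),
                            missing_rate = 0, seed = 91)
  expect_identical(unclass(sim$matrix), unclass(sim$truth$clean_matrix))
  expect_true(all(unclass(sim$matrix) %in% 0:1))
  # two-state characters from one genealogy: carrier sets pairwise nested
  # or disjoint
  calls <- unclass(sim$matrix)
  for (a in 1:7) for (b in (a + 1):8) {
    sa <- calls[a, ] == 1; sb <- calls[b, ] == 1
    expect_true(all(!sa | sb) || all(!sb | sa) || !any(sa & sb))
  }
})

test_that("planted relations are consistent with clean carrier sets", {
  sim <- simulate_genotypes(15, 10, alpha = 0.6, e = error_rates(0, 0),
                            missing_rate = 0, seed = 92)
  calls <- unclass(sim$truth$clean_matrix)
  rel <- sim$truth$relations
  for (r in seq_len(nrow(rel))) {
    sa <- calls[rel$site_x[r], ] == 1
    sb <- calls[rel$site_y[r], ] == 1
    switch(rel$relation[r],
           forward = expect_true(all(!sb | sa)),
           backward = expect_true(all(!sa | sb)),
           independent = expect_false(any(sa & sb)))
  }
})

test_that("corruption rates match the error model", {
  # among true heterozygous calls, a fraction AD is pushed to homozygous
  sim <- simulate_genotypes(40, 60, alpha = 0.7,
                            e = error_rates(0, 0.4309), missing_rate = 0,
                            seed = 93)
  clean <- unclass(sim$truth$clean_matrix)
  obs <- unclass(sim$matrix)
  het <- clean == 1
  n_het <- sum(het)
  expect_gt(n_het, 200)
  dropped <- mean(obs[het] != 1)
  se <- sqrt(0.4309 * (1 - 0.4309) / n_het)
  expect_lt(abs(dropped - 0.4309), 3 * se)
  # dropout splits evenly between homozygous wildtype and mutant
  expect_gt(sum(obs[het] == 0), 0)
  expect_gt(sum(obs[het] == 2), 0)
})

test_that("missingness matches the masking rate", {
  sim <- simulate_genotypes(30, 40, alpha = 0.5, e = error_rates(),
                            missing_rate = 0.45, seed = 94)
  n <- length(unclass(sim$matrix))
  frac <- missing_count(sim$matrix) / n
  se <- sqrt(0.45 * 0.55 / n)
  expect_lt(abs(frac - 0.45), 3 * se)
})

test_that("simulation is reproducible under a fixed seed", {
  s1 <- simulate_genotypes(10, 6, alpha = 0.8, seed = 95)
  s2 <- simulate_genotypes(10, 6, alpha = 0.8, seed = 95)
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(s1$truth$relations, s2$truth$relations)
})

test_that("error-free pipelines recover every distinguishable planted order", {
  prior <- estimate_priors(coalescent_config(20, 0.5, b_tree = 300,
                                             b_mut = 2000, seed = 96))
  for (rep_seed in c(961, 962, 963)) {
    sim <- simulate_genotypes(20, 8, alpha = 0.5, e = error_rates(0, 0),
                              missing_rate = 0, seed = rep_seed)
    pm <- classify_pairs(sim$matrix, prior, error_rates(0, 0))
    calls <- unclass(sim$truth$clean_matrix)
    truth <- sim$truth$relations
    joined <- merge(tibble::as_tibble(pm), truth,
                    by = c("site_x", "site_y"))
    for (r in seq_len(nrow(joined))) {
      sa <- calls[joined$site_x[r], ] == 1
      sb <- calls[joined$site_y[r], ] == 1
      distinct_branches <- !identical(sa, sb)
      if (distinct_branches) {
        expect_identical(joined$map_relation[r], joined$relation[r])
      } else {
        # same-branch pairs are observationally symmetric: direction is a
        # reported tie, never independence
        expect_true(joined$map_relation[r] %in% c("forward", "backward"))
        expect_true(joined$tie[r])
      }
    }
  }
})

test_that("the inferred clean-data tree matches the planted ancestry", {
  sim <- simulate_genotypes(25, 6, alpha = 0.6, e = error_rates(0, 0),
                            missing_rate = 0, seed = 197)
  calls <- unclass(sim$truth$clean_matrix)
  # this seed yields pairwise-distinct carrier sets, so every direction
  # is identifiable
  carriers <- apply(calls, 1, paste, collapse = "")
  expect_identical(anyDuplicated(carriers), 0L)
  res <- infer_mutation_tree(sim$matrix, e = error_rates(0, 0), alpha = 0.6,
                             b_tree = 300, b_mut = 2000, seed = 98)
  # every inferred branch must be a planted same-lineage order
  truth <- sim$truth$relations
  for (r in seq_len(nrow(res$tree$edges))) {
    from <- res$tree$edges$from[r]; to <- res$tree$edges$to[r]
    hit <- truth[(truth$site_x == from & truth$site_y == to) |
                   (truth$site_x == to & truth$site_y == from), ]
    expected <- if (hit$site_x[1] == from) "forward" else "backward"
    expect_identical(hit$relation[1], expected)
  }
})

test_that("simulation files are written in the package dialects", {
  sim <- simulate_genotypes(8, 5, alpha = 0.7, seed = 99)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genotypes.tsv", "clean_genotypes.tsv", "true_relations.tsv",
    "truth.json")))))
  back <- read_genotype_matrix(file.path(dir, "genotypes.tsv"))
  expect_identical(unclass(back), unclass(sim$matrix))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$alpha, 0.7, tolerance = 1e-9)
})
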