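#' Simulate a single-cell genotype matrix with known ground truth
#'
#' Runs the generative model that the inference assumes, forward: sample
#' one stem-extended Kingman genealogy of `n_cells` leaves at stem-time
#' fraction `alpha`; place each site's single mutation on a (branch, time)
#' point chosen branch-length-uniformly; read off clean 0/1 leaf genotypes
#' by subtree membership; corrupt every call through the false-discovery /
#' allelic-dropout observation model; and finally mask entries missing
#' completely at random at `missing_rate`.
#'
#' The default `missing_rate` of 0.45 mirrors the worked ET dataset, where
#' about 45% of calls failed quality criteria.
#'
#' @param n_cells number of cells (leaves), at least 2.
#' @param n_sites number of mutation sites, at least 2.
#' @param alpha stem-time fraction in (0, 1).
#' @param e an [error_rates()] object; `error_rates(0, 0)` gives clean
#'   perfect-phylogeny data.
#' @param missing_rate per-entry masking probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return A list with `matrix` (the corrupted [genotype_matrix()]) and
#'   `truth`: `genealogy`, `placements` (tibble `site`, `branch`, `time`),
#'   `clean_matrix` (error-free 0/1 calls), and `relations` (tibble
#'   `site_x`, `site_y`, `relation` for every unordered site pair, the
#'   planted order relations).
#' @examples
#' sim <- simulate_genotypes(10, 5, alpha = 0.5, e = error_rates(0, 0),
#'                           missing_rate = 0, seed = 42)
#' sim$truth$relations
#' @export
simulate_genotypes <- function(n_cells, n_sites, alpha = 0.92,
                               e = error_rates(), missing_rate = 0.45,
                               seed = NULL) {
  stopifnot(n_cells >= 2, n_sites >= 2,
            missing_rate >= 0, missing_rate <= 1)
  with_local_seed(seed, {
    g <- sample_genealogy(n_cells, alpha)
    placements <- lapply(seq_len(n_sites), function(s) place_mutation(g))
    branches <- vapply(placements, function(p) as.integer(p$branch),
                       integer(1))
    times <- vapply(placements, `[[`, numeric(1), "time")
    site_labels <- sprintf("S%02d", seq_len(n_sites))
    sample_ids <- sprintf("cell%02d", seq_len(n_cells))
    clean <- matrix(0L, n_sites, n_cells,
                    dimnames = list(site_labels, sample_ids))
    for (s in seq_len(n_sites))
      clean[s, ] <- as.integer(g$leafset[branches[s], ])
    # planted pairwise relations from ancestry of the placements
    rel <- list()
    for (a in seq_len(n_sites - 1)) for (b in seq(a + 1, n_sites)) {
      sa <- g$leafset[branches[a], ]; sb <- g$leafset[branches[b], ]
      r <- if (branches[a] == branches[b]) {
        if (times[a] <= times[b]) "forward" else "backward"
      } else if (all(!sb | sa)) "forward"
      else if (all(!sa | sb)) "backward"
      else "independent"
      rel[[length(rel) + 1]] <- tibble::tibble(
        site_x = site_labels[a], site_y = site_labels[b], relation = r)
    }
    # corrupt through the observation model, then mask
    P <- observation_probs(e)
    obs <- clean
    for (v in 0:1) {
      idx <- which(clean == v)
      if (length(idx))
        obs[idx] <- sample(0:2, length(idx), replace = TRUE,
                           prob = P[v + 1L, ])
    }
    if (missing_rate > 0)
      obs[stats::runif(length(obs)) < missing_rate] <- NA_integer_
    list(
      matrix = genotype_matrix(obs),
      truth = list(genealogy = g,
                   placements = tibble::tibble(site = site_labels,
                                               branch = branches,
                                               time = times),
                   clean_matrix = genotype_matrix(clean),
                   relations = dplyr::bind_rows(rel))
    )
  })
}

#' Write a simulated dataset and its ground truth to files
#'
#' @param sim a [simulate_genotypes()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `genotypes.tsv` (observed matrix, same
#'   dialect as [write_genotype_matrix()]), `clean_genotypes.tsv`,
#'   `true_relations.tsv` and `truth.json` (placements and interval
#'   durations).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_matrix(sim$matrix, file.path(dir, "genotypes.tsv"))
  write_genotype_matrix(sim$truth$clean_matrix,
                        file.path(dir, "clean_genotypes.tsv"))
  utils::write.table(sim$truth$relations,
                     file.path(dir, "true_relations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(placements = sim$truth$placements,
         intervals = sim$truth$genealogy$intervals,
         alpha = sim$truth$genealogy$intervals[1] /
           sum(sim$truth$genealogy$intervals)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
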