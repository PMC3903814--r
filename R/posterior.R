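obs_pair_levels <- c("00", "10", "20", "01", "11", "21", "02", "12", "22")

# 3 x 9 matrix: Pr(observed pair | relation) for each relation row and the
# nine observed genotype cells (column order obs_pair_levels, i.e. i + 3*j)
relation_cell_matrix <- function(prior, e) {
  P <- observation_probs(e)
  # 4 x 9: rows true pairs "00","10","01","11"; cols observed pairs
  O <- matrix(0, 4, 9, dimnames = list(genotype_pair_levels, obs_pair_levels))
  true_pairs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (t in 1:4) {
    tp <- true_pairs[[t]]
    for (i in 0:2) for (j in 0:2)
      O[t, i + 3L * j + 1L] <- P[tp[1] + 1L, i + 1L] * P[tp[2] + 1L, j + 1L]
  }
  prior$cond_genotype[, genotype_pair_levels, drop = FALSE] %*% O
}

#' Probability of an observed genotype pair under an order relation
#'
#' Marginalizes the observation model over the four possible true genotype
#' pairs, weighting by the coalescent-prior conditional distribution of
#' true genotypes given the relation.
#'
#' @param obs_pair length-2 vector of observed genotypes, each 0, 1 or 2.
#' @param relation `"forward"`, `"backward"` or `"independent"`.
#' @param prior a `prior_table` from [estimate_priors()].
#' @param e an [error_rates()] object.
#' @return `Pr(obs_pair | relation)`.
#' @export
relation_cell_prob <- function(obs_pair, relation, prior, e) {
  relation <- match.arg(relation, relation_levels)
  stopifnot(length(obs_pair) == 2)
  if (!all(obs_pair %in% 0:2))
    stop("observed genotypes must be 0, 1 or 2, got: ",
         paste(obs_pair, collapse = ", "))
  M <- relation_cell_matrix(prior, e)
  M[relation, obs_pair[1] + 3L * obs_pair[2] + 1L]
}

# 9-cell tally of jointly observed genotype pairs for sites x, y
pair_cell_counts <- function(m, x, y) {
  gx <- m[x, ]; gy <- m[y, ]
  ok <- !is.na(gx) & !is.na(gy)
  counts <- tabulate(gx[ok] + 3L * gy[ok] + 1L, nbins = 9L)
  names(counts) <- obs_pair_levels
  counts
}

loglik_from_counts <- function(counts, cellmat) {
  # sum counts * log p with the convention 0 * log 0 = 0
  vapply(relation_levels, function(rel) {
    p <- cellmat[rel, ]
    used <- counts > 0
    if (any(used & p == 0)) return(-Inf)
    sum(counts[used] * log(p[used]))
  }, numeric(1))
}

#' Log-likelihood of a site pair under one order relation
#'
#' The likelihood of the observed data for sites `x` and `y` under a
#' relation is the product over cells of the per-cell observation
#' probability; cells missing at either site are excluded from this pair
#' only. `-Inf` signals an observed genotype pair that is impossible under
#' the relation (e.g. a cell carrying the descendant but not the ancestor
#' with a zero-error model).
#'
#' @param m a [genotype_matrix()].
#' @param x,y site labels or indices.
#' @param relation `"forward"`, `"backward"` or `"independent"`.
#' @inheritParams relation_cell_prob
#' @return The log-likelihood (may be `-Inf`).
#' @export
pair_loglik <- function(m, x, y, relation, prior, e) {
  stopifnot(inherits(m, "genotype_matrix"))
  relation <- match.arg(relation, relation_levels)
  counts <- pair_cell_counts(m, x, y)
  if (sum(counts) == 0)
    stop("no cell has both sites observed for pair (", x, ", ", y, ")")
  loglik_from_counts(counts, relation_cell_matrix(prior, e))[[relation]]
}

#' Posterior over the three order relations for one site pair
#'
#' Bayes theorem in log space: `Pr(relation | D) proportional to
#' L(relation) * Pr(relation)`, normalized by log-sum-exp. If every
#' relation has zero posterior mass (all likelihoods `-Inf`) the pair is
#' unclassifiable and flagged rather than silently dropped.
#'
#' @inheritParams pair_loglik
#' @return A one-row tibble with columns `site_x`, `site_y`, `n_used`,
#'   `loglik_forward/backward/independent`, `p_forward/backward/independent`,
#'   `map_relation`, `tie`, `unclassifiable`.
#' @export
pair_posterior <- function(m, x, y, prior, e) {
  stopifnot(inherits(m, "genotype_matrix"))
  counts <- pair_cell_counts(m, x, y)
  if (sum(counts) == 0)
    stop("no cell has both sites observed for pair (", x, ", ", y, ")")
  cellmat <- relation_cell_matrix(prior, e)
  xl <- if (is.numeric(x)) rownames(m)[x] else x
  yl <- if (is.numeric(y)) rownames(m)[y] else y
  posterior_row(counts, cellmat, prior$order_prior, xl, yl)
}

posterior_row <- function(counts, cellmat, order_prior, xlab, ylab) {
  ll <- loglik_from_counts(counts, cellmat)
  lp <- ll + log(order_prior)
  if (all(lp == -Inf)) {
    post <- rep(NA_real_, 3)
    map <- NA_character_
    tie <- FALSE
    unclass_ <- TRUE
  } else {
    mx <- max(lp[is.finite(lp)])
    w <- exp(lp - mx)
    w[!is.finite(lp)] <- 0
    post <- w / sum(w)
    top <- max(post)
    winners <- relation_levels[abs(post - top) < 1e-12]
    tie <- length(winners) > 1
    # ties: refuse to invent a direction without evidence
    map <- if ("independent" %in% winners) "independent" else winners[1]
    unclass_ <- FALSE
  }
  tibble::tibble(
    site_x = xlab, site_y = ylab, n_used = as.integer(sum(counts)),
    loglik_forward = ll[["forward"]], loglik_backward = ll[["backward"]],
    loglik_independent = ll[["independent"]],
    p_forward = unname(post[1]), p_backward = unname(post[2]),
    p_independent = unname(post[3]),
    map_relation = map, tie = tie, unclassifiable = unclass_
  )
}

#' Classify every site pair by its maximum-posterior order relation
#'
#' Computes the posterior over forward / backward / independent for every
#' unordered pair of sites and reports the maximum a posteriori relation.
#' The result is antisymmetric by construction: the row for `(x, y)` with
#' relation forward corresponds to `(y, x)` backward with identical
#' posterior mass.
#'
#' @param m a [genotype_matrix()] with at least 2 sites.
#' @inheritParams relation_cell_prob
#' @param on_empty what to do with a pair having no jointly observed cell:
#'   `"flag"` (default) marks it unclassifiable with `NA` posteriors,
#'   `"error"` stops.
#' @return A tibble of class `posterior_matrix`, one row per unordered
#'   pair (`site_x` before `site_y` in matrix row order), with the columns
#'   of [pair_posterior()].
#' @examples
#' \donttest{
#' m <- et_genotypes()
#' prior <- estimate_priors(coalescent_config(n = ncol(m), alpha = 0.92,
#'                                            b_tree = 100, b_mut = 1000,
#'                                            seed = 7))
#' pp <- classify_pairs(m, prior, error_rates())
#' nrow(pp)  # 153 unordered pairs
#' }
#' @export
classify_pairs <- function(m, prior, e, on_empty = c("flag", "error")) {
  stopifnot(inherits(m, "genotype_matrix"))
  on_empty <- match.arg(on_empty)
  S <- nrow(m)
  if (S < 2) stop("need at least 2 sites")
  cellmat <- relation_cell_matrix(prior, e)
  sites <- rownames(m)
  rows <- list()
  for (a in seq_len(S - 1)) for (b in seq((a + 1), S)) {
    counts <- pair_cell_counts(m, a, b)
    if (sum(counts) == 0) {
      if (on_empty == "error")
        stop("no cell has both sites observed for pair (",
             sites[a], ", ", sites[b], ")")
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_x = sites[a], site_y = sites[b], n_used = 0L,
        loglik_forward = NA_real_, loglik_backward = NA_real_,
        loglik_independent = NA_real_, p_forward = NA_real_,
        p_backward = NA_real_, p_independent = NA_real_,
        map_relation = NA_character_, tie = FALSE, unclassifiable = TRUE)
    } else {
      rows[[length(rows) + 1]] <-
        posterior_row(counts, cellmat, prior$order_prior, sites[a], sites[b])
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("posterior_matrix", class(out))
  attr(out, "sites") <- sites
  out
}

#' Both-orientation view of a posterior matrix
#'
#' Expands the per-unordered-pair table to ordered pairs: the `(y, x)` row
#' mirrors `(x, y)` with forward and backward swapped.
#'
#' @param pm a `posterior_matrix` from [classify_pairs()].
#' @return A tibble with `2 * nrow(pm)` rows.
#' @export
orient_pairs <- function(pm) {
  stopifnot(inherits(pm, "posterior_matrix"))
  flip_rel <- c(forward = "backward", backward = "forward",
                independent = "independent")
  flipped <- pm |>
    dplyr::mutate(
      tmp = .data$site_x, site_x = .data$site_y, site_y = .data$tmp,
      tmp2 = .data$p_forward, p_forward = .data$p_backward,
      p_backward = .data$tmp2,
      tmp3 = .data$loglik_forward, loglik_forward = .data$loglik_backward,
      loglik_backward = .data$tmp3,
      map_relation = unname(flip_rel[.data$map_relation])
    ) |>
    dplyr::select(-"tmp", -"tmp2", -"tmp3")
  dplyr::bind_rows(tibble::as_tibble(pm), flipped)
}

#' Write a posterior matrix as TSV
#'
#' Long-format export: `site_x, site_y, p_forward, p_backward,
#' p_independent, n_used, map_relation`.
#'
#' @param pm a `posterior_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_posteriors_tsv <- function(pm, path) {
  out <- tibble::as_tibble(pm)[, c("site_x", "site_y", "p_forward",
                                   "p_backward", "p_independent", "n_used",
                                   "map_relation")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
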