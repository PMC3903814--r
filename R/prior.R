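#' Monte Carlo configuration for the coalescent prior
#'
#' @param n number of sampled cells (leaves) in the simulated genealogies;
#'   set it to the number of cells in the genotype matrix under analysis.
#' @param alpha stem-time fraction in (0, 1): the proportion of time from
#'   the earliest mutation event to the MRCA of the sample.
#' @param b_tree number of genealogies simulated (default 1000).
#' @param b_mut number of mutation pairs dropped on each genealogy
#'   (default 10000).
#' @param seed RNG seed; `NULL` draws from the current RNG stream (results
#'   are then only reproducible via an enclosing `set.seed()`).
#' @return A list of class `coalescent_config`.
#' @export
coalescent_config <- function(n, alpha, b_tree = 1000, b_mut = 10000,
                              seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 2,
            is.numeric(alpha), length(alpha) == 1,
            is.numeric(b_tree), b_tree >= 1,
            is.numeric(b_mut), b_mut >= 1)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie strictly in (0, 1)")
  structure(list(n = as.integer(n), alpha = alpha,
                 b_tree = as.integer(b_tree), b_mut = as.integer(b_mut),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "coalescent_config")
}

.prior_cache <- new.env(parent = emptyenv())

# run thunk under a locally-seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

relation_levels <- c("forward", "backward", "independent")
genotype_pair_levels <- c("00", "10", "01", "11")  # (true x, true y)

# assemble a prior_table from one row of C++ tallies
build_prior_table <- function(tallies, config) {
  n <- config$n
  n_pairs <- tallies[["n_pairs"]]
  n_same <- tallies[["n_same"]]
  n_ind <- n_pairs - n_same
  p_same_dir <- 0.5 * n_same / n_pairs
  order_prior <- c(forward = p_same_dir, backward = p_same_dir,
                   independent = 1 - 2 * p_same_dir)
  cond <- matrix(0, nrow = 3, ncol = 4,
                 dimnames = list(relation_levels, genotype_pair_levels))
  if (n_same > 0) {
    tot <- n * n_same
    cond["forward", ] <- c(tallies[["f00"]], tallies[["f10"]], 0,
                           tallies[["f11"]]) / tot
    # pooled same-lineage draws symmetrized: backward is the transpose
    cond["backward", ] <- c(tallies[["f00"]], 0, tallies[["f10"]],
                            tallies[["f11"]]) / tot
  }
  if (n_ind > 0) {
    tot <- n * n_ind
    off <- (tallies[["i10"]] + tallies[["i01"]]) / 2
    cond["independent", ] <- c(tallies[["i00"]], off, off, 0) / tot
  }
  structure(list(order_prior = order_prior, cond_genotype = cond,
                 mc_counts = tallies, config = config),
            class = "prior_table")
}

#' @export
print.prior_table <- function(x, ...) {
  cfg <- x$config
  cat("<prior_table> n =", cfg$n, " alpha =", cfg$alpha,
      " (", cfg$b_tree, "trees x", cfg$b_mut, "pairs )\n")
  cat("order prior:\n")
  print(round(x$order_prior, 4))
  cat("Pr(true genotype pair | relation):\n")
  print(round(x$cond_genotype, 4))
  invisible(x)
}

#' Estimate the prior over pairwise mutation orders
#'
#' Simulates `b_tree` stem-extended Kingman genealogies of `n` cells and
#' drops `b_mut` independent mutation pairs on each, tallying how often the
#' pair falls on one lineage (ancestral order, either direction) versus
#' distinct lineages, and the distribution of true leaf genotype pairs
#' conditional on each relation. The two directed relations get equal prior
#' mass by construction (same-lineage draws are pooled and halved), and the
#' conditional genotype table for the backward relation is the transpose of
#' the forward one.
#'
#' Structural zeros hold exactly: a descendant mutation is never carried
#' without its ancestor (`Pr((0,1) | forward) = 0`, mirrored backward), and
#' independent mutations are never co-carried (`Pr((1,1) | independent) = 0`).
#'
#' Results for seeded configurations are cached within the session, keyed
#' on `(n, alpha, b_tree, b_mut, seed)`.
#'
#' @param config a [coalescent_config()].
#' @return A `prior_table`: list with `order_prior` (length-3 probability
#'   vector over forward/backward/independent), `cond_genotype` (3 x 4
#'   matrix of `Pr((i', j') | relation)` with columns "00", "10", "01",
#'   "11"), `mc_counts` (raw tallies) and `config`.
#' @examples
#' p <- estimate_priors(coalescent_config(n = 10, alpha = 0.9,
#'                                        b_tree = 50, b_mut = 200, seed = 1))
#' p$order_prior
#' @export
estimate_priors <- function(config) {
  stopifnot(inherits(config, "coalescent_config"))
  prior_grid(config$n, config$alpha, b_tree = config$b_tree,
             b_mut = config$b_mut, seed = config$seed)[[1]]
}

#' Estimate priors on a grid of stem-time fractions
#'
#' One Monte Carlo pass shared across the grid: each simulated genealogy's
#' topology and coalescent intervals are reused for every `alpha` (common
#' random numbers), which smooths the empirical-Bayes objective of
#' [fit_alpha()] in `alpha`.
#'
#' @inheritParams coalescent_config
#' @param alphas numeric vector of stem-time fractions in (0, 1).
#' @return A named list of `prior_table`s, one per `alpha`.
#' @export
prior_grid <- function(n, alphas, b_tree = 1000, b_mut = 10000, seed = NULL) {
  stopifnot(is.numeric(alphas), length(alphas) >= 1,
            all(alphas > 0), all(alphas < 1))
  keys <- if (!is.null(seed))
    sprintf("n%d_a%.17g_t%d_m%d_s%d", as.integer(n), alphas,
            as.integer(b_tree), as.integer(b_mut), as.integer(seed))
  if (!is.null(seed) && all(vapply(keys, exists, logical(1),
                                   envir = .prior_cache))) {
    out <- lapply(keys, get, envir = .prior_cache)
    names(out) <- format(alphas)
    return(out)
  }
  tallies <- with_local_seed(seed,
    prior_mc_cpp(as.integer(n), as.numeric(alphas),
                 as.integer(b_tree), as.integer(b_mut)))
  out <- lapply(seq_along(alphas), function(i) {
    build_prior_table(tallies[i, ],
                      coalescent_config(n, alphas[i], b_tree, b_mut, seed))
  })
  names(out) <- format(alphas)
  if (!is.null(seed))
    for (i in seq_along(keys)) assign(keys[i], out[[i]], envir = .prior_cache)
  out
}

#' Serialize a prior table to JSON
#'
#' @param prior a `prior_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prior_json <- function(prior, path) {
  stopifnot(inherits(prior, "prior_table"))
  obj <- list(
    config = unclass(prior$config),
    order_prior = as.list(prior$order_prior),
    cond_genotype = apply(prior$cond_genotype, 1, as.list, simplify = FALSE),
    mc_counts = as.list(prior$mc_counts)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
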