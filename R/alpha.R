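#' Observed genotype-pair frequencies of a dataset
#'
#' Tallies the observed genotype pair `(i, j)` over every ordered pair of
#' distinct sites and every cell with both sites observed, normalized to
#' sum to 1. Ordered-pair tallying makes the table symmetric
#' (`f[i, j] = f[j, i]`) automatically.
#'
#' @param m a [genotype_matrix()] with at least 2 sites.
#' @return A 3 x 3 matrix `f` with `f[i + 1, j + 1]` the relative
#'   frequency of observing genotypes `(i, j)` at an ordered site pair.
#' @export
observed_pair_freqs <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (nrow(m) < 2) stop("need at least 2 sites")
  counts <- numeric(9)
  S <- nrow(m)
  for (a in seq_len(S - 1)) for (b in seq(a + 1, S)) {
    cnt <- pair_cell_counts(m, a, b)
    # count each unordered pair in both orientations
    counts <- counts + cnt + cnt[c(1, 4, 7, 2, 5, 8, 3, 6, 9)]
  }
  if (sum(counts) == 0)
    stop("no site pair has any jointly observed cell")
  matrix(counts / sum(counts), nrow = 3,
         dimnames = list(as.character(0:2), as.character(0:2)))
}

#' Model marginal distribution of observed genotype pairs
#'
#' The mixture, over the three order relations weighted by their prior
#' probabilities, of the observed-pair distribution given the relation:
#' `p[i, j] = sum over relations of Pr((i, j) | relation) Pr(relation)`.
#'
#' @param prior a `prior_table`.
#' @param e an [error_rates()] object.
#' @return A 3 x 3 matrix summing to 1, symmetric because the two directed
#'   relations share prior mass and transposed conditionals.
#' @export
model_marginals <- function(prior, e) {
  M <- relation_cell_matrix(prior, e)      # 3 x 9
  p <- as.numeric(prior$order_prior %*% M)
  matrix(p, nrow = 3, dimnames = list(as.character(0:2), as.character(0:2)))
}

#' Estimate the stem-time fraction alpha by empirical Bayes
#'
#' `alpha` is the proportion of time from the tumor's earliest mutation to
#' the MRCA of the sampled cells, and the single tunable parameter of the
#' coalescent prior. It is estimated by matching the model's marginal
#' distribution of observed genotype pairs against the dataset's observed
#' pair frequencies: `alpha_hat` minimizes the squared distance
#' `sum over i, j of (p[i, j](alpha) - f[i, j])^2` over a grid.
#'
#' Prior tables across the grid share simulated genealogies (common random
#' numbers; see [prior_grid()]), which keeps the objective curve smooth in
#' `alpha`. Because the prior does not depend on the data, a precomputed
#' grid of prior tables can be supplied and reused across datasets.
#'
#' @param m a [genotype_matrix()]; tuning uses all site pairs of `m`, so
#'   supply the largest matrix available (the estimate does not depend on
#'   any particular subset of sites).
#' @param grid candidate `alpha` values in (0, 1); default
#'   `seq(0.01, 0.99, by = 0.01)`.
#' @param e an [error_rates()] object.
#' @param b_tree,b_mut,seed Monte Carlo settings, as [coalescent_config()].
#' @param priors optional precomputed list of `prior_table`s matching
#'   `grid` (from [prior_grid()]); overrides the Monte Carlo settings.
#' @return An `alpha_fit` object: list with `alpha_hat`, `curve` (tibble of
#'   `alpha`, `objective`), `f_ij`, `p_ij` (the model marginals at
#'   `alpha_hat`), and the settings used.
#' @examples
#' \donttest{
#' fit <- fit_alpha(et_genotypes(), grid = seq(0.1, 0.9, by = 0.2),
#'                  b_tree = 50, b_mut = 500, seed = 1)
#' fit$alpha_hat
#' }
#' @export
fit_alpha <- function(m, grid = seq(0.01, 0.99, by = 0.01),
                      e = error_rates(), b_tree = 1000, b_mut = 10000,
                      seed = NULL, priors = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (length(grid) < 2) stop("`grid` needs at least 2 candidate alphas")
  if (any(grid <= 0 | grid >= 1)) stop("`grid` values must lie in (0, 1)")
  f <- observed_pair_freqs(m)
  if (is.null(priors))
    priors <- prior_grid(ncol(m), grid, b_tree = b_tree, b_mut = b_mut,
                         seed = seed)
  if (length(priors) != length(grid))
    stop("`priors` must have one prior_table per grid point")
  marginals <- lapply(priors, model_marginals, e = e)
  objective <- vapply(marginals, function(p) sum((p - f)^2), numeric(1))
  best <- which.min(objective)
  structure(list(
    alpha_hat = grid[best],
    curve = tibble::tibble(alpha = grid, objective = unname(objective)),
    f_ij = f,
    p_ij = marginals[[best]],
    error_rates = e,
    n = ncol(m),
    b_tree = b_tree, b_mut = b_mut, seed = seed
  ), class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat("<alpha_fit> alpha_hat =", format(x$alpha_hat),
      "over", nrow(x$curve), "grid points (n =", x$n, "cells)\n")
  cat("objective at optimum:",
      format(min(x$curve$objective), digits = 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Objective curve of an alpha fit
#'
#' @param x an `alpha_fit`.
#' @param ... unused.
#' @return The `(alpha, objective)` tibble.
#' @export
tidy.alpha_fit <- function(x, ...) x$curve

#' One-row summary of an alpha fit
#'
#' @param x an `alpha_fit`.
#' @param ... unused.
#' @return A one-row tibble: `alpha_hat`, `objective`, `n`, grid size and
#'   Monte Carlo settings.
#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(alpha_hat = x$alpha_hat,
                 objective = min(x$curve$objective),
                 n = x$n, grid_size = nrow(x$curve),
                 b_tree = x$b_tree, b_mut = x$b_mut)
}

#' Plot the empirical-Bayes objective curve
#'
#' @param object an `alpha_fit`.
#' @param ... unused.
#' @return A ggplot: squared distance between model marginals and observed
#'   pair frequencies against `alpha`, with the minimizer marked.
#' @export
autoplot.alpha_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$alpha,
                                             y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$alpha_hat, linetype = "dashed") +
    ggplot2::labs(
      x = expression(alpha),
      y = "squared distance to observed pair frequencies",
      title = sprintf("Stem-time fraction estimate: alpha = %.2f",
                      object$alpha_hat)
    ) +
    ggplot2::theme_minimal()
}

#' Write the alpha objective curve and estimate
#'
#' @param fit an `alpha_fit`.
#' @param curve_path TSV path for the `(alpha, objective)` curve, or `NULL`.
#' @param json_path JSON path for the fit summary, or `NULL`.
#' @return `fit`, invisibly.
#' @export
write_alpha_fit <- function(fit, curve_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "alpha_fit"))
  if (!is.null(curve_path))
    utils::write.table(fit$curve, curve_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(alpha_hat = fit$alpha_hat, objective = min(fit$curve$objective),
           n = fit$n, b_tree = fit$b_tree, b_mut = fit$b_mut,
           seed = fit$seed),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(fit)
}
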