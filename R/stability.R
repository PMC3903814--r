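branch_keys <- function(tree) {
  if (nrow(tree$edges) == 0) return(character(0))
  paste0(tree$edges$from, "->", tree$edges$to)
}

new_stability_report <- function(kind, n_replicates, root_counts,
                                 branch_counts, full_tree, failures) {
  structure(list(kind = kind, n_replicates = n_replicates,
                 root_counts = root_counts, branch_counts = branch_counts,
                 full_tree = full_tree, failures = failures),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", x$n_replicates, x$kind,
      "leave-one-out replicates\n")
  cat("full-tree root", x$full_tree$root, "recovered as root in",
      x$root_counts$count[x$root_counts$site == x$full_tree$root],
      "replicates\n")
  if (nrow(x$branch_counts))
    cat("branch recovery range:", min(x$branch_counts$count), "to",
        max(x$branch_counts$count), "\n")
  if (length(x$failures)) cat(length(x$failures), "replicates failed\n")
  invisible(x)
}

#' Leave-one-out stability over samples
#'
#' Re-runs the full pipeline `n` times, omitting one cell each time, and
#' tallies how often the full-data tree's root site recurs as root and how
#' often each of its branches recurs. Because the coalescent prior depends
#' only on the number of cells (not on which cell is dropped), a single
#' prior table at `n - 1` cells is shared across all replicates.
#'
#' @param m a [genotype_matrix()] with at least 3 cells.
#' @param e an [error_rates()] object.
#' @param alpha stem-time fraction (held fixed across replicates).
#' @param b_tree,b_mut Monte Carlo settings for the shared priors.
#' @param seed master seed; the full-data and leave-one-out priors use
#'   seeds derived from it.
#' @param full optional precomputed full-data `mutation_analysis` (must
#'   match `m`); saves one prior estimation.
#' @return A `stability_report`: `root_counts` (tibble `site`, `count`
#'   over all sites appearing as a replicate root), `branch_counts`
#'   (tibble `from`, `to`, `count` for every branch of the full-data
#'   tree), `n_replicates`, the full-data tree, and any replicate
#'   failures.
#' @export
loo_samples <- function(m, e = error_rates(), alpha = 0.92, b_tree = 1000,
                        b_mut = 10000, seed = NULL, full = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  n <- ncol(m)
  if (n < 3) stop("need at least 3 cells for leave-one-out")
  if (is.null(full))
    full <- infer_mutation_tree(m, e, alpha, b_tree, b_mut, seed = seed)
  prior_loo <- estimate_priors(coalescent_config(
    n - 1L, alpha, b_tree = b_tree, b_mut = b_mut,
    seed = if (!is.null(seed)) seed + 1L))
  run_loo(lapply(seq_len(n), function(k) m[, -k]),
          "sample", prior_loo, e, full$tree)
}

#' Leave-one-out stability over sites
#'
#' As [loo_samples()] but dropping one mutation site per replicate; branch
#' recovery is tallied over full-tree branches not incident to the dropped
#' site. The prior is unchanged (it depends on cells, not sites) and is
#' reused from the full-data analysis.
#'
#' @inheritParams loo_samples
#' @return A `stability_report`.
#' @export
loo_sites <- function(m, e = error_rates(), alpha = 0.92, b_tree = 1000,
                      b_mut = 10000, seed = NULL, full = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (nrow(m) < 3) stop("need at least 3 sites for leave-one-out")
  if (is.null(full))
    full <- infer_mutation_tree(m, e, alpha, b_tree, b_mut, seed = seed)
  run_loo(lapply(seq_len(nrow(m)), function(k) m[-k, ]),
          "site", full$prior, e, full$tree,
          dropped_sites = rownames(m))
}

run_loo <- function(matrices, kind, prior, e, full_tree,
                    dropped_sites = NULL) {
  full_branches <- branch_keys(full_tree)
  full_from <- full_tree$edges$from
  full_to <- full_tree$edges$to
  branch_tally <- stats::setNames(integer(length(full_branches)),
                                  full_branches)
  branch_possible <- stats::setNames(integer(length(full_branches)),
                                     full_branches)
  root_tally <- list()
  failures <- character(0)
  for (k in seq_along(matrices)) {
    res <- tryCatch({
      pm <- classify_pairs(matrices[[k]], prior, e)
      min_arborescence(build_order_digraph(pm))
    }, error = function(err) err)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", k,
                                      conditionMessage(res)))
      next
    }
    root_tally[[length(root_tally) + 1]] <- res$root
    rep_branches <- branch_keys(res)
    eligible <- if (is.null(dropped_sites)) full_branches
      else full_branches[full_from != dropped_sites[k] &
                           full_to != dropped_sites[k]]
    branch_possible[eligible] <- branch_possible[eligible] + 1L
    hits <- intersect(eligible, rep_branches)
    branch_tally[hits] <- branch_tally[hits] + 1L
  }
  roots <- unlist(root_tally)
  root_counts <- tibble::tibble(site = names(table(roots)),
                                count = as.integer(table(roots))) |>
    dplyr::arrange(dplyr::desc(.data$count))
  branch_counts <- if (length(full_branches)) {
    tibble::tibble(
      from = full_from,
      to = full_to,
      count = unname(branch_tally),
      n_eligible = unname(branch_possible)
    )
  } else {
    tibble::tibble(from = character(0), to = character(0),
                   count = integer(0), n_eligible = integer(0))
  }
  new_stability_report(kind, length(matrices), root_counts, branch_counts,
                       full_tree, failures)
}

#' Tidy branch-recovery table of a stability report
#'
#' @param x a `stability_report`.
#' @param ... unused.
#' @return The `branch_counts` tibble.
#' @export
tidy.stability_report <- function(x, ...) x$branch_counts

#' Plot leave-one-out branch recovery
#'
#' @param object a `stability_report`.
#' @param ... unused.
#' @return A ggplot bar chart of per-branch recovery counts.
#' @export
autoplot.stability_report <- function(object, ...) {
  d <- object$branch_counts |>
    dplyr::mutate(branch = paste(.data$from, .data$to, sep = " → "))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$branch,
                                                     .data$count),
                                  y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("replicates (of %d) containing branch",
                                        object$n_replicates),
                  title = sprintf("%s leave-one-out branch recovery",
                                  tools::toTitleCase(object$kind))) +
    ggplot2::theme_minimal()
}

#' Write a stability report as TSV and/or JSON
#'
#' @param report a `stability_report`.
#' @param tsv_path branch-count TSV path, or `NULL`.
#' @param json_path JSON path, or `NULL`.
#' @return `report`, invisibly.
#' @export
write_stability_report <- function(report, tsv_path = NULL,
                                   json_path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  if (!is.null(tsv_path))
    utils::write.table(report$branch_counts, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(kind = report$kind, n_replicates = report$n_replicates,
           root_counts = report$root_counts,
           branch_counts = report$branch_counts,
           failures = report$failures),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
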