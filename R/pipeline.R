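#' Full mutation-tree inference pipeline
#'
#' Runs the whole method on a genotype matrix: estimate the coalescent
#' prior at the supplied stem-time fraction `alpha` (with `n` set to the
#' number of cells), compute posterior order relations for every site
#' pair, build the directed order graph, and extract the maximum-posterior
#' mutation tree as the minimum-weight spanning arborescence.
#'
#' @param m a [genotype_matrix()].
#' @param e an [error_rates()] object; defaults to the measured
#'   single-cell assay rates (FD = 6.04e-5, AD = 0.4309).
#' @param alpha stem-time fraction for the prior; estimate it from data
#'   with [fit_alpha()] (0.92 for the ET dataset's full 712-site matrix).
#' @param b_tree,b_mut,seed Monte Carlo settings for [estimate_priors()].
#' @param prior optional precomputed `prior_table` (overrides the Monte
#'   Carlo settings; its `n` must match `ncol(m)`).
#' @return A `mutation_analysis`: list with `tree` (a `mutation_tree`),
#'   `posteriors` (a `posterior_matrix`), `digraph`, `prior`, and the
#'   inputs used.
#' @examples
#' \donttest{
#' res <- infer_mutation_tree(et_genotypes(), alpha = 0.92,
#'                            b_tree = 100, b_mut = 1000, seed = 1)
#' res$tree
#' }
#' @export
infer_mutation_tree <- function(m, e = error_rates(), alpha = 0.92,
                                b_tree = 1000, b_mut = 10000, seed = NULL,
                                prior = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (is.null(prior)) {
    prior <- estimate_priors(coalescent_config(ncol(m), alpha,
                                               b_tree = b_tree,
                                               b_mut = b_mut, seed = seed))
  } else {
    stopifnot(inherits(prior, "prior_table"))
    if (prior$config$n != ncol(m))
      stop("prior was estimated for n = ", prior$config$n,
           " cells but the matrix has ", ncol(m))
  }
  pm <- classify_pairs(m, prior, e)
  g <- build_order_digraph(pm)
  tree <- min_arborescence(g)
  structure(list(tree = tree, posteriors = pm, digraph = g, prior = prior,
                 error_rates = e, alpha = alpha),
            class = "mutation_analysis")
}

#' @export
print.mutation_analysis <- function(x, ...) {
  cat("<mutation_analysis> alpha =", x$alpha, "\n")
  print(x$tree)
  nn <- tree_nodes(x$tree)
  cat("  ", length(nn$leaves), "terminal leaves,", length(nn$internal),
      "internal nodes\n")
  invisible(x)
}

#' Export a mutation tree as DOT (Graphviz)
#'
#' Nodes are annotated with per-site mutation rates when a genotype matrix
#' is supplied; edges carry their `-log` posterior weights.
#'
#' @param tree a `mutation_tree`.
#' @param path output path.
#' @param m optional [genotype_matrix()] for node annotations.
#' @param branch_counts optional named counts (e.g. leave-one-out branch
#'   recovery) to print on edges, named `"from->to"`.
#' @return `path`, invisibly.
#' @export
write_tree_dot <- function(tree, path, m = NULL, branch_counts = NULL) {
  stopifnot(inherits(tree, "mutation_tree"))
  rates <- if (!is.null(m)) {
    r <- mutation_rates(m)
    stats::setNames(r$rate, r$site)
  }
  nodes <- unique(c(tree$root, tree$edges$from, tree$edges$to))
  nodes <- nodes[!is.na(nodes)]
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  node_lines <- vapply(nodes, function(v) {
    lab <- if (!is.null(rates) && v %in% names(rates))
      sprintf("%s\\nrate %.3f", v, rates[[v]]) else v
    sprintf("  %s [label=%s%s];", q(v), q(lab),
            if (identical(v, tree$root)) ", shape=doublecircle" else "")
  }, character(1))
  edge_lines <- vapply(seq_len(nrow(tree$edges)), function(i) {
    key <- paste0(tree$edges$from[i], "->", tree$edges$to[i])
    extra <- if (!is.null(branch_counts) && key %in% names(branch_counts))
      sprintf(" (%d)", branch_counts[[key]]) else ""
    sprintf("  %s -> %s [label=\"%.3g%s\"];", q(tree$edges$from[i]),
            q(tree$edges$to[i]), tree$edges$weight[i], extra)
  }, character(1))
  writeLines(c("digraph mutation_tree {", "  rankdir=TB;",
               node_lines, edge_lines, "}"), path)
  invisible(path)
}

#' Export a mutation tree as edge-list TSV and/or JSON
#'
#' @param tree a `mutation_tree`.
#' @param tsv_path edge-list TSV path, or `NULL`.
#' @param json_path JSON path, or `NULL`.
#' @return `tree`, invisibly.
#' @export
write_tree <- function(tree, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(tree, "mutation_tree"))
  if (!is.null(tsv_path))
    utils::write.table(tree$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(root = tree$root, total_weight = tree$total_weight,
           excluded = tree$excluded,
           edges = tree$edges),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(tree)
}

# depth-layered layout for plotting: x by in-order leaf position, y by depth
tree_layout <- function(tree) {
  nodes <- unique(c(tree$root, tree$edges$from, tree$edges$to))
  nodes <- nodes[!is.na(nodes)]
  depth <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  depth[tree$root] <- 0
  frontier <- tree$root
  while (length(frontier)) {
    nxt <- tree$edges$to[tree$edges$from %in% frontier]
    depth[nxt] <- depth[tree$edges$from[match(nxt, tree$edges$to)]] + 1
    frontier <- nxt
  }
  xpos <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  counter <- 0
  assign_x <- function(v) {
    kids <- sort(tree$edges$to[tree$edges$from == v])
    if (length(kids) == 0) {
      counter <<- counter + 1
      xpos[v] <<- counter
    } else {
      for (k in kids) assign_x(k)
      xpos[v] <<- mean(xpos[kids])
    }
  }
  assign_x(tree$root)
  tibble::tibble(node = nodes, x = xpos[nodes], y = -depth[nodes])
}

#' Plot a mutation tree
#'
#' @param object a `mutation_tree`.
#' @param ... unused.
#' @return A ggplot of the rooted tree, branches directed downwards from
#'   the root.
#' @export
autoplot.mutation_tree <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty tree") +
             ggplot2::theme_void())
  }
  lay <- tree_layout(object)
  seg <- dplyr::left_join(object$edges, lay, by = c(from = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(lay, by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_label(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node), size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste("Mutation tree rooted at", object$root))
}

#' @rdname autoplot.mutation_tree
#' @param tree a `mutation_tree`.
#' @export
plot_mutation_tree <- function(tree) autoplot.mutation_tree(tree)
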