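#' Directed order graph of maximum-posterior pairwise relations
#'
#' One directed edge per unordered site pair whose maximum a posteriori
#' relation is ancestral, oriented ancestor to descendant, weighted
#' `-log Pr(relation | D)`; independent pairs contribute no edge.
#'
#' @param pm a `posterior_matrix` from [classify_pairs()].
#' @return An `order_digraph`: list with `nodes` (all site labels) and
#'   `edges` (tibble `from`, `to`, `weight`, `posterior`).
#' @export
build_order_digraph <- function(pm) {
  stopifnot(inherits(pm, "posterior_matrix"))
  nodes <- attr(pm, "sites")
  fwd <- dplyr::filter(pm, .data$map_relation %in% "forward")
  bwd <- dplyr::filter(pm, .data$map_relation %in% "backward")
  edges <- dplyr::bind_rows(
    tibble::tibble(from = fwd$site_x, to = fwd$site_y,
                   posterior = fwd$p_forward),
    tibble::tibble(from = bwd$site_y, to = bwd$site_x,
                   posterior = bwd$p_backward)
  ) |>
    dplyr::mutate(weight = -log(.data$posterior)) |>
    dplyr::select("from", "to", "weight", "posterior")
  structure(list(nodes = nodes, edges = edges), class = "order_digraph")
}

#' @export
print.order_digraph <- function(x, ...) {
  cat("<order_digraph>", length(x$nodes), "sites,", nrow(x$edges),
      "directed order edges\n")
  invisible(x)
}

#' Sites involved in circular order relations
#'
#' With sequencing errors and missing data the raw pairwise relations can
#' be cyclic (x before y, y before z, z before x); this diagnostic reports
#' the sites lying on at least one directed cycle. Nodes are trimmed
#' iteratively while some node lacks either in- or out-edges; survivors lie
#' on cycles.
#'
#' @param g an `order_digraph`.
#' @return Character vector of site labels on cycles (empty when acyclic).
#' @export
digraph_cycles <- function(g) {
  stopifnot(inherits(g, "order_digraph"))
  e <- g$edges[, c("from", "to")]
  repeat {
    keep <- intersect(unique(e$from), unique(e$to))
    e2 <- e[e$from %in% keep & e$to %in% keep, ]
    if (nrow(e2) == nrow(e)) break
    e <- e2
  }
  sort(unique(c(e$from, e$to)))
}

# --- Chu-Liu/Edmonds -------------------------------------------------------

# minimal in-edge per target with deterministic tie-break
min_in_edges <- function(edges, nodes, root) {
  chosen <- integer(0)
  for (v in setdiff(nodes, root)) {
    cand <- which(edges$to == v)
    if (length(cand) == 0) return(NULL)           # v unreachable
    sub <- edges[cand, ]
    ord <- order(sub$w, sub$from_lab, sub$to_lab)
    chosen <- c(chosen, cand[ord[1]])
  }
  chosen
}

# recursive contraction; edges carry original ids. Returns vector of
# original edge ids forming a min arborescence rooted at `root`, or NULL
# when some node is unreachable.
chu_liu_edmonds <- function(edges, nodes, root) {
  edges <- edges[edges$to != root, , drop = FALSE]
  chosen <- min_in_edges(edges, nodes, root)
  if (is.null(chosen)) return(NULL)
  parent <- stats::setNames(edges$from[chosen], edges$to[chosen])
  # find a cycle in the parent function, if any
  cyc <- NULL
  state <- stats::setNames(integer(length(nodes)), nodes)  # 0 new 1 open 2 done
  for (v in nodes) {
    u <- v; path <- character(0)
    while (state[u] == 0 && u != root) {
      state[u] <- 1L; path <- c(path, u)
      u <- parent[[u]]
    }
    if (!is.na(state[u]) && state[u] == 1L && u != root) {
      cyc <- path[seq(match(u, path), length(path))]
      break
    }
    state[path] <- 2L
  }
  if (is.null(cyc)) return(edges$id[chosen])

  # contract the cycle into a supernode
  super <- paste0(".C", length(nodes))
  min_w <- stats::setNames(edges$w[chosen][match(cyc, edges$to[chosen])], cyc)
  in_cyc_chosen <- edges[chosen, ][edges$to[chosen] %in% cyc, ]
  keep <- !(edges$from %in% cyc & edges$to %in% cyc)
  e2 <- edges[keep, , drop = FALSE]
  into <- e2$to %in% cyc
  outof <- e2$from %in% cyc
  # reduced weights for edges entering the cycle
  e2$w[into] <- e2$w[into] - min_w[e2$to[into]]
  e2$entry <- ifelse(into, e2$to, NA_character_)
  e2$to[into] <- super
  e2$from[outof] <- super
  nodes2 <- c(setdiff(nodes, cyc), super)
  sub_ids <- chu_liu_edmonds(e2[, c("from", "to", "w", "id", "from_lab",
                                    "to_lab", "entry")],
                             nodes2, root)
  if (is.null(sub_ids)) return(NULL)
  # which original edge entered the cycle?
  entry_edge <- e2[e2$id %in% sub_ids & e2$to == super, ]
  entry_node <- entry_edge$entry[1]
  cycle_ids <- in_cyc_chosen$id[in_cyc_chosen$to != entry_node]
  c(sub_ids, cycle_ids)
}

#' Minimum-weight spanning arborescence (maximum-posterior mutation tree)
#'
#' Extracts the mutation tree from the directed order graph: the spanning
#' arborescence minimizing total `-log` posterior weight, which is the
#' maximum-posterior tree over all candidate trees and roots. The rooted
#' Chu-Liu/Edmonds algorithm is run from every node and the global minimum
#' kept. When no node reaches all others (heavily independent data can
#' disconnect the graph), the tree covers the largest root-reachable node
#' set and the excluded sites are flagged.
#'
#' @param g an `order_digraph` from [build_order_digraph()].
#' @return A `mutation_tree`: list with `root`, `edges` (tibble `from`,
#'   `to`, `weight`), `total_weight`, `excluded` (sites not spanned),
#'   `tie` (`TRUE` when another root achieves the same total weight).
#' @export
min_arborescence <- function(g) {
  stopifnot(inherits(g, "order_digraph"))
  nodes <- g$nodes
  if (nrow(g$edges) == 0)
    return(structure(list(root = NA_character_,
                          edges = tibble::tibble(from = character(0),
                                                 to = character(0),
                                                 weight = numeric(0)),
                          total_weight = 0, excluded = nodes, tie = FALSE),
                     class = "mutation_tree"))
  reach <- function(r) {
    seen <- r; frontier <- r
    while (length(frontier)) {
      nxt <- setdiff(g$edges$to[g$edges$from %in% frontier], seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    seen
  }
  reach_sets <- lapply(nodes, reach)
  sizes <- lengths(reach_sets)
  cover <- max(sizes)
  roots <- nodes[sizes == cover]
  base <- tibble::tibble(from = g$edges$from, to = g$edges$to,
                         w = g$edges$weight, id = seq_len(nrow(g$edges)),
                         from_lab = g$edges$from, to_lab = g$edges$to,
                         entry = NA_character_)
  best <- NULL
  tie <- FALSE
  for (r in roots) {
    span <- reach_sets[[match(r, nodes)]]
    er <- base[base$from %in% span & base$to %in% span, , drop = FALSE]
    ids <- chu_liu_edmonds(er, span, r)
    if (is.null(ids)) next
    tw <- sum(g$edges$weight[ids])
    if (is.null(best) || tw < best$tw - 1e-12) {
      best <- list(root = r, ids = ids, tw = tw)
      tie <- FALSE
    } else if (abs(tw - best$tw) <= 1e-12) {
      tie <- TRUE
      # deterministic tie-break: lexicographically smallest sorted edge list
      key <- function(ii) paste(sort(paste(g$edges$from[ii], g$edges$to[ii],
                                           sep = "->")), collapse = ";")
      if (key(ids) < key(best$ids)) best <- list(root = r, ids = ids, tw = tw)
    }
  }
  if (is.null(best)) stop("internal error: no arborescence found")
  edges <- g$edges[best$ids, c("from", "to", "weight")]
  edges <- edges[order(edges$from, edges$to), ]
  structure(list(root = best$root, edges = tibble::as_tibble(edges),
                 total_weight = best$tw,
                 excluded = setdiff(nodes, c(best$root, edges$to)),
                 tie = tie),
            class = "mutation_tree")
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat("<mutation_tree> root:", x$root, "|", nrow(x$edges), "branches,",
      "total weight", format(x$total_weight, digits = 6), "\n")
  if (length(x$excluded))
    cat("  excluded (unreachable) sites:",
        paste(x$excluded, collapse = ", "), "\n")
  if (isTRUE(x$tie)) cat("  note: tied alternative arborescence exists\n")
  invisible(x)
}

#' Leaves and internal nodes of a mutation tree
#'
#' @param tree a `mutation_tree`.
#' @return A list with `root`, `leaves` (nodes without children) and
#'   `internal` (non-root nodes with children).
#' @export
tree_nodes <- function(tree) {
  stopifnot(inherits(tree, "mutation_tree"))
  nodes <- unique(c(tree$root, tree$edges$from, tree$edges$to))
  nodes <- nodes[!is.na(nodes)]
  leaves <- setdiff(nodes, tree$edges$from)
  list(root = tree$root, leaves = sort(leaves),
       internal = sort(setdiff(nodes, c(leaves, tree$root))))
}
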