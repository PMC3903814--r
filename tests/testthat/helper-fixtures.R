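# small builders and independent oracles shared across test files

# the 7-sample, 2-site toy dataset used to illustrate pairwise ordering:
# genotype pairs (0,0),(0,0),(0,1),(0,1),(1,1),(1,1),(0,1) - the mutation
# at y is ancestral to the mutation at x
toy_two_site <- function() {
  genotype_matrix(rbind(
    x = c(0L, 0L, 0L, 0L, 1L, 1L, 0L),
    y = c(0L, 0L, 1L, 1L, 1L, 1L, 1L)
  ), sample_ids = paste0("s", 1:7))
}

random_genotype_matrix <- function(n_sites, n_cells, missing_rate = 0.2) {
  calls <- matrix(sample(c(0L, 1L, 2L), n_sites * n_cells, replace = TRUE,
                         prob = c(0.5, 0.35, 0.15)),
                  n_sites, n_cells)
  calls[runif(length(calls)) < missing_rate] <- NA_integer_
  genotype_matrix(calls, site_labels = paste0("g", seq_len(n_sites)),
                  sample_ids = paste0("c", seq_len(n_cells)))
}

# a deterministic prior table for likelihood tests (no Monte Carlo noise)
fixed_prior <- function(p_same = 0.3,
                        fwd = c(0.2, 0.3, 0, 0.5),
                        ind = c(0.2, 0.4, 0.4, 0)) {
  cond <- rbind(forward = fwd,
                backward = fwd[c(1, 3, 2, 4)],
                independent = ind)
  colnames(cond) <- c("00", "10", "01", "11")
  structure(list(
    order_prior = c(forward = p_same, backward = p_same,
                    independent = 1 - 2 * p_same),
    cond_genotype = cond,
    mc_counts = NULL,
    config = coalescent_config(2, 0.5)
  ), class = "prior_table")
}

# brute-force likelihood oracle: sums over every assignment of true
# genotype pairs to samples instead of using the per-sample factorization
brute_force_loglik <- function(m, x, y, relation, prior, e) {
  gx <- unclass(m)[x, ]; gy <- unclass(m)[y, ]
  ok <- !is.na(gx) & !is.na(gy)
  gx <- gx[ok]; gy <- gy[ok]
  K <- length(gx)
  true_pairs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  cond <- prior$cond_genotype[relation, c("00", "10", "01", "11")]
  total <- 0
  assignment <- rep(1L, K)
  repeat {
    term <- 1
    for (k in seq_len(K)) {
      tp <- true_pairs[[assignment[k]]]
      term <- term * pair_observation_prob(e, tp, c(gx[k], gy[k])) *
        cond[assignment[k]]
    }
    total <- total + term
    pos <- 1L
    while (pos <= K && assignment[pos] == 4L) {
      assignment[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > K) break
    assignment[pos] <- assignment[pos] + 1L
  }
  unname(log(total))
}

# exhaustive minimum-arborescence oracle: tries every root and every
# parent function, keeping the lightest acyclic spanning choice
brute_force_arborescence <- function(edges, nodes) {
  best <- NULL
  for (root in nodes) {
    others <- setdiff(nodes, root)
    in_edges <- lapply(others, function(v) which(edges$to == v))
    if (any(lengths(in_edges) == 0)) next
    combos <- expand.grid(in_edges)
    for (r in seq_len(nrow(combos))) {
      idx <- as.integer(combos[r, ])
      parent <- setNames(edges$from[idx], others)
      # spanning arborescence iff every node walks back to the root
      ok <- TRUE
      for (v in others) {
        u <- v; steps <- 0
        while (u != root && steps <= length(nodes)) {
          if (!u %in% names(parent)) { ok <- FALSE; break }
          u <- parent[[u]]; steps <- steps + 1
        }
        if (!ok || u != root) { ok <- FALSE; break }
      }
      if (!ok) next
      tw <- sum(edges$weight[idx])
      if (is.null(best) || tw < best$tw) best <- list(tw = tw, root = root)
    }
  }
  best
}

random_digraph <- function(n_nodes, edge_prob = 0.6) {
  nodes <- LETTERS[seq_len(n_nodes)]
  from <- character(0); to <- character(0)
  for (a in nodes) for (b in setdiff(nodes, a)) {
    if (runif(1) < edge_prob) { from <- c(from, a); to <- c(to, b) }
  }
  # at most one direction per unordered pair, as in an order digraph
  keep <- if (length(from))
    !duplicated(t(apply(cbind(from, to), 1, sort))) else logical(0)
  w <- round(runif(sum(keep), 0.1, 5), 3)
  edges <- tibble::tibble(from = from[keep], to = to[keep],
                          weight = w, posterior = exp(-w))
  structure(list(nodes = nodes, edges = edges), class = "order_digraph")
}
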