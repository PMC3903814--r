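#' @title Coalescent genealogies with a mutation stem
#' @description
#' The prior over pairwise mutation orders is defined by a neutral
#' Wright-Fisher (Kingman) genealogy of the `n` sampled cells, extended at
#' the root by a *stem*: the single-lineage branch running from the tumor's
#' earliest mutation event down to the MRCA of the sample. The stem
#' occupies a fraction `alpha` of the total time. Mutations placed on the
#' stem are carried by every sampled cell.
#'
#' These R-level samplers are the reference implementation used by the
#' forward simulator and by small-scale tests; the bulk Monte Carlo prior
#' estimation runs an equivalent compiled core (see [estimate_priors()]).
#' @name coalescent
NULL

#' Sample a Kingman coalescent topology
#'
#' Starting from `n` labelled lineages, repeatedly merges a uniformly
#' chosen pair until a single lineage remains, then adds the stem branch
#' above the MRCA. Branches are numbered `1..n` for the leaf branches,
#' `n+1..2n-2` for internal branches in merge order, and `2n-1` for the
#' stem.
#'
#' @param n number of sampled cells (leaves), at least 2.
#' @return A list of class `coalescent_topology` with elements `n`;
#'   `parent` (integer, `NA` for the stem); `k_birth` (number of lineages
#'   present when the branch first exists, looking backward in time);
#'   `k_merge` (number of lineages during whose interval the branch
#'   coalesces into its parent; 1 for the stem); and `leafset` (logical
#'   `(2n-1) x n` matrix, `leafset[b, l]` true when leaf `l` descends from
#'   branch `b`).
#' @export
sample_topology <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("`n` must be a single integer >= 2")
  n <- as.integer(n)
  m <- 2L * n - 1L
  parent <- rep(NA_integer_, m)
  k_birth <- rep(NA_integer_, m)
  k_merge <- rep(NA_integer_, m)
  leafset <- matrix(FALSE, m, n)
  leafset[cbind(seq_len(n), seq_len(n))] <- TRUE
  k_birth[seq_len(n)] <- n
  active <- seq_len(n)
  nxt <- n
  for (k in seq(n, 2L)) {
    pick <- sample.int(length(active), 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    nxt <- nxt + 1L
    parent[c(a, b)] <- nxt
    k_merge[c(a, b)] <- k
    k_birth[nxt] <- k - 1L
    leafset[nxt, ] <- leafset[a, ] | leafset[b, ]
    active <- c(active[-pick], nxt)
  }
  k_merge[nxt] <- 1L  # the stem persists to the earliest mutation event
  structure(list(n = n, parent = parent, k_birth = k_birth,
                 k_merge = k_merge, leafset = leafset),
            class = "coalescent_topology")
}

#' Sample coalescent interval durations with a fixed stem fraction
#'
#' `T[k]` is the duration during which exactly `k` ancestral lineages
#' exist. For `k >= 2` these are independent exponentials with rate
#' `choose(k, 2) = k (k - 1) / 2`, the neutral Wright-Fisher coalescent
#' rates. The stem duration `T[1]` is then set deterministically so that
#' `T[1] / sum(T) = alpha` exactly.
#'
#' @param n number of sampled cells, at least 2.
#' @param alpha stem-time fraction, strictly between 0 and 1.
#' @return Numeric vector `T` of length `n`, `T[1]` the stem.
#' @export
sample_intervals <- function(n, alpha) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("`n` must be a single integer >= 2")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1")
  k <- seq(2L, n)
  t_coal <- stats::rexp(length(k), rate = k * (k - 1) / 2)
  c(alpha / (1 - alpha) * sum(t_coal), t_coal)
}

#' Sample a complete genealogy (topology + intervals + branch lengths)
#'
#' @inheritParams sample_intervals
#' @return A list of class `genealogy`: the [sample_topology()] fields plus
#'   `intervals` (the `T` vector), `t_start` (forward time, measured from
#'   the earliest mutation event, at which each branch begins), `length`
#'   (branch durations) and `total_length` (`sum(k * T[k])`).
#' @export
sample_genealogy <- function(n, alpha) {
  topo <- sample_topology(n)
  tt <- sample_intervals(n, alpha)
  S <- cumsum(tt)                       # S[j] = end of interval j, forward time
  # branch b is alive through intervals k_merge(b) .. k_birth(b), which are
  # contiguous in forward time
  t_start <- c(0, S)[topo$k_merge]
  len <- S[topo$k_birth] - t_start
  structure(c(topo, list(intervals = tt, t_start = t_start, length = len,
                         total_length = sum(seq_len(n) * tt))),
            class = c("genealogy", "coalescent_topology"))
}

# one branch-length-uniform mutation placement: branch index + forward time
place_mutation <- function(g, placement = c("branch-length", "interval-uniform")) {
  placement <- match.arg(placement)
  if (placement == "branch-length") {
    u <- stats::runif(1, 0, g$total_length)
    cum <- cumsum(g$length)
    b <- which(u <= cum)[1]
    list(branch = b, time = g$t_start[b] + (u - c(0, cum)[b]))
  } else {
    # the alternative reading: a time uniform on (0, sum(T)), then one of the
    # lineages extant at that time chosen uniformly
    tt <- stats::runif(1, 0, sum(g$intervals))
    k <- which(tt <= cumsum(g$intervals))[1]
    alive <- which(g$k_merge <= k & k <= g$k_birth)
    list(branch = alive[sample.int(length(alive), 1)], time = tt)
  }
}

#' Place a pair of mutations on a genealogy and read off their order
#'
#' Two mutations are dropped independently on the genealogy, each landing
#' on a (branch, time) point uniformly over total branch length
#' `sum(k * T[k])`. The pair's order relation is `"forward"` (first
#' mutation ancestral to the second), `"backward"`, or `"independent"`
#' (distinct lineages: disjoint carrier sets). If both land on one branch
#' the earlier placement is the ancestor.
#'
#' @param g a [sample_genealogy()] result.
#' @param placement `"branch-length"` (default; placement probability of a
#'   lineage during interval k is `T[k] / sum(i * T[i])`) or
#'   `"interval-uniform"` (time uniform on `sum(T)`, then a uniformly
#'   chosen extant lineage).
#' @return A list with `relation` (one of `"forward"`, `"backward"`,
#'   `"independent"`), `branches`, `times`, and `genotypes`: an `n x 2`
#'   0/1 matrix, row `l` giving leaf `l`'s true genotype at the two sites
#'   (1 when the leaf descends from the mutation's branch).
#' @export
place_mutation_pair <- function(g, placement = "branch-length") {
  stopifnot(inherits(g, "genealogy"))
  p1 <- place_mutation(g, placement)
  p2 <- place_mutation(g, placement)
  s1 <- g$leafset[p1$branch, ]
  s2 <- g$leafset[p2$branch, ]
  # on a tree two carrier sets are nested or disjoint; nesting = ancestry
  relation <- if (p1$branch == p2$branch) {
    if (p1$time <= p2$time) "forward" else "backward"
  } else if (all(!s2 | s1)) {
    "forward"
  } else if (all(!s1 | s2)) {
    "backward"
  } else if (!any(s1 & s2)) {
    "independent"
  } else {
    stop("internal error: overlapping, non-nested leaf sets on a tree")
  }
  list(relation = relation,
       branches = c(p1$branch, p2$branch),
       times = c(p1$time, p2$time),
       genotypes = cbind(x = as.integer(s1), y = as.integer(s2)))
}
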