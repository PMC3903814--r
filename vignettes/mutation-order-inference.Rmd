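---
title: "Inferring the temporal order of somatic mutations from single-cell genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the temporal order of somatic mutations from single-cell genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutorder)
```

## The problem

Single-cell DNA sequencing of a tumor yields, for each sampled cell, a
genotype call at each candidate mutation site: 0 (homozygous wildtype), 1
(heterozygous mutation) or 2 (homozygous mutation), with many entries
missing where amplification failed. If the calls were error-free and each
site mutated exactly once, the sites' carrier sets would form a perfect
phylogeny and the temporal order of any two mutations could be read off
by set inclusion: if every cell carrying mutation $y$ also carries $x$,
then $x$ happened first on the same lineage. Real single-cell data break
this logic: multiple-displacement amplification loses one allele at a
heterozygous site almost half the time (allelic dropout), occasionally
invents a variant (false discovery), and leaves a large fraction of calls
missing. `mutorder` implements a probabilistic treatment of exactly this
setting.

For each unordered pair of sites $(x, y)$ the method weighs three
mutually exclusive order relations: $x \rightarrow y$ ($x$ ancestral to
$y$ on one cell lineage), $x \leftarrow y$, and $x \nleftrightarrow y$
(distinct lineages). It combines

* a **coalescent prior** over the three relations and over the true
  binary genotype pair a random cell shows under each relation,
* an **error model** mapping true genotypes $\{0, 1\}$ to observed calls
  $\{0, 1, 2\}$, and
* **Bayes theorem**, applied independently per pair, cells with either
  call missing being dropped from that pair only.

The maximum-posterior relations define a directed order graph with edge
weights $-\log \Pr(x \sim y \mid D)$, and the **mutation tree** is its
minimum-weight spanning arborescence — equivalently the rooted tree with
maximum posterior product over its branches.

## The prior: a Kingman genealogy with a stem

The $n$ sampled cells are assumed exchangeable draws from a neutral
Wright–Fisher population. Their genealogy has interval durations $T_k$
(the time during which exactly $k$ ancestral lineages exist),
$T_k \sim \text{Exponential}(k(k-1)/2)$ for $k \ge 2$. Above the MRCA
sits a *stem*: the single lineage running back to the tumor's earliest
mutation event. Its duration $T_1$ is fixed so that

$$\alpha = \frac{T_1}{\sum_{k=1}^n T_k}$$

is the fraction of total time from the earliest mutation to the MRCA.
Mutations dropped on the stem are carried by every sampled cell.

The prior is estimated by Monte Carlo (`estimate_priors()`): simulate
`b_tree` genealogies, drop `b_mut` independent mutation pairs on each,
with each mutation landing on a lineage-interval point with probability
proportional to branch length, i.e. a specific lineage during interval
$k$ receives mass $T_k / \sum_i i \, T_i$. A pair on one lineage is
ancestral (the earlier placement is the ancestor — including the
probability-zero-in-theory case of a shared branch, where placement times
break the tie); otherwise the carrier sets are disjoint and the pair is
independent. Directed priors are symmetrized by construction,
$\Pr(x \rightarrow y) = \Pr(x \leftarrow y) = \tfrac12 \Pr(\text{same
lineage})$, so Monte Carlo noise never favors a direction.

Two modeling choices deserve a note, both made once and used throughout:

* **Placement weighting.** A description of this placement step as "a
  uniform time, then a uniformly chosen extant lineage" would weight a
  lineage in interval $k$ by $T_k / (k \sum_i T_i)$ instead. The two
  differ for $k \ge 2$; we use the branch-length-proportional form, the
  standard infinite-sites assumption that mutation opportunity scales
  with lineage duration, and expose the alternative in the R-level
  sampler (`place_mutation(..., placement = "interval-uniform")`) for
  comparison.
* **Counting unit for genotype conditionals.** The conditional
  distribution of a true genotype pair given a relation,
  $\Pr((i', j') \mid x \sim y)$, is tallied *per leaf*: each simulated
  pair contributes one observation per sampled cell. This is the unit the
  per-cell likelihood factor consumes. The tallies follow exactly from
  carrier-set sizes (an ancestor/descendant pair with carrier sizes
  $(a, d)$ gives $n - a$ cells $(0,0)$, $a - d$ cells $(1,0)$ and $d$
  cells $(1,1)$), so no per-leaf loop is needed.

The Monte Carlo core is compiled (Rcpp) and consumes R's RNG stream, so
every result is reproducible under a seed. Defaults `b_tree = 1000`,
`b_mut = 10000` give prior standard errors on the order of $10^{-3}$ or
less; with these sizes a full 18-site analysis runs in seconds and a
99-point $\alpha$ grid at $n = 58$ in about three minutes on one core.
Priors are cached per `(n, alpha, b_tree, b_mut, seed)` within a session,
and a whole grid is computed in one pass that reuses each genealogy's
topology and coalescent intervals across $\alpha$ values (common random
numbers), which smooths the empirical-Bayes objective.

Correctness anchors tested in the suite: at $n = 2$ the independence
prior has the closed form $2 / (c + 2)^2$ with $c = \alpha/(1-\alpha)$
(the stem/leaf length ratio is deterministic at $n = 2$); the
conditional-genotype table carries exact structural zeros
($\Pr((0,1) \mid x \rightarrow y) = 0$, mirrored for the backward
relation, and $\Pr((1,1) \mid x \nleftrightarrow y) = 0$); and the
compiled tallies agree with the independent R-level genealogy sampler.

## The error model

True genotypes are binary — a true homozygous mutation at a base pair is
considered vanishingly unlikely — while observed calls are ternary.
With false-discovery rate $FD$ and allelic-dropout rate $AD$:

| true \\ observed | 0 | 1 | 2 |
|---|---|---|---|
| 0 | $1 - FD - c$ | $FD$ | $c$ |
| 1 | $AD/2$ | $1 - AD$ | $AD/2$ |

$c = \Pr(\text{obs } 2 \mid \text{true } 0)$ is not derivable from $FD$
and $AD$; it defaults to 0 (negligible) but is exposed as `hom_fd`.
Errors at the two sites of a pair are independent, so pair probabilities
factorize. Defaults $FD = 6.04 \times 10^{-5}$, $AD = 0.4309$ are the
rates measured for the essential-thrombocythemia (ET) single-cell assay
the package's worked dataset comes from.

All likelihood arithmetic is done in log space with explicit $-\infty$
for structurally impossible observations (relevant when error rates are
set to zero), and posteriors are normalized by log-sum-exp. Posterior
ties — degenerate but reachable, e.g. two sites with identical carrier
sets under a zero-error model, where the two directions are
observationally equivalent — are resolved by preferring independence,
then the forward direction, and are flagged in the output: the package
refuses to invent a direction silently. A pair with no jointly observed
cell is reported unclassifiable rather than guessed at, and contributes
no edge to the order graph.

## Estimating the stem fraction

$\alpha$ is the single tuned parameter. `fit_alpha()` estimates it by
empirical Bayes: the model's marginal distribution over observed
genotype pairs, $p_{ij}(\alpha) = \sum_{x \sim y} \Pr((i,j) \mid x \sim
y) \Pr(x \sim y)$, is matched to the pooled observed relative
frequencies $f_{ij}$ (tallied over all ordered site pairs and all
jointly observed cells, hence symmetric), minimizing
$\sum_{i,j} (p_{ij} - f_{ij})^2$ over a grid, by default
$0.01, 0.02, \ldots, 0.99$. Grid search (not continuous optimization) is
deliberate: the objective is a Monte Carlo surface and the common-random-
numbers grid keeps it smooth enough for an argmin to be stable.

Because the prior is data-independent, the same prior grid can be — and
in the test suite is — shared across datasets and replicates. Tuning
should use the *largest* available matrix (for the ET study, the full
712-site assay, which yields $\hat\alpha = 0.92$); the estimate does not
depend on which subset of sites is analyzed afterwards. The full
712-site matrix is not redistributed here, so the packaged analyses take
$\alpha = 0.92$ as the published estimate, and the generator-based
recovery study below characterizes the estimator instead.

**Identifiability limitation.** All sites of one dataset share one
genealogy, so $f_{ij}$ fluctuates with the realized coalescent
branch-length profile no matter how many sites are typed. Simulation at
the study's scale ($n = 58$ cells, default error and missingness) shows
the estimator is nearly unbiased across $\alpha$ (the median of
$\hat\alpha$ over replicates sits within a few hundredths of the truth),
but single-replicate errors are large when the stem is short: the median
of $|\hat\alpha - \alpha|$ is roughly 0.25 at $\alpha = 0.3$ and 0.1 at
$\alpha = 0.6$, shrinking to about 0.05 at $\alpha = 0.9$. Using 100
instead of 18 sites does not help, confirming the shared genealogy as
the noise source. A strong stem — the regime the ET data occupy — is
also the regime where $\alpha$ is well determined; weak-stem estimates
should be treated as order-of-magnitude only.

## From pairwise posteriors to a tree

Each pair's maximum-posterior relation contributes at most one directed
edge (none when independent wins), weighted $-\log$ posterior. The
directed graph is generally not a tree and, with errors and missingness,
often contains cycles; `digraph_cycles()` reports the sites involved as
a diagnostic (the transitive-reduction alternative to tree-building is
exactly what cycles break, which is why the spanning-tree route is
used). `min_arborescence()` runs the rooted Chu–Liu/Edmonds algorithm
from every candidate root and keeps the global minimum-weight spanning
arborescence; minimizing summed $-\log$ posteriors is maximizing the
posterior product, so the result is the maximum-posterior tree over all
roots and topologies. The implementation is validated against exhaustive
enumeration of all spanning arborescences on hundreds of random small
digraphs. Weight ties between arborescences are broken by lexicographic
edge lists and reported. When no root reaches every site (heavily
independent data), the tree covers the largest reachable set and the
excluded sites are flagged rather than failing.

## The synthetic-data generator

`simulate_genotypes()` runs the assumed generative process forward: one
stem-extended genealogy per dataset, one branch-length-uniform mutation
per site, leaf genotypes by subtree membership, FD/AD corruption, then
masking completely at random. Defaults mirror the worked ET dataset
(45% missingness; FD/AD as above). What it deliberately does *not*
emulate: genotype-dependent missingness (the real assay's dropout is
unlikely to be independent of amplification quality), doublets, copy
number events, or site-specific error rates. Passing recovery tests on
this generator therefore demonstrate correctness of the inference under
its own assumptions, not robustness to real-assay artifacts beyond them.

With errors and missingness switched off the generator emits perfect
phylogenies, and the pipeline then provably recovers every planted
relation among sites with distinct carrier sets (tested); sites whose
mutations land on the same branch are observationally symmetric and are
reported as flagged direction ties.

## Numerical and design choices, collected

* Log-space likelihoods, log-sum-exp normalization, explicit $-\infty$.
* Pairwise-complete case analysis: a cell is dropped only from pairs
  where one of the two sites is missing.
* Tie-breaks: posterior ties prefer independence then forward, flagged;
  arborescence ties broken lexicographically, flagged.
* The stem interval $T_1$ is set deterministically from $\alpha$ and the
  simulated $T_2, \ldots, T_n$, so $T_1/\sum T_k = \alpha$ holds exactly
  in every genealogy.
* Leave-one-out over samples shares a single prior at $n - 1$ cells
  across all replicates — the prior depends on how many cells, never on
  which — making the 58-replicate study cost two prior estimations
  total.
* Problem sizes used by the shipped tests: full-default prior estimation
  (1000 × 10000) for the 18-site analyses; reduced Monte Carlo sizes
  (hundreds × thousands) for distributional unit checks where the
  statistical resolution required is far coarser.

## The worked dataset

`et_genotypes()` ships the 18-site × 58-cell transformed genotype table
of the ET tumor study (Hou et al. 2012 selection): 468 missing entries
(45%), per-site mutated fractions ranging from 0.86 (DLEC1) down to 0.10
(PABPC1). Running `infer_mutation_tree()` at $\alpha = 0.92$ with
default error rates yields a tree rooted at DLEC1 with 12 terminal
leaves and 5 internal nodes, with SESN2 the direct ancestor of nine
sites; 58 sample leave-one-out replicates recover DLEC1 as root in 50
and every full-tree branch in at least 49. The transcription of the
published table used here differs from the journal rendering by roughly
one call per row (the printed extreme rates are 0.864 and 0.122); the
rank order of sites and every tree-level result are unaffected.
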