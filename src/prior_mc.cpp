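#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Monte Carlo tallies for the coalescent prior over pairwise mutation
// orders, for one sample size n and a vector of stem-time fractions alpha.
//
// For each of b_tree genealogies: sample a Kingman topology and the
// coalescent intervals T_2..T_n (shared across the alpha grid - common
// random numbers in alpha), then per alpha set the stem T_1 =
// alpha/(1-alpha) * sum(T_k) and drop b_mut independent mutation pairs,
// each placed branch-length-uniformly (lineage during interval k has mass
// T_k / sum(i*T_i)). A pair is "same lineage" when one branch is ancestral
// to the other (carrier sets nested) or both land on one branch (earlier
// placement is the ancestor); otherwise the carrier sets are disjoint and
// the pair is independent.
//
// True-genotype tallies are per leaf and follow from carrier-set sizes:
// an ancestor/descendant pair with carrier sizes (a, d), d <= a, gives
// n-a leaves (0,0), a-d leaves (1,0), d leaves (1,1) and none (0,1);
// an independent pair with sizes (s1, s2) gives n-s1-s2 (0,0), s1 (1,0),
// s2 (0,1) and none (1,1).
//
// Returns an (n_alpha x 8) matrix: n_pairs, n_same, f00, f10, f11
// (ancestor-first per-leaf tallies over same-lineage pairs), i00, i10, i01
// (per-leaf tallies over independent pairs, unsymmetrized).
//
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix prior_mc_cpp(int n, NumericVector alphas, int b_tree, int b_mut) {
  if (n < 2) stop("n must be >= 2");
  if (b_tree < 1 || b_mut < 1) stop("b_tree and b_mut must be >= 1");
  const int na = alphas.size();
  for (int a = 0; a < na; ++a)
    if (!(alphas[a] > 0.0 && alphas[a] < 1.0))
      stop("every alpha must lie strictly in (0, 1)");

  const int m = 2 * n - 1;              // branches incl. the stem
  const int words = (n + 63) / 64;
  NumericMatrix out(na, 8);
  colnames(out) = CharacterVector::create("n_pairs", "n_same", "f00", "f10",
                                          "f11", "i00", "i10", "i01");

  std::vector<uint64_t> bits(static_cast<size_t>(m) * words);
  std::vector<int> sz(m), k_birth(m), k_merge(m), active(n);
  std::vector<double> tcoal(n + 1), S(n + 1), cum(m), tstart(m);

  for (int t = 0; t < b_tree; ++t) {
    // --- topology ---
    std::fill(bits.begin(), bits.end(), 0ULL);
    for (int l = 0; l < n; ++l) {
      bits[static_cast<size_t>(l) * words + l / 64] = 1ULL << (l % 64);
      sz[l] = 1; k_birth[l] = n; active[l] = l;
    }
    int nxt = n;
    for (int k = n; k >= 2; --k) {
      int i = static_cast<int>(unif_rand() * k); if (i >= k) i = k - 1;
      int j = static_cast<int>(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = active[i], b = active[j];
      k_merge[a] = k; k_merge[b] = k;
      k_birth[nxt] = k - 1;
      sz[nxt] = sz[a] + sz[b];
      for (int w = 0; w < words; ++w)
        bits[static_cast<size_t>(nxt) * words + w] =
          bits[static_cast<size_t>(a) * words + w] |
          bits[static_cast<size_t>(b) * words + w];
      // replace slots i, j by the parent and the last active lineage
      int hi = std::max(i, j), lo = std::min(i, j);
      active[lo] = nxt;
      active[hi] = active[k - 1];
      ++nxt;
    }
    k_merge[m - 1] = 1;                 // the stem

    // --- intervals T_2..T_n, shared across the alpha grid ---
    double tail = 0.0;
    for (int k = 2; k <= n; ++k) {
      tcoal[k] = exp_rand() / (k * (k - 1) / 2.0);
      tail += tcoal[k];
    }

    for (int a = 0; a < na; ++a) {
      const double alpha = alphas[a];
      tcoal[1] = alpha / (1.0 - alpha) * tail;
      S[0] = 0.0;
      for (int k = 1; k <= n; ++k) S[k] = S[k - 1] + tcoal[k];
      double tot = 0.0;
      for (int b = 0; b < m; ++b) {
        tstart[b] = S[k_merge[b] - 1];
        tot += S[k_birth[b]] - tstart[b];
        cum[b] = tot;
      }

      double n_same = 0, f00 = 0, f10 = 0, f11 = 0, i00 = 0, i10 = 0, i01 = 0;
      for (int p = 0; p < b_mut; ++p) {
        double u1 = unif_rand() * tot;
        double u2 = unif_rand() * tot;
        int b1 = std::lower_bound(cum.begin(), cum.end(), u1) - cum.begin();
        int b2 = std::lower_bound(cum.begin(), cum.end(), u2) - cum.begin();
        if (b1 >= m) b1 = m - 1;
        if (b2 >= m) b2 = m - 1;
        int anc, desc;
        if (b1 == b2) {
          anc = desc = b1;              // order by time; tallies need sizes only
        } else {
          const uint64_t *s1 = &bits[static_cast<size_t>(b1) * words];
          const uint64_t *s2 = &bits[static_cast<size_t>(b2) * words];
          bool sub21 = true, sub12 = true, disjoint = true;
          for (int w = 0; w < words; ++w) {
            uint64_t inter = s1[w] & s2[w];
            if (inter != s2[w]) sub21 = false;
            if (inter != s1[w]) sub12 = false;
            if (inter) disjoint = false;
          }
          if (sub21)      { anc = b1; desc = b2; }
          else if (sub12) { anc = b2; desc = b1; }
          else {
            // disjoint carrier sets: independent lineages
            (void)disjoint;
            i00 += n - sz[b1] - sz[b2];
            i10 += sz[b1];
            i01 += sz[b2];
            continue;
          }
        }
        n_same += 1;
        f00 += n - sz[anc];
        f10 += sz[anc] - sz[desc];
        f11 += sz[desc];
      }
      out(a, 0) += static_cast<double>(b_mut);
      out(a, 1) += n_same;
      out(a, 2) += f00; out(a, 3) += f10; out(a, 4) += f11;
      out(a, 5) += i00; out(a, 6) += i10; out(a, 7) += i01;
    }
  }
  return out;
}
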