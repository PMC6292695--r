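// Hudson-style coalescent without recombination, with deme structure,
// deme mergers and mass-migration pulses. Time is in units of 4N
// generations (ms convention): pairwise coalescence rate 2 within a
// deme, mutations Poisson with mean theta * branch length, so that
// E[S] = theta * a1 and E[pairwise diff] = theta for a panmictic pair.
//
// Sample capacity is 64 haplotypes (leaf sets are uint64_t bit masks).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

namespace {

struct Lineage {
  uint64_t mask;
  int deme;
  double birth;
};

struct Branch {
  uint64_t mask;
  double len;
};

struct Tree {
  std::vector<Branch> branches;
  uint64_t migrant; // union of leaf sets that jumped demes at a pulse
};

// events: columns (time, kind, from, to, prob); kind 0 = merge (all
// lineages in `from` move to `to`), kind 1 = pulse (each lineage in
// `from` moves to `to` with probability prob). Rows sorted by time.
Tree sim_tree(const std::vector<int>& n_per_deme, const NumericMatrix& events) {
  const int K = (int)n_per_deme.size();
  std::vector<Lineage> lin;
  int idx = 0;
  for (int d = 0; d < K; ++d)
    for (int i = 0; i < n_per_deme[d]; ++i)
      lin.push_back({1ULL << (idx++), d, 0.0});

  Tree out;
  out.migrant = 0;
  out.branches.reserve(2 * lin.size());
  double t = 0.0;
  int ev = 0;
  const int nev = events.nrow();
  std::vector<int> cnt(K);

  while (lin.size() > 1) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (const auto& l : lin) cnt[l.deme]++;
    double rate = 0.0;
    for (int d = 0; d < K; ++d) rate += (double)cnt[d] * (cnt[d] - 1);

    double dt = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
    if (ev < nev && (rate == 0.0 || t + dt >= events(ev, 0))) {
      t = events(ev, 0);
      const int kind = (int)events(ev, 1);
      const int from = (int)events(ev, 2);
      const int to = (int)events(ev, 3);
      if (kind == 0) {
        for (auto& l : lin) if (l.deme == from) l.deme = to;
      } else {
        const double p = events(ev, 4);
        for (auto& l : lin)
          if (l.deme == from && R::unif_rand() < p) {
            l.deme = to;
            out.migrant |= l.mask;
          }
      }
      ++ev;
      continue;
    }
    if (rate == 0.0)
      stop("lineages stranded in disconnected demes (missing merge event)");
    t += dt;

    // deme chosen proportional to k(k-1), then an unordered pair in it
    double u = R::unif_rand() * rate, acc = 0.0;
    int dsel = 0;
    for (int d = 0; d < K; ++d) {
      acc += (double)cnt[d] * (cnt[d] - 1);
      if (u <= acc) { dsel = d; break; }
    }
    std::vector<int> ids;
    for (int i = 0; i < (int)lin.size(); ++i)
      if (lin[i].deme == dsel) ids.push_back(i);
    int a = ids[(int)(R::unif_rand() * ids.size())];
    int b = a;
    while (b == a) b = ids[(int)(R::unif_rand() * ids.size())];

    out.branches.push_back({lin[a].mask, t - lin[a].birth});
    out.branches.push_back({lin[b].mask, t - lin[b].birth});
    lin[a].mask |= lin[b].mask;
    lin[a].birth = t;
    lin.erase(lin.begin() + b);
  }
  return out;
}

inline int bit(uint64_t m, int i) { return (int)((m >> i) & 1ULL); }

} // namespace

// Null distribution of cross-population pairwise difference counts for a
// clean two-population split at time tau (deme 0 merges into deme 1).
// Returns reps x 2 matrix: min and mean difference count over the
// n1 x n2 cross pairs.
// [[Rcpp::export]]
NumericMatrix cpp_cross_pair_null(int n1, int n2, double tau, double theta,
                                  int reps) {
  if (n1 < 1 || n2 < 1) stop("need at least one haplotype per population");
  if (n1 + n2 > 64) stop("at most 64 haplotypes supported");
  std::vector<int> n_per_deme = {n1, n2};
  NumericMatrix events(1, 5);
  events(0, 0) = tau; events(0, 1) = 0; events(0, 2) = 0; events(0, 3) = 1;

  NumericMatrix out(reps, 2);
  std::vector<double> dist((size_t)n1 * n2);
  for (int r = 0; r < reps; ++r) {
    Tree tr = sim_tree(n_per_deme, events);
    std::fill(dist.begin(), dist.end(), 0.0);
    for (const auto& br : tr.branches) {
      const double m = R::rpois(theta * br.len);
      if (m == 0.0) continue;
      for (int i = 0; i < n1; ++i) {
        const int bi = bit(br.mask, i);
        for (int j = 0; j < n2; ++j)
          if (bi != bit(br.mask, n1 + j)) dist[(size_t)i * n2 + j] += m;
      }
    }
    double mn = dist[0], sum = 0.0;
    for (double d : dist) { if (d < mn) mn = d; sum += d; }
    out(r, 0) = mn;
    out(r, 1) = sum / ((double)n1 * n2);
  }
  return out;
}

// Full haplotype output under the general deme/merge/pulse model with
// infinite-sites mutation on a discrete lattice of locus_length sites
// (collisions resolved by resampling the position).
// Returns a list of replicates, each a list(alleles, positions, migrant):
// alleles is an n x S 0/1 integer matrix (rows in deme order), positions
// 0-based integer site coordinates (strictly increasing), migrant a
// logical per sample marking descent from a pulse-migrant lineage.
// [[Rcpp::export]]
List cpp_sim_haplotypes(IntegerVector n_per_deme, NumericMatrix events,
                        double theta, int locus_length, int reps) {
  std::vector<int> npd = as<std::vector<int>>(n_per_deme);
  int n = 0;
  for (int k : npd) {
    if (k < 0) stop("negative sample size");
    n += k;
  }
  if (n < 1 || n > 64) stop("total sample size must be in 1..64");
  if (locus_length < 1) stop("locus_length must be positive");

  List out(reps);
  for (int r = 0; r < reps; ++r) {
    Tree tr = sim_tree(npd, events);

    std::vector<std::pair<int, uint64_t>> muts; // (position, carrier mask)
    std::unordered_set<int> used;
    for (const auto& br : tr.branches) {
      const int m = (int)R::rpois(theta * br.len);
      for (int k = 0; k < m; ++k) {
        int pos;
        do {
          pos = (int)(R::unif_rand() * locus_length);
          if (pos >= locus_length) pos = locus_length - 1;
        } while (used.count(pos));
        used.insert(pos);
        muts.push_back({pos, br.mask});
      }
    }
    std::sort(muts.begin(), muts.end());

    const int S = (int)muts.size();
    IntegerMatrix alleles(n, S);
    IntegerVector positions(S);
    for (int s = 0; s < S; ++s) {
      positions[s] = muts[s].first;
      for (int i = 0; i < n; ++i) alleles(i, s) = bit(muts[s].second, i);
    }
    LogicalVector migrant(n);
    for (int i = 0; i < n; ++i) migrant[i] = bit(tr.migrant, i) == 1;
    out[r] = List::create(_["alleles"] = alleles, _["positions"] = positions,
                          _["migrant"] = migrant);
  }
  return out;
}
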