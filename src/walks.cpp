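#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Deterministic uniform double in [0,1) from the raw mt19937_64 stream;
// avoids std::uniform_* distributions whose output is implementation-defined.
static inline double unif01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

static inline int pick_uniform(std::mt19937_64 &rng, int n) {
  int k = (int)(unif01(rng) * n);
  return k >= n ? n - 1 : k;
}

// adjacency: per node, neighbor indices split by walk class (C/H/N) + ALL
struct Adjacency {
  std::vector<std::array<std::vector<int>, 3> > by_class;
  std::vector<std::vector<int> > all;
};

static Adjacency convert_adjacency(const List &adj) {
  Adjacency a;
  int n = adj.size();
  a.by_class.resize(n);
  a.all.resize(n);
  for (int i = 0; i < n; ++i) {
    List node = adj[i];
    IntegerVector c = node["C"], h = node["H"], nn = node["N"],
                  al = node["ALL"];
    a.by_class[i][0].assign(c.begin(), c.end());
    a.by_class[i][1].assign(h.begin(), h.end());
    a.by_class[i][2].assign(nn.begin(), nn.end());
    a.all[i].assign(al.begin(), al.end());
  }
  return a;
}

// choose uniformly from sorted `cand`, excluding `excl` (when >= 0 and
// alternatives exist); returns -1 when no choice remains
static int choose_next(std::mt19937_64 &rng, const std::vector<int> &cand,
                       int excl) {
  int n = (int)cand.size();
  if (n == 0) return -1;
  bool has_excl = excl >= 0 &&
    std::binary_search(cand.begin(), cand.end(), excl);
  if (!has_excl) return cand[pick_uniform(rng, n)];
  if (n == 1) return -1; // the repeat is the only option: terminate
  int k = pick_uniform(rng, n - 1);
  int v = cand[k];
  if (v >= excl) v = cand[k + 1]; // skip over the excluded position
  return v;
}

// [[Rcpp::export]]
List walk_metapath_cpp(List adj, IntegerVector node_class,
                       IntegerVector cycle, IntegerVector starts,
                       int walks_per_start, int max_len, bool distinct,
                       int seed) {
  Adjacency a = convert_adjacency(adj);
  std::mt19937_64 rng((uint64_t)(uint32_t)seed);
  int cyc = cycle.size();
  std::vector<IntegerVector> out;
  out.reserve((size_t)starts.size() * walks_per_start);
  std::vector<int> walk;
  for (int si = 0; si < starts.size(); ++si) {
    int s = starts[si];
    for (int w = 0; w < walks_per_start; ++w) {
      walk.clear();
      walk.push_back(s);
      int last_of_class[3] = {-1, -1, -1};
      last_of_class[node_class[s]] = s;
      int cur = s;
      for (int pos = 1; pos < max_len; ++pos) {
        int next_class = cycle[pos % cyc];
        const std::vector<int> &cand = a.by_class[cur][next_class];
        int excl = distinct ? last_of_class[next_class] : -1;
        int nxt = choose_next(rng, cand, excl);
        if (nxt < 0) break;
        walk.push_back(nxt);
        last_of_class[node_class[nxt]] = nxt;
        cur = nxt;
      }
      out.push_back(IntegerVector(walk.begin(), walk.end()));
    }
  }
  return List(out.begin(), out.end());
}

// [[Rcpp::export]]
List walk_uniform_cpp(List adj, IntegerVector starts, int walks_per_start,
                      int max_len, int seed) {
  Adjacency a = convert_adjacency(adj);
  std::mt19937_64 rng((uint64_t)(uint32_t)seed);
  std::vector<IntegerVector> out;
  out.reserve((size_t)starts.size() * walks_per_start);
  std::vector<int> walk;
  for (int si = 0; si < starts.size(); ++si) {
    int s = starts[si];
    for (int w = 0; w < walks_per_start; ++w) {
      walk.clear();
      walk.push_back(s);
      int cur = s;
      for (int pos = 1; pos < max_len; ++pos) {
        const std::vector<int> &cand = a.all[cur];
        if (cand.empty()) break;
        int nxt = cand[pick_uniform(rng, (int)cand.size())];
        walk.push_back(nxt);
        cur = nxt;
      }
      out.push_back(IntegerVector(walk.begin(), walk.end()));
    }
  }
  return List(out.begin(), out.end());
}
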