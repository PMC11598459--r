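#include <Rcpp.h>
#include <climits>
#include <set>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdio>
using namespace Rcpp;

// Exhaustive enumeration of pattern tilings of an integer pulse train.
//
// A segment is a set of pulse positions (ticks, relative to the first pulse)
// with positive integer multiplicities. A pattern is an arithmetic run
// (anchor, spacing, count): it contributes one unit of multiplicity at
// anchor + j*spacing for j = 0..count-1. A decomposition is a multiset of
// patterns whose superposition reproduces the multiplicities exactly,
// subject to: at most nsg_max patterns; count in [nd_min, nd_max]; spacing
// drawn from the candidate set; every anchor within max_anchor_diff ticks of
// the first pattern's anchor (realizability as a travel-time difference of
// the layout).
//
// The search anchors each new pattern at the earliest pulse with remaining
// multiplicity; this is complete (any remaining pattern covering that pulse
// as a non-anchor element would need an anchor at an earlier, already
// exhausted pulse) and near-duplicate-free. Identical pattern multisets
// reached through different orderings at a shared anchor are removed with a
// canonical-signature set.

namespace {

struct Pattern { int anchor, spacing, count; };

struct SearchState {
  std::vector<int> ticks;            // sorted distinct pulse positions
  std::vector<int> residual;         // remaining multiplicity per tick
  std::vector<int> cand;             // candidate spacings (ticks)
  std::vector<int> pos_of;           // dense tick -> index map (-1 absent)
  int nsg_max, nd_min, nd_max, max_anchor_diff;
  int span_ticks;                    // max pattern span: one active period
  int total_residual;
  int max_run_cap;                   // longest run actually present
  long long nodes, node_budget;
  bool aborted;                      // node budget hit (search incomplete)
  bool prune_by_k;                   // count-set mode (see decompose_count_set)
  int emit_cap;                      // solutions stored for signatures/witness
  std::set<int> k_found;
  std::vector<Pattern> current;
  std::set<std::string> seen;
  std::vector<std::vector<Pattern>> solutions;

  int index_of(int tick) const {
    if (tick < 0 || tick >= (int)pos_of.size()) return -1;
    return pos_of[tick];
  }

  void emit() {
    k_found.insert((int)current.size());
    if ((int)solutions.size() >= emit_cap) return;
    std::vector<Pattern> sol = current;
    std::sort(sol.begin(), sol.end(), [](const Pattern &a, const Pattern &b) {
      if (a.anchor != b.anchor) return a.anchor < b.anchor;
      if (a.spacing != b.spacing) return a.spacing < b.spacing;
      return a.count < b.count;
    });
    std::string sig;
    char buf[64];
    for (size_t i = 0; i < sol.size(); ++i) {
      std::snprintf(buf, sizeof(buf), "%d,%d,%d;", sol[i].anchor,
                    sol[i].spacing, sol[i].count);
      sig += buf;
    }
    if (seen.insert(sig).second) solutions.push_back(sol);
  }

  void search() {
    if (aborted) return;
    if (++nodes > node_budget) { aborted = true; return; }
    if (total_residual == 0) { emit(); return; }
    int used = (int)current.size();
    if (used >= nsg_max) return;
    // earliest unexplained pulse and largest remaining multiplicity
    int i = -1, max_res = 0;
    for (int j = 0; j < (int)residual.size(); ++j) {
      if (residual[j] > 0) {
        if (i < 0) i = j;
        if (residual[j] > max_res) max_res = residual[j];
      }
    }
    // capacity prunes: the remaining pattern budget must absorb the whole
    // residual with runs no longer than any run present, and every pattern
    // covers a tick at most once, so a tick with multiplicity m needs m
    // more patterns
    int budget = nsg_max - used;
    if ((long long)budget * max_run_cap < total_residual) return;
    if (budget < max_res) return;
    if (prune_by_k && (int)solutions.size() >= emit_cap) {
      // this subtree can only finish with pattern counts in
      // [used + kneed, nsg_max]; once every such count is known and enough
      // solutions are stored, nothing new can be learned here
      int kneed = (total_residual + max_run_cap - 1) / max_run_cap;
      if (kneed < max_res) kneed = max_res;
      bool novel = false;
      for (int k = used + kneed; k <= nsg_max; ++k)
        if (!k_found.count(k)) { novel = true; break; }
      if (!novel) return;
    }
    int anchor = ticks[i];
    // ticks are offsets from the segment's first pulse, which is always the
    // first pattern's anchor; realizability of the travel-time offset
    if (anchor > max_anchor_diff)
      return;  // no admissible pattern can cover the earliest pulse
    int run_idx[160];
    for (size_t c = 0; c < cand.size(); ++c) {
      int s = cand[c];
      // a gland secretes at a constant rate through the whole active
      // period, so a pattern with spacing s must hold the count the
      // physiology realizes: first droplet within s ticks of the period
      // start and droplets continuing until its end
      int lo = (span_ticks + s) / s - 1;   // ceil((T+1)/s) - 1
      int hi = (span_ticks - 1) / s + 1;   // floor((T-1)/s) + 1
      if (lo < nd_min) lo = nd_min;
      if (hi > nd_max) hi = nd_max;
      if (lo > hi) continue;
      // longest run of available pulses at this spacing
      int L = 1;
      run_idx[0] = i;
      int t = anchor + s;
      while (L < hi) {
        int j = index_of(t);
        if (j < 0 || residual[j] == 0) break;
        run_idx[L++] = j;
        t += s;
      }
      if (L < lo) continue;
      // take the first lo pulses, then extend one by one
      for (int n = 0; n < lo; ++n) --residual[run_idx[n]];
      total_residual -= lo;
      for (int n = lo; n <= L; ++n) {
        Pattern p; p.anchor = anchor; p.spacing = s; p.count = n;
        current.push_back(p);
        search();
        current.pop_back();
        if (n < L) { --residual[run_idx[n]]; --total_residual; }
      }
      for (int n = 0; n < L; ++n) ++residual[run_idx[n]];
      total_residual += L;
    }
  }
  // ---- memoized achievable-pattern-count recursion -------------------
  //
  // gmask(residual) = bitmask of k (0..nsg_max) such that the residual can
  // be exactly covered by k admissible patterns. The value depends only on
  // the residual vector, so it memoizes across the heavily shared subtrees
  // that arise when independent runs can be consumed in any order.
  std::unordered_map<std::string, unsigned int> memo;
  long long memo_budget;
  bool memo_aborted;

  unsigned int gmask() {
    if (memo_aborted) return 0u;
    if (total_residual == 0) return 1u;  // coverable with zero patterns
    int i = -1, max_res = 0;
    for (int j = 0; j < (int)residual.size(); ++j) {
      if (residual[j] > 0) {
        if (i < 0) i = j;
        if (residual[j] > max_res) max_res = residual[j];
      }
    }
    int kmin = (total_residual + max_run_cap - 1) / max_run_cap;
    if (kmin < max_res) kmin = max_res;
    if (kmin > nsg_max) return 0u;
    int anchor = ticks[i];
    if (anchor > max_anchor_diff) return 0u;
    // translation-invariant key: remaining pulses relative to the anchor,
    // plus the remaining anchor allowance (capped at the remaining span so
    // that unconstrained states collapse); near-periodic gland structures
    // then share subproblems massively
    int last = (int)residual.size() - 1;
    while (residual[last] == 0) --last;
    int span_rem = ticks[last] - anchor;
    int allow = max_anchor_diff - anchor;
    if (allow > span_rem) allow = span_rem;
    std::string key;
    key.reserve(3 * (last - i + 1) + 2);
    key.push_back((char)(allow & 0xff));
    key.push_back((char)((allow >> 8) & 0xff));
    for (int j = i; j <= last; ++j) {
      if (residual[j] == 0) continue;
      int d = ticks[j] - anchor;
      key.push_back((char)(d & 0xff));
      key.push_back((char)((d >> 8) & 0xff));
      key.push_back((char)(residual[j] & 0xff));
    }
    std::unordered_map<std::string, unsigned int>::iterator it =
        memo.find(key);
    if (it != memo.end()) return it->second;
    if ((long long)memo.size() > memo_budget) {
      memo_aborted = true;
      return 0u;
    }
    unsigned int mask = 0;
    const unsigned int full = (1u << (nsg_max + 1)) - 1u;
    int run_idx[160];
    for (size_t c = 0; c < cand.size(); ++c) {
      int s = cand[c];
      int lo = (span_ticks + s) / s - 1;
      int hi = (span_ticks - 1) / s + 1;
      if (lo < nd_min) lo = nd_min;
      if (hi > nd_max) hi = nd_max;
      if (lo > hi) continue;
      int L = 1;
      run_idx[0] = i;
      int t = anchor + s;
      while (L < hi) {
        int j = index_of(t);
        if (j < 0 || residual[j] == 0) break;
        run_idx[L++] = j;
        t += s;
      }
      if (L < lo) continue;
      for (int n = 0; n < lo; ++n) --residual[run_idx[n]];
      total_residual -= lo;
      for (int n = lo; n <= L; ++n) {
        mask |= (gmask() << 1) & full;
        if (n < L) { --residual[run_idx[n]]; --total_residual; }
      }
      for (int n = 0; n < L; ++n) ++residual[run_idx[n]];
      total_residual += L;
    }
    memo[key] = mask;
    return mask;
  }
};

}  // namespace

static List run_search(IntegerVector ticks, IntegerVector mult,
                       IntegerVector cand_spacings, int nsg_max, int nd_min,
                       int nd_max, int max_anchor_diff, int span_ticks,
                       double node_budget, bool prune_by_k, int emit_cap,
                       double memo_budget) {
  SearchState st;
  st.prune_by_k = prune_by_k;
  st.emit_cap = emit_cap;
  st.span_ticks = span_ticks;
  st.ticks = as<std::vector<int>>(ticks);
  st.residual = as<std::vector<int>>(mult);
  st.cand = as<std::vector<int>>(cand_spacings);
  std::sort(st.cand.begin(), st.cand.end());
  st.cand.erase(std::unique(st.cand.begin(), st.cand.end()), st.cand.end());
  st.nsg_max = nsg_max; st.nd_min = nd_min; st.nd_max = nd_max;
  st.max_anchor_diff = max_anchor_diff;
  st.nodes = 0; st.node_budget = (long long)node_budget;
  st.aborted = false;
  st.memo_budget = (long long)memo_budget;
  st.memo_aborted = false;
  st.total_residual = 0;
  for (size_t i = 0; i < st.residual.size(); ++i) {
    if (st.residual[i] <= 0) stop("multiplicities must be positive integers");
    st.total_residual += st.residual[i];
  }
  // dense tick -> index map (ticks are small non-negative offsets)
  int span = st.ticks.empty() ? 0 : st.ticks.back();
  st.pos_of.assign(span + 1, -1);
  for (size_t i = 0; i < st.ticks.size(); ++i) st.pos_of[st.ticks[i]] = (int)i;
  // longest evenly spaced run actually present in the pulse train, over all
  // anchors and candidate spacings; runs can only shrink as multiplicity is
  // consumed, so this bounds every pattern's droplet count
  int lmax = 1;
  for (size_t i = 0; i < st.ticks.size(); ++i) {
    for (size_t c = 0; c < st.cand.size(); ++c) {
      int s = st.cand[c];
      int hi = (span_ticks - 1) / s + 1;
      if (hi > nd_max) hi = nd_max;
      int L = 1, t = st.ticks[i] + s;
      while (L < hi && st.index_of(t) >= 0) { ++L; t += s; }
      if (L > lmax) lmax = L;
    }
  }
  st.max_run_cap = std::min(nd_max, lmax);
  // All simulated glands share one per-gland sweat rate, so every pattern
  // of a decomposition carries the same inter-droplet interval: the search
  // runs once per candidate spacing with that spacing alone.
  bool complete = true;
  std::vector<int> all_cand = st.cand;
  if (st.total_residual > 0) {
    for (size_t c = 0; c < all_cand.size(); ++c) {
      int s = all_cand[c];
      st.cand.assign(1, s);
      int hi = (span_ticks - 1) / s + 1;
      if (hi > nd_max) hi = nd_max;
      int ls = 1;
      for (size_t i = 0; i < st.ticks.size(); ++i) {
        int L = 1, t = st.ticks[i] + s;
        while (L < hi && st.index_of(t) >= 0) { ++L; t += s; }
        if (L > ls) ls = L;
      }
      st.max_run_cap = ls;
      st.aborted = false;
      st.search();
      if (st.aborted) {
        if (!prune_by_k)
          stop("decomposition search exceeded its node budget");
        // recover the achievable-count set for this spacing with the
        // memoized recursion; stored solutions stay partial either way
        st.memo.clear();
        st.memo_aborted = false;
        unsigned int mask = st.gmask();
        if (st.memo_aborted) { complete = false; continue; }
        for (int k = 1; k <= nsg_max; ++k)
          if (mask & (1u << k)) st.k_found.insert(k);
      }
    }
  }

  List out(st.solutions.size());
  for (size_t k = 0; k < st.solutions.size(); ++k) {
    const std::vector<Pattern> &sol = st.solutions[k];
    IntegerMatrix m((int)sol.size(), 3);
    for (size_t i = 0; i < sol.size(); ++i) {
      m((int)i, 0) = sol[i].anchor;
      m((int)i, 1) = sol[i].spacing;
      m((int)i, 2) = sol[i].count;
    }
    colnames(m) = CharacterVector::create("anchor", "spacing", "count");
    out[(int)k] = m;
  }
  out.attr("k_set") = IntegerVector(st.k_found.begin(), st.k_found.end());
  out.attr("complete") = complete;
  return out;
}

// Full enumeration of all distinct decompositions.
// [[Rcpp::export]]
List decompose_ticks(IntegerVector ticks, IntegerVector mult,
                     IntegerVector cand_spacings, int nsg_max, int nd_min,
                     int nd_max, int max_anchor_diff, int span_ticks = 60,
                     double node_budget = 5e7) {
  return run_search(ticks, mult, cand_spacings, nsg_max, nd_min, nd_max,
                    max_anchor_diff, span_ticks, node_budget, false, INT_MAX,
                    0);
}

// Exact set of achievable pattern counts, with up to emit_cap stored
// solutions: subtrees whose whole achievable count range is already known
// are pruned once the store is full.
// [[Rcpp::export]]
List decompose_count_set(IntegerVector ticks, IntegerVector mult,
                         IntegerVector cand_spacings, int nsg_max,
                         int nd_min, int nd_max, int max_anchor_diff,
                         int span_ticks = 60, double node_budget = 1e6,
                         int emit_cap = 500, double memo_budget = 2e5) {
  return run_search(ticks, mult, cand_spacings, nsg_max, nd_min, nd_max,
                    max_anchor_diff, span_ticks, node_budget, true, emit_cap,
                    memo_budget);
}
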