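// Hairpin-only secondary-structure folding by nearest-neighbor dynamic
// programming. Single stem with bulges/internal loops, no multiloops or
// pseudoknots: V(i,j) = best energy of a hairpin closed by pair (i,j).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double BIG = 1e9;

inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': case 'T': return 3;
  default: return -1;
  }
}

// pair type: 0 none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA
inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

struct EnergyModel {
  double stack[7][7];
  std::vector<double> hairpin;  // index = loop length
  std::vector<double> bulge;
  std::vector<double> internal_;
  double asym;       // per-nt asymmetry penalty for internal loops
  double asym_max;
  double lxc;        // log extrapolation coefficient

  double hairpin_loop(int n) const {
    if (n < 3) return BIG;
    if (n < (int)hairpin.size()) return hairpin[n];
    return hairpin.back() + lxc * std::log((double)n / (hairpin.size() - 1));
  }
  double bulge_loop(int n) const {
    if (n < (int)bulge.size()) return bulge[n];
    return bulge.back() + lxc * std::log((double)n / (bulge.size() - 1));
  }
  double internal_loop(int n1, int n2) const {
    int n = n1 + n2;
    double e = (n < (int)internal_.size())
      ? internal_[n]
      : internal_.back() + lxc * std::log((double)n / (internal_.size() - 1));
    double a = asym * std::abs(n1 - n2);
    return e + std::min(a, asym_max);
  }
};

EnergyModel build_model(List table) {
  EnergyModel m;
  NumericMatrix st = table["stack"];
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j)
      m.stack[i][j] = (i == 0 || j == 0) ? BIG : st(i - 1, j - 1);
  NumericVector hp = table["hairpin"];
  NumericVector bu = table["bulge"];
  NumericVector il = table["internal"];
  m.hairpin.assign(hp.begin(), hp.end());
  m.bulge.assign(bu.begin(), bu.end());
  m.internal_.assign(il.begin(), il.end());
  m.asym = as<double>(table["asym"]);
  m.asym_max = as<double>(table["asym_max"]);
  m.lxc = as<double>(table["lxc"]);
  return m;
}

}  // namespace

// Fill V and traceback matrices for one sequence. Pair span limited to
// `max_span`; unpaired stretches in bulges/internal loops limited to
// `max_bulge` per side.
// [[Rcpp::export(name = ".hairpin_dp")]]
List hairpin_dp(std::string seq, List energy_table, int max_span,
                int max_bulge, int min_loop) {
  int n = seq.size();
  EnergyModel em = build_model(energy_table);
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  // V stored as dense (n x span) band; index (i, j-i)
  int W = std::min(max_span, n);
  std::vector<double> V((size_t)n * W, BIG);
  std::vector<int> TBk((size_t)n * W, -1), TBl((size_t)n * W, -1);
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i); };

  for (int span = min_loop + 2; span <= W; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      if (code[i] < 0 || code[j] < 0) continue;
      int pt = pair_type(code[i], code[j]);
      if (pt == 0) continue;
      double best = em.hairpin_loop(j - i - 1);
      int bk = -1, bl = -1;
      int kmax = std::min(i + 1 + max_bulge, j - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        if (code[k] < 0) continue;
        int lmin = std::max(k + min_loop + 1, j - 1 - max_bulge);
        for (int l = j - 1; l >= lmin; --l) {
          if (l - k + 1 < min_loop + 2) break;
          int pt2 = pair_type(code[k], code[l]);
          if (pt2 == 0) continue;
          double inner = V[idx(k, l)];
          if (inner >= BIG) continue;
          int d1 = k - i - 1, d2 = j - l - 1;
          double loop;
          if (d1 == 0 && d2 == 0) loop = em.stack[pt][pt2];
          else if (d1 == 0 || d2 == 0) loop = em.bulge_loop(d1 + d2);
          else loop = em.internal_loop(d1, d2);
          double e = inner + loop;
          if (e < best) { best = e; bk = k; bl = l; }
        }
      }
      V[idx(i, j)] = best;
      TBk[idx(i, j)] = bk;
      TBl[idx(i, j)] = bl;
    }
  }

  // Greedy extraction of non-overlapping hairpins, best energy first.
  std::vector<bool> used(n, false);
  List hits;
  for (;;) {
    double best = -1e-9;  // only report stabilizing structures
    int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      for (int j = i + min_loop + 1; j < std::min(n, i + W); ++j) {
        double v = V[idx(i, j)];
        if (v < best) {
          bool clash = false;
          for (int p = i; p <= j && !clash; ++p) clash = used[p];
          if (!clash) { best = v; bi = i; bj = j; }
        }
      }
    }
    if (bi < 0) break;
    // traceback pairs
    std::vector<int> p5, p3;
    int i = bi, j = bj;
    while (i >= 0) {
      p5.push_back(i + 1);  // 1-based
      p3.push_back(j + 1);
      int k = TBk[idx(i, j)], l = TBl[idx(i, j)];
      i = k; j = l;
      if (k < 0) break;
    }
    for (int p = bi; p <= bj; ++p) used[p] = true;
    hits.push_back(List::create(
      _["i"] = bi + 1, _["j"] = bj + 1, _["energy"] = best,
      _["pair5"] = wrap(p5), _["pair3"] = wrap(p3)));
  }
  return hits;
}

// Hand-check helper: energy of an explicitly given nested pair list
// (outermost first). Used as the internal-consistency oracle in tests.
// [[Rcpp::export(name = ".hairpin_energy_of_pairs")]]
double hairpin_energy_of_pairs(std::string seq, List energy_table,
                               IntegerVector pair5, IntegerVector pair3) {
  EnergyModel em = build_model(energy_table);
  int np = pair5.size();
  if (np == 0) return 0.0;
  std::vector<int> code(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) code[i] = base_code(seq[i]);
  double e = 0.0;
  for (int a = 0; a < np - 1; ++a) {
    int i = pair5[a] - 1, j = pair3[a] - 1;
    int k = pair5[a + 1] - 1, l = pair3[a + 1] - 1;
    int pt = pair_type(code[i], code[j]);
    int pt2 = pair_type(code[k], code[l]);
    if (pt == 0 || pt2 == 0) return NA_REAL;
    int d1 = k - i - 1, d2 = j - l - 1;
    if (d1 == 0 && d2 == 0) e += em.stack[pt][pt2];
    else if (d1 == 0 || d2 == 0) e += em.bulge_loop(d1 + d2);
    else e += em.internal_loop(d1, d2);
  }
  int ic = pair5[np - 1] - 1, jc = pair3[np - 1] - 1;
  e += em.hairpin_loop(jc - ic - 1);
  return e;
}
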