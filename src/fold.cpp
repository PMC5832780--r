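// Nearest-neighbor minimum-free-energy folding engine (no pseudoknots).
//
// Recurrences are the classic Zuker decomposition restricted to the model
// premirscan ships: stacking energies over canonical pairs (incl. GU),
// size-dependent hairpin/bulge/internal-loop initiation penalties with
// logarithmic extrapolation beyond the tabulated sizes, and an affine
// multiloop penalty (offset + per-branch + per-unpaired).  No dangles,
// terminal mismatches, or special tetraloops: the standalone R re-scorer
// (score_structure) must reproduce every energy this engine reports, so
// the model is kept to terms a loop decomposition can recompute exactly.
//
// Base encoding: A=0, C=1, G=2, U/T=3, N=4 (N never pairs).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-9;

struct EModel {
  double stack[7][7];            // [pair(i,j)][pair(i+1,j-1)], types 1..6
  std::vector<double> hairpin;   // penalty by unpaired loop size (1-based)
  std::vector<double> bulge;
  std::vector<double> internal;
  double ml_a, ml_b, ml_c;       // multiloop offset / per-branch / per-unpaired
  double lxc;                    // log-extrapolation coefficient
  double asym, asym_max;         // internal-loop asymmetry penalty (per unit, cap)
  double term_au;                // helix-end penalty for AU/UA/GU/UG closing pairs
  int min_loop;                  // min unpaired bases in a hairpin loop
  int max_interior;              // cap on total unpaired bases in interior loops
};

// pair type: CG=1 GC=2 GU=3 UG=4 AU=5 UA=6, 0 = not pairable
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

static inline double end_pen(const EModel &em, int pt) {
  return (pt >= 3) ? em.term_au : 0.0; // GU/UG/AU/UA helix ends
}

static inline double loop_tab(const std::vector<double> &tab, int n, double lxc) {
  if (n <= 0) return INF;
  int m = (int)tab.size();
  if (n <= m) return tab[n - 1];
  return tab[m - 1] + lxc * std::log((double)n / (double)m);
}

static EModel model_from_list(const List &params) {
  EModel em;
  NumericMatrix st = params["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j) em.stack[i][j] = INF;
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) em.stack[i + 1][j + 1] = st(i, j);
  em.hairpin  = as<std::vector<double> >(params["hairpin_loop"]);
  em.bulge    = as<std::vector<double> >(params["bulge_loop"]);
  em.internal = as<std::vector<double> >(params["internal_loop"]);
  em.ml_a = as<double>(params["multiloop_offset"]);
  em.ml_b = as<double>(params["multiloop_branch"]);
  em.ml_c = as<double>(params["multiloop_unpaired"]);
  em.lxc  = as<double>(params["loop_extrapolation"]);
  em.asym = as<double>(params["internal_asymmetry"]);
  em.asym_max = as<double>(params["internal_asymmetry_max"]);
  em.term_au = as<double>(params["terminal_au"]);
  em.min_loop = as<int>(params["min_hairpin_loop"]);
  em.max_interior = as<int>(params["max_interior_size"]);
  if (em.min_loop < 3) stop("min_hairpin_loop must be >= 3");
  return em;
}

// Interior-loop extension energy for outer pair (i,j), inner pair (k,l):
// stack when contiguous; bulge when one side is unpaired (a single-base
// bulge keeps the stacking interaction of its flanking pairs, the standard
// nearest-neighbor rule); internal loop otherwise, with a capped linear
// asymmetry penalty.
static inline double interior_energy(const EModel &em, int pt_out, int pt_in,
                                     int n1, int n2) {
  if (n1 == 0 && n2 == 0) return em.stack[pt_out][pt_in];
  if (n1 + n2 == 1)
    return loop_tab(em.bulge, 1, em.lxc) + em.stack[pt_out][pt_in];
  double ends = end_pen(em, pt_out) + end_pen(em, pt_in);
  if (n1 == 0 || n2 == 0)
    return loop_tab(em.bulge, n1 + n2, em.lxc) + ends;
  double a = em.asym * std::abs(n1 - n2);
  if (a > em.asym_max) a = em.asym_max;
  return loop_tab(em.internal, n1 + n2, em.lxc) + a + ends;
}

struct FoldDP {
  int n;
  const EModel *em;
  std::vector<int> s;
  std::vector<double> V, WM, W; // V,WM: n*n; W: prefix external energies
  double at(const std::vector<double> &M, int i, int j) const {
    return M[(size_t)i * n + j];
  }
  void set(std::vector<double> &M, int i, int j, double v) {
    M[(size_t)i * n + j] = v;
  }
};

static void run_dp(FoldDP &dp) {
  int n = dp.n;
  const EModel &em = *dp.em;
  const std::vector<int> &s = dp.s;
  dp.V.assign((size_t)n * n, INF);
  dp.WM.assign((size_t)n * n, INF);
  dp.W.assign(n, 0.0);

  for (int span = 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      int pt = pair_type(s[i], s[j]);
      double v = INF;
      if (pt != 0 && j - i - 1 >= em.min_loop) {
        // interior extensions (stack / bulge / internal), fixed scan order
        for (int k = i + 1; k < j; ++k) {
          int n1 = k - i - 1;
          if (n1 > em.max_interior) break;
          for (int l = j - 1; l > k; --l) {
            int n2 = j - l - 1;
            if (n1 + n2 > em.max_interior) break;
            double vin = dp.at(dp.V, k, l);
            if (vin >= INF) continue;
            int pin = pair_type(s[k], s[l]);
            double e = vin + interior_energy(em, pt, pin, n1, n2);
            if (e < v) v = e;
          }
        }
        // hairpin loop
        double hp = loop_tab(em.hairpin, j - i - 1, em.lxc) + end_pen(em, pt);
        if (hp < v) v = hp;
        // multiloop: >=2 branches inside [i+1, j-1]
        for (int u = i + 1; u < j - 1; ++u) {
          double a = dp.at(dp.WM, i + 1, u), b = dp.at(dp.WM, u + 1, j - 1);
          if (a >= INF || b >= INF) continue;
          double e = em.ml_a + em.ml_b + end_pen(em, pt) + a + b;
          if (e < v) v = e;
        }
        dp.set(dp.V, i, j, v);
      }
      // WM: >=1 branch in [i,j], ml_c per unpaired base
      double wm = INF;
      if (j > i) {
        double prev = dp.at(dp.WM, i, j - 1);
        if (prev < INF) wm = prev + em.ml_c;
      }
      for (int k = i; k <= j; ++k) {
        double vb = dp.at(dp.V, k, j);
        if (vb >= INF) continue;
        double pre = 0.0;
        if (k > i) {
          double wpre = dp.at(dp.WM, i, k - 1);
          double cpre = em.ml_c * (k - i);
          pre = (wpre < cpre) ? wpre : cpre;
        }
        double e = pre + vb + em.ml_b + end_pen(em, pair_type(s[k], s[j]));
        if (e < wm) wm = e;
      }
      dp.set(dp.WM, i, j, wm);
    }
  }
  // external prefix energies: W[j] = MFE of s[0..j]
  for (int j = 0; j < n; ++j) {
    double w = (j == 0) ? 0.0 : dp.W[j - 1];
    for (int i = 0; i <= j; ++i) {
      double v = dp.at(dp.V, i, j);
      if (v >= INF) continue;
      double pre = (i == 0) ? 0.0 : dp.W[i - 1];
      double e = pre + v + end_pen(em, pair_type(dp.s[i], dp.s[j]));
      if (e < w) w = e;
    }
    dp.W[j] = w;
  }
}

// --- traceback (fixed case order; mirrors DP scan order exactly) ---

static void trace_V(const FoldDP &dp, int i, int j, std::string &db);

static void trace_WM(const FoldDP &dp, int i, int j, std::string &db) {
  const EModel &em = *dp.em;
  double target = dp.at(dp.WM, i, j);
  for (int k = i; k <= j; ++k) {
    double vb = dp.at(dp.V, k, j);
    if (vb >= INF) continue;
    double wpre = (k > i) ? dp.at(dp.WM, i, k - 1) : INF;
    double cpre = em.ml_c * (k - i);
    double pre = (k == i) ? 0.0 : ((wpre < cpre) ? wpre : cpre);
    double brpen = end_pen(em, pair_type(dp.s[k], dp.s[j]));
    if (std::fabs(pre + vb + em.ml_b + brpen - target) < EPS) {
      trace_V(dp, k, j, db);
      if (k > i && wpre <= cpre + EPS && wpre < INF) trace_WM(dp, i, k - 1, db);
      return;
    }
  }
  // trailing unpaired base
  trace_WM(dp, i, j - 1, db);
}

static void trace_V(const FoldDP &dp, int i, int j, std::string &db) {
  const EModel &em = *dp.em;
  const std::vector<int> &s = dp.s;
  double target = dp.at(dp.V, i, j);
  db[i] = '(';
  db[j] = ')';
  int pt = pair_type(s[i], s[j]);
  for (int k = i + 1; k < j; ++k) {
    int n1 = k - i - 1;
    if (n1 > em.max_interior) break;
    for (int l = j - 1; l > k; --l) {
      int n2 = j - l - 1;
      if (n1 + n2 > em.max_interior) break;
      double vin = dp.at(dp.V, k, l);
      if (vin >= INF) continue;
      int pin = pair_type(s[k], s[l]);
      if (std::fabs(vin + interior_energy(em, pt, pin, n1, n2) - target) < EPS) {
        trace_V(dp, k, l, db);
        return;
      }
    }
  }
  double hp = loop_tab(em.hairpin, j - i - 1, em.lxc) + end_pen(em, pt);
  if (std::fabs(hp - target) < EPS) return; // hairpin loop, nothing inside
  for (int u = i + 1; u < j - 1; ++u) {
    double a = dp.at(dp.WM, i + 1, u), b = dp.at(dp.WM, u + 1, j - 1);
    if (a >= INF || b >= INF) continue;
    if (std::fabs(em.ml_a + em.ml_b + end_pen(em, pt) + a + b - target) < EPS) {
      trace_WM(dp, i + 1, u, db);
      trace_WM(dp, u + 1, j - 1, db);
      return;
    }
  }
  stop("traceback failed at V(%d,%d)", i, j);
}

// trace external structure of prefix [0, j]
static void trace_W(const FoldDP &dp, int jend, std::string &db) {
  const EModel &em = *dp.em;
  int j = jend;
  while (j > 0) {
    if (std::fabs(dp.W[j] - dp.W[j - 1]) < EPS) { // j left unpaired
      --j;
      continue;
    }
    bool found = false;
    for (int i = 0; i <= j; ++i) {
      double v = dp.at(dp.V, i, j);
      if (v >= INF) continue;
      double pre = (i == 0) ? 0.0 : dp.W[i - 1];
      double e = pre + v + end_pen(em, pair_type(dp.s[i], dp.s[j]));
      if (std::fabs(e - dp.W[j]) < EPS) {
        trace_V(dp, i, j, db);
        j = i - 1;
        found = true;
        break;
      }
    }
    if (!found) stop("external traceback failed at %d", j);
  }
}

// [[Rcpp::export]]
List c_fold(IntegerVector seq, List params) {
  EModel em = model_from_list(params);
  FoldDP dp;
  dp.n = seq.size();
  dp.em = &em;
  dp.s = as<std::vector<int> >(seq);
  if (dp.n < 1) stop("empty sequence");
  if (dp.n == 1)
    return List::create(_["structure"] = ".", _["mfe"] = 0.0);
  run_dp(dp);
  double mfe = dp.W[dp.n - 1];
  std::string db(dp.n, '.');
  if (mfe < -EPS) trace_W(dp, dp.n - 1, db);
  else mfe = 0.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// Nussinov maximum-pairing DP (used by the conservative prescreen and as a
// pair-count bound in tests).
// [[Rcpp::export]]
int c_max_pairs(IntegerVector seq, int min_loop) {
  int n = seq.size();
  if (n < 2) return 0;
  std::vector<int> s = as<std::vector<int> >(seq);
  std::vector<int> N((size_t)n * n, 0);
  for (int span = min_loop + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      int best = N[(size_t)(i + 1) * n + j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (pair_type(s[i], s[k]) == 0) continue;
        int inner = (k - i > 1) ? N[(size_t)(i + 1) * n + (k - 1)] : 0;
        int rest = (k < j) ? N[(size_t)(k + 1) * n + j] : 0;
        int cand = 1 + inner + rest;
        if (cand > best) best = cand;
      }
      N[(size_t)i * n + j] = best;
    }
  }
  return N[(size_t)0 * n + (n - 1)];
}

// Batched window scan over one strand of one sequence.
//
// For every start offset, a single DP over the longest admissible window
// yields the MFE of every prefix (= every window length) via the external
// array W, so the per-start cost is one O(n^3) fold instead of one per
// length.  Windows failing the Nussinov prescreen bound are never folded;
// the bound is conservative because |MFE| <= max|stack| * (pairs - 1) for
// any structure under this model, so a window whose maximum possible pair
// count is below `prescreen_min_pairs` cannot reach the energy cutoff.
// [[Rcpp::export]]
DataFrame c_scan(IntegerVector seq, List params, int min_len, int max_len,
                 double mfe_cutoff, bool strict_less, int prescreen_min_pairs) {
  EModel em = model_from_list(params);
  int L = seq.size();
  std::vector<int> full = as<std::vector<int> >(seq);
  std::vector<int> starts, lens;
  std::vector<double> mfes;
  std::vector<std::string> structs;
  if (L < min_len)
    return DataFrame::create(_["start"] = IntegerVector(0),
                             _["len"] = IntegerVector(0),
                             _["mfe"] = NumericVector(0),
                             _["structure"] = CharacterVector(0));
  FoldDP dp;
  dp.em = &em;
  for (int s0 = 0; s0 + min_len <= L; ++s0) {
    int wmax = std::min(max_len, L - s0);
    dp.n = wmax;
    dp.s.assign(full.begin() + s0, full.begin() + s0 + wmax);
    if (prescreen_min_pairs > 0) {
      IntegerVector sub(dp.s.begin(), dp.s.end());
      if (c_max_pairs(sub, em.min_loop) < prescreen_min_pairs) continue;
    }
    run_dp(dp);
    for (int l = min_len; l <= wmax; ++l) {
      double e = dp.W[l - 1];
      bool pass = strict_less ? (e < mfe_cutoff) : (e <= mfe_cutoff + EPS);
      if (!pass) continue;
      std::string db(wmax, '.');
      trace_W(dp, l - 1, db);
      starts.push_back(s0);
      lens.push_back(l);
      mfes.push_back(e);
      structs.push_back(db.substr(0, l));
    }
    if (s0 % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["start"] = wrap(starts), _["len"] = wrap(lens),
                           _["mfe"] = wrap(mfes),
                           _["structure"] = wrap(structs),
                           _["stringsAsFactors"] = false);
}
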