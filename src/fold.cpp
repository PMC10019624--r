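// Minimum-free-energy RNA secondary structure under a compact
// nearest-neighbour model: Watson-Crick + GU stacks parameterised by
// (dH, dS) so that dG(T) = dH - T*dS, and purely entropic loop
// penalties scaled from 310.15 K. Standard Zuker-style recursions with
// V (closed), WM (multiloop segment, >= 1 branch) and W (exterior);
// internal loops capped, no pseudoknots, no dangles, no coaxial
// stacking. Tie-breaking is fixed: candidates are scanned in a
// deterministic order and only strict improvements replace the
// incumbent, so the traceback (which re-scans in the same order and
// takes the first candidate achieving the stored energy) is
// deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INFE = 1e9;
static const double T37 = 310.15;

struct FoldCtx {
  int n;
  std::vector<int> code;            // 1..4 = A,C,G,U; 0 = N
  std::vector<int> ptype;           // pair type per (i,j), 0 if unpairable
  std::vector<double> stackG;       // 6x6 scaled stack free energies
  std::vector<double> hairpinG, bulgeG, internalG;
  double ml_a, ml_b, ml_c, asym_per_nt, asym_max;
  int min_hairpin, max_internal;
  std::vector<double> V, WM;
  std::vector<double> W;

  int pt(int i, int j) const { return ptype[i * n + j]; }

  double hairpin_e(int size) const {
    if (size < min_hairpin) return INFE;
    if (size > (int)hairpinG.size()) return INFE;
    return hairpinG[size - 1];
  }
  double loop_e(int u1, int u2, int i, int j, int k, int l) const {
    int u = u1 + u2;
    if (u == 0) return stackG[(pt(i, j) - 1) * 6 + (pt(k, l) - 1)];
    if (u > max_internal) return INFE;
    if (u1 == 0 || u2 == 0) return bulgeG[u - 1];
    double asym = asym_per_nt * std::abs(u1 - u2);
    if (asym > asym_max) asym = asym_max;
    return internalG[u - 1] + asym;
  }
};

static double Vget(const FoldCtx &c, int i, int j) {
  return c.V[i * c.n + j];
}
static double WMget(const FoldCtx &c, int i, int j) {
  if (i > j) return INFE;
  return c.WM[i * c.n + j];
}

// energy of the best closed structure on [i, j] given inner results
static double computeV(FoldCtx &c, int i, int j) {
  if (c.pt(i, j) == 0 || j - i - 1 < c.min_hairpin) return INFE;
  double best = c.hairpin_e(j - i - 1);
  // stack / bulge / internal: inner pair (k, l)
  int kmax = std::min(j - c.min_hairpin - 2, i + 1 + c.max_internal);
  for (int k = i + 1; k <= kmax; ++k) {
    int u1 = k - i - 1;
    for (int l = j - 1; l >= k + c.min_hairpin + 1; --l) {
      int u2 = j - l - 1;
      if (u1 + u2 > c.max_internal) break;
      if (c.pt(k, l) == 0) continue;
      double inner = Vget(c, k, l);
      if (inner >= INFE) continue;
      double e = c.loop_e(u1, u2, i, j, k, l) + inner;
      if (e < best) best = e;
    }
  }
  // multiloop: a + b (closing pair) + two WM segments
  for (int k = i + 2; k <= j - 2; ++k) {
    double left = WMget(c, i + 1, k), right = WMget(c, k + 1, j - 1);
    if (left >= INFE || right >= INFE) continue;
    double e = c.ml_a + c.ml_b + left + right;
    if (e < best) best = e;
  }
  return best;
}

static double computeWM(FoldCtx &c, int i, int j) {
  double best = INFE;
  double v = Vget(c, i, j);
  if (v < INFE) best = v + c.ml_b;
  if (i + 1 <= j) {
    double e = WMget(c, i + 1, j);
    if (e < INFE && e + c.ml_c < best) best = e + c.ml_c;
    e = WMget(c, i, j - 1);
    if (e < INFE && e + c.ml_c < best) best = e + c.ml_c;
  }
  for (int k = i; k < j; ++k) {
    double a = WMget(c, i, k), b = WMget(c, k + 1, j);
    if (a >= INFE || b >= INFE) continue;
    if (a + b < best) best = a + b;
  }
  return best;
}

struct Frame { int type; int i; int j; };  // 0=W prefix, 1=V, 2=WM

static void traceback(FoldCtx &c, std::vector<int> &pairs) {
  std::vector<Frame> st;
  st.push_back({0, 0, c.n - 1});
  const double eps = 1e-7;
  while (!st.empty()) {
    Frame f = st.back(); st.pop_back();
    if (f.type == 0) {  // exterior prefix ending at j
      int j = f.j;
      while (j >= 0) {
        double wj = c.W[j];
        if (j == 0) {
          if (wj >= -eps) break;  // unpaired
        } else if (std::abs(wj - c.W[j - 1]) <= eps) { --j; continue; }
        bool found = false;
        for (int i = 0; i <= j; ++i) {
          double v = Vget(c, i, j);
          if (v >= INFE) continue;
          double cand = (i > 0 ? c.W[i - 1] : 0.0) + v;
          if (std::abs(cand - wj) <= eps) {
            st.push_back({1, i, j});
            j = i - 1;
            found = true;
            break;
          }
        }
        if (!found) break;  // numerical safety; treat rest as unpaired
      }
    } else if (f.type == 1) {  // V(i, j): (i, j) paired
      int i = f.i, j = f.j;
      pairs[i] = j; pairs[j] = i;
      double vij = Vget(c, i, j);
      if (std::abs(vij - c.hairpin_e(j - i - 1)) <= eps) continue;
      bool found = false;
      int kmax = std::min(j - c.min_hairpin - 2, i + 1 + c.max_internal);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int u1 = k - i - 1;
        for (int l = j - 1; l >= k + c.min_hairpin + 1; --l) {
          int u2 = j - l - 1;
          if (u1 + u2 > c.max_internal) break;
          if (c.pt(k, l) == 0) continue;
          double inner = Vget(c, k, l);
          if (inner >= INFE) continue;
          if (std::abs(c.loop_e(u1, u2, i, j, k, l) + inner - vij) <= eps) {
            st.push_back({1, k, l});
            found = true;
            break;
          }
        }
      }
      if (found) continue;
      for (int k = i + 2; k <= j - 2; ++k) {
        double left = WMget(c, i + 1, k), right = WMget(c, k + 1, j - 1);
        if (left >= INFE || right >= INFE) continue;
        if (std::abs(c.ml_a + c.ml_b + left + right - vij) <= eps) {
          st.push_back({2, i + 1, k});
          st.push_back({2, k + 1, j - 1});
          break;
        }
      }
    } else {  // WM(i, j)
      int i = f.i, j = f.j;
      double wm = WMget(c, i, j);
      if (wm >= INFE) continue;
      double v = Vget(c, i, j);
      if (v < INFE && std::abs(v + c.ml_b - wm) <= eps) {
        st.push_back({1, i, j});
        continue;
      }
      if (i + 1 <= j) {
        double e = WMget(c, i + 1, j);
        if (e < INFE && std::abs(e + c.ml_c - wm) <= eps) {
          st.push_back({2, i + 1, j});
          continue;
        }
        e = WMget(c, i, j - 1);
        if (e < INFE && std::abs(e + c.ml_c - wm) <= eps) {
          st.push_back({2, i, j - 1});
          continue;
        }
      }
      for (int k = i; k < j; ++k) {
        double a = WMget(c, i, k), b = WMget(c, k + 1, j);
        if (a >= INFE || b >= INFE) continue;
        if (std::abs(a + b - wm) <= eps) {
          st.push_back({2, i, k});
          st.push_back({2, k + 1, j});
          break;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector codes, double tempK,
                  NumericMatrix stack_dH, NumericMatrix stack_dS,
                  NumericVector hairpin37, NumericVector bulge37,
                  NumericVector internal37,
                  double ml_a, double ml_b, double ml_c,
                  int min_hairpin, int max_internal,
                  double asym_per_nt, double asym_max,
                  IntegerMatrix pair_type) {
  FoldCtx c;
  c.n = codes.size();
  int n = c.n;
  c.code.assign(codes.begin(), codes.end());
  c.min_hairpin = min_hairpin;
  c.max_internal = max_internal;
  double scale = tempK / T37;
  c.ml_a = ml_a * scale; c.ml_b = ml_b * scale; c.ml_c = ml_c * scale;
  c.asym_per_nt = asym_per_nt * scale;
  c.asym_max = asym_max * scale;
  c.stackG.resize(36);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      c.stackG[a * 6 + b] = stack_dH(a, b) - tempK * stack_dS(a, b);
  auto scaleVec = [&](NumericVector v) {
    std::vector<double> out(v.size());
    for (int i = 0; i < v.size(); ++i)
      out[i] = R_finite(v[i]) ? v[i] * scale : INFE;
    return out;
  };
  c.hairpinG = scaleVec(hairpin37);
  c.bulgeG = scaleVec(bulge37);
  c.internalG = scaleVec(internal37);

  c.ptype.assign((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      int a = c.code[i], b = c.code[j];
      if (a > 0 && b > 0) c.ptype[i * n + j] = pair_type(a - 1, b - 1);
    }

  std::vector<int> pairs(n, -1);
  double dG = 0.0;
  if (n >= min_hairpin + 2) {
    c.V.assign((size_t)n * n, INFE);
    c.WM.assign((size_t)n * n, INFE);
    for (int span = min_hairpin + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        c.V[i * n + j] = computeV(c, i, j);
        c.WM[i * n + j] = computeWM(c, i, j);
      }
      // WM for short spans stays INFE (cannot hold a branch)
    }
    // fill WM for spans shorter than a hairpin explicitly (stay INFE)
    c.W.assign(n, 0.0);
    for (int j = 0; j < n; ++j) {
      double best = (j > 0) ? c.W[j - 1] : 0.0;
      for (int i = 0; i <= j; ++i) {
        double v = Vget(c, i, j);
        if (v >= INFE) continue;
        double cand = (i > 0 ? c.W[i - 1] : 0.0) + v;
        if (cand < best) best = cand;
      }
      c.W[j] = best;
    }
    dG = c.W[n - 1];
    if (dG < 0.0) traceback(c, pairs);
    else dG = 0.0;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pairs[i] + 1;  // 1-based, 0 = unpaired
  return List::create(_["pairs"] = out, _["dG"] = dG);
}
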