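// Minimum-free-energy secondary structure for a single DNA strand folding
// on itself (probe hairpin screening), and the Hamming window scan used by
// the specificity screen.
//
// Energy model (shared with the R-side brute-force oracle through the same
// table list): Watson-Crick pairs (optionally G.T wobble), helices of at
// least two consecutive pairs, hairpin loops of >= 3 unpaired bases,
// stacking free energies from the nearest-neighbor table, affine loop
// penalties for hairpin/bulge/internal loops, and an affine multiloop
// penalty a + b*(branches) + c*(unpaired). The exterior loop is free.
//
// Arrays (0-based, i < j):
//   H[i][j] : min energy of a helix rooted at pair (i,j), i.e. (i,j) and
//             (i+1,j-1) both paired.
//   L[i][j] : min energy given pair (i,j) closes a non-stack loop
//             (hairpin, bulge/internal to an inner helix, or multiloop).
//   M[i][j] : multiloop interior of region [i,j] holding >= 1 helix branch,
//             with per-branch and per-unpaired-base costs.
//   Wsuf[i] : exterior minimum over suffix [i, n-1].
//
// The traceback is co-optimal-greedy: scanning left to right it pairs the
// leftmost position that can be paired in some minimum-energy completion,
// with the smallest possible partner, which makes ties deterministic and
// reproducible by the enumeration oracle.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

const double INF_E = 1e9;
const double EPS = 1e-7;

struct Folder {
  int n;
  std::vector<int> s; // A=0 C=1 G=2 T=3
  std::vector<double> stack16;
  std::vector<double> hp, bu, il; // indexed [size-1]
  double ml_a, ml_b, ml_c;
  bool wobble;
  double wobble_stack;
  std::vector<double> H, L, M;
  std::vector<double> Wsuf;
  std::vector<std::pair<int, int>> pairs;

  inline int at(int i, int j) const { return i * n + j; }

  inline bool canPair(int i, int j) const {
    int a = s[i], b = s[j];
    if (a + b == 3) return true;
    return wobble && ((a == 2 && b == 3) || (a == 3 && b == 2));
  }
  inline bool isWC(int i, int j) const { return s[i] + s[j] == 3; }

  // stack between pairs (i,j) and (i+1,j-1)
  inline double stackval(int i, int j) const {
    if (isWC(i, j) && isWC(i + 1, j - 1))
      return stack16[s[i] * 4 + s[i + 1]];
    return wobble_stack;
  }

  inline double hairpinE(int sz) const {
    if (sz < 3 || sz > (int)hp.size()) return INF_E;
    return hp[sz - 1];
  }
  inline double bulgeE(int sz) const {
    if (sz < 1 || sz > (int)bu.size()) return INF_E;
    return bu[sz - 1];
  }
  inline double internalE(int sz) const {
    if (sz < 2 || sz > (int)il.size()) return INF_E;
    return il[sz - 1];
  }

  void fill() {
    H.assign(n * n, INF_E);
    L.assign(n * n, INF_E);
    M.assign(n * n, INF_E);
    for (int d = 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        // L
        if (d >= 4 && canPair(i, j)) {
          double best = hairpinE(d - 1);
          for (int p = i + 1; p + 6 <= j - 1; ++p) {
            for (int q = p + 6; q <= j - 1; ++q) {
              if (p == i + 1 && q == j - 1) continue;
              if (H[at(p, q)] >= INF_E) continue;
              int n1 = p - i - 1, n2 = j - q - 1;
              if (n1 + n2 < 1) continue;
              double pen =
                  (n1 == 0 || n2 == 0) ? bulgeE(n1 + n2) : internalE(n1 + n2);
              double cand = pen + H[at(p, q)];
              if (cand < best) best = cand;
            }
          }
          for (int k = i + 1; k <= j - 2; ++k) {
            if (M[at(i + 1, k)] >= INF_E || M[at(k + 1, j - 1)] >= INF_E)
              continue;
            double cand =
                ml_a + ml_b + M[at(i + 1, k)] + M[at(k + 1, j - 1)];
            if (cand < best) best = cand;
          }
          L[at(i, j)] = best;
        }
        // H
        if (d >= 6 && canPair(i, j) && canPair(i + 1, j - 1)) {
          double inner = std::min(L[at(i + 1, j - 1)], H[at(i + 1, j - 1)]);
          if (inner < INF_E) H[at(i, j)] = stackval(i, j) + inner;
        }
        // M
        double best = INF_E;
        if (M[at(i + 1, j)] < INF_E) best = std::min(best, M[at(i + 1, j)] + ml_c);
        if (M[at(i, j - 1)] < INF_E) best = std::min(best, M[at(i, j - 1)] + ml_c);
        if (H[at(i, j)] < INF_E) best = std::min(best, H[at(i, j)] + ml_b);
        for (int k = i + 1; k <= j; ++k) {
          if (M[at(i, k - 1)] < INF_E && M[at(k, j)] < INF_E)
            best = std::min(best, M[at(i, k - 1)] + M[at(k, j)]);
        }
        M[at(i, j)] = best;
      }
    }
    Wsuf.assign(n + 1, 0.0);
    for (int i = n - 1; i >= 0; --i) {
      double best = Wsuf[i + 1];
      for (int q = i + 6; q < n; ++q) {
        if (H[at(i, q)] >= INF_E) continue;
        double cand = H[at(i, q)] + Wsuf[q + 1];
        if (cand < best) best = cand;
      }
      Wsuf[i] = best;
    }
  }

  void traceHelixRoot(int p, int q) {
    pairs.push_back({p, q});
    pairs.push_back({p + 1, q - 1});
    traceInterior(p + 1, q - 1, H[at(p, q)] - stackval(p, q));
  }

  // After the first multiloop branch is committed, greedily add further
  // branches while the multiloop accounting stays co-optimal.
  void phaseMulti(int P, int Q, double V, int firstp, int firstq) {
    double running = ml_a + ml_b + ml_c * (firstp - P - 1) +
                     H[at(firstp, firstq)] + ml_b;
    int last = firstq;
    int u = last + 1;
    while (u <= Q - 1) {
      int bestw = -1;
      for (int w = u + 6; w <= Q - 1; ++w) {
        if (H[at(u, w)] >= INF_E) continue;
        double tail = (w == Q - 1) ? 0.0 : ml_c * (Q - 1 - w);
        if (w + 1 <= Q - 1 && M[at(w + 1, Q - 1)] < INF_E)
          tail = std::min(tail, M[at(w + 1, Q - 1)]);
        double tot = running + ml_c * (u - last - 1) + H[at(u, w)] + ml_b + tail;
        if (tot <= V + EPS) { bestw = w; break; }
      }
      if (bestw >= 0) {
        running += ml_c * (u - last - 1) + H[at(u, bestw)] + ml_b;
        traceHelixRoot(u, bestw);
        last = bestw;
        u = bestw + 1;
      } else {
        ++u;
      }
    }
  }

  // Interior of recorded pair (P,Q); V is the exact optimal value of its
  // decomposition: min(H[P][Q] continuation, L[P][Q] loop alternatives).
  void traceInterior(int P, int Q, double V) {
    bool stackFeasible = (Q - P >= 6) && H[at(P, Q)] < INF_E &&
                         H[at(P, Q)] <= V + EPS;
    for (int p = P + 1; p <= Q - 1; ++p) {
      int bestq = -1;
      bool isStack = false;
      int lim = Q - 1;
      if (p == P + 1 && stackFeasible) {
        bestq = Q - 1;
        isStack = true;
        lim = Q - 2;
      }
      for (int q = p + 6; q <= lim; ++q) {
        if (H[at(p, q)] >= INF_E) continue;
        if (p == P + 1 && q == Q - 1) continue;
        int n1 = p - P - 1, n2 = Q - q - 1;
        bool ok = false;
        if (n1 + n2 >= 1) {
          double pen =
              (n1 == 0 || n2 == 0) ? bulgeE(n1 + n2) : internalE(n1 + n2);
          if (pen + H[at(p, q)] <= V + EPS) ok = true;
        }
        if (!ok && q + 1 <= Q - 1 && M[at(q + 1, Q - 1)] < INF_E) {
          double tot = ml_a + ml_b + ml_c * n1 + H[at(p, q)] + ml_b +
                       M[at(q + 1, Q - 1)];
          if (tot <= V + EPS) ok = true;
        }
        if (ok) { bestq = q; isStack = false; break; }
      }
      if (bestq >= 0) {
        if (isStack) {
          pairs.push_back({P + 1, Q - 1});
          traceInterior(P + 1, Q - 1, H[at(P, Q)] - stackval(P, Q));
        } else {
          traceHelixRoot(p, bestq);
          phaseMulti(P, Q, V, p, bestq);
        }
        return;
      }
    }
    // hairpin: nothing further to record
  }

  void traceback() {
    pairs.clear();
    int p = 0;
    while (p < n) {
      int chosen = -1;
      for (int q = p + 6; q < n; ++q) {
        if (H[at(p, q)] >= INF_E) continue;
        if (H[at(p, q)] + Wsuf[q + 1] <= Wsuf[p] + EPS) { chosen = q; break; }
      }
      if (chosen >= 0) {
        traceHelixRoot(p, chosen);
        p = chosen + 1;
      } else {
        ++p;
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_fold(IntegerVector seq_codes, List tables) {
  Folder f;
  f.n = seq_codes.size();
  f.s.assign(seq_codes.begin(), seq_codes.end());
  f.stack16 = as<std::vector<double>>(tables["stack16"]);
  f.hp = as<std::vector<double>>(tables["hairpin"]);
  f.bu = as<std::vector<double>>(tables["bulge"]);
  f.il = as<std::vector<double>>(tables["internal"]);
  f.ml_a = as<double>(tables["ml_a"]);
  f.ml_b = as<double>(tables["ml_b"]);
  f.ml_c = as<double>(tables["ml_c"]);
  f.wobble = as<bool>(tables["wobble"]);
  f.wobble_stack = as<double>(tables["wobble_stack"]);

  double mfe = 0.0;
  IntegerMatrix pm(0, 2);
  if (f.n >= 7) {
    f.fill();
    mfe = f.Wsuf[0];
    if (mfe < -EPS) {
      f.traceback();
      pm = IntegerMatrix(f.pairs.size(), 2);
      for (size_t k = 0; k < f.pairs.size(); ++k) {
        pm(k, 0) = f.pairs[k].first + 1;
        pm(k, 1) = f.pairs[k].second + 1;
      }
    } else {
      mfe = 0.0;
    }
  }
  return List::create(_["mfe"] = mfe, _["pairs"] = pm);
}

namespace {
inline const int *iupac_masks() {
  static int mask[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) mask[i] = 0;
    mask['A'] = 1; mask['C'] = 2; mask['G'] = 4; mask['T'] = 8;
    mask['R'] = 1 | 4; mask['Y'] = 2 | 8; mask['S'] = 2 | 4; mask['W'] = 1 | 8;
    mask['K'] = 4 | 8; mask['M'] = 1 | 2;
    mask['B'] = 2 | 4 | 8; mask['D'] = 1 | 4 | 8; mask['H'] = 1 | 2 | 8;
    mask['V'] = 1 | 2 | 4; mask['N'] = 1 | 2 | 4 | 8;
    init = true;
  }
  return mask;
}
} // namespace

// Per-offset Hamming mismatch counts of a concrete probe (already
// reverse-complemented to the sense strand) against every length-matched
// window of an IUPAC subject. A degenerate subject position matches iff the
// probe base lies in the code's set.
// [[Rcpp::export]]
IntegerVector cpp_window_mismatches(std::string probe, std::string subject) {
  const int *mask = iupac_masks();
  int L = probe.size(), m = subject.size();
  if (L > m) stop("probe longer than subject");
  std::vector<int> pb(L), sb(m);
  for (int i = 0; i < L; ++i) pb[i] = mask[(unsigned char)probe[i]];
  for (int i = 0; i < m; ++i) sb[i] = mask[(unsigned char)subject[i]];
  IntegerVector out(m - L + 1);
  for (int off = 0; off <= m - L; ++off) {
    int mm = 0;
    for (int k = 0; k < L; ++k)
      if ((pb[k] & sb[off + k]) == 0) ++mm;
    out[off] = mm;
  }
  return out;
}

// Batched minimum-mismatch scan: every probe (reverse-complemented to the
// sense strand by the caller) against every subject. Returns an
// n_probes x (2 * n_subjects) matrix of [min count, leftmost 1-based pos]
// pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_min_mismatch_multi(CharacterVector probes_rc,
                                     CharacterVector subjects) {
  const int *mask = iupac_masks();
  int np = probes_rc.size(), ns = subjects.size();
  std::vector<std::vector<int>> sub(ns);
  for (int s = 0; s < ns; ++s) {
    const char *str = CHAR(STRING_ELT(subjects, s));
    int m = LENGTH(STRING_ELT(subjects, s));
    sub[s].resize(m);
    for (int i = 0; i < m; ++i) sub[s][i] = mask[(unsigned char)str[i]];
  }
  IntegerMatrix out(np, 2 * ns);
  for (int p = 0; p < np; ++p) {
    const char *pstr = CHAR(STRING_ELT(probes_rc, p));
    int L = LENGTH(STRING_ELT(probes_rc, p));
    std::vector<int> pb(L);
    for (int i = 0; i < L; ++i) pb[i] = mask[(unsigned char)pstr[i]];
    for (int s = 0; s < ns; ++s) {
      int m = sub[s].size();
      if (L > m) stop("probe longer than subject");
      int best = L + 1, bestpos = 1;
      for (int off = 0; off <= m - L; ++off) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if ((pb[k] & sub[s][off + k]) == 0) {
            ++mm;
            if (mm >= best) break;
          }
        }
        if (mm < best) {
          best = mm;
          bestpos = off + 1;
          if (best == 0) break;
        }
      }
      out(p, 2 * s) = best;
      out(p, 2 * s + 1) = bestpos;
    }
  }
  return out;
}
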