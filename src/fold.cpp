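// Minimum-free-energy folding kernels.
//
// Two energy modes share one admissibility notion (allowed pair classes,
// minimum hairpin loop, optional no-lone-pair constraint):
//
//   PAIRMAX: every pair contributes a per-pair-class weight (Nussinov-style).
//   NN:      simplified nearest-neighbor model: stacking energies, loop
//            penalties by size, affine multiloops; no dangling ends or
//            coaxial stacking.
//
// The no-lone-pair constraint is handled exactly by decomposing structures
// into helices of >= 2 stacked pairs:
//   V(i,j)  — (i,j) is a helix pair;
//   LC(i,j) — (i,j) is the innermost pair of its helix and closes a hairpin,
//             bulge/internal loop (>= 1 unpaired) or multiloop.
// With lone pairs allowed V(i,j) may also close a loop directly.
//
// Ties in the traceback are broken by a fixed branch-preference order; the
// external loop prefers pairing the leftmost position with its smallest
// admissible partner, so the 5'-most pair opens as early as possible.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-7;

struct EModel {
  int mode;                 // 0 = pairmax, 1 = nn
  bool lone_ok;
  int min_hp;
  int max_loop;
  double pairw[4][4];
  bool canpair[4][4];
  double stack[4][4][4][4]; // [a][b][c][d]: outer pair a-b enclosing c-d
  std::vector<double> hairpin, bulge, internal_;
  double ml_a, ml_b, ml_c;
};

static EModel build_model(const List& m, int n) {
  EModel e;
  e.mode = as<int>(m["mode_code"]);
  e.lone_ok = as<bool>(m["lone_pair_allowed"]);
  e.min_hp = as<int>(m["min_hairpin_loop"]);
  e.max_loop = as<int>(m["max_interior_loop"]);
  NumericMatrix pw = m["pair_weight_matrix"];
  LogicalMatrix cp = m["can_pair_matrix"];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      e.pairw[a][b] = pw(a, b);
      e.canpair[a][b] = cp(a, b);
    }
  NumericVector st = m["stack_flat"]; // length 256, index a*64+b*16+c*4+d
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 4; ++c)
        for (int d = 0; d < 4; ++d)
          e.stack[a][b][c][d] = st[a * 64 + b * 16 + c * 4 + d];
  NumericVector hp = m["hairpin_by_size"], bu = m["bulge_by_size"],
                il = m["internal_by_size"];
  e.hairpin.assign(n + 2, INF);
  e.bulge.assign(n + 2, INF);
  e.internal_.assign(n + 2, INF);
  for (int s = 0; s <= n + 1 && s < hp.size(); ++s) e.hairpin[s] = hp[s];
  for (int s = 0; s <= n + 1 && s < bu.size(); ++s) e.bulge[s] = bu[s];
  for (int s = 0; s <= n + 1 && s < il.size(); ++s) e.internal_[s] = il[s];
  e.ml_a = as<double>(m["multiloop_offset"]);
  e.ml_b = as<double>(m["multiloop_branch"]);
  e.ml_c = as<double>(m["multiloop_unpaired"]);
  return e;
}

// ---------------------------------------------------------------- PAIRMAX

struct PairmaxFold {
  int n, min_hp;
  bool lone_ok;
  const EModel* em;
  const std::vector<int>* s;
  std::vector<double> W, V, LC;
  std::vector<int> pairtab;

  double w(int i, int j) const {
    int a = (*s)[i], b = (*s)[j];
    return em->canpair[a][b] ? em->pairw[a][b] : INF;
  }
  bool ok(int i, int j) const {
    return j - i - 1 >= min_hp && em->canpair[(*s)[i]][(*s)[j]];
  }
  inline double& at(std::vector<double>& A, int i, int j) { return A[i * n + j]; }
  double getW(int i, int j) const { return (i > j) ? 0.0 : W[i * n + j]; }
  double getV(int i, int j) const { return V[i * n + j]; }
  double getLC(int i, int j) const { return LC[i * n + j]; }

  void fill() {
    W.assign(n * n, 0.0);
    if (!lone_ok) { V.assign(n * n, INF); LC.assign(n * n, INF); }
    for (int len = 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        if (!lone_ok) {
          if (ok(i, j)) at(LC, i, j) = w(i, j) + getW(i + 1, j - 1);
          if (ok(i, j) && ok(i + 1, j - 1)) {
            double inner = std::min(getV(i + 1, j - 1), getLC(i + 1, j - 1));
            if (inner < INF / 2) at(V, i, j) = w(i, j) + inner;
          }
        }
        double best = getW(i + 1, j); // i unpaired
        for (int k = i + min_hp + 1; k <= j; ++k) {
          double vik = lone_ok
                         ? (ok(i, k) ? w(i, k) + getW(i + 1, k - 1) : INF)
                         : getV(i, k);
          if (vik < INF / 2) {
            double cand = vik + getW(k + 1, j);
            if (cand < best) best = cand;
          }
        }
        at(W, i, j) = best;
      }
    }
  }

  void traceW(int i, int j) {
    if (i >= j) return;
    double tgt = getW(i, j);
    for (int k = i + min_hp + 1; k <= j; ++k) {
      double vik = lone_ok ? (ok(i, k) ? w(i, k) + getW(i + 1, k - 1) : INF)
                           : getV(i, k);
      if (vik < INF / 2 && vik + getW(k + 1, j) <= tgt + EPS) {
        if (lone_ok) {
          pairtab[i] = k; pairtab[k] = i;
          traceW(i + 1, k - 1);
        } else {
          traceV(i, k);
        }
        traceW(k + 1, j);
        return;
      }
    }
    traceW(i + 1, j);
  }
  void traceV(int i, int j) { // !lone_ok helix pair
    pairtab[i] = j; pairtab[j] = i;
    double tgt = getV(i, j) - w(i, j);
    if (getV(i + 1, j - 1) <= tgt + EPS) { traceV(i + 1, j - 1); return; }
    traceLC(i + 1, j - 1);
  }
  void traceLC(int i, int j) {
    pairtab[i] = j; pairtab[j] = i;
    traceW(i + 1, j - 1);
  }

  List run() {
    fill();
    pairtab.assign(n, -1);
    traceW(0, n - 1);
    return List::create(_["energy"] = getW(0, n - 1), _["pairtab"] = wrap(pairtab));
  }
};

// --------------------------------------------------------------------- NN

struct NNFold {
  int n, min_hp, max_loop;
  bool lone_ok;
  const EModel* em;
  const std::vector<int>* s;
  std::vector<double> V, LC, M, E;
  std::vector<int> pairtab;

  bool cp(int i, int j) const { return em->canpair[(*s)[i]][(*s)[j]]; }
  double stk(int i, int j) const { // pair (i,j) stacked on (i+1,j-1)
    return em->stack[(*s)[i]][(*s)[j]][(*s)[i + 1]][(*s)[j - 1]];
  }
  double getV(int i, int j) const { return (i < j) ? V[i * n + j] : INF; }
  double getLC(int i, int j) const { return (i < j) ? LC[i * n + j] : INF; }
  double getM(int i, int j) const { return (i <= j) ? M[i * n + j] : INF; }

  double lc_value(int i, int j, int* tp2 = 0, int* tq2 = 0, int* tk = 0) {
    // best way for (i,j), innermost pair of its helix, to close a loop;
    // reports the chosen decomposition when pointers are given
    double best = em->hairpin[j - i - 1];
    int bp2 = -1, bq2 = -1, bk = -1;
    for (int p2 = i + 1; p2 < j - 1; ++p2) {
      int l1 = p2 - i - 1;
      if (l1 > max_loop) break;
      for (int q2 = j - 1; q2 > p2; --q2) {
        int l2 = j - q2 - 1;
        int tot = l1 + l2;
        if (tot < 1) continue;
        if (tot > max_loop) break;
        double br = getV(p2, q2);
        if (br >= INF / 2) continue;
        double pen = (l1 == 0 || l2 == 0) ? em->bulge[tot] : em->internal_[tot];
        double cand = pen + br;
        if (cand < best - EPS) { best = cand; bp2 = p2; bq2 = q2; bk = -1; }
      }
    }
    for (int k = i + 1; k < j - 1; ++k) {
      double cand = em->ml_a + getM(i + 1, k) + getM(k + 1, j - 1);
      if (cand < best - EPS) { best = cand; bp2 = -1; bq2 = -1; bk = k; }
    }
    if (tp2) { *tp2 = bp2; *tq2 = bq2; *tk = bk; }
    return best;
  }

  void fill() {
    V.assign(n * n, INF);
    LC.assign(n * n, INF);
    M.assign(n * n, INF);
    for (int len = min_hp + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        if (cp(i, j)) {
          LC[i * n + j] = lc_value(i, j);
          double v = INF;
          if (lone_ok) v = LC[i * n + j];
          if (cp(i + 1, j + -1) && j - 1 > i + 1) {
            double inner = lone_ok
                             ? getV(i + 1, j - 1)
                             : std::min(getV(i + 1, j - 1), getLC(i + 1, j - 1));
            if (inner < INF / 2) v = std::min(v, stk(i, j) + inner);
          }
          V[i * n + j] = v;
        }
        // M over [i, j]
        double m = INF;
        if (getV(i, j) < INF / 2) m = getV(i, j) + em->ml_b;
        if (j - 1 >= i) m = std::min(m, getM(i, j - 1) + em->ml_c);
        if (i + 1 <= j) m = std::min(m, getM(i + 1, j) + em->ml_c);
        for (int k = i; k < j; ++k) {
          double a = getM(i, k), b = getM(k + 1, j);
          if (a < INF / 2 && b < INF / 2) m = std::min(m, a + b);
        }
        M[i * n + j] = m;
      }
    }
    E.assign(n + 1, 0.0);
    for (int i = n - 1; i >= 0; --i) {
      double best = E[i + 1];
      for (int j = i + 1; j < n; ++j) {
        double v = getV(i, j);
        if (v < INF / 2) best = std::min(best, v + E[j + 1]);
      }
      E[i] = best;
    }
  }

  void traceE(int i) {
    while (i < n) {
      bool advanced = false;
      for (int j = i + 1; j < n; ++j) {
        double v = getV(i, j);
        if (v < INF / 2 && v + E[j + 1] <= E[i] + EPS) {
          traceV(i, j);
          i = j + 1;
          advanced = true;
          break;
        }
      }
      if (!advanced) i += 1;
    }
  }
  void traceV(int i, int j) {
    pairtab[i] = j; pairtab[j] = i;
    double tgt = getV(i, j);
    if (j - 1 > i + 1 && cp(i + 1, j - 1)) {
      double inner = lone_ok ? getV(i + 1, j - 1)
                             : std::min(getV(i + 1, j - 1), getLC(i + 1, j - 1));
      if (inner < INF / 2 && stk(i, j) + inner <= tgt + EPS) {
        if (lone_ok || getV(i + 1, j - 1) <= inner + EPS) traceV(i + 1, j - 1);
        else traceLCbody(i + 1, j - 1);
        return;
      }
    }
    traceLCbody(i, j); // pair already recorded
  }
  void traceLCbody(int i, int j) {
    pairtab[i] = j; pairtab[j] = i;
    int p2, q2, k;
    lc_value(i, j, &p2, &q2, &k);
    if (p2 >= 0) { traceV(p2, q2); return; }
    if (k >= 0) { traceM(i + 1, k); traceM(k + 1, j - 1); return; }
    // hairpin: nothing inside
  }
  void traceM(int i, int j) {
    double tgt = getM(i, j);
    if (getV(i, j) < INF / 2 && getV(i, j) + em->ml_b <= tgt + EPS) {
      traceV(i, j); return;
    }
    if (j - 1 >= i && getM(i, j - 1) + em->ml_c <= tgt + EPS) {
      traceM(i, j - 1); return;
    }
    if (i + 1 <= j && getM(i + 1, j) + em->ml_c <= tgt + EPS) {
      traceM(i + 1, j); return;
    }
    for (int k = i; k < j; ++k) {
      double a = getM(i, k), b = getM(k + 1, j);
      if (a < INF / 2 && b < INF / 2 && a + b <= tgt + EPS) {
        traceM(i, k); traceM(k + 1, j); return;
      }
    }
    stop("multiloop traceback failed"); // not reachable for consistent tables
  }

  List run() {
    fill();
    pairtab.assign(n, -1);
    if (E[0] < -EPS) traceE(0);
    double e = E[0] < -EPS ? E[0] : 0.0;
    return List::create(_["energy"] = e, _["pairtab"] = wrap(pairtab));
  }
};

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(IntegerVector seq_code, List model) {
  int n = seq_code.size();
  if (n < 1) stop("empty sequence");
  if (n > 5000) stop("sequence too long for the built-in engines");
  std::vector<int> s(seq_code.begin(), seq_code.end());
  for (int i = 0; i < n; ++i)
    if (s[i] < 0 || s[i] > 3) stop("invalid residue code");
  EModel em = build_model(model, n);

  List res;
  if (em.mode == 0) {
    PairmaxFold f;
    f.n = n; f.min_hp = em.min_hp; f.lone_ok = em.lone_ok;
    f.em = &em; f.s = &s;
    res = f.run();
  } else {
    NNFold f;
    f.n = n; f.min_hp = em.min_hp; f.max_loop = em.max_loop;
    f.lone_ok = em.lone_ok; f.em = &em; f.s = &s;
    res = f.run();
  }

  IntegerVector pt = res["pairtab"];
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (pt[i] >= 0) db[i] = (pt[i] > i) ? '(' : ')';
  }
  double e = as<double>(res["energy"]);
  if (e > 0) { e = 0.0; db.assign(n, '.'); }
  return List::create(_["structure"] = db, _["delta_g"] = e);
}
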