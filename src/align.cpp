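#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels. Gap run of length m costs
// alpha + (m-1)*beta: the first gapped position in a run pays alpha,
// each extension pays beta. All scores are integers.
//
// States: M = a[i] aligned to b[j] (diagonal),
//         X = a[i] aligned to a gap (vertical, gap in b),
//         Y = b[j] aligned to a gap (horizontal, gap in a).
// Traceback tie-break: M, then X, then Y, evaluated from the terminal cell.

static const int NEG = std::numeric_limits<int>::min() / 4;

struct DpTables {
  int n, m;
  std::vector<int> M, X, Y;
  DpTables(int n_, int m_) : n(n_), m(m_),
    M((n_ + 1) * (m_ + 1), NEG), X((n_ + 1) * (m_ + 1), NEG),
    Y((n_ + 1) * (m_ + 1), NEG) {}
  inline int idx(int i, int j) const { return i * (m + 1) + j; }
};

static void nw_fill(const int* a, int n, const int* b, int m,
                    const IntegerMatrix& S, int alpha, int beta,
                    bool free_ends, DpTables& T) {
  T.M[T.idx(0, 0)] = 0;
  for (int i = 1; i <= n; ++i)
    T.X[T.idx(i, 0)] = free_ends ? 0 : -(alpha + (i - 1) * beta);
  for (int j = 1; j <= m; ++j)
    T.Y[T.idx(0, j)] = free_ends ? 0 : -(alpha + (j - 1) * beta);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int d = T.idx(i - 1, j - 1), u = T.idx(i - 1, j),
                l = T.idx(i, j - 1), c = T.idx(i, j);
      int best = T.M[d];
      if (T.X[d] > best) best = T.X[d];
      if (T.Y[d] > best) best = T.Y[d];
      T.M[c] = (best <= NEG) ? NEG : best + S(a[i - 1], b[j - 1]);
      int x = T.M[u] <= NEG ? NEG : T.M[u] - alpha;
      if (T.X[u] > NEG && T.X[u] - beta > x) x = T.X[u] - beta;
      if (T.Y[u] > NEG && T.Y[u] - alpha > x) x = T.Y[u] - alpha;
      T.X[c] = x;
      int y = T.M[l] <= NEG ? NEG : T.M[l] - alpha;
      if (T.X[l] > NEG && T.X[l] - alpha > y) y = T.X[l] - alpha;
      if (T.Y[l] > NEG && T.Y[l] - beta > y) y = T.Y[l] - beta;
      T.Y[c] = y;
    }
  }
}

// Traceback from (n, m); emits 1-based indices per column, 0 = gap.
// Returns pairs in reverse order.
static void nw_traceback(const DpTables& T, int alpha, int beta,
                         bool free_ends,
                         std::vector<int>& ca, std::vector<int>& cb,
                         int& score) {
  int n = T.n, m = T.m;
  int i = n, j = m;
  int state;
  if (!free_ends) {
    // terminal state: priority M > X > Y
    int sM = T.M[T.idx(n, m)], sX = T.X[T.idx(n, m)], sY = T.Y[T.idx(n, m)];
    if (sM >= sX && sM >= sY) { state = 0; score = sM; }
    else if (sX >= sY)        { state = 1; score = sX; }
    else                      { state = 2; score = sY; }
  } else {
    // trailing gaps are free: best cell on the last row or last column,
    // preferring cells nearest (n, m)
    score = NEG; state = 0;
    for (int jj = m; jj >= 0; --jj) {
      int c = T.idx(n, jj);
      int v[3] = { T.M[c], T.X[c], T.Y[c] };
      for (int s = 0; s < 3; ++s)
        if (v[s] > score) { score = v[s]; state = s; i = n; j = jj; }
    }
    for (int ii = n; ii >= 0; --ii) {
      int c = T.idx(ii, m);
      int v[3] = { T.M[c], T.X[c], T.Y[c] };
      for (int s = 0; s < 3; ++s)
        if (v[s] > score) { score = v[s]; state = s; i = ii; j = m; }
    }
    for (int jj = m; jj > j; --jj) { ca.push_back(0); cb.push_back(jj); }
    for (int ii = n; ii > i; --ii) { ca.push_back(ii); cb.push_back(0); }
  }
  while (i > 0 || j > 0) {
    if (state == 0) {
      // diagonal move; predecessor among M/X/Y at (i-1, j-1)
      ca.push_back(i); cb.push_back(j);
      const int d = T.idx(i - 1, j - 1);
      int v = T.M[T.idx(i, j)]; (void)v;
      int pM = T.M[d], pX = T.X[d], pY = T.Y[d];
      --i; --j;
      if (pM >= pX && pM >= pY) state = 0;
      else if (pX >= pY) state = 1;
      else state = 2;
    } else if (state == 1) {
      ca.push_back(i); cb.push_back(0);
      if (j == 0) {  // leading vertical run
        --i;
        if (i == 0) state = 0;
        continue;
      }
      const int u = T.idx(i - 1, j);
      int cur = T.X[T.idx(i, j)];
      // which predecessor reproduced cur? priority M > X > Y
      if (T.M[u] > NEG && T.M[u] - alpha == cur) state = 0;
      else if (T.X[u] > NEG && T.X[u] - beta == cur) state = 1;
      else state = 2;
      --i;
    } else {
      ca.push_back(0); cb.push_back(j);
      if (i == 0) {
        --j;
        if (j == 0) state = 0;
        continue;
      }
      const int l = T.idx(i, j - 1);
      int cur = T.Y[T.idx(i, j)];
      if (T.M[l] > NEG && T.M[l] - alpha == cur) state = 0;
      else if (T.X[l] > NEG && T.X[l] - alpha == cur) state = 1;
      else state = 2;
      --j;
    }
  }
  (void)free_ends;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  int alpha, int beta, bool free_ends) {
  int n = a.size(), m = b.size();
  DpTables T(n, m);
  nw_fill(a.begin(), n, b.begin(), m, S, alpha, beta, free_ends, T);
  std::vector<int> ca, cb;
  int score;
  nw_traceback(T, alpha, beta, free_ends, ca, cb, score);
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  return List::create(_["score"] = score,
                      _["cols_a"] = IntegerVector(ca.begin(), ca.end()),
                      _["cols_b"] = IntegerVector(cb.begin(), cb.end()));
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  int alpha, int beta) {
  int n = a.size(), m = b.size();
  // H = best local score ending at (i, j); E = gap-in-a (left), F = gap-in-b (up)
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto id = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = H[id(i, j - 1)] - alpha;
      if (E[id(i, j - 1)] > NEG && E[id(i, j - 1)] - beta > e)
        e = E[id(i, j - 1)] - beta;
      E[id(i, j)] = e;
      int f = H[id(i - 1, j)] - alpha;
      if (F[id(i - 1, j)] > NEG && F[id(i - 1, j)] - beta > f)
        f = F[id(i - 1, j)] - beta;
      F[id(i, j)] = f;
      int h = H[id(i - 1, j - 1)] + S(a[i - 1], b[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[id(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> ca, cb;
  int i = bi, j = bj;
  // state 0 = H(diag entry), 1 = F (up), 2 = E (left)
  int state = 0;
  while (i > 0 && j > 0 && H[id(i, j)] > 0) {
    if (state == 0) {
      int h = H[id(i, j)];
      int diag = H[id(i - 1, j - 1)] + S(a[i - 1], b[j - 1]);
      if (h == diag) {
        ca.push_back(i); cb.push_back(j); --i; --j;
      } else if (h == F[id(i, j)]) {
        state = 1;
      } else if (h == E[id(i, j)]) {
        state = 2;
      } else break;  // h == 0 handled by loop guard
    } else if (state == 1) {
      ca.push_back(i); cb.push_back(0);
      int cur = F[id(i, j)];
      if (H[id(i - 1, j)] - alpha == cur) state = 0;
      --i;
    } else {
      ca.push_back(0); cb.push_back(j);
      int cur = E[id(i, j)];
      if (H[id(i, j - 1)] - alpha == cur) state = 0;
      --j;
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  return List::create(_["score"] = best,
                      _["cols_a"] = IntegerVector(ca.begin(), ca.end()),
                      _["cols_b"] = IntegerVector(cb.begin(), cb.end()));
}

// Score-only Smith-Waterman of one query against many subjects
// (rolling rows); used by the homology-search null distribution.
// [[Rcpp::export(name = ".sw_best_scores_cpp")]]
IntegerVector sw_best_scores_cpp(IntegerVector q, List db, IntegerMatrix S,
                                 int alpha, int beta) {
  int nq = q.size();
  IntegerVector out(db.size());
  for (int k = 0; k < db.size(); ++k) {
    IntegerVector b = db[k];
    int m = b.size();
    std::vector<int> Hp(m + 1, 0), H(m + 1, 0), Ep(m + 1, NEG), E(m + 1, NEG),
        Fp(m + 1, NEG), F(m + 1, NEG);
    int best = 0;
    for (int i = 1; i <= nq; ++i) {
      H[0] = 0; E[0] = NEG; F[0] = NEG;
      for (int j = 1; j <= m; ++j) {
        int e = H[j - 1] - alpha;
        if (E[j - 1] > NEG && E[j - 1] - beta > e) e = E[j - 1] - beta;
        E[j] = e;
        int f = Hp[j] - alpha;
        if (Fp[j] > NEG && Fp[j] - beta > f) f = Fp[j] - beta;
        F[j] = f;
        int h = Hp[j - 1] + S(q[i - 1], b[j - 1]);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        H[j] = h;
        if (h > best) best = h;
      }
      std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
    }
    out[k] = best;
  }
  return out;
}

// Grid search hot loop: for every (alpha, beta) combination align every
// training pair and score it against its reference alignment with the
// Q = (f_D + f_M)/2 accuracy measure, where l_R / l_T are the counts of
// aligned residue pairs in the reference / test alignment. ref_map gives,
// for each position of sequence a (1-based), the reference-aligned
// position of b, or 0. Returns mean Q (percent), rows alphas, cols betas.
// [[Rcpp::export(name = ".grid_q_cpp")]]
NumericMatrix grid_q_cpp(List pairs, IntegerMatrix S, IntegerVector alphas,
                         IntegerVector betas, bool free_ends) {
  int np = pairs.size();
  NumericMatrix out(alphas.size(), betas.size());
  std::vector<IntegerVector> av(np), bs(np), maps(np);
  std::vector<int> lref(np);
  for (int p = 0; p < np; ++p) {
    List pr = pairs[p];
    av[p] = IntegerVector(pr["a"]);
    bs[p] = IntegerVector(pr["b"]);
    maps[p] = IntegerVector(pr["ref_map"]);
    lref[p] = Rcpp::as<int>(pr["l_ref"]);
  }
  for (int ia = 0; ia < alphas.size(); ++ia) {
    for (int ib = 0; ib < betas.size(); ++ib) {
      const int alpha = alphas[ia], beta = betas[ib];
      double qsum = 0.0;
      for (int p = 0; p < np; ++p) {
        int n = av[p].size(), m = bs[p].size();
        DpTables T(n, m);
        nw_fill(av[p].begin(), n, bs[p].begin(), m, S, alpha, beta,
                free_ends, T);
        std::vector<int> ca, cb;
        int score;
        nw_traceback(T, alpha, beta, free_ends, ca, cb, score);
        int lT = 0, nI = 0;
        for (size_t c = 0; c < ca.size(); ++c) {
          if (ca[c] > 0 && cb[c] > 0) {
            ++lT;
            if (maps[p][ca[c] - 1] == cb[c]) ++nI;
          }
        }
        double fD = 100.0 * nI / lref[p];
        double fM = lT > 0 ? 100.0 * nI / lT : 0.0;
        qsum += (fD + fM) / 2.0;
      }
      out(ia, ib) = qsum / np;
    }
  }
  return out;
}
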