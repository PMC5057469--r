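// Core numerical routines for the maximum-likelihood engine:
//  - GTR+Gamma transition probabilities from a precomputed eigen system
//  - Felsenstein pruning log-likelihood with per-node scaling
//  - edge-wise branch-length optimization (Brent) with partial caching
//  - NNI candidate scoring around every internal edge
//  - Fitch parsimony and randomized stepwise addition
//
// Trees arrive as ape-style edge matrices (tips 1..nTip, root nTip+1),
// together with a postorder list of internal nodes and per-node child-edge
// lists computed in R. All node/edge indices are 1-based on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

typedef std::vector<double> dvec;

// ---------------------------------------------------------------------------
// small helpers

struct Model {
  double U[16], Ui[16], lam[4], pi[4];
  std::vector<double> rates; // gamma category rates, mean 1
  int ncat() const { return (int)rates.size(); }
};

// P(t) = U diag(exp(lam*t)) Ui, clamped to [0, inf)
static inline void pmat(const Model &M, double t, double P[16]) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(M.lam[k] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += M.U[i * 4 + k] * e[k] * M.Ui[k * 4 + j];
      P[i * 4 + j] = s > 0.0 ? s : 0.0;
    }
}

// Layout of a partial: idx = (cat*npat + pat)*4 + state
static inline size_t pidx(int cat, int pat, int npat) {
  return ((size_t)cat * npat + pat) * 4;
}

struct Engine {
  int nTip, nNodes, nEdge, npat, ncat;
  std::vector<int> epar, echild;       // per edge (1-based node ids)
  dvec el;                             // edge lengths
  std::vector<int> po;                 // internal nodes, postorder, root last
  std::vector<std::vector<int> > kids; // child edge indices per node (0-based edges)
  const int *tipcode;                  // nTip x npat, column-major, values 1..15
  dvec codeTab;                        // 15 x 4 row-major: code -> 0/1 state row
  const double *w;                     // pattern weights
  Model M;

  std::vector<dvec> D;      // per node partials (internal only; tips via codeTab)
  std::vector<dvec> scaleD; // per node per-pattern log scalers

  int root() const { return nTip + 1; }

  double tipstate(int tip, int pat, int s) const {
    // tip is 1-based; tipcode column-major with nTip rows
    int code = tipcode[(size_t)pat * nTip + (tip - 1)];
    return codeTab[(size_t)(code - 1) * 4 + s];
  }

  // transported tip partials: tp[code][i] = sum_j P_ij * codeTab[code][j]
  void tip_table(const double P[16], double tp[15][4]) const {
    for (int code = 0; code < 15; ++code)
      for (int i = 0; i < 4; ++i) {
        double s = 0.0;
        for (int j = 0; j < 4; ++j)
          s += P[i * 4 + j] * codeTab[(size_t)code * 4 + j];
        tp[code][i] = s;
      }
  }

  // X = P(t*r) applied to the subtree partial of `child` (contribution at parent)
  void transport_down(int child, double t, dvec &X) const {
    double P[16];
    if (child <= nTip) {
      double tp[15][4];
      const int *tc = tipcode + (child - 1);
      for (int c = 0; c < ncat; ++c) {
        pmat(M, t * M.rates[c], P);
        tip_table(P, tp);
        for (int p = 0; p < npat; ++p) {
          size_t o = pidx(c, p, npat);
          const double *row = tp[tc[(size_t)p * nTip] - 1];
          X[o] = row[0]; X[o + 1] = row[1];
          X[o + 2] = row[2]; X[o + 3] = row[3];
        }
      }
      return;
    }
    if (D[child].empty())
      Rcpp::stop("internal error: node %d visited before its subtree", child);
    for (int c = 0; c < ncat; ++c) {
      pmat(M, t * M.rates[c], P);
      const double *Dc = D[child].data();
      for (int p = 0; p < npat; ++p) {
        size_t o = pidx(c, p, npat);
        const double *in = Dc + o;
        for (int i = 0; i < 4; ++i) {
          double s = 0.0;
          for (int j = 0; j < 4; ++j) s += P[i * 4 + j] * in[j];
          X[o + i] = s;
        }
      }
    }
  }

  // Tc_j = sum_i P_ji(t*r) S_i : move a parent-side partial across an edge
  void transport_up(const dvec &S, double t, dvec &Tc) const {
    double P[16];
    for (int c = 0; c < ncat; ++c) {
      pmat(M, t * M.rates[c], P);
      for (int p = 0; p < npat; ++p) {
        size_t o = pidx(c, p, npat);
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int i = 0; i < 4; ++i) s += P[j * 4 + i] * S[o + i];
          Tc[o + j] = s;
        }
      }
    }
  }

  // rescale a partial per pattern; adds log scaler into sc (sc must be sized npat)
  void rescale(dvec &A, dvec &sc) const {
    for (int p = 0; p < npat; ++p) {
      double m = 0.0;
      for (int c = 0; c < ncat; ++c) {
        size_t o = pidx(c, p, npat);
        for (int s = 0; s < 4; ++s)
          if (A[o + s] > m) m = A[o + s];
      }
      if (m <= 0.0) m = 1e-300;
      double inv = 1.0 / m;
      for (int c = 0; c < ncat; ++c) {
        size_t o = pidx(c, p, npat);
        for (int s = 0; s < 4; ++s) A[o + s] *= inv;
      }
      sc[p] += std::log(m);
    }
  }

  // recompute D[v] from its children (v internal), refreshing scaleD[v]
  void refreshD(int v) {
    dvec &Dv = D[v];
    std::fill(Dv.begin(), Dv.end(), 1.0);
    dvec &sc = scaleD[v];
    std::fill(sc.begin(), sc.end(), 0.0);
    dvec X((size_t)ncat * npat * 4);
    for (size_t k = 0; k < kids[v].size(); ++k) {
      int e = kids[v][k];
      int c = echild[e];
      transport_down(c, el[e], X);
      for (size_t i = 0; i < Dv.size(); ++i) Dv[i] *= X[i];
      if (c > nTip)
        for (int p = 0; p < npat; ++p) sc[p] += scaleD[c][p];
    }
    rescale(Dv, sc);
  }

  void computeAllD() {
    D.assign(nNodes + 1, dvec());
    scaleD.assign(nNodes + 1, dvec());
    for (size_t k = 0; k < po.size(); ++k) {
      int v = po[k];
      D[v].assign((size_t)ncat * npat * 4, 1.0);
      scaleD[v].assign(npat, 0.0);
      refreshD(v);
    }
  }

  double rootLoglik() const {
    int r = root();
    double ll = 0.0;
    double invK = 1.0 / ncat;
    for (int p = 0; p < npat; ++p) {
      double site = 0.0;
      for (int c = 0; c < ncat; ++c) {
        size_t o = pidx(c, p, npat);
        for (int s = 0; s < 4; ++s) site += M.pi[s] * D[r][o + s];
      }
      site *= invK;
      ll += w[p] * (std::log(site) + scaleD[r][p]);
    }
    return ll;
  }

  // log-likelihood as a function of one edge length, given SP = pi * (parent
  // side partial) and the child subtree partial (or tip).
  double edgeLoglik(const dvec &SP, const dvec &scS, int child,
                    double t) const {
    double P[16];
    dvec site(npat, 0.0);
    for (int c = 0; c < ncat; ++c) {
      pmat(M, t * M.rates[c], P);
      if (child <= nTip) {
        double tp[15][4];
        tip_table(P, tp);
        const int *tc = tipcode + (child - 1);
        for (int p = 0; p < npat; ++p) {
          size_t o = pidx(c, p, npat);
          const double *row = tp[tc[(size_t)p * nTip] - 1];
          site[p] += SP[o] * row[0] + SP[o + 1] * row[1] +
                     SP[o + 2] * row[2] + SP[o + 3] * row[3];
        }
        continue;
      }
      const double *Dc = D[child].data();
      for (int p = 0; p < npat; ++p) {
        size_t o = pidx(c, p, npat);
        const double *in = Dc + o;
        double acc = 0.0;
        for (int i = 0; i < 4; ++i) {
          double x = 0.0;
          for (int j = 0; j < 4; ++j) x += P[i * 4 + j] * in[j];
          acc += SP[o + i] * x;
        }
        site[p] += acc;
      }
    }
    double ll = 0.0, invK = 1.0 / ncat;
    const double *scC = (child > nTip) ? scaleD[child].data() : NULL;
    for (int p = 0; p < npat; ++p) {
      double s = site[p] * invK;
      if (s <= 0.0) s = 1e-300;
      ll += w[p] * (std::log(s) + scS[p] + (scC ? scC[p] : 0.0));
    }
    return ll;
  }

  // generic variant where the "child" side is an explicit partial
  double edgeLoglik2(const dvec &SP, const dvec &B, const dvec &scTot,
                     double t) const {
    double P[16];
    double ll = 0.0, invK = 1.0 / ncat;
    dvec site(npat, 0.0);
    for (int c = 0; c < ncat; ++c) {
      pmat(M, t * M.rates[c], P);
      for (int p = 0; p < npat; ++p) {
        size_t o = pidx(c, p, npat);
        double acc = 0.0;
        for (int i = 0; i < 4; ++i) {
          double x = 0.0;
          for (int j = 0; j < 4; ++j) x += P[i * 4 + j] * B[o + j];
          acc += SP[o + i] * x;
        }
        site[p] += acc;
      }
    }
    for (int p = 0; p < npat; ++p) {
      double s = site[p] * invK;
      if (s <= 0.0) s = 1e-300;
      ll += w[p] * (std::log(s) + scTot[p]);
    }
    return ll;
  }
};

// ---------------------------------------------------------------------------
// Brent maximization on [a,b] (local, parabolic + golden section)

static double brent_max(const std::function<double(double)> &f, double a,
                        double b, double tol, int maxit, double *fout) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), wx = x, v = x;
  double fx = -f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < maxit; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    if (std::fabs(e) > tol1) {
      r = (x - wx) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - wx) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(p) >= std::fabs(0.5 * q * etmp) || p <= q * (a - x) ||
          p >= q * (b - x)) {
        e = (x < m) ? b - x : a - x;
        d = gold * e;
      } else {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
      }
    } else {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = -f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = wx; fv = fw; wx = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wx == x) { v = wx; fv = fw; wx = u; fw = fu; }
      else if (fu <= fv || v == x || v == wx) { v = u; fv = fu; }
    }
  }
  if (fout) *fout = -fx;
  return x;
}

// ---------------------------------------------------------------------------
// construction from R arguments

static Engine make_engine(const IntegerMatrix &edge, const NumericVector &el,
                          int nTip, const IntegerVector &po,
                          const List &childEdges, const IntegerMatrix &tipcode,
                          const NumericMatrix &codeTab, const NumericVector &w,
                          const NumericMatrix &U, const NumericMatrix &Ui,
                          const NumericVector &lam, const NumericVector &pi,
                          const NumericVector &rates) {
  Engine E;
  E.nTip = nTip;
  E.nEdge = edge.nrow();
  E.nNodes = nTip + childEdges.size() - nTip; // see below; childEdges has one slot per node
  E.nNodes = childEdges.size();
  E.npat = tipcode.ncol();
  E.ncat = rates.size();
  E.epar.assign(E.nEdge + 1, 0);
  E.echild.assign(E.nEdge + 1, 0);
  E.el.assign(E.nEdge + 1, 0.0);
  for (int e = 0; e < E.nEdge; ++e) {
    E.epar[e + 1] = edge(e, 0);
    E.echild[e + 1] = edge(e, 1);
    E.el[e + 1] = el[e];
  }
  E.po.assign(po.begin(), po.end());
  E.kids.assign(E.nNodes + 1, std::vector<int>());
  for (int v = 0; v < (int)childEdges.size(); ++v) {
    IntegerVector k = childEdges[v];
    for (int i = 0; i < k.size(); ++i) E.kids[v + 1].push_back(k[i]);
  }
  E.tipcode = INTEGER(tipcode);
  E.codeTab.assign(codeTab.nrow() * 4, 0.0);
  for (int r = 0; r < codeTab.nrow(); ++r)
    for (int j = 0; j < 4; ++j) E.codeTab[(size_t)r * 4 + j] = codeTab(r, j);
  E.w = REAL(w);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      E.M.U[i * 4 + j] = U(i, j);
      E.M.Ui[i * 4 + j] = Ui(i, j);
    }
  for (int i = 0; i < 4; ++i) {
    E.M.lam[i] = lam[i];
    E.M.pi[i] = pi[i];
  }
  E.M.rates.assign(rates.begin(), rates.end());
  return E;
}

// [[Rcpp::export]]
double cpp_loglik(IntegerMatrix edge, NumericVector el, int nTip,
                  IntegerVector po, List childEdges, IntegerMatrix tipcode,
                  NumericMatrix codeTab, NumericVector w, NumericMatrix U,
                  NumericMatrix Ui, NumericVector lam, NumericVector pi,
                  NumericVector rates) {
  Engine E = make_engine(edge, el, nTip, po, childEdges, tipcode, codeTab, w,
                         U, Ui, lam, pi, rates);
  E.computeAllD();
  return E.rootLoglik();
}

// ---------------------------------------------------------------------------
// branch-length optimization: coordinate ascent over edges, depth-first,
// refreshing subtree partials on the way back up so every 1-D Brent step
// works against exact conditionals (log-likelihood is non-decreasing).

struct OptCtx {
  Engine *E;
  double minbl, maxbl, ttol;
  int brent_maxit;
};

static void optim_visit(OptCtx &C, int v, dvec &T, dvec &scT) {
  Engine &E = *C.E;
  size_t plen = (size_t)E.ncat * E.npat * 4;
  dvec X(plen), S(plen), SP(plen), scS(E.npat);
  for (size_t k = 0; k < E.kids[v].size(); ++k) {
    int e = E.kids[v][k];
    int c = E.echild[e];
    // parent-side partial excluding edge e
    std::copy(T.begin(), T.end(), S.begin());
    std::copy(scT.begin(), scT.end(), scS.begin());
    for (size_t k2 = 0; k2 < E.kids[v].size(); ++k2) {
      if (k2 == k) continue;
      int e2 = E.kids[v][k2];
      int c2 = E.echild[e2];
      E.transport_down(c2, E.el[e2], X);
      for (size_t i = 0; i < plen; ++i) S[i] *= X[i];
      if (c2 > E.nTip)
        for (int p = 0; p < E.npat; ++p) scS[p] += E.scaleD[c2][p];
    }
    for (int cat = 0; cat < E.ncat; ++cat)
      for (int p = 0; p < E.npat; ++p) {
        size_t o = pidx(cat, p, E.npat);
        for (int s = 0; s < 4; ++s) SP[o + s] = E.M.pi[s] * S[o + s];
      }
    std::function<double(double)> f = [&](double t) {
      return E.edgeLoglik(SP, scS, c, t);
    };
    double t = brent_max(f, C.minbl, C.maxbl, C.ttol, C.brent_maxit, NULL);
    E.el[e] = t;
    if (c > E.nTip) {
      dvec Tc(plen), scTc(scS);
      E.transport_up(S, t, Tc);
      E.rescale(Tc, scTc);
      optim_visit(C, c, Tc, scTc);
      E.refreshD(c);
    }
  }
}

// [[Rcpp::export]]
List cpp_optim_bl(IntegerMatrix edge, NumericVector el, int nTip,
                  IntegerVector po, List childEdges, IntegerMatrix tipcode,
                  NumericMatrix codeTab, NumericVector w, NumericMatrix U,
                  NumericMatrix Ui, NumericVector lam, NumericVector pi,
                  NumericVector rates, double tol, int max_rounds,
                  double minbl, double maxbl, double ttol) {
  Engine E = make_engine(edge, el, nTip, po, childEdges, tipcode, codeTab, w,
                         U, Ui, lam, pi, rates);
  OptCtx C;
  C.E = &E;
  C.minbl = minbl;
  C.maxbl = maxbl;
  C.ttol = ttol;
  C.brent_maxit = 100;
  E.computeAllD();
  double ll = E.rootLoglik();
  double ll0 = ll;
  int rounds = 0;
  bool converged = false;
  size_t plen = (size_t)E.ncat * E.npat * 4;
  for (int r = 0; r < max_rounds; ++r) {
    dvec T(plen, 1.0), scT(E.npat, 0.0);
    optim_visit(C, E.root(), T, scT);
    E.refreshD(E.root());
    double llnew = E.rootLoglik();
    ++rounds;
    double gain = llnew - ll;
    ll = llnew;
    if (gain < tol) {
      converged = true;
      break;
    }
  }
  NumericVector elout(E.nEdge);
  for (int e = 0; e < E.nEdge; ++e) elout[e] = E.el[e + 1];
  return List::create(_["el"] = elout, _["loglik"] = ll,
                      _["loglik0"] = ll0, _["rounds"] = rounds,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// NNI scoring. For each internal edge (v,c) the four surrounding subtree
// contributions (transported across their own pendant edges) are combined
// in the three possible ways; only the central edge length is re-optimized.
// Returned per edge: current and swapped log-likelihoods + optimal lengths.

// [[Rcpp::export]]
NumericMatrix cpp_nni_eval(IntegerMatrix edge, NumericVector el, int nTip,
                           IntegerVector po, List childEdges,
                           IntegerMatrix tipcode, NumericMatrix codeTab,
                           NumericVector w, NumericMatrix U, NumericMatrix Ui,
                           NumericVector lam, NumericVector pi,
                           NumericVector rates, double minbl, double maxbl,
                           double ttol) {
  Engine E = make_engine(edge, el, nTip, po, childEdges, tipcode, codeTab, w,
                         U, Ui, lam, pi, rates);
  E.computeAllD();
  size_t plen = (size_t)E.ncat * E.npat * 4;

  // transported contribution of every edge's child side, at its parent
  std::vector<dvec> X(E.nEdge + 1);
  std::vector<dvec> scX(E.nEdge + 1);
  for (int e = 1; e <= E.nEdge; ++e) {
    X[e].assign(plen, 0.0);
    E.transport_down(E.echild[e], E.el[e], X[e]);
    scX[e].assign(E.npat, 0.0);
    if (E.echild[e] > E.nTip) scX[e] = E.scaleD[E.echild[e]];
  }

  // parent-side partial at every internal non-root node (transported across
  // the edge above it)
  std::vector<dvec> Tn(E.nNodes + 1);
  std::vector<dvec> scTn(E.nNodes + 1);
  {
    std::function<void(int, const dvec &, const dvec &)> visit =
        [&](int v, const dvec &T, const dvec &scT) {
          for (size_t k = 0; k < E.kids[v].size(); ++k) {
            int e = E.kids[v][k];
            int c = E.echild[e];
            if (c <= E.nTip) continue;
            dvec S(T), scS(scT);
            for (size_t k2 = 0; k2 < E.kids[v].size(); ++k2) {
              if (k2 == k) continue;
              int e2 = E.kids[v][k2];
              for (size_t i = 0; i < plen; ++i) S[i] *= X[e2][i];
              for (int p = 0; p < E.npat; ++p) scS[p] += scX[e2][p];
            }
            Tn[c].assign(plen, 0.0);
            E.transport_up(S, E.el[e], Tn[c]);
            scTn[c] = scS;
            E.rescale(Tn[c], scTn[c]);
            visit(c, Tn[c], scTn[c]);
          }
        };
    dvec T(plen, 1.0), scT(E.npat, 0.0);
    visit(E.root(), T, scT);
  }

  // collect internal edges
  std::vector<int> iedges;
  for (int e = 1; e <= E.nEdge; ++e)
    if (E.echild[e] > E.nTip) iedges.push_back(e);

  NumericMatrix out(iedges.size(), 7);
  dvec A(plen), B(plen), SP(plen), scTot(E.npat);
  for (size_t r = 0; r < iedges.size(); ++r) {
    int e = iedges[r];
    int v = E.epar[e], c = E.echild[e];
    const std::vector<int> &ck = E.kids[c];
    int ex = ck[0], ey = ck[1];
    const dvec *W1, *W2, *sW1, *sW2;
    if (v == E.root()) {
      std::vector<int> others;
      for (size_t k = 0; k < E.kids[v].size(); ++k)
        if (E.kids[v][k] != e) others.push_back(E.kids[v][k]);
      W1 = &X[others[0]]; sW1 = &scX[others[0]];
      W2 = &X[others[1]]; sW2 = &scX[others[1]];
    } else {
      int ea = (E.kids[v][0] == e) ? E.kids[v][1] : E.kids[v][0];
      W1 = &X[ea]; sW1 = &scX[ea];
      W2 = &Tn[v]; sW2 = &scTn[v];
    }
    for (int p = 0; p < E.npat; ++p)
      scTot[p] = (*sW1)[p] + (*sW2)[p] + scX[ex][p] + scX[ey][p];
    double lls[3], ts[3];
    for (int cfg = 0; cfg < 3; ++cfg) {
      const dvec *a2, *b1, *b2;
      // cfg 0: (W1,W2)|(X,Y)  1: (W1,X)|(W2,Y)  2: (W1,Y)|(W2,X)
      if (cfg == 0) { a2 = W2; b1 = &X[ex]; b2 = &X[ey]; }
      else if (cfg == 1) { a2 = &X[ex]; b1 = W2; b2 = &X[ey]; }
      else { a2 = &X[ey]; b1 = W2; b2 = &X[ex]; }
      for (size_t i = 0; i < plen; ++i) {
        A[i] = (*W1)[i] * (*a2)[i];
        B[i] = (*b1)[i] * (*b2)[i];
      }
      for (int cat = 0; cat < E.ncat; ++cat)
        for (int p = 0; p < E.npat; ++p) {
          size_t o = pidx(cat, p, E.npat);
          for (int s = 0; s < 4; ++s) SP[o + s] = E.M.pi[s] * A[o + s];
        }
      std::function<double(double)> f = [&](double t) {
        return E.edgeLoglik2(SP, B, scTot, t);
      };
      double fb;
      double t = brent_max(f, minbl, maxbl, ttol, 60, &fb);
      lls[cfg] = fb;
      ts[cfg] = t;
    }
    out(r, 0) = e;
    out(r, 1) = lls[0];
    out(r, 2) = ts[0];
    out(r, 3) = lls[1];
    out(r, 4) = ts[1];
    out(r, 5) = lls[2];
    out(r, 6) = ts[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fitch parsimony on bitmask-encoded patterns

struct FitchTree {
  std::vector<std::pair<int, int> > edges; // (parent, child), 1-based
  int maxNode;
};

static double fitch_score_impl(const std::vector<std::pair<int, int> > &edges,
                               int nTip, const int *tipmask, int npat,
                               const double *w, int maxNode) {
  // children lists
  std::vector<std::vector<int> > ch(maxNode + 1);
  std::vector<int> isChild(maxNode + 1, 0);
  for (size_t e = 0; e < edges.size(); ++e) {
    ch[edges[e].first].push_back(edges[e].second);
    isChild[edges[e].second] = 1;
  }
  int root = -1;
  for (size_t e = 0; e < edges.size(); ++e)
    if (!isChild[edges[e].first]) { root = edges[e].first; break; }
  // iterative postorder
  std::vector<int> order, stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < ch[v].size(); ++i)
      if (!ch[ch[v][i]].empty() || ch[v][i] > nTip) stack.push_back(ch[v][i]);
  }
  std::reverse(order.begin(), order.end());
  std::vector<int> mask((size_t)(maxNode + 1) * npat, 0);
  double score = 0.0;
  for (size_t k = 0; k < order.size(); ++k) {
    int v = order[k];
    if (v <= nTip) continue;
    for (int p = 0; p < npat; ++p) {
      int acc = -1;
      double add = 0.0;
      for (size_t i = 0; i < ch[v].size(); ++i) {
        int u = ch[v][i];
        int mu = (u <= nTip) ? tipmask[(size_t)p * nTip + (u - 1)]
                             : mask[(size_t)u * npat + p];
        if (acc < 0) acc = mu;
        else {
          int a = acc & mu;
          if (a) acc = a;
          else { acc |= mu; add += 1.0; }
        }
      }
      mask[(size_t)v * npat + p] = acc;
      score += add * w[p];
    }
  }
  return score;
}

// [[Rcpp::export]]
double cpp_fitch_score(IntegerMatrix edge, int nTip, IntegerMatrix tipmask,
                       NumericVector w) {
  std::vector<std::pair<int, int> > edges;
  int maxNode = nTip;
  for (int e = 0; e < edge.nrow(); ++e) {
    edges.push_back(std::make_pair(edge(e, 0), edge(e, 1)));
    if (edge(e, 0) > maxNode) maxNode = edge(e, 0);
    if (edge(e, 1) > maxNode) maxNode = edge(e, 1);
  }
  return fitch_score_impl(edges, nTip, INTEGER(tipmask), tipmask.ncol(),
                          REAL(w), maxNode);
}

// Randomized stepwise addition under the Fitch criterion. `order` is the
// (already shuffled) 1-based taxon order; ties broken by first minimum, so
// the result is fully determined by `order`.
// [[Rcpp::export]]
List cpp_parsimony_addition(int nTip, IntegerMatrix tipmask, NumericVector w,
                            IntegerVector order) {
  int npat = tipmask.ncol();
  const int *tm = INTEGER(tipmask);
  const double *wp = REAL(w);
  std::vector<std::pair<int, int> > edges;
  int root = nTip + 1;
  int nextNode = nTip + 2;
  edges.push_back(std::make_pair(root, order[0]));
  edges.push_back(std::make_pair(root, nextNode));
  edges.push_back(std::make_pair(nextNode, order[1]));
  edges.push_back(std::make_pair(nextNode, order[2]));
  ++nextNode;
  double score = 0.0;
  for (int k = 3; k < nTip; ++k) {
    int tip = order[k];
    int bestEdge = -1;
    double bestScore = R_PosInf;
    int m = nextNode;
    for (size_t e = 0; e < edges.size(); ++e) {
      std::vector<std::pair<int, int> > trial(edges);
      int p = trial[e].first, c = trial[e].second;
      trial[e] = std::make_pair(p, m);
      trial.push_back(std::make_pair(m, c));
      trial.push_back(std::make_pair(m, tip));
      double s = fitch_score_impl(trial, nTip, tm, npat, wp,
                                  std::max(m, nTip + nTip));
      if (s < bestScore) {
        bestScore = s;
        bestEdge = (int)e;
      }
    }
    int p = edges[bestEdge].first, c = edges[bestEdge].second;
    edges[bestEdge] = std::make_pair(p, m);
    edges.push_back(std::make_pair(m, c));
    edges.push_back(std::make_pair(m, tip));
    ++nextNode;
    score = bestScore;
  }
  IntegerMatrix out(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    out(e, 0) = edges[e].first;
    out(e, 1) = edges[e].second;
  }
  if (nTip == 3) {
    int maxN = nTip + 2;
    score = fitch_score_impl(edges, nTip, tm, npat, wp, maxN);
  }
  return List::create(_["edge"] = out, _["score"] = score);
}
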