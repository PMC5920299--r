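#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning under JC69 on pattern-compressed data, plus Fitch
// parsimony.  Trees arrive as postorder edge lists (1-based ape node ids:
// tips 1..ntip, basal trichotomy root ntip+1).  Tip states are 4-bit sets
// (A=1, C=2, G=4, T=8; ambiguity = union, missing = 15).

// JC69 transition probabilities and t-derivatives.
struct JCP {
  double ps, pd;     // P(same), P(diff)
  double dps, dpd;   // d/dt
  double d2ps, d2pd; // d2/dt2
};

static inline JCP jc_probs(double t) {
  JCP p;
  double e = std::exp(-4.0 * t / 3.0);
  p.ps = 0.25 + 0.75 * e;
  p.pd = 0.25 - 0.25 * e;
  p.dps = -e;
  p.dpd = e / 3.0;
  p.d2ps = (4.0 / 3.0) * e;
  p.d2pd = -(4.0 / 9.0) * e;
  return p;
}

// y[a] = sum_b P_t(a,b) x[b] = pd * sum(x) + (ps - pd) * x[a]
static inline void matvec(double ps, double pd, const double* x, double* y) {
  double s = x[0] + x[1] + x[2] + x[3];
  double d = ps - pd;
  y[0] = pd * s + d * x[0];
  y[1] = pd * s + d * x[1];
  y[2] = pd * s + d * x[2];
  y[3] = pd * s + d * x[3];
}

static inline void set_from_bits(int bits, double* v) {
  v[0] = (bits & 1) ? 1.0 : 0.0;
  v[1] = (bits & 2) ? 1.0 : 0.0;
  v[2] = (bits & 4) ? 1.0 : 0.0;
  v[3] = (bits & 8) ? 1.0 : 0.0;
}

// Rescale partials only when they leave this band; scale factors are kept
// in log space per pattern.
static const double SCALE_LO = 1e-100;

static inline void rescale_block(double* vals, double* sc, int P) {
  for (int s = 0; s < P; s++) {
    double* v = vals + 4 * s;
    double m = std::max(std::max(v[0], v[1]), std::max(v[2], v[3]));
    if (m <= 0.0) stop("zero partial likelihood");
    if (m < SCALE_LO) {
      for (int a = 0; a < 4; a++) v[a] /= m;
      sc[s] += std::log(m);
    }
  }
}

// Postorder pass computing, for every edge, the conditional likelihoods of
// the clade below its child node (no transition across the edge itself),
// with per-pattern log scale factors.
static void down_pass(const IntegerMatrix& edge, const NumericVector& elen,
                      int ntip, const IntegerMatrix& tipstate,
                      std::vector<double>& D, std::vector<double>& Dsc) {
  int E = edge.nrow(), P = tipstate.ncol();
  int maxnode = 0;
  for (int i = 0; i < E; i++) {
    maxnode = std::max(maxnode, edge(i, 0));
    maxnode = std::max(maxnode, edge(i, 1));
  }
  // children edges of each node
  std::vector<std::vector<int> > kids(maxnode + 1);
  for (int i = 0; i < E; i++) kids[edge(i, 0)].push_back(i);

  D.assign((size_t)E * P * 4, 0.0);
  Dsc.assign((size_t)E * P, 0.0);
  double tmp[4];
  for (int i = 0; i < E; i++) {
    int v = edge(i, 1);
    double* Di = &D[(size_t)i * P * 4];
    double* Si = &Dsc[(size_t)i * P];
    if (v <= ntip) {
      for (int s = 0; s < P; s++) set_from_bits(tipstate(v - 1, s), Di + 4 * s);
      continue;
    }
    const std::vector<int>& ch = kids[v];
    for (int s = 0; s < 4 * P; s++) Di[s] = 1.0;
    for (size_t k = 0; k < ch.size(); k++) {
      int f = ch[k];
      JCP p = jc_probs(elen[f]);
      const double* Df = &D[(size_t)f * P * 4];
      const double* Sf = &Dsc[(size_t)f * P];
      for (int s = 0; s < P; s++) {
        matvec(p.ps, p.pd, Df + 4 * s, tmp);
        double* d = Di + 4 * s;
        for (int a = 0; a < 4; a++) d[a] *= tmp[a];
        Si[s] += Sf[s];
      }
    }
    rescale_block(Di, Si, P);
  }
}

// [[Rcpp::export]]
double cpp_loglik(IntegerMatrix edge, NumericVector elen, int ntip,
                  IntegerMatrix tipstate, NumericVector weights) {
  int E = edge.nrow(), P = tipstate.ncol();
  std::vector<double> D, Dsc;
  down_pass(edge, elen, ntip, tipstate, D, Dsc);
  int root = ntip + 1;
  std::vector<int> re;
  for (int i = 0; i < E; i++) if (edge(i, 0) == root) re.push_back(i);
  std::vector<double> acc((size_t)4 * P, 1.0), sc(P, 0.0);
  double tmp[4];
  for (size_t k = 0; k < re.size(); k++) {
    int f = re[k];
    JCP p = jc_probs(elen[f]);
    const double* Df = &D[(size_t)f * P * 4];
    const double* Sf = &Dsc[(size_t)f * P];
    for (int s = 0; s < P; s++) {
      matvec(p.ps, p.pd, Df + 4 * s, tmp);
      for (int a = 0; a < 4; a++) acc[4 * s + a] *= tmp[a];
      sc[s] += Sf[s];
    }
  }
  double ll = 0.0;
  for (int s = 0; s < P; s++) {
    double lik = 0.25 * (acc[4 * s] + acc[4 * s + 1] + acc[4 * s + 2] + acc[4 * s + 3]);
    ll += weights[s] * (std::log(lik) + sc[s]);
  }
  return ll;
}

// Per-edge inside (D) and outside (U) arrays.  U for edge e=(p,v) holds the
// likelihood of all data outside the clade below v, as a function of the
// state at p, with the 1/4 root frequency folded in.  The per-pattern site
// likelihood of the tree is sum_{j,i} U_e(j) P_{|e|}(j,i) D_e(i) times
// exp(Dscale + Uscale).
// [[Rcpp::export]]
List cpp_edge_arrays(IntegerMatrix edge, NumericVector elen, int ntip,
                     IntegerMatrix tipstate) {
  int E = edge.nrow(), P = tipstate.ncol();
  std::vector<double> D, Dsc;
  down_pass(edge, elen, ntip, tipstate, D, Dsc);
  int root = ntip + 1;
  int maxnode = 0;
  for (int i = 0; i < E; i++) maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int> > kids(maxnode + 1);
  std::vector<int> upedge(maxnode + 1, -1);
  for (int i = 0; i < E; i++) {
    kids[edge(i, 0)].push_back(i);
    upedge[edge(i, 1)] = i;
  }
  std::vector<double> U((size_t)E * P * 4), Usc((size_t)E * P, 0.0);
  double tmp[4];
  // reverse postorder: an edge's parent edge is processed before it
  for (int i = E - 1; i >= 0; i--) {
    int p = edge(i, 0);
    double* Ui = &U[(size_t)i * P * 4];
    double* Si = &Usc[(size_t)i * P];
    if (p == root) {
      for (int s = 0; s < 4 * P; s++) Ui[s] = 0.25;
      for (int s = 0; s < P; s++) Si[s] = 0.0;
    } else {
      int g = upedge[p];
      JCP pg = jc_probs(elen[g]);
      const double* Ug = &U[(size_t)g * P * 4];
      const double* Sg = &Usc[(size_t)g * P];
      for (int s = 0; s < P; s++) {
        // sum_{j'} U_g(j') P(j' -> j); JC69 is symmetric so reuse matvec
        matvec(pg.ps, pg.pd, Ug + 4 * s, Ui + 4 * s);
        Si[s] = Sg[s];
      }
    }
    const std::vector<int>& sib = kids[p];
    for (size_t k = 0; k < sib.size(); k++) {
      int f = sib[k];
      if (f == i) continue;
      JCP pf = jc_probs(elen[f]);
      const double* Df = &D[(size_t)f * P * 4];
      const double* Sf = &Dsc[(size_t)f * P];
      for (int s = 0; s < P; s++) {
        matvec(pf.ps, pf.pd, Df + 4 * s, tmp);
        double* u = Ui + 4 * s;
        for (int a = 0; a < 4; a++) u[a] *= tmp[a];
        Si[s] += Sf[s];
      }
    }
    rescale_block(Ui, Si, P);
  }
  NumericVector Dv(D.begin(), D.end()), Uv(U.begin(), U.end());
  NumericVector Dscv(Dsc.begin(), Dsc.end()), Uscv(Usc.begin(), Usc.end());
  Dv.attr("dim") = IntegerVector::create(4, P, E);
  Uv.attr("dim") = IntegerVector::create(4, P, E);
  Dscv.attr("dim") = IntegerVector::create(P, E);
  Uscv.attr("dim") = IntegerVector::create(P, E);
  return List::create(_["D"] = Dv, _["Dscale"] = Dscv,
                      _["U"] = Uv, _["Uscale"] = Uscv);
}

// Log-likelihood of the tree with a new taxon attached to one edge, plus
// analytic first/second derivatives in the distal length x and the pendant
// length y.  Dm/Um etc. are the slices of cpp_edge_arrays for that edge.
// Returns (ll, dll/dx, d2ll/dx2, dll/dy, d2ll/dy2).
// [[Rcpp::export]]
NumericVector cpp_attach_loglik(NumericVector Dm, NumericVector Dscale,
                                NumericVector Um, NumericVector Uscale,
                                NumericVector weights, IntegerVector newstate,
                                double elen, double x, double y,
                                bool derivs) {
  int P = weights.size();
  double prox = elen - x;
  if (prox < 0) prox = 0;
  JCP px = jc_probs(x), pp = jc_probs(prox), py = jc_probs(y);
  double ll = 0, dx = 0, d2x = 0, dy = 0, d2y = 0;
  double A[4], A1[4], A2[4], B[4], B1[4], B2[4], C[4], C1[4], C2[4], T[4];
  for (int s = 0; s < P; s++) {
    const double* Ds = &Dm[4 * s];
    const double* Us = &Um[4 * s];
    set_from_bits(newstate[s], T);
    matvec(px.ps, px.pd, Ds, A);
    matvec(pp.ps, pp.pd, Us, B);   // JC69 symmetric: row/col sums agree
    matvec(py.ps, py.pd, T, C);
    double L = 0;
    for (int a = 0; a < 4; a++) L += A[a] * B[a] * C[a];
    if (L <= 0) return NumericVector::create(R_NegInf, NA_REAL, NA_REAL, NA_REAL, NA_REAL);
    ll += weights[s] * (std::log(L) + Dscale[s] + Uscale[s]);
    if (derivs) {
      matvec(px.dps, px.dpd, Ds, A1);
      matvec(px.d2ps, px.d2pd, Ds, A2);
      matvec(pp.dps, pp.dpd, Us, B1);
      matvec(pp.d2ps, pp.d2pd, Us, B2);
      for (int a = 0; a < 4; a++) { B1[a] = -B1[a]; }  // d prox / dx = -1
      matvec(py.dps, py.dpd, T, C1);
      matvec(py.d2ps, py.d2pd, T, C2);
      double Lx = 0, Lxx = 0, Ly = 0, Lyy = 0;
      for (int a = 0; a < 4; a++) {
        Lx  += (A1[a] * B[a] + A[a] * B1[a]) * C[a];
        Lxx += (A2[a] * B[a] + 2.0 * A1[a] * B1[a] + A[a] * B2[a]) * C[a];
        Ly  += A[a] * B[a] * C1[a];
        Lyy += A[a] * B[a] * C2[a];
      }
      double rx = Lx / L, ry = Ly / L;
      dx += weights[s] * rx;
      d2x += weights[s] * (Lxx / L - rx * rx);
      dy += weights[s] * ry;
      d2y += weights[s] * (Lyy / L - ry * ry);
    }
  }
  return NumericVector::create(ll, dx, d2x, dy, d2y);
}

// ---------------------------------------------------------------------------
// Fitch parsimony (first pass) on 4-bit state sets.
// ---------------------------------------------------------------------------

struct FitchArrays {
  std::vector<int> bset;     // E x P below state sets
  std::vector<double> bcost; // E x P below change counts
};

static void fitch_down(const IntegerMatrix& edge, int ntip,
                       const IntegerMatrix& tipstate, FitchArrays& F) {
  int E = edge.nrow(), P = tipstate.ncol();
  int maxnode = 0;
  for (int i = 0; i < E; i++) maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int> > kids(maxnode + 1);
  for (int i = 0; i < E; i++) kids[edge(i, 0)].push_back(i);
  F.bset.assign((size_t)E * P, 0);
  F.bcost.assign((size_t)E * P, 0.0);
  for (int i = 0; i < E; i++) {
    int v = edge(i, 1);
    if (v <= ntip) {
      for (int s = 0; s < P; s++) F.bset[(size_t)i * P + s] = tipstate(v - 1, s);
      continue;
    }
    const std::vector<int>& ch = kids[v];
    for (int s = 0; s < P; s++) {
      int set = 15; double cost = 0.0; bool first = true;
      for (size_t k = 0; k < ch.size(); k++) {
        int f = ch[k];
        int sf = F.bset[(size_t)f * P + s];
        cost += F.bcost[(size_t)f * P + s];
        if (first) { set = sf; first = false; }
        else {
          int inter = set & sf;
          if (inter) set = inter; else { set |= sf; cost += 1.0; }
        }
      }
      F.bset[(size_t)i * P + s] = set;
      F.bcost[(size_t)i * P + s] = cost;
    }
  }
}

// [[Rcpp::export]]
double cpp_fitch(IntegerMatrix edge, int ntip, IntegerMatrix tipstate,
                 NumericVector weights) {
  int E = edge.nrow(), P = tipstate.ncol();
  FitchArrays F;
  fitch_down(edge, ntip, tipstate, F);
  int root = ntip + 1;
  std::vector<int> re;
  for (int i = 0; i < E; i++) if (edge(i, 0) == root) re.push_back(i);
  double total = 0.0;
  for (int s = 0; s < P; s++) {
    int set = 15; double cost = 0.0; bool first = true;
    for (size_t k = 0; k < re.size(); k++) {
      int f = re[k];
      int sf = F.bset[(size_t)f * P + s];
      cost += F.bcost[(size_t)f * P + s];
      if (first) { set = sf; first = false; }
      else {
        int inter = set & sf;
        if (inter) set = inter; else { set |= sf; cost += 1.0; }
      }
    }
    total += weights[s] * cost;
  }
  return total;
}

// Parsimony scores of attaching a new leaf to each edge: the score of the
// augmented tree, exact (equals re-running Fitch on the attached tree),
// computed with shared below/outside state-set caches.
// [[Rcpp::export]]
NumericVector cpp_fitch_attach(IntegerMatrix edge, int ntip,
                               IntegerMatrix tipstate, NumericVector weights,
                               IntegerVector newstate) {
  int E = edge.nrow(), P = tipstate.ncol();
  FitchArrays F;
  fitch_down(edge, ntip, tipstate, F);
  int root = ntip + 1;
  int maxnode = 0;
  for (int i = 0; i < E; i++) maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int> > kids(maxnode + 1);
  std::vector<int> upedge(maxnode + 1, -1);
  for (int i = 0; i < E; i++) {
    kids[edge(i, 0)].push_back(i);
    upedge[edge(i, 1)] = i;
  }
  // outside sets/costs per edge (Fitch state of the rooted tree formed by
  // everything outside the edge's clade, rooted at the edge's parent node)
  std::vector<int> oset((size_t)E * P);
  std::vector<double> ocost((size_t)E * P, 0.0);
  for (int i = E - 1; i >= 0; i--) {
    int p = edge(i, 0);
    for (int s = 0; s < P; s++) {
      int set = 15; double cost = 0.0; bool first = true;
      if (p != root) {
        int g = upedge[p];
        set = oset[(size_t)g * P + s];
        cost = ocost[(size_t)g * P + s];
        first = false;
      }
      const std::vector<int>& sib = kids[p];
      for (size_t k = 0; k < sib.size(); k++) {
        int f = sib[k];
        if (f == i) continue;
        int sf = F.bset[(size_t)f * P + s];
        cost += F.bcost[(size_t)f * P + s];
        if (first) { set = sf; first = false; }
        else {
          int inter = set & sf;
          if (inter) set = inter; else { set |= sf; cost += 1.0; }
        }
      }
      oset[(size_t)i * P + s] = set;
      ocost[(size_t)i * P + s] = cost;
    }
  }
  NumericVector out(E);
  for (int i = 0; i < E; i++) {
    double total = 0.0;
    for (int s = 0; s < P; s++) {
      int sb = F.bset[(size_t)i * P + s];
      int so = oset[(size_t)i * P + s];
      double cost = F.bcost[(size_t)i * P + s] + ocost[(size_t)i * P + s];
      int s1 = sb & so;
      if (!s1) { s1 = sb | so; cost += 1.0; }
      int s2 = s1 & newstate[s];
      if (!s2) cost += 1.0;
      total += weights[s] * cost;
    }
    out[i] = total;
  }
  return out;
}
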