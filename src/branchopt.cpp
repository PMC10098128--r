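#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

// One full in-place branch-length optimisation sweep for the GTR+I+G model.
//
// For each edge, the tree likelihood factorises as
//   L(site) = sum_i A_i [P(t) d]_i
// where A is the partial likelihood of everything outside the child's
// subtree (stationary frequencies included) and d the partial below the
// child. A preorder traversal keeps A and the below-partials D current while
// each branch is optimised by golden-section search, so each 1-D evaluation
// costs O(npat * ncat) instead of a full pruning pass.

namespace {

struct Ctx {
  int ntips, npat, ncat, nnode, root;
  const int *codes;            // ntips x npat, column-major
  const double *w;             // pattern weights
  std::vector<double> evec, ievc, eval, pi, rates;
  double pinv;
  std::vector<std::vector<std::pair<int, int>>> children;  // node -> (child, edge)
  std::vector<double> elen;
  // per category c, node v: partials [((c*nnode+v)*npat+s)*4+i], log scalers
  std::vector<double> D, SD, A, SA;
  std::vector<double> Linv;    // invariant-site likelihood per pattern

  double *Dp(int c, int v) { return &D[(((size_t)c * nnode + v) * npat) * 4]; }
  double *SDp(int c, int v) { return &SD[((size_t)c * nnode + v) * npat]; }
  double *Ap(int c, int v) { return &A[(((size_t)c * nnode + v) * npat) * 4]; }
  double *SAp(int c, int v) { return &SA[((size_t)c * nnode + v) * npat]; }

  void computeP(double t, double r, double *P) const {
    double ex[4];
    for (int k = 0; k < 4; ++k) ex[k] = std::exp(eval[k] * r * t);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        double s = 0.0;
        for (int k = 0; k < 4; ++k)
          s += evec[i + 4 * k] * ex[k] * ievc[k + 4 * j];
        P[4 * i + j] = s > 0.0 ? s : 0.0;
      }
  }

  // child partial at pattern s (tip indicator or D), no copy for internals
  inline void tipPartial(int tip, int s, double *out) const {
    int mask = codes[tip + (size_t)ntips * s];
    out[0] = (mask & 1) ? 1.0 : 0.0;
    out[1] = (mask & 2) ? 1.0 : 0.0;
    out[2] = (mask & 4) ? 1.0 : 0.0;
    out[3] = (mask & 8) ? 1.0 : 0.0;
  }

  // multiply dst (4 per pattern) by P * (child partial); add child scaler
  void foldChild(int c, int ch, double t, double *dst, double *dscal) {
    double P[16];
    computeP(t, rates[c], P);
    bool tip = ch < ntips;
    const double *cp = tip ? nullptr : Dp(c, ch);
    const double *cs = tip ? nullptr : SDp(c, ch);
    for (int s = 0; s < npat; ++s) {
      double x[4];
      if (tip) tipPartial(ch, s, x);
      else { const double *q = cp + (size_t)s * 4; x[0]=q[0]; x[1]=q[1]; x[2]=q[2]; x[3]=q[3]; }
      double *d = dst + (size_t)s * 4;
      double mx = 0.0;
      for (int i = 0; i < 4; ++i) {
        double acc = P[4*i]*x[0] + P[4*i+1]*x[1] + P[4*i+2]*x[2] + P[4*i+3]*x[3];
        d[i] *= acc;
        if (d[i] > mx) mx = d[i];
      }
      if (!tip) dscal[s] += cs[s];
      if (mx > 0.0 && mx < 1e-140) {
        for (int i = 0; i < 4; ++i) d[i] *= 1e140;
        dscal[s] -= 322.3619130191664;
      }
    }
  }

  // push the outside-partial at a node down through its subtending edge:
  // re-index A[ch] from the parent's state to the child's state,
  // a'_j = sum_i a_i P_ij(t)
  void transportA(int ch, double t) {
    for (int c = 0; c < ncat; ++c) {
      double P[16];
      computeP(t, rates[c], P);
      double *a = Ap(c, ch);
      double *as = SAp(c, ch);
      for (int s = 0; s < npat; ++s) {
        double *x = a + (size_t)s * 4;
        double out[4];
        double mx = 0.0;
        for (int j = 0; j < 4; ++j) {
          out[j] = x[0]*P[j] + x[1]*P[4+j] + x[2]*P[8+j] + x[3]*P[12+j];
          if (out[j] > mx) mx = out[j];
        }
        if (mx > 0.0 && mx < 1e-140) {
          for (int j = 0; j < 4; ++j) out[j] *= 1e140;
          as[s] -= 322.3619130191664;
        }
        for (int j = 0; j < 4; ++j) x[j] = out[j];
      }
    }
  }

  void computeD(int v) {
    for (int c = 0; c < ncat; ++c) {
      double *d = Dp(c, v);
      double *ds = SDp(c, v);
      std::fill(d, d + (size_t)npat * 4, 1.0);
      std::fill(ds, ds + npat, 0.0);
      for (auto &ce : children[v]) foldChild(c, ce.first, elen[ce.second], d, ds);
    }
  }

  // edge log-likelihood as a function of t, for edge to child ch with A[ch]
  double edgeLnL(int ch, double t) {
    double lnL = 0.0;
    std::vector<double> terms((size_t)ncat * npat);
    for (int c = 0; c < ncat; ++c) {
      double P[16];
      computeP(t, rates[c], P);
      const double *ac = Ap(c, ch);
      const double *sa = SAp(c, ch);
      const double *dc = (ch < ntips) ? nullptr : Dp(c, ch);
      const double *sd = (ch < ntips) ? nullptr : SDp(c, ch);
      for (int s = 0; s < npat; ++s) {
        const double *a = ac + (size_t)s * 4;
        double x[4];
        if (ch < ntips) tipPartial(ch, s, x);
        else { const double *q = dc + (size_t)s * 4; x[0]=q[0]; x[1]=q[1]; x[2]=q[2]; x[3]=q[3]; }
        double dot = 0.0;
        for (int i = 0; i < 4; ++i)
          dot += a[i] * (P[4*i]*x[0] + P[4*i+1]*x[1] + P[4*i+2]*x[2] + P[4*i+3]*x[3]);
        double sc = sa[s] + (ch < ntips ? 0.0 : sd[s]);
        terms[(size_t)c * npat + s] =
            (dot > 0 ? std::log(dot) : -INFINITY) + sc;
      }
    }
    for (int s = 0; s < npat; ++s) {
      double m = -INFINITY;
      for (int c = 0; c < ncat; ++c) {
        double tc = terms[(size_t)c * npat + s];
        if (tc > m) m = tc;
      }
      double sum = 0.0;
      for (int c = 0; c < ncat; ++c)
        sum += std::exp(terms[(size_t)c * npat + s] - m);
      double logvar = m + std::log(sum / ncat);
      double logsite;
      double invpart = pinv * Linv[s];
      if (invpart <= 0.0) logsite = std::log(1.0 - pinv) + logvar;
      else {
        double a1 = std::log(invpart);
        double b1 = std::log(1.0 - pinv) + logvar;
        double mm = a1 > b1 ? a1 : b1;
        logsite = mm + std::log(std::exp(a1 - mm) + std::exp(b1 - mm));
      }
      lnL += w[s] * logsite;
    }
    return lnL;
  }
};

// golden-section maximisation of f over [lo, hi] on the log scale
template <typename F>
double golden(F f, double lo, double hi, int iters, double &fbest) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = f(std::exp(c)), fd = f(std::exp(d));
  for (int i = 0; i < iters; ++i) {
    if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = f(std::exp(c)); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = f(std::exp(d)); }
  }
  double xm = (fc > fd) ? std::exp(c) : std::exp(d);
  fbest = (fc > fd) ? fc : fd;
  return xm;
}

// shared-topology sweep over one or more partitions: each partition has its
// own substitution model and rate multiplier; the optimised quantity per
// edge is the summed log-likelihood at shared length t (partition p sees
// t * mult[p])
void processNode(std::vector<Ctx> &ctxs, const std::vector<double> &mult,
                 std::vector<double> &elen, int v, double lower, double upper,
                 int iters) {
  int nch = ctxs[0].children[v].size();
  size_t np = ctxs.size();
  for (int idx = 0; idx < nch; ++idx) {
    int ch = ctxs[0].children[v][idx].first;
    int e = ctxs[0].children[v][idx].second;
    for (size_t p = 0; p < np; ++p) {
      Ctx &ctx = ctxs[p];
      for (int c = 0; c < ctx.ncat; ++c) {
        double *a = ctx.Ap(c, ch);
        double *as = ctx.SAp(c, ch);
        std::copy(ctx.Ap(c, v), ctx.Ap(c, v) + (size_t)ctx.npat * 4, a);
        std::copy(ctx.SAp(c, v), ctx.SAp(c, v) + ctx.npat, as);
        for (int j = 0; j < nch; ++j) {
          if (j == idx) continue;
          ctx.foldChild(c, ctx.children[v][j].first,
                        elen[ctx.children[v][j].second] * mult[p], a, as);
        }
      }
    }
    auto obj = [&](double t) {
      double s = 0.0;
      for (size_t p = 0; p < np; ++p)
        s += ctxs[p].edgeLnL(ch, t * mult[p]);
      return s;
    };
    double fbest;
    double tstar = golden(obj, lower, upper, iters, fbest);
    if (fbest > obj(elen[e])) elen[e] = tstar;
    if (ch >= ctxs[0].ntips) {
      for (size_t p = 0; p < np; ++p)
        ctxs[p].transportA(ch, elen[e] * mult[p]);
      processNode(ctxs, mult, elen, ch, lower, upper, iters);
      for (size_t p = 0; p < np; ++p) {
        ctxs[p].elen.clear();
        for (size_t q = 0; q < elen.size(); ++q)
          ctxs[p].elen.push_back(elen[q] * mult[p]);
        ctxs[p].computeD(ch);  // refresh with the subtree's new lengths
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".optimize_branches")]]
List optimize_branches(List codes_list, IntegerMatrix edge,
                       NumericVector elen0, int nnode_total,
                       List evec_list, List ievc_list, List eval_list,
                       List pi_list, List rates_list, NumericVector pinv,
                       List weights_list, NumericVector mult,
                       double lower, double upper, int nsweeps,
                       int golden_iters) {
  int np = codes_list.size();
  int nedge = edge.nrow();
  std::vector<double> elen(elen0.begin(), elen0.end());
  std::vector<double> mv(mult.begin(), mult.end());
  std::vector<Ctx> ctxs(np);
  std::vector<IntegerMatrix> keep_codes(np);
  std::vector<NumericVector> keep_w(np);
  for (int p = 0; p < np; ++p) {
    Ctx &ctx = ctxs[p];
    keep_codes[p] = as<IntegerMatrix>(codes_list[p]);
    keep_w[p] = as<NumericVector>(weights_list[p]);
    ctx.ntips = keep_codes[p].nrow();
    ctx.npat = keep_codes[p].ncol();
    ctx.nnode = nnode_total;
    ctx.codes = INTEGER(keep_codes[p]);
    ctx.w = REAL(keep_w[p]);
    NumericMatrix evec = evec_list[p], ievc = ievc_list[p];
    NumericVector eval = eval_list[p], pi = pi_list[p], rates = rates_list[p];
    ctx.ncat = rates.size();
    ctx.evec.assign(evec.begin(), evec.end());
    ctx.ievc.assign(ievc.begin(), ievc.end());
    ctx.eval.assign(eval.begin(), eval.end());
    ctx.pi.assign(pi.begin(), pi.end());
    ctx.rates.assign(rates.begin(), rates.end());
    ctx.pinv = pinv[p];
    ctx.children.assign(nnode_total, {});
    for (int e = 0; e < nedge; ++e)
      ctx.children[edge(e, 0) - 1].push_back({edge(e, 1) - 1, e});
    ctx.root = edge(nedge - 1, 0) - 1;
    ctx.elen.clear();
    for (int e = 0; e < nedge; ++e) ctx.elen.push_back(elen[e] * mv[p]);
    size_t sz = (size_t)ctx.ncat * nnode_total * ctx.npat;
    ctx.D.assign(sz * 4, 1.0);
    ctx.SD.assign(sz, 0.0);
    ctx.A.assign(sz * 4, 1.0);
    ctx.SA.assign(sz, 0.0);
    ctx.Linv.assign(ctx.npat, 0.0);
    for (int s = 0; s < ctx.npat; ++s) {
      int andmask = 15;
      for (int i = 0; i < ctx.ntips; ++i)
        andmask &= ctx.codes[i + (size_t)ctx.ntips * s];
      double L = 0.0;
      if (andmask & 1) L += ctx.pi[0];
      if (andmask & 2) L += ctx.pi[1];
      if (andmask & 4) L += ctx.pi[2];
      if (andmask & 8) L += ctx.pi[3];
      ctx.Linv[s] = L;
    }
    std::function<void(int)> computeDAll = [&ctx, &computeDAll](int v) {
      for (auto &ce : ctx.children[v])
        if (ce.first >= ctx.ntips) computeDAll(ce.first);
      ctx.computeD(v);
    };
    computeDAll(ctx.root);
  }

  int root = ctxs[0].root;
  for (int sw = 0; sw < nsweeps; ++sw) {
    for (int p = 0; p < np; ++p) {
      Ctx &ctx = ctxs[p];
      for (int c = 0; c < ctx.ncat; ++c) {
        double *a = ctx.Ap(c, root);
        for (int s = 0; s < ctx.npat; ++s)
          for (int i = 0; i < 4; ++i) a[(size_t)s * 4 + i] = ctx.pi[i];
        std::fill(ctx.SAp(c, root), ctx.SAp(c, root) + ctx.npat, 0.0);
      }
    }
    processNode(ctxs, mv, elen, root, lower, upper, golden_iters);
    if (sw + 1 < nsweeps)
      for (int p = 0; p < np; ++p) {
        ctxs[p].elen.clear();
        for (int e = 0; e < nedge; ++e)
          ctxs[p].elen.push_back(elen[e] * mv[p]);
        ctxs[p].computeD(root);
      }
  }

  return List::create(Named("elen") = NumericVector(elen.begin(),
                                                    elen.end()));
}
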