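#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns for a GTR+I+G model.
//
// tip_codes : ntips x npat integer bitmasks over (A=1, C=2, G=4, T=8);
//             15 = gap/unknown. Row i corresponds to node id i+1 (ape).
// edge      : nedge x 2 (parent, child), ape 1-based ids, postorder
//             (every child row appears before any row using it as parent).
// elen      : per-edge branch lengths (same row order as edge).
// evec/ievc/eval : eigen system of Q, P(t) = evec diag(exp(eval t)) ievc.
// pi        : stationary frequencies.
// rates     : gamma category rates (mean 1).
// pinv      : proportion of invariant sites.
// nnode_total : total node count (tips + internals).
//
// Returns per-pattern log site likelihoods (length npat).
// [[Rcpp::export(name = ".pruning_loglik")]]
NumericVector pruning_loglik(IntegerMatrix tip_codes, IntegerMatrix edge,
                             NumericVector elen, int nnode_total,
                             NumericMatrix evec, NumericMatrix ievc,
                             NumericVector eval, NumericVector pi,
                             NumericVector rates, double pinv) {
  const int ntips = tip_codes.nrow();
  const int npat = tip_codes.ncol();
  const int nedge = edge.nrow();
  const int ncat = rates.size();
  const int root = edge(nedge - 1, 0) - 1;  // parent of last postorder edge

  // mixture accumulator of the variable-rate part, per pattern (linear scale
  // with per-pattern log scalers handled per category)
  std::vector<double> mixL(npat, 0.0);
  std::vector<double> partial((size_t)nnode_total * npat * 4);
  std::vector<double> scal((size_t)nnode_total * npat);
  std::vector<char> seen(nnode_total);

  for (int c = 0; c < ncat; ++c) {
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      int par = edge(e, 0) - 1;
      int ch = edge(e, 1) - 1;
      double t = elen[e] * rates[c];
      // P = evec diag(exp(eval t)) ievc
      double P[4][4];
      double ex[4];
      for (int k = 0; k < 4; ++k) ex[k] = std::exp(eval[k] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += evec(i, k) * ex[k] * ievc(k, j);
          P[i][j] = s > 0.0 ? s : 0.0;
        }
      double *pp = &partial[(size_t)par * npat * 4];
      double *ps = &scal[(size_t)par * npat];
      if (!seen[par]) {
        std::fill(pp, pp + (size_t)npat * 4, 1.0);
        std::fill(ps, ps + npat, 0.0);
        seen[par] = 1;
      }
      if (ch < ntips) {
        for (int s = 0; s < npat; ++s) {
          int mask = tip_codes(ch, s);
          double v[4];
          for (int i = 0; i < 4; ++i) {
            double acc = 0.0;
            if (mask & 1) acc += P[i][0];
            if (mask & 2) acc += P[i][1];
            if (mask & 4) acc += P[i][2];
            if (mask & 8) acc += P[i][3];
            v[i] = acc;
          }
          double *dst = pp + (size_t)s * 4;
          for (int i = 0; i < 4; ++i) dst[i] *= v[i];
        }
      } else {
        double *cp = &partial[(size_t)ch * npat * 4];
        double *cs = &scal[(size_t)ch * npat];
        for (int s = 0; s < npat; ++s) {
          double *x = cp + (size_t)s * 4;
          double *dst = pp + (size_t)s * 4;
          double mx = 0.0;
          for (int i = 0; i < 4; ++i) {
            double acc = P[i][0] * x[0] + P[i][1] * x[1] + P[i][2] * x[2] +
                         P[i][3] * x[3];
            dst[i] *= acc;
            if (dst[i] > mx) mx = dst[i];
          }
          ps[s] += cs[s];
          if (mx > 0.0 && mx < 1e-140) {
            for (int i = 0; i < 4; ++i) dst[i] *= 1e140;
            ps[s] -= 322.3619130191664;  // log(1e-140)
          }
        }
      }
    }
    double *rp = &partial[(size_t)root * npat * 4];
    double *rs = &scal[(size_t)root * npat];
    for (int s = 0; s < npat; ++s) {
      double *x = rp + (size_t)s * 4;
      double L = pi[0] * x[0] + pi[1] * x[1] + pi[2] * x[2] + pi[3] * x[3];
      mixL[s] += std::exp(std::log(L) + rs[s]) / ncat;
    }
  }

  // invariant-site component: a pattern can be invariant for state k iff all
  // tips allow k (bitwise AND of masks)
  NumericVector out(npat);
  for (int s = 0; s < npat; ++s) {
    double Linv = 0.0;
    if (pinv > 0.0) {
      int andmask = 15;
      for (int i = 0; i < ntips; ++i) andmask &= tip_codes(i, s);
      if (andmask & 1) Linv += pi[0];
      if (andmask & 2) Linv += pi[1];
      if (andmask & 4) Linv += pi[2];
      if (andmask & 8) Linv += pi[3];
    }
    out[s] = std::log(pinv * Linv + (1.0 - pinv) * mixL[s]);
  }
  return out;
}
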