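#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning under JC69 with per-pattern scaling.
// edge: postorder-ordered (children before parents), 1-based node ids;
// tips are 1..ntip, root is ntip+1. tipp: list of 4 x npat tip partials.

static double jc_loglik_impl(const IntegerMatrix &edge,
                             const std::vector<double> &elen,
                             int ntip, int nnode,
                             const std::vector<const double *> &tipp,
                             const NumericVector &weights, int npat) {
  std::vector<double> part(static_cast<size_t>(nnode) * 4 * npat, 1.0);
  std::vector<double> logsc(static_cast<size_t>(nnode) * npat, 0.0);
  int nedge = edge.nrow();
  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0) - ntip - 1; // internal index
    int child = edge(e, 1);
    double t = elen[e];
    double es = std::exp(-4.0 * t / 3.0);
    double psame = 0.25 + 0.75 * es;
    double pdiff = 0.25 - 0.25 * es;
    double *pp = &part[static_cast<size_t>(parent) * 4 * npat];
    double *psc = &logsc[static_cast<size_t>(parent) * npat];
    if (child <= ntip) {
      const double *cp = tipp[child - 1];
      for (int j = 0; j < npat; ++j) {
        double s = cp[4 * j] + cp[4 * j + 1] + cp[4 * j + 2] + cp[4 * j + 3];
        for (int k = 0; k < 4; ++k) {
          pp[4 * j + k] *= pdiff * s + (psame - pdiff) * cp[4 * j + k];
        }
      }
    } else {
      int ci = child - ntip - 1;
      const double *cp = &part[static_cast<size_t>(ci) * 4 * npat];
      const double *csc = &logsc[static_cast<size_t>(ci) * npat];
      for (int j = 0; j < npat; ++j) {
        double s = cp[4 * j] + cp[4 * j + 1] + cp[4 * j + 2] + cp[4 * j + 3];
        double mx = 0.0;
        for (int k = 0; k < 4; ++k) {
          pp[4 * j + k] *= pdiff * s + (psame - pdiff) * cp[4 * j + k];
          if (pp[4 * j + k] > mx) mx = pp[4 * j + k];
        }
        psc[j] += csc[j];
        if (mx > 0 && mx < 1e-100) { // rescale to dodge underflow
          for (int k = 0; k < 4; ++k) pp[4 * j + k] /= mx;
          psc[j] += std::log(mx);
        }
      }
    }
  }
  const double *rp = &part[0]; // root is internal index 0 (node ntip+1)
  const double *rsc = &logsc[0];
  double ll = 0.0;
  for (int j = 0; j < npat; ++j) {
    double L = 0.25 * (rp[4 * j] + rp[4 * j + 1] + rp[4 * j + 2] + rp[4 * j + 3]);
    if (L <= 0) return R_NegInf;
    ll += weights[j] * (std::log(L) + rsc[j]);
  }
  return ll;
}

static std::vector<const double *> tip_ptrs(const List &tipp) {
  std::vector<const double *> out(tipp.size());
  for (int i = 0; i < tipp.size(); ++i) {
    NumericMatrix m = tipp[i];
    out[i] = REAL(m);
  }
  return out;
}

// [[Rcpp::export]]
double jc_loglik_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                     int nnode, List tipp, NumericVector weights) {
  int npat = weights.size();
  std::vector<double> el(elen.begin(), elen.end());
  return jc_loglik_impl(edge, el, ntip, nnode, tip_ptrs(tipp), weights, npat);
}

// golden-section maximization of the likelihood in log(branch length)
// for one edge, all others fixed; returns the best length found
static void golden_opt_edge(const IntegerMatrix &edge,
                            std::vector<double> &elen, int which, int ntip,
                            int nnode,
                            const std::vector<const double *> &tipp,
                            const NumericVector &weights, int npat,
                            double lo, double hi, double &best_ll) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  auto f = [&](double lx) {
    elen[which] = std::exp(lx);
    return jc_loglik_impl(edge, elen, ntip, nnode, tipp, weights, npat);
  };
  double f1 = f(x1), f2 = f(x2);
  for (int it = 0; it < 50; ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = f(x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = f(x1);
    }
    if (b - a < 1e-10) break;
  }
  double lx = (f1 > f2) ? x1 : x2;
  double fv = (f1 > f2) ? f1 : f2;
  if (fv >= best_ll) { // monotone ascent: keep only improvements
    elen[which] = std::exp(lx);
    best_ll = fv;
  } else {
    // restore: re-evaluate at previous best length is handled by caller
  }
}

// [[Rcpp::export]]
List jc_opt_edges_cpp(IntegerMatrix edge, NumericVector elen0, int ntip,
                      int nnode, List tipp, NumericVector weights,
                      double min_len, double max_len, double tol,
                      int max_sweeps) {
  int npat = weights.size();
  std::vector<const double *> tp = tip_ptrs(tipp);
  std::vector<double> elen(elen0.begin(), elen0.end());
  int nedge = edge.nrow();
  double ll = jc_loglik_impl(edge, elen, ntip, nnode, tp, weights, npat);
  bool converged = false;
  int sweeps = 0;
  for (int s = 0; s < max_sweeps; ++s) {
    ++sweeps;
    double ll_before = ll;
    double max_change = 0.0;
    for (int e = 0; e < nedge; ++e) {
      double keep = elen[e];
      double best = ll;
      golden_opt_edge(edge, elen, e, ntip, nnode, tp, weights, npat,
                      min_len, max_len, best);
      if (best >= ll) {
        ll = best;
      } else {
        elen[e] = keep;
      }
      double ch = std::fabs(elen[e] - keep);
      if (ch > max_change) max_change = ch;
    }
    // elen currently holds last tried value for final edge; recompute
    ll = jc_loglik_impl(edge, elen, ntip, nnode, tp, weights, npat);
    if (ll - ll_before < tol || max_change < 1e-9) {
      converged = true;
      break;
    }
  }
  return List::create(_["lengths"] = NumericVector(elen.begin(), elen.end()),
                      _["loglik"] = ll, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
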