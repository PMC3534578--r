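#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "ptrng.h"

using namespace Rcpp;

// Gaussian-kernel overlap machinery used by the bootstrap of the
// pause-position estimator.  Mirrors the R-level densityOverlap():
// Silverman (nrd0) bandwidths per sample, a shared evaluation grid spanning
// both samples plus three bandwidths, and a trapezoidal integral of the
// pointwise minimum of the two kernel density estimates.

namespace {

double quantile7(std::vector<double> x, double p) {
  std::sort(x.begin(), x.end());
  const int n = (int)x.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = lo + 1 < n ? lo + 1 : lo;
  return x[lo] + (h - lo) * (x[hi] - x[lo]);
}

double bwNrd0(const std::vector<double> &x) {
  const int n = (int)x.size();
  double mean = 0.0;
  for (double v : x) mean += v;
  mean /= n;
  double ss = 0.0;
  for (double v : x) ss += (v - mean) * (v - mean);
  double sd = n > 1 ? std::sqrt(ss / (n - 1)) : 0.0;
  double iqr = quantile7(x, 0.75) - quantile7(x, 0.25);
  double lo = std::min(sd, iqr / 1.34);
  if (lo == 0.0) lo = sd;
  if (lo == 0.0) lo = std::abs(x[0]);
  if (lo == 0.0) lo = 1.0;
  return 0.9 * lo * std::pow((double)n, -0.2);
}

double kdeAt(const std::vector<double> &x, double bw, double g) {
  const double inv = 1.0 / bw;
  double s = 0.0;
  for (double v : x) {
    double z = (g - v) * inv;
    s += std::exp(-0.5 * z * z);
  }
  return s * inv * 0.3989422804014327 / (double)x.size();
}

double overlapC(const std::vector<double> &f, const std::vector<double> &g,
                int nGrid) {
  double bwF = bwNrd0(f), bwG = bwNrd0(g);
  double loF = *std::min_element(f.begin(), f.end());
  double hiF = *std::max_element(f.begin(), f.end());
  double loG = *std::min_element(g.begin(), g.end());
  double hiG = *std::max_element(g.begin(), g.end());
  double lo = std::min(loF - 3 * bwF, loG - 3 * bwG);
  double hi = std::max(hiF + 3 * bwF, hiG + 3 * bwG);
  double step = (hi - lo) / (nGrid - 1);
  double prev = 0.0, integral = 0.0;
  for (int i = 0; i < nGrid; ++i) {
    double x = lo + i * step;
    double m = std::min(kdeAt(f, bwF, x), kdeAt(g, bwG, x));
    if (i > 0) integral += 0.5 * (prev + m) * step;
    prev = m;
  }
  if (integral < 0.0) integral = 0.0;
  if (integral > 1.0) integral = 1.0;
  return integral;
}

} // namespace

// [[Rcpp::export(name = ".cpp_density_overlap")]]
double cpp_density_overlap(NumericVector f, NumericVector g, int nGrid) {
  return overlapC(as<std::vector<double>>(f), as<std::vector<double>>(g),
                  nGrid);
}

// For each of B bootstrap resamples of the observed feature rows, recompute
// the per-theta log-likelihood against the cached simulated feature sets and
// return the index (1-based) of the maximising theta (ties -> smallest).
// [[Rcpp::export(name = ".cpp_overlap_bootstrap")]]
IntegerVector cpp_overlap_bootstrap(NumericMatrix obs, List refSets, int B,
                                    int nGrid, double floorP, double seed) {
  const int S = obs.nrow(), V = obs.ncol();
  const int nTheta = refSets.size();
  std::vector<std::vector<std::vector<double>>> refs(nTheta);
  for (int th = 0; th < nTheta; ++th) {
    NumericMatrix m = refSets[th];
    refs[th].resize(V);
    for (int j = 0; j < V; ++j) {
      refs[th][j].resize(m.nrow());
      for (int i = 0; i < m.nrow(); ++i) refs[th][j][i] = m(i, j);
    }
  }

  PtRng rng((uint64_t)seed);
  IntegerVector out(B);
  std::vector<std::vector<double>> res(V, std::vector<double>(S));

  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < S; ++i) {
      int r = (int)(rng.unif() * S);
      if (r == S) r = S - 1;
      for (int j = 0; j < V; ++j) res[j][i] = obs(r, j);
    }
    int best = 0;
    double bestLL = -std::numeric_limits<double>::infinity();
    for (int th = 0; th < nTheta; ++th) {
      double ll = 0.0;
      for (int j = 0; j < V; ++j) {
        double p = overlapC(res[j], refs[th][j], nGrid);
        if (p < floorP) p = floorP;
        ll += std::log(p);
      }
      if (ll > bestLL + 1e-12) {
        bestLL = ll;
        best = th;
      }
    }
    out[b] = best + 1;
  }
  return out;
}
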