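#include <Rcpp.h>
#include <queue>
#include <vector>
#include "ptrng.h"

using namespace Rcpp;

// Generic delayed stochastic simulation engine: exact SSA over mass-action
// channels, extended with a waiting list that releases reaction products
// after arbitrarily distributed delays.  Ties between a reaction firing and
// a waiting-list release at the same instant are resolved release-first.

namespace {

struct DelayedProduct {
  int species;
  int count;
  Delay delay;
};

struct Channel {
  std::vector<int> reactIdx;
  std::vector<int> reactStoich;
  std::vector<int> prodIdx;
  std::vector<int> prodStoich;
  std::vector<DelayedProduct> delayed;
  double rate;
  std::vector<int> guardIdx;
  std::vector<double> guardMin;
  std::vector<double> guardMax;
};

struct WaitEntry {
  double time;
  int species;
  int count;
  bool operator>(const WaitEntry &o) const { return time > o.time; }
};

double propensity(const Channel &ch, const std::vector<long long> &x) {
  for (size_t g = 0; g < ch.guardIdx.size(); ++g) {
    long long c = x[ch.guardIdx[g]];
    if (c < ch.guardMin[g] || c > ch.guardMax[g]) return 0.0;
  }
  double a = ch.rate;
  for (size_t r = 0; r < ch.reactIdx.size(); ++r) {
    long long c = x[ch.reactIdx[r]];
    int m = ch.reactStoich[r];
    for (int k = 0; k < m; ++k) {
      a *= (double)(c - k);
      if (c - k <= 0) return 0.0;
    }
  }
  return a;
}

} // namespace

// [[Rcpp::export(name = ".cpp_ssa_run")]]
List cpp_ssa_run(NumericVector init, List reactions, double tEnd,
                 double sampleInterval, IntegerVector obsIdx, double seed,
                 double maxEvents, List waitingInit) {
  const int nSp = init.size();
  std::vector<long long> x(nSp);
  for (int i = 0; i < nSp; ++i) x[i] = (long long)init[i];

  std::vector<Channel> chans;
  for (int i = 0; i < reactions.size(); ++i) {
    List r = reactions[i];
    Channel ch;
    ch.reactIdx = as<std::vector<int>>(r["reactIdx"]);
    ch.reactStoich = as<std::vector<int>>(r["reactStoich"]);
    ch.prodIdx = as<std::vector<int>>(r["prodIdx"]);
    ch.prodStoich = as<std::vector<int>>(r["prodStoich"]);
    ch.rate = as<double>(r["rate"]);
    ch.guardIdx = as<std::vector<int>>(r["guardIdx"]);
    ch.guardMin = as<std::vector<double>>(r["guardMin"]);
    ch.guardMax = as<std::vector<double>>(r["guardMax"]);
    IntegerVector di = r["delIdx"];
    IntegerVector dn = r["delCount"];
    IntegerVector dk = r["delKind"];
    NumericVector d1 = r["delP1"];
    NumericVector d2 = r["delP2"];
    for (int j = 0; j < di.size(); ++j) {
      DelayedProduct dp;
      dp.species = di[j];
      dp.count = dn[j];
      dp.delay.kind = dk[j];
      dp.delay.p1 = d1[j];
      dp.delay.p2 = d2[j];
      ch.delayed.push_back(dp);
    }
    chans.push_back(ch);
  }

  std::priority_queue<WaitEntry, std::vector<WaitEntry>, std::greater<WaitEntry>>
      heap;
  if (waitingInit.size() == 3) {
    NumericVector wt = waitingInit[0];
    IntegerVector ws = waitingInit[1];
    IntegerVector wc = waitingInit[2];
    for (int i = 0; i < wt.size(); ++i)
      heap.push(WaitEntry{wt[i], ws[i], wc[i]});
  }

  PtRng rng((uint64_t)seed);
  const int nChan = (int)chans.size();
  std::vector<double> a(nChan);

  const bool sampling = sampleInterval > 0;
  long nSamples = sampling ? (long)std::floor(tEnd / sampleInterval + 1e-9) + 1 : 0;
  NumericMatrix samples(sampling ? nSamples : 0,
                        sampling ? obsIdx.size() + 1 : 0);
  long sampleK = 0; // next sample index to record

  auto record = [&](long k) {
    samples(k, 0) = k * sampleInterval;
    for (int j = 0; j < obsIdx.size(); ++j)
      samples(k, j + 1) = (double)x[obsIdx[j]];
  };

  double t = 0.0;
  double nEvents = 0;
  std::string status = "completed";

  for (;;) {
    double a0 = 0.0;
    for (int i = 0; i < nChan; ++i) {
      a[i] = propensity(chans[i], x);
      a0 += a[i];
    }
    double tReact = (a0 > 0.0) ? t + rng.rexp(a0) : R_PosInf;
    double tRelease = heap.empty() ? R_PosInf : heap.top().time;

    if (a0 == 0.0 && heap.empty()) {
      status = "exhausted";
      break;
    }
    double tNext = (tRelease <= tReact) ? tRelease : tReact;
    if (tNext > tEnd) {
      t = tEnd;
      break;
    }
    if (sampling) {
      while (sampleK < nSamples && sampleK * sampleInterval < tNext) {
        record(sampleK);
        ++sampleK;
      }
    }
    if (tRelease <= tReact) {
      WaitEntry w = heap.top();
      heap.pop();
      x[w.species] += w.count;
    } else {
      // select channel by cumulative propensity
      double u = rng.unif() * a0;
      int sel = nChan - 1;
      double cum = 0.0;
      for (int i = 0; i < nChan; ++i) {
        cum += a[i];
        if (u <= cum) {
          sel = i;
          break;
        }
      }
      const Channel &ch = chans[sel];
      for (size_t r = 0; r < ch.reactIdx.size(); ++r)
        x[ch.reactIdx[r]] -= ch.reactStoich[r];
      for (size_t p = 0; p < ch.prodIdx.size(); ++p)
        x[ch.prodIdx[p]] += ch.prodStoich[p];
      for (size_t d = 0; d < ch.delayed.size(); ++d) {
        const DelayedProduct &dp = ch.delayed[d];
        heap.push(WaitEntry{tNext + drawDelayC(dp.delay, rng), dp.species,
                            dp.count});
      }
    }
    t = tNext;
    nEvents += 1;
    if (maxEvents > 0 && nEvents >= maxEvents) {
      status = "maxEvents";
      break;
    }
  }

  if (sampling && status != "maxEvents") {
    // state is constant after the last processed event
    while (sampleK < nSamples) {
      record(sampleK);
      ++sampleK;
    }
  }

  NumericVector state(nSp);
  for (int i = 0; i < nSp; ++i) state[i] = (double)x[i];

  int nw = (int)heap.size();
  NumericVector wt(nw);
  IntegerVector ws(nw), wc(nw);
  for (int i = 0; i < nw; ++i) {
    WaitEntry w = heap.top();
    heap.pop();
    wt[i] = w.time;
    ws[i] = w.species;
    wc[i] = w.count;
  }

  return List::create(
      _["samples"] = sampling ? (SEXP)samples : R_NilValue,
      _["state"] = state, _["time"] = t, _["status"] = status,
      _["nEvents"] = nEvents,
      _["waitingTime"] = wt, _["waitingSpecies"] = ws,
      _["waitingCount"] = wc);
}

// [[Rcpp::export(name = ".cpp_draw_delay")]]
NumericVector cpp_draw_delay(int kind, double p1, double p2, int n,
                             double seed) {
  PtRng rng((uint64_t)seed);
  Delay d;
  d.kind = kind;
  d.p1 = p1;
  d.p2 = p2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = drawDelayC(d, rng);
  return out;
}
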