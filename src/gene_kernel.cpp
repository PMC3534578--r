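#include <Rcpp.h>
#include <queue>
#include <vector>
#include "ptrng.h"

using namespace Rcpp;

// Nucleotide/codon-resolution simulator of single-gene expression.
//
// Transcription: promoter binding with an open-complex-formation delay,
// promoter clearance, per-nucleotide activation and stepwise elongation with
// RNAP footprint exclusion, ubiquitous and sequence-dependent pausing,
// collision-mediated pause release/induction, arrests, editing excursions,
// premature termination, pyrophosphorolysis and termination.
//
// Translation is tracked per transcript (each nascent or complete mRNA
// carries its own ribonucleotide lattice and ribosome list): initiation at
// the ribosome binding site, codon-class-specific activation, three-stage
// translocation, back-translocation, drop-off, trans-translation, completion
// with a protein-folding delay, and protein degradation.
//
// The sampled observables are the number of intact mRNA molecules (nascent
// transcripts under elongation plus completed transcripts, i.e. what a
// single-molecule RNA tag reports), the current protein count, and the
// cumulative number of proteins produced.

namespace {

enum RnapState { R_O = 0, R_A = 1, R_PAUSED = 2, R_ARREST = 3, R_EDIT = 4 };
enum RiboState { B_O = 0, B_A = 1, B_T1 = 2, B_T2 = 3 };
enum PromState { P_FREE = 0, P_FORMING = 1, P_READY = 2 };
enum HeapType { H_OC = 0, H_PROTEIN = 1 };

struct Rnap {
  int pos;
  int state;
  int trIdx;       // owning transcript
  double startTime;
};

struct Ribo {
  int pos;   // codon-aligned position of the last O/A state
  int state;
};

struct Transcript {
  int exposed;   // ribonucleotides 1..exposed are available
  bool complete; // full-length (reaction-12 product)
  bool intact;   // false once degradation has fired; no new initiation
  int rnapIdx;   // owning RNAP while nascent, else -1
  std::vector<Ribo> ribos; // ordered leader-first (descending pos)
};

struct HeapEvent {
  double time;
  int type;
  bool operator>(const HeapEvent &o) const { return time > o.time; }
};

// channel action codes
enum Act {
  A_BIND, A_CLEAR, A_ACT, A_PAUSE, A_UNPAUSE, A_COLL_REL, A_COLL_IND,
  A_ARREST, A_UNARREST, A_EDIT, A_UNEDIT, A_PRE, A_PYR, A_ELONG, A_TERM,
  A_DEG, A_TT, A_TLINIT, A_RACT, A_RBT, A_RDROP, A_RTSTART, A_RTSUB,
  A_RCOMPLETE, A_PDEG
};

struct Kernel {
  // configuration
  int L, nCodons, lastPos, deltaP, deltaR, fp; // fp = 2*deltaP + 1
  std::vector<double> ktr;          // per-codon activation rate
  std::vector<double> pauseRate;    // per-nt pause entry rate (from state O)
  std::vector<double> pauseExit;    // per-nt pause exit rate (1/mean duration)
  double ktc, tocMean, tocSd, km, kaSlow, kaFast;
  int kaBoundary;
  double kar, tar, ked, ded, kpre, kpyr, kf, kdr, ktl, ktm, kbt, kdrop, ktt,
      ktlf, foldMean, foldSd, kdp;

  // state
  int prom;
  long long rpFree, ribFree, mRNA, nIntact, P;
  double E; // cumulative proteins produced
  std::vector<Rnap> rnaps;            // ordered leader-first (descending pos)
  std::vector<Transcript> trs;
  std::priority_queue<HeapEvent, std::vector<HeapEvent>, std::greater<HeapEvent>>
      heap;

  // channel buffers, rebuilt every step
  std::vector<double> prop;
  std::vector<int> act, ai, aj;

  // diagnostics
  double nCompleted = 0, nPremature = 0, nSeqPauseEntries = 0;
  std::vector<double> passStart, passEnd;
  bool recordPassages = false;

  double kaAt(int n) const { return n <= kaBoundary ? kaSlow : kaFast; }

  int riboOccL(const Ribo &b) const { return b.pos - deltaR + 1; }
  int riboOccR(const Ribo &b) const {
    return b.state == B_O || b.state == B_A ? b.pos + deltaR - 1
                                            : b.pos + deltaR + 2;
  }

  void push(double p, int a, int i, int j) {
    if (p <= 0.0) return;
    prop.push_back(p);
    act.push_back(a);
    ai.push_back(i);
    aj.push_back(j);
  }

  // positions 1..deltaP+1 on the template must be free for clearance
  bool promoterRegionFree() const {
    if (rnaps.empty()) return true;
    return rnaps.back().pos > 2 * deltaP + 1;
  }

  void buildChannels() {
    prop.clear();
    act.clear();
    ai.clear();
    aj.clear();

    if (prom == P_FREE && rpFree > 0) push(ktc * (double)rpFree, A_BIND, 0, 0);
    if (prom == P_READY && promoterRegionFree()) push(km, A_CLEAR, 0, 0);

    const int nR = (int)rnaps.size();
    for (int i = 0; i < nR; ++i) {
      const Rnap &r = rnaps[i];
      const int n = r.pos;
      const bool trailerAdj =
          (i + 1 < nR) && rnaps[i + 1].pos == n - fp && rnaps[i + 1].state == R_A;
      switch (r.state) {
      case R_O: {
        push(kaAt(n), A_ACT, i, 0);
        push(pauseRate[n - 1], A_PAUSE, i, 0);
        if (trailerAdj) push(0.2 * km, A_COLL_IND, i, 0);
        push(kar, A_ARREST, i, 0);
        push(ked, A_EDIT, i, 0);
        push(kpre, A_PRE, i, 0);
        if (n >= deltaP + 2) {
          bool dnaFree = (i + 1 >= nR) || rnaps[i + 1].pos < n - fp;
          const Transcript &tr = trs[r.trIdx];
          bool rnaFree =
              tr.ribos.empty() || riboOccR(tr.ribos.front()) < n - deltaP - 1;
          if (dnaFree && rnaFree) push(kpyr, A_PYR, i, 0);
        }
        break;
      }
      case R_A: {
        if (n == L) {
          push(kf, A_TERM, i, 0);
        } else {
          bool free = (i == 0) || rnaps[i - 1].pos > n + fp;
          if (free) push(km, A_ELONG, i, 0);
        }
        break;
      }
      case R_PAUSED: {
        push(pauseExit[n - 1], A_UNPAUSE, i, 0);
        if (trailerAdj) push(0.8 * km, A_COLL_REL, i, 0);
        break;
      }
      case R_ARREST:
        push(1.0 / tar, A_UNARREST, i, 0);
        break;
      case R_EDIT:
        push(1.0 / ded, A_UNEDIT, i, 0);
        break;
      }
    }

    const int nT = (int)trs.size();
    for (int k = 0; k < nT; ++k) {
      const Transcript &tr = trs[k];
      if (tr.complete && tr.intact) {
        push(kdr, A_DEG, k, 0);
        push(ktt, A_TT, k, 0);
      }
      if (tr.intact && ribFree > 0 && tr.exposed >= deltaR + 1) {
        bool rbsFree = tr.ribos.empty() || riboOccL(tr.ribos.back()) > deltaR + 1;
        if (rbsFree) push(ktl * (double)ribFree, A_TLINIT, k, 0);
      }
      const int nB = (int)tr.ribos.size();
      for (int j = 0; j < nB; ++j) {
        const Ribo &b = tr.ribos[j];
        const int p = b.pos;
        switch (b.state) {
        case B_O: {
          push(ktr[(p - 1) / 3], A_RACT, k, j);
          push(kdrop, A_RDROP, k, j);
          if (p >= deltaR + 1) {
            bool behindFree =
                (j + 1 >= nB) || riboOccR(tr.ribos[j + 1]) < p - deltaR - 2;
            if (behindFree) push(kbt, A_RBT, k, j);
          }
          break;
        }
        case B_A: {
          if (p == lastPos) {
            push(ktlf, A_RCOMPLETE, k, j);
          } else {
            // flags [p+dR, p+dR+2] must exist-and-be-exposed (positions
            // beyond the template are boundary-free) and uncovered; the
            // target codon must be transcribed
            bool exposedOk = (p + 5 <= tr.exposed); // target codon transcribed
            if (p + deltaR <= L && std::min(p + deltaR + 2, L) > tr.exposed)
              exposedOk = false; // a needed flag is not yet transcribed
            bool aheadFree = (j == 0) || tr.ribos[j - 1].pos > p + 2 * deltaR + 1;
            if (exposedOk && aheadFree) push(ktm, A_RTSTART, k, j);
          }
          break;
        }
        default:
          push(ktm, A_RTSUB, k, j);
        }
      }
    }

    if (P > 0) push(kdp * (double)P, A_PDEG, 0, 0);
  }

  void removeRnap(int i) {
    rnaps.erase(rnaps.begin() + i);
    for (size_t k = 0; k < trs.size(); ++k)
      if (trs[k].rnapIdx > i) trs[k].rnapIdx -= 1;
  }

  void removeTranscript(int k) {
    int last = (int)trs.size() - 1;
    if (k != last) {
      trs[k] = trs[last];
      if (trs[k].rnapIdx >= 0) rnaps[trs[k].rnapIdx].trIdx = k;
    }
    trs.pop_back();
  }

  void zombieCleanup(int k) {
    if (!trs[k].intact && trs[k].ribos.empty()) removeTranscript(k);
  }

  void fire(int c, double t, PtRng &rng) {
    const int a = act[c], i = ai[c], j = aj[c];
    switch (a) {
    case A_BIND:
      rpFree -= 1;
      prom = P_FORMING;
      heap.push(HeapEvent{t + rng.rnormPos(tocMean, tocSd), H_OC});
      break;
    case A_CLEAR: {
      prom = P_FREE;
      Transcript tr;
      tr.exposed = 0;
      tr.complete = false;
      tr.intact = true;
      tr.rnapIdx = (int)rnaps.size();
      trs.push_back(tr);
      nIntact += 1; // the transcript is visible to single-molecule tagging

      Rnap r;
      r.pos = 1;
      r.state = R_O;
      r.trIdx = (int)trs.size() - 1;
      r.startTime = t;
      rnaps.push_back(r);
      break;
    }
    case A_ACT:
      rnaps[i].state = R_A;
      break;
    case A_PAUSE:
      rnaps[i].state = R_PAUSED;
      break;
    case A_UNPAUSE:
    case A_COLL_REL:
      rnaps[i].state = R_O;
      break;
    case A_COLL_IND:
      rnaps[i].state = R_PAUSED;
      break;
    case A_ARREST:
      rnaps[i].state = R_ARREST;
      break;
    case A_UNARREST:
      rnaps[i].state = R_O;
      break;
    case A_EDIT:
      rnaps[i].state = R_EDIT;
      break;
    case A_UNEDIT:
      rnaps[i].state = R_O;
      break;
    case A_PRE: {
      int k = rnaps[i].trIdx;
      ribFree += (long long)trs[k].ribos.size();
      nIntact -= 1;
      removeTranscript(k);
      removeRnap(i);
      rpFree += 1;
      nPremature += 1;
      break;
    }
    case A_PYR: {
      rnaps[i].pos -= 1;
      Transcript &tr = trs[rnaps[i].trIdx];
      tr.exposed = std::max(0, rnaps[i].pos - deltaP - 1);
      break;
    }
    case A_ELONG: {
      rnaps[i].pos += 1;
      rnaps[i].state = R_O; // reaction 4 yields the pre-activation state O_{n+1}

      Transcript &tr = trs[rnaps[i].trIdx];
      tr.exposed = std::max(tr.exposed, rnaps[i].pos - deltaP - 1);
      break;
    }
    case A_TERM: {
      int k = rnaps[i].trIdx;
      trs[k].complete = true;
      trs[k].exposed = L;
      trs[k].rnapIdx = -1;
      mRNA += 1;
      if (recordPassages) {
        passStart.push_back(rnaps[i].startTime);
        passEnd.push_back(t);
      }
      removeRnap(i);
      rpFree += 1;
      nCompleted += 1;
      break;
    }
    case A_DEG:
      trs[i].intact = false;
      mRNA -= 1;
      nIntact -= 1;
      zombieCleanup(i);
      break;
    case A_TT:
      ribFree += (long long)trs[i].ribos.size();
      mRNA -= 1;
      nIntact -= 1;
      removeTranscript(i);
      break;
    case A_TLINIT: {
      ribFree -= 1;
      Ribo b;
      b.pos = 1;
      b.state = B_O;
      trs[i].ribos.push_back(b);
      break;
    }
    case A_RACT:
      trs[i].ribos[j].state = B_A;
      break;
    case A_RBT:
      trs[i].ribos[j].pos -= 3;
      trs[i].ribos[j].state = B_A;
      break;
    case A_RDROP:
      trs[i].ribos.erase(trs[i].ribos.begin() + j);
      ribFree += 1;
      zombieCleanup(i);
      break;
    case A_RTSTART:
      trs[i].ribos[j].state = B_T1;
      break;
    case A_RTSUB:
      if (trs[i].ribos[j].state == B_T1) {
        trs[i].ribos[j].state = B_T2;
      } else {
        trs[i].ribos[j].state = B_O;
        trs[i].ribos[j].pos += 3;
      }
      break;
    case A_RCOMPLETE:
      trs[i].ribos.erase(trs[i].ribos.begin() + j);
      ribFree += 1;
      heap.push(HeapEvent{t + rng.rnormPos(foldMean, foldSd), H_PROTEIN});
      zombieCleanup(i);
      break;
    case A_PDEG:
      P -= 1;
      break;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_gene_sim")]]
List cpp_gene_sim(int geneLength, NumericVector ktrCodon,
                  NumericVector pauseRate, NumericVector pauseMeanDur,
                  List params, double tEnd, double sampleInterval, double seed,
                  bool recordPassages) {
  Kernel K;
  K.L = geneLength;
  K.nCodons = ktrCodon.size();
  K.lastPos = 3 * (K.nCodons - 1) + 1;
  K.deltaP = as<int>(params["deltaP"]);
  K.deltaR = as<int>(params["deltaR"]);
  K.fp = 2 * K.deltaP + 1;
  K.ktr = as<std::vector<double>>(ktrCodon);
  K.pauseRate = as<std::vector<double>>(pauseRate);
  K.pauseExit.resize(geneLength);
  for (int n = 0; n < geneLength; ++n)
    K.pauseExit[n] = pauseMeanDur[n] > 0 ? 1.0 / pauseMeanDur[n] : 0.0;
  K.ktc = as<double>(params["ktc"]);
  K.tocMean = as<double>(params["tocMean"]);
  K.tocSd = as<double>(params["tocSd"]);
  K.km = as<double>(params["km"]);
  K.kaSlow = as<double>(params["kaSlow"]);
  K.kaFast = as<double>(params["kaFast"]);
  K.kaBoundary = as<int>(params["kaBoundary"]);
  K.kar = as<double>(params["kar"]);
  K.tar = as<double>(params["tauArrest"]);
  K.ked = as<double>(params["ked"]);
  K.ded = as<double>(params["dEdit"]);
  K.kpre = as<double>(params["kpre"]);
  K.kpyr = as<double>(params["kpyr"]);
  K.kf = as<double>(params["kf"]);
  K.kdr = as<double>(params["kdr"]);
  K.ktl = as<double>(params["ktl"]);
  K.ktm = as<double>(params["ktm"]);
  K.kbt = as<double>(params["kbt"]);
  K.kdrop = as<double>(params["kdrop"]);
  K.ktt = as<double>(params["ktt"]);
  K.ktlf = as<double>(params["ktlf"]);
  K.foldMean = as<double>(params["foldMean"]);
  K.foldSd = as<double>(params["foldSd"]);
  K.kdp = as<double>(params["kdp"]);
  K.prom = P_FREE;
  K.rpFree = (long long)as<double>(params["nRnap"]);
  K.ribFree = (long long)as<double>(params["nRib"]);
  K.mRNA = 0;
  K.nIntact = 0;
  K.P = 0;
  K.E = 0;
  K.recordPassages = recordPassages;

  PtRng rng((uint64_t)seed);

  const long nSamples = (long)std::floor(tEnd / sampleInterval + 1e-9) + 1;
  NumericMatrix samples(nSamples, 4);
  long sampleK = 0;
  auto record = [&](long k) {
    samples(k, 0) = k * sampleInterval;
    samples(k, 1) = (double)K.nIntact;
    samples(k, 2) = (double)K.P;
    samples(k, 3) = K.E;
  };

  double t = 0.0;
  double nEvents = 0;

  for (;;) {
    K.buildChannels();
    double a0 = 0.0;
    for (size_t c = 0; c < K.prop.size(); ++c) a0 += K.prop[c];
    double tReact = (a0 > 0.0) ? t + rng.rexp(a0) : R_PosInf;
    double tRelease = K.heap.empty() ? R_PosInf : K.heap.top().time;
    if (a0 == 0.0 && K.heap.empty()) break;
    double tNext = (tRelease <= tReact) ? tRelease : tReact;
    if (tNext > tEnd) {
      t = tEnd;
      break;
    }
    while (sampleK < nSamples && sampleK * sampleInterval < tNext) {
      record(sampleK);
      ++sampleK;
    }
    if (tRelease <= tReact) {
      HeapEvent e = K.heap.top();
      K.heap.pop();
      if (e.type == H_OC) {
        K.prom = P_READY;
      } else {
        K.P += 1;
        K.E += 1;
      }
    } else {
      double u = rng.unif() * a0;
      int sel = (int)K.prop.size() - 1;
      double cum = 0.0;
      for (size_t c = 0; c < K.prop.size(); ++c) {
        cum += K.prop[c];
        if (u <= cum) {
          sel = (int)c;
          break;
        }
      }
      K.fire(sel, tNext, rng);
    }
    t = tNext;
    nEvents += 1;
    if (((long long)nEvents & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  while (sampleK < nSamples) {
    record(sampleK);
    ++sampleK;
  }

  colnames(samples) =
      CharacterVector::create("time", "rna", "protein", "proteinTotal");

  List out = List::create(
      _["samples"] = samples, _["nEvents"] = nEvents,
      _["nCompleted"] = K.nCompleted, _["nPremature"] = K.nPremature,
      _["finalRna"] = (double)K.mRNA, _["finalProtein"] = (double)K.P,
      _["rnapFree"] = (double)K.rpFree, _["ribFree"] = (double)K.ribFree,
      _["rnapOnTemplate"] = (double)K.rnaps.size());
  if (recordPassages) {
    out["passageStart"] = wrap(K.passStart);
    out["passageEnd"] = wrap(K.passEnd);
  }
  return out;
}

// Count of template positions made unavailable by a single elongating RNAP
// at the given position, by direct evaluation of the kernel's footprint rule.
// [[Rcpp::export(name = ".cpp_rnap_footprint")]]
IntegerVector cpp_rnap_footprint(int pos, int deltaP, int geneLength) {
  std::vector<int> occ;
  for (int q = 1; q <= geneLength; ++q)
    if (q >= pos - deltaP && q <= pos + deltaP) occ.push_back(q);
  return wrap(occ);
}
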