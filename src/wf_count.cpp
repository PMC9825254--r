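// Count-based sexed Wright-Fisher engine for a single selected locus.
//
// The population is summarised per generation by derived-allele dosage
// counts within each sex plus per-origin copy counts within each sex.
// Offspring genotypes are drawn by random union of gametes; selection acts
// through parent sampling weights (fecundity selection).  Derived copies of
// a given sex are exchangeable, so transmitted derived gametes are
// partitioned among mutational origins multinomially and split between
// offspring sexes hypergeometrically.  X males are hemizygous: they carry
// one copy, receive it from their mother, and pass it to daughters only;
// a male carrier has the homozygote fitness (dosage compensation).
//
// All randomness flows through R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct OriginTab {
  std::vector<int> id;
  std::vector<double> cnt;
  double total() const {
    double t = 0;
    for (double c : cnt) t += c;
    return t;
  }
  void prune() {
    size_t j = 0;
    for (size_t i = 0; i < id.size(); ++i) {
      if (cnt[i] > 0) { id[j] = id[i]; cnt[j] = cnt[i]; ++j; }
    }
    id.resize(j); cnt.resize(j);
  }
};

// multinomial draw of n among tab's origins, probabilities prop. to counts
static std::vector<double> multinom_part(const OriginTab &tab, double n) {
  std::vector<double> out(tab.id.size(), 0.0);
  double rem = n, crem = tab.total();
  for (size_t i = 0; i + 1 < tab.id.size() && rem > 0; ++i) {
    double x = R::rbinom(rem, tab.cnt[i] / crem);
    out[i] = x; rem -= x; crem -= tab.cnt[i];
  }
  if (!tab.id.empty()) out[tab.id.size() - 1] += rem;
  return out;
}

// split each origin's transmitted copies into a subset of size kDaughters
// (uniform subset of the total), via sequential hypergeometric draws
static void hyper_split(const std::vector<double> &tot, double kDaughters,
                        std::vector<double> &toF, std::vector<double> &toM) {
  double n = 0;
  for (double t : tot) n += t;
  double remF = kDaughters, remTot = n;
  toF.assign(tot.size(), 0.0);
  toM.assign(tot.size(), 0.0);
  for (size_t i = 0; i < tot.size(); ++i) {
    double x;
    if (remTot <= 0) x = 0;
    else x = R::rhyper(remF, remTot - remF, tot[i]);
    toF[i] = x;
    toM[i] = tot[i] - x;
    remF -= x;
    remTot -= tot[i];
  }
}

static OriginTab tab_from(List st, const char *ids, const char *cnts) {
  OriginTab t;
  IntegerVector i = st[ids];
  NumericVector c = st[cnts];
  t.id.assign(i.begin(), i.end());
  t.cnt.assign(c.begin(), c.end());
  return t;
}

static void tab_to(List &st, const char *ids, const char *cnts,
                   const OriginTab &t) {
  st[ids] = IntegerVector(t.id.begin(), t.id.end());
  st[cnts] = NumericVector(t.cnt.begin(), t.cnt.end());
}

} // namespace

// Run the count engine.
// stopMode: 0 = run exactly `gens` generations;
//           1 = run until derived allele fixed (or gens cap);
//           2 = run until fixed or lost (or gens cap).
// sF,hF: selection/dominance in females; sM,hM in males (autosomal males
// use (1, 1+hM*sM, 1+sM); hemizygous X males use (1, 1+sM)).
// mu: adaptive mutation probability per transmitted wildtype copy.
// [[Rcpp::export]]
List cc_run(List state, double sF, double hF, double sM, double hM,
            double mu, double gens, int stopMode) {
  RNGScope scope;
  bool isX = as<bool>(state["isX"]);
  double N = as<double>(state["N"]);
  double gen = as<double>(state["gen"]);
  int nextId = as<int>(state["nextId"]);
  NumericVector fD = clone(as<NumericVector>(state["femDos"])); // f0,f1,f2
  NumericVector mD = clone(as<NumericVector>(state["maleDos"]));
  OriginTab fem = tab_from(state, "femOriginId", "femOriginCnt");
  OriginTab male = tab_from(state, "maleOriginId", "maleOriginCnt");

  double nf = fD[0] + fD[1] + fD[2];
  double nm = isX ? (mD[0] + mD[1]) : (mD[0] + mD[1] + mD[2]);

  std::string status = "ran";
  double fixGen = NA_REAL;
  double g = 0;
  for (g = 0; g < gens; ++g) {
    double wf0 = 1.0, wf1 = 1.0 + hF * sF, wf2 = 1.0 + sF;
    double Wf = fD[0] * wf0 + fD[1] * wf1 + fD[2] * wf2;
    if (Wf <= 0) stop("female mean fitness is non-positive");
    double pm = (0.5 * fD[1] * wf1 + fD[2] * wf2) / Wf;

    double pp;
    if (isX) {
      double wm1 = 1.0 + sM; // hemizygous carrier = homozygote fitness
      double Wm = mD[0] * 1.0 + mD[1] * wm1;
      if (Wm <= 0) stop("male mean fitness is non-positive");
      pp = mD[1] * wm1 / Wm;
    } else {
      double wm1 = 1.0 + hM * sM, wm2 = 1.0 + sM;
      double Wm = mD[0] * 1.0 + mD[1] * wm1 + mD[2] * wm2;
      if (Wm <= 0) stop("male mean fitness is non-positive");
      pp = (0.5 * mD[1] * wm1 + mD[2] * wm2) / Wm;
    }

    double nfp = R::rbinom(N, 0.5);
    double nmp = N - nfp;
    if (nfp < 1 || nmp < 1)
      stop("one sex went extinct (population too small)");

    // maternal gametes: one per offspring
    double DmF = R::rbinom(nfp, pm);
    double DmM = R::rbinom(nmp, pm);
    // paternal gametes: autosome -> every offspring; X -> daughters only
    double DpF = R::rbinom(nfp, pp);
    double DpM = isX ? 0.0 : R::rbinom(nmp, pp);

    // adaptive mutation on transmitted wildtype copies
    double MmF = (mu > 0) ? R::rbinom(nfp - DmF, mu) : 0.0;
    double MmM = (mu > 0) ? R::rbinom(nmp - DmM, mu) : 0.0;
    double MpF = (mu > 0) ? R::rbinom(nfp - DpF, mu) : 0.0;
    double MpM = (!isX && mu > 0) ? R::rbinom(nmp - DpM, mu) : 0.0;

    double DmF2 = DmF + MmF, DmM2 = DmM + MmM;
    double DpF2 = DpF + MpF, DpM2 = DpM + MpM;

    // offspring genotype counts
    double Hf = (DmF2 > 0 && DpF2 > 0)
                    ? R::rhyper(DmF2, nfp - DmF2, DpF2)
                    : 0.0;
    NumericVector fDn(3);
    fDn[2] = Hf;
    fDn[1] = DmF2 + DpF2 - 2 * Hf;
    fDn[0] = nfp - fDn[1] - fDn[2];
    NumericVector mDn(isX ? 2 : 3);
    if (isX) {
      mDn[1] = DmM2;
      mDn[0] = nmp - DmM2;
    } else {
      double Hm = (DmM2 > 0 && DpM2 > 0)
                      ? R::rhyper(DmM2, nmp - DmM2, DpM2)
                      : 0.0;
      mDn[2] = Hm;
      mDn[1] = DmM2 + DpM2 - 2 * Hm;
      mDn[0] = nmp - mDn[1] - mDn[2];
    }

    // partition transmitted derived gametes among origins
    std::vector<double> matPart = multinom_part(fem, DmF + DmM);
    std::vector<double> patPart = multinom_part(male, DpF + DpM);
    std::vector<double> matF, matM, patF, patM;
    hyper_split(matPart, DmF, matF, matM);
    hyper_split(patPart, DpF, patF, patM);

    OriginTab femN, maleN;
    // carry over surviving origins from both parental pools
    for (size_t i = 0; i < fem.id.size(); ++i) {
      if (matF[i] > 0 || matM[i] > 0) {
        femN.id.push_back(fem.id[i]); femN.cnt.push_back(matF[i]);
        maleN.id.push_back(fem.id[i]); maleN.cnt.push_back(matM[i]);
      }
    }
    for (size_t i = 0; i < male.id.size(); ++i) {
      if (patF[i] > 0 || patM[i] > 0) {
        // merge with an existing id if present
        bool merged = false;
        for (size_t j = 0; j < femN.id.size(); ++j) {
          if (femN.id[j] == male.id[i]) {
            femN.cnt[j] += patF[i]; maleN.cnt[j] += patM[i];
            merged = true; break;
          }
        }
        if (!merged) {
          femN.id.push_back(male.id[i]); femN.cnt.push_back(patF[i]);
          maleN.id.push_back(male.id[i]); maleN.cnt.push_back(patM[i]);
        }
      }
    }
    // fresh origins from this generation's mutations
    for (int j = 0; j < (int)MmF; ++j) {
      femN.id.push_back(nextId); femN.cnt.push_back(1);
      maleN.id.push_back(nextId); maleN.cnt.push_back(0); ++nextId;
    }
    for (int j = 0; j < (int)MpF; ++j) {
      femN.id.push_back(nextId); femN.cnt.push_back(1);
      maleN.id.push_back(nextId); maleN.cnt.push_back(0); ++nextId;
    }
    for (int j = 0; j < (int)MmM; ++j) {
      femN.id.push_back(nextId); femN.cnt.push_back(0);
      maleN.id.push_back(nextId); maleN.cnt.push_back(1); ++nextId;
    }
    for (int j = 0; j < (int)MpM; ++j) {
      femN.id.push_back(nextId); femN.cnt.push_back(0);
      maleN.id.push_back(nextId); maleN.cnt.push_back(1); ++nextId;
    }
    // drop origins extinct in both pools
    {
      size_t j = 0;
      for (size_t i = 0; i < femN.id.size(); ++i) {
        if (femN.cnt[i] > 0 || maleN.cnt[i] > 0) {
          femN.id[j] = femN.id[i]; femN.cnt[j] = femN.cnt[i];
          maleN.id[j] = maleN.id[i]; maleN.cnt[j] = maleN.cnt[i];
          ++j;
        }
      }
      femN.id.resize(j); femN.cnt.resize(j);
      maleN.id.resize(j); maleN.cnt.resize(j);
    }

    fem = femN; male = maleN;
    fD = fDn; mD = mDn;
    nf = nfp; nm = nmp;
    gen += 1;

    double totalCopies = isX ? (2 * nf + nm) : (2 * N);
    double derived = fem.total() + male.total();
    if (derived >= totalCopies && stopMode >= 1) {
      status = "fixed"; fixGen = gen; g += 1; break;
    }
    if (derived <= 0 && stopMode == 2 && mu <= 0) {
      status = "lost"; g += 1; break;
    }
    if ((g + 1) >= gens && stopMode >= 1) status = "cap";
  }

  List out = clone(state);
  out["femDos"] = fD;
  out["maleDos"] = mD;
  out["gen"] = gen;
  out["nextId"] = nextId;
  tab_to(out, "femOriginId", "femOriginCnt", fem);
  tab_to(out, "maleOriginId", "maleOriginCnt", male);
  out["status"] = status;
  out["fixGen"] = fixGen;
  out["gensRun"] = g;
  return out;
}
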