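// Sequence-level sexed Wright-Fisher engine.
//
// Each chromosome copy carries a sorted vector of derived neutral-site
// positions (real-valued in (0, L), de-duplicated at output) plus the state
// of one selected site at selPos: 0 = wildtype, >0 = mutational origin id.
// Individuals are explicit; mothers/fathers are drawn proportional to
// genotype fitness at the selected site; gametes recombine with a Poisson
// number of crossovers; neutral mutation is infinite-sites at a per-copy
// rate; adaptive mutation converts a wildtype selected site to a fresh
// origin.  X males are hemizygous (single copy, from the mother, passed
// unrecombined to daughters; carrier fitness = homozygote, i.e. dosage
// compensation).
//
// Randomness flows through R's RNG (set.seed() reproducible).

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct Copy {
  std::vector<double> pos; // sorted derived neutral positions
  int sel = 0;             // origin id at the selected site (0 = wildtype)
};

struct Pop {
  std::vector<Copy> fem;  // 2 per female
  std::vector<Copy> male; // 2 per male (autosome) or 1 (X)
  bool isX = false;
  double L = 10000.0;
  double selPos = 5000.0;
  int nextId = 1;
  int nf() const { return (int)fem.size() / 2; }
  int nm() const { return isX ? (int)male.size() : (int)male.size() / 2; }
  int copies() const { return (int)(fem.size() + male.size()); }
  int derived() const {
    int d = 0;
    for (const Copy &c : fem) d += c.sel > 0;
    for (const Copy &c : male) d += c.sel > 0;
    return d;
  }
};

// recombinant gamete from two parental copies
static Copy meiosis(const Copy &a, const Copy &b, double L, double selPos,
                    double rTotal) {
  int nx = (rTotal > 0) ? (int)R::rpois(rTotal) : 0;
  bool first = unif_rand() < 0.5;
  if (nx == 0) return first ? a : b;
  std::vector<double> bp(nx);
  for (int i = 0; i < nx; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  bp.push_back(L + 1.0);
  Copy g;
  g.pos.reserve(a.pos.size() + b.pos.size());
  const Copy *cur = first ? &a : &b;
  const Copy *oth = first ? &b : &a;
  double lo = 0.0;
  bool selDone = false;
  for (double hi : bp) {
    // copy cur's positions in [lo, hi)
    auto s = std::lower_bound(cur->pos.begin(), cur->pos.end(), lo);
    auto e = std::lower_bound(cur->pos.begin(), cur->pos.end(), hi);
    g.pos.insert(g.pos.end(), s, e);
    if (!selDone && selPos >= lo && selPos < hi) {
      g.sel = cur->sel;
      selDone = true;
    }
    std::swap(cur, oth);
    lo = hi;
  }
  return g;
}

static void mutate(Copy &g, double L, double muNTotal) {
  if (muNTotal <= 0) return;
  int k = (int)R::rpois(muNTotal);
  for (int i = 0; i < k; ++i) {
    double p = unif_rand() * L;
    auto it = std::lower_bound(g.pos.begin(), g.pos.end(), p);
    if (it == g.pos.end() || *it != p) g.pos.insert(it, p);
  }
}

// weighted index draw from cumulative weights
static int wdraw(const std::vector<double> &cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// one generation; sF/hF female selection, sM/hM male selection
static void generation(Pop &p, double sF, double hF, double sM, double hM,
                       double muA, double muNTotal, double rTotal) {
  int nf = p.nf(), nm = p.nm();
  int N = nf + nm;
  std::vector<double> cumF(nf), cumM(nm);
  double wf[3] = {1.0, 1.0 + hF * sF, 1.0 + sF};
  double acc = 0;
  for (int i = 0; i < nf; ++i) {
    int d = (p.fem[2 * i].sel > 0) + (p.fem[2 * i + 1].sel > 0);
    acc += wf[d];
    cumF[i] = acc;
  }
  acc = 0;
  if (p.isX) {
    double wm[2] = {1.0, 1.0 + sM}; // dosage compensation
    for (int i = 0; i < nm; ++i) {
      acc += wm[p.male[i].sel > 0 ? 1 : 0];
      cumM[i] = acc;
    }
  } else {
    double wm[3] = {1.0, 1.0 + hM * sM, 1.0 + sM};
    for (int i = 0; i < nm; ++i) {
      int d = (p.male[2 * i].sel > 0) + (p.male[2 * i + 1].sel > 0);
      acc += wm[d];
      cumM[i] = acc;
    }
  }

  int nfp = (int)R::rbinom((double)N, 0.5);
  int nmp = N - nfp;
  if (nfp < 1 || nmp < 1) stop("one sex went extinct (population too small)");

  std::vector<Copy> femN, maleN;
  femN.reserve(2 * nfp);
  maleN.reserve(p.isX ? nmp : 2 * nmp);

  auto maternal = [&]() {
    int mi = wdraw(cumF);
    Copy g = meiosis(p.fem[2 * mi], p.fem[2 * mi + 1], p.L, p.selPos, rTotal);
    mutate(g, p.L, muNTotal);
    if (muA > 0 && g.sel == 0 && unif_rand() < muA) g.sel = p.nextId++;
    return g;
  };
  auto paternal = [&]() {
    int fi = wdraw(cumM);
    Copy g;
    if (p.isX) {
      g = p.male[fi]; // unrecombined single X
    } else {
      g = meiosis(p.male[2 * fi], p.male[2 * fi + 1], p.L, p.selPos, rTotal);
    }
    mutate(g, p.L, muNTotal);
    if (muA > 0 && g.sel == 0 && unif_rand() < muA) g.sel = p.nextId++;
    return g;
  };

  for (int i = 0; i < nfp; ++i) {
    femN.push_back(maternal());
    femN.push_back(paternal());
  }
  for (int i = 0; i < nmp; ++i) {
    maleN.push_back(maternal());
    if (!p.isX) maleN.push_back(paternal());
  }
  p.fem = std::move(femN);
  p.male = std::move(maleN);
}

// drop neutral sites fixed in every copy (invisible as polymorphism)
static void compact(Pop &p) {
  std::unordered_map<double, int> cnt;
  int tot = p.copies();
  for (const Copy &c : p.fem) for (double x : c.pos) ++cnt[x];
  for (const Copy &c : p.male) for (double x : c.pos) ++cnt[x];
  auto strip = [&](Copy &c) {
    size_t j = 0;
    for (size_t i = 0; i < c.pos.size(); ++i)
      if (cnt[c.pos[i]] < tot) c.pos[j++] = c.pos[i];
    c.pos.resize(j);
  };
  for (Copy &c : p.fem) strip(c);
  for (Copy &c : p.male) strip(c);
}

static Pop pop_init(int N, bool isX, double L, double selPos,
                    const NumericMatrix &init, const NumericVector &initPos) {
  Pop p;
  p.isX = isX;
  p.L = L;
  p.selPos = selPos;
  int nf = N / 2, nm = N - N / 2;
  int need = isX ? (2 * nf + nm) : (2 * N);
  p.fem.resize(2 * nf);
  p.male.resize(isX ? nm : 2 * nm);
  if (init.nrow() > 0) {
    if (init.nrow() < need)
      stop("initial haplotype matrix has fewer rows than chromosome copies");
    auto fill = [&](Copy &c, int r) {
      for (int j = 0; j < init.ncol(); ++j)
        if (init(r, j) == 1) c.pos.push_back(initPos[j]);
    };
    int r = 0;
    for (Copy &c : p.fem) fill(c, r++);
    for (Copy &c : p.male) fill(c, r++);
  }
  return p;
}

// sample k copies uniformly without replacement; returns 0/1 matrix over the
// union of segregating neutral positions, plus selected-site origin labels
static List take_sample(const Pop &p, int k) {
  int tot = p.copies();
  if (k > tot) stop("sample size exceeds chromosome copy count");
  std::vector<int> idx(tot);
  for (int i = 0; i < tot; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (tot - i));
    if (j >= tot) j = tot - 1;
    std::swap(idx[i], idx[j]);
  }
  std::vector<const Copy *> chosen(k);
  for (int i = 0; i < k; ++i) {
    int r = idx[i];
    chosen[i] = (r < (int)p.fem.size()) ? &p.fem[r]
                                        : &p.male[r - p.fem.size()];
  }
  // union of positions segregating within the sample
  std::unordered_map<double, int> cnt;
  for (int i = 0; i < k; ++i)
    for (double x : chosen[i]->pos) ++cnt[x];
  std::vector<double> sites;
  sites.reserve(cnt.size());
  for (auto &kv : cnt)
    if (kv.second > 0 && kv.second < k) sites.push_back(kv.first);
  std::sort(sites.begin(), sites.end());
  IntegerMatrix mat(k, (int)sites.size());
  for (int i = 0; i < k; ++i) {
    const std::vector<double> &ps = chosen[i]->pos;
    size_t a = 0;
    for (int j = 0; j < (int)sites.size(); ++j) {
      while (a < ps.size() && ps[a] < sites[j]) ++a;
      mat(i, j) = (a < ps.size() && ps[a] == sites[j]) ? 1 : 0;
    }
  }
  IntegerVector sel(k);
  for (int i = 0; i < k; ++i) sel[i] = chosen[i]->sel;
  return List::create(_["haplotypes"] = mat,
                      _["positions"] = NumericVector(sites.begin(), sites.end()),
                      _["selOrigin"] = sel);
}

} // namespace

// Neutral forward run: start from optional standing haplotypes, evolve
// `gens` generations with s = 0, sample k copies.
// [[Rcpp::export]]
List cs_neutral_run(int N, bool isX, double L, double muNTotal,
                    double rTotal, double gens, int k,
                    NumericMatrix init, NumericVector initPos) {
  RNGScope scope;
  Pop p = pop_init(N, isX, L, L / 2.0, init, initPos);
  for (double g = 0; g < gens; ++g) {
    generation(p, 0, 0, 0, 0, 0.0, muNTotal, rTotal);
    if (((long)g) % 25 == 24) compact(p);
  }
  compact(p);
  return take_sample(p, k);
}

// ABC-style training replicate: recurrent adaptive mutation + selection
// until the selected-allele frequency first reaches PF (or maxGens), then
// selection and adaptive mutation cease and the population drifts for
// decayGens generations before sampling.  With introduceFirst the first
// origin is placed at generation 0 on a random copy (conditioning on the
// sweep starting immediately: the pre-sweep waiting time is dead time at
// neutral equilibrium) and loss of all derived copies before PF restarts
// the attempt from the stored initial population, up to maxRestarts.
// muNSweepFactor scales the neutral mutation rate during the selective
// phase: under rescaling the per-sweep mutation load mu_window x duration
// shrinks to near zero at full size while desk-scale rates are inflated
// by Q, so the sweep phase runs at a reduced rate that restores the
// full-scale load; the decay phase uses the full rate (its length is
// already chosen erosion-invariant).
// [[Rcpp::export]]
List cs_training_run(int N, bool isX, double L, double muNTotal,
                     double rTotal, double muA, double s, double h,
                     double PF, double decayGens, double maxGens, int k,
                     bool introduceFirst, int maxRestarts,
                     double muNSweepFactor,
                     NumericMatrix init, NumericVector initPos) {
  RNGScope scope;
  Pop init_p = pop_init(N, isX, L, L / 2.0, init, initPos);
  int tot = init_p.copies();
  Pop p;
  double g = 0;
  bool reached = false;
  int restarts = 0;
  while (true) {
    p = init_p;
    if (introduceFirst) {
      int r = (int)(unif_rand() * tot);
      if (r >= tot) r = tot - 1;
      if (r < (int)p.fem.size()) p.fem[r].sel = p.nextId++;
      else p.male[r - p.fem.size()].sel = p.nextId++;
    }
    bool lost = false;
    for (g = 0; g < maxGens; ++g) {
      generation(p, s, h, s, h, muA, muNTotal * muNSweepFactor, rTotal);
      if (((long)g) % 25 == 24) compact(p);
      int d = p.derived();
      if ((double)d / tot >= PF) { reached = true; break; }
      if (introduceFirst && d == 0 && muA * tot < 0.05) { lost = true; break; }
    }
    if (!lost || restarts >= maxRestarts) break;
    ++restarts;
  }
  for (double d = 0; d < decayGens; ++d) {
    generation(p, 0, 0, 0, 0, 0.0, muNTotal, rTotal);
    if (((long)d) % 25 == 24) compact(p);
  }
  compact(p);
  List out = take_sample(p, k);
  out["reachedPF"] = reached;
  out["sweepGens"] = g;
  out["restarts"] = restarts;
  out["finalFreq"] = (double)p.derived() / tot;
  return out;
}

// Single-origin standing-variation sweep: one mutation is introduced on a
// random copy; phase 1 runs under (sD, hD) until frequency >= PF (loss
// restarts from the stored initial population, up to maxRestarts); phase 2
// switches to (sB, hB) and runs to fixation or loss.
// [[Rcpp::export]]
List cs_single_origin_run(int N, bool isX, double L, double muNTotal,
                          double rTotal, double sD, double hD, double PF,
                          double sB, double hB, double maxGens,
                          int maxRestarts, int k,
                          NumericMatrix init, NumericVector initPos) {
  RNGScope scope;
  Pop init_p = pop_init(N, isX, L, L / 2.0, init, initPos);
  int tot = init_p.copies();
  int restarts = 0;
  std::string status = "cap";
  Pop p;
  while (restarts <= maxRestarts) {
    p = init_p;
    // introduce the variant on one uniformly-chosen copy
    int r = (int)(unif_rand() * tot);
    if (r >= tot) r = tot - 1;
    if (r < (int)p.fem.size()) p.fem[r].sel = 1;
    else p.male[r - p.fem.size()].sel = 1;
    bool lostPre = false, reached = false;
    for (double g = 0; g < maxGens; ++g) {
      generation(p, sD, hD, sD, hD, 0.0, muNTotal, rTotal);
      if (((long)g) % 25 == 24) compact(p);
      int d = p.derived();
      if (d == 0) { lostPre = true; break; }
      if ((double)d / tot >= PF) { reached = true; break; }
    }
    if (lostPre) { ++restarts; continue; }
    if (!reached) { status = "cap"; break; }
    // phase 2: beneficial
    status = "cap";
    for (double g = 0; g < maxGens; ++g) {
      generation(p, sB, hB, sB, hB, 0.0, muNTotal, rTotal);
      if (((long)g) % 25 == 24) compact(p);
      int d = p.derived();
      if (d == 0) { status = "lost"; break; }
      if (d == tot) { status = "fixed"; break; }
    }
    break;
  }
  if (restarts > maxRestarts)
    stop("restart cap exceeded before the conditioning frequency was reached");
  compact(p);
  List out = take_sample(p, k);
  out["status"] = status;
  out["restarts"] = restarts;
  return out;
}
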