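// Sliding-window haplotype-homozygosity scan.
//
// Windows are n consecutive SNPs stepping by one SNP.  Within a window a
// haplotype with more than maxMissFrac missing calls is assigned its own
// class of frequency 1/N; remaining haplotypes are grouped by exact
// identity over the window's SNPs with residual missing calls treated as a
// distinct allele state.  Optional per-window down-sampling draws
// downTo SNPs without replacement from the window (fresh draw per window,
// from R's RNG stream).

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct HOut {
  double h1, h2, h12, h2h1;
  int nForced;
};

static HOut window_stats(const IntegerMatrix &m,
                         const std::vector<int> &cols, double maxMiss) {
  int n = m.nrow();
  int w = (int)cols.size();
  std::unordered_map<std::string, int> classes;
  int forced = 0;
  std::string key(w, '0');
  for (int i = 0; i < n; ++i) {
    int miss = 0;
    for (int j = 0; j < w; ++j) {
      int v = m(i, cols[j]);
      if (v == NA_INTEGER) {
        ++miss;
        key[j] = '2';
      } else {
        key[j] = (char)('0' + v);
      }
    }
    if ((double)miss / w > maxMiss) {
      ++forced;
    } else {
      ++classes[key];
    }
  }
  std::vector<double> p;
  p.reserve(classes.size() + forced);
  for (auto &kv : classes) p.push_back((double)kv.second / n);
  for (int i = 0; i < forced; ++i) p.push_back(1.0 / n);
  std::sort(p.begin(), p.end(), std::greater<double>());
  double h1 = 0;
  for (double x : p) h1 += x * x;
  double p1 = p.empty() ? 0 : p[0];
  double p2 = p.size() > 1 ? p[1] : 0;
  double h12 = (p1 + p2) * (p1 + p2);
  for (size_t i = 2; i < p.size(); ++i) h12 += p[i] * p[i];
  double h2 = h1 - p1 * p1;
  HOut o;
  o.h1 = h1;
  o.h2 = h2;
  o.h12 = h12;
  o.h2h1 = h1 > 0 ? h2 / h1 : 0.0;
  o.nForced = forced;
  return o;
}

} // namespace

// [[Rcpp::export]]
DataFrame cpp_sliding_h12(IntegerMatrix haps, NumericVector positions,
                          int nSnps, int downTo, double maxMissFrac) {
  RNGScope scope;
  int m = haps.ncol();
  if (m < nSnps) stop("window spec larger than the data");
  int nw = m - nSnps + 1;
  NumericVector start(nw), end(nw), center(nw), h12(nw), h2h1(nw), h1(nw),
      h2(nw);
  IntegerVector forced(nw);
  std::vector<int> cols(downTo > 0 ? downTo : nSnps);
  for (int w = 0; w < nw; ++w) {
    if (downTo > 0 && downTo < nSnps) {
      // partial Fisher-Yates draw of downTo offsets in [0, nSnps)
      std::vector<int> pool(nSnps);
      for (int i = 0; i < nSnps; ++i) pool[i] = i;
      for (int i = 0; i < downTo; ++i) {
        int j = i + (int)(unif_rand() * (nSnps - i));
        if (j >= nSnps) j = nSnps - 1;
        std::swap(pool[i], pool[j]);
      }
      pool.resize(downTo);
      std::sort(pool.begin(), pool.end());
      for (int i = 0; i < downTo; ++i) cols[i] = w + pool[i];
    } else {
      cols.resize(nSnps);
      for (int i = 0; i < nSnps; ++i) cols[i] = w + i;
    }
    HOut o = window_stats(haps, cols, maxMissFrac);
    start[w] = positions[w];
    end[w] = positions[w + nSnps - 1];
    center[w] = (start[w] + end[w]) / 2.0;
    h1[w] = o.h1;
    h2[w] = o.h2;
    h12[w] = o.h12;
    h2h1[w] = o.h2h1;
    forced[w] = o.nForced;
  }
  return DataFrame::create(
      _["start"] = start, _["end"] = end, _["center"] = center,
      _["h1"] = h1, _["h2"] = h2, _["h12"] = h12, _["h2h1"] = h2h1,
      _["nForced"] = forced);
}
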