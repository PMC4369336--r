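#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Size-varying sliding-window CNV scan over one chromosome.
//
// x      : per-base depth in standard-deviation units (NaN where undefined)
// ab     : per-base abnormality direction (-1 deletion-like, +1
//          duplication-like, 0 normal) from the raw-depth screen
// hard   : bases that windows must never include (excessive-coverage mask)
// mu, sg : window-mean distribution parameters for every window size
//          w_min..w_max (length w_max - w_min + 1)
// zthr   : |z| threshold equivalent to the one-sided tail probability alpha
//
// A candidate base j must be abnormal and have at least half of
// [j, j + w_min) abnormal in the same direction. The window grows in
// one-base increments while at least half its bases stay abnormal; a call
// fires when the window z exceeds the threshold in the tested direction.
// After reaching w_max a w_max-sized window slides right while it stays
// significant and half-abnormal; the end breakpoint is the last abnormal
// base within the final passing window. Scanning resumes after a call.
// [[Rcpp::export(name = ".scan_cnv_chrom")]]
DataFrame scan_cnv_chrom(NumericVector x, IntegerVector ab, LogicalVector hard,
                         NumericVector mu, NumericVector sg,
                         int wmin, int wmax, double zthr) {
  const int n = x.size();
  std::vector<double> px(n + 1, 0.0);
  std::vector<int> pv(n + 1, 0), pd(n + 1, 0), pu(n + 1, 0), ph(n + 1, 0);
  for (int i = 0; i < n; i++) {
    const double xi = x[i];
    const bool val = !ISNAN(xi);
    px[i + 1] = px[i] + (val ? xi : 0.0);
    pv[i + 1] = pv[i] + (val ? 1 : 0);
    pd[i + 1] = pd[i] + (ab[i] == -1 ? 1 : 0);
    pu[i + 1] = pu[i] + (ab[i] == 1 ? 1 : 0);
    ph[i + 1] = ph[i] + (hard[i] ? 1 : 0);
  }
  std::vector<int> rs, re, rdir;
  std::vector<double> rz;
  int j = 0;  // 0-based window start
  while (j + wmin <= n) {
    const int d = ab[j];
    if (d == 0) { j++; continue; }
    if (ph[j + wmin] - ph[j] > 0) { j++; continue; }
    const std::vector<int>& pa = (d == -1) ? pd : pu;
    if (2 * (pa[j + wmin] - pa[j]) < wmin) { j++; continue; }

    bool called = false;
    double bestz = 0.0;
    int lastsig = wmin, lastl = wmin - 1;
    const int lmaxfit = std::min(wmax, n - j);
    for (int l = wmin; l <= lmaxfit; l++) {
      if (hard[j + l - 1]) break;
      if (2 * (pa[j + l] - pa[j]) < l) break;
      const int nv = pv[j + l] - pv[j];
      lastl = l;
      if (nv == 0) continue;
      const double mean = (px[j + l] - px[j]) / nv;
      double s = sg[l - wmin];
      if (s <= 0) s = 1e-12;
      const double z = (mean - mu[l - wmin]) / s;
      const bool sig = (d == -1) ? (z < -zthr) : (z > zthr);
      if (sig) {
        called = true;
        lastsig = l;
        if (std::fabs(z) > std::fabs(bestz)) bestz = z;
      }
    }
    if (!called) { j++; continue; }

    int call_end;
    if (lastl == wmax) {
      // extension: slide a w_max window right while it keeps passing
      double mu_m = mu[wmax - wmin];
      double sg_m = sg[wmax - wmin];
      if (sg_m <= 0) sg_m = 1e-12;
      int s = j, last_pass = j;
      while (s + wmax <= n) {
        if (ph[s + wmax] - ph[s] > 0) break;
        if (2 * (pa[s + wmax] - pa[s]) < wmax) break;
        const int nv = pv[s + wmax] - pv[s];
        if (nv == 0) break;
        const double z = ((px[s + wmax] - px[s]) / nv - mu_m) / sg_m;
        const bool sig = (d == -1) ? (z < -zthr) : (z > zthr);
        if (!sig) break;
        if (std::fabs(z) > std::fabs(bestz)) bestz = z;
        last_pass = s;
        s++;
      }
      call_end = last_pass + wmax - 1;
    } else {
      // largest significant window; the refinement below trims overshoot
      call_end = j + lastsig - 1;
    }
    // refine the end breakpoint: last maximizer over the call span of
    // (abnormal count) - (span / 2), i.e. the changepoint where the local
    // abnormal density drops below one half. Extending past the true end
    // costs proportionally to the distance, so isolated background-abnormal
    // bases far from the event cannot drag the breakpoint out. The
    // maximizer is always an abnormal base.
    {
      const int emin = j + wmin - 1;
      double best = -1e18;
      int beste = emin;
      for (int e = emin; e <= call_end; e++) {
        const double a = (pa[e + 1] - pa[j]) - 0.5 * (e - j + 1);
        if (a >= best) { best = a; beste = e; }
      }
      call_end = beste;
    }
    // mirrored refinement of the start breakpoint (leftmost maximizer);
    // trims leading stretches whose abnormal density is below one half
    int call_start = j;
    {
      const int smax = call_end - wmin + 1;
      double best = -1e18;
      for (int s = j; s <= smax; s++) {
        const double a = (pa[call_end + 1] - pa[s]) - 0.5 * (call_end - s + 1);
        if (a > best) { best = a; call_start = s; }
      }
    }
    rs.push_back(call_start + 1);
    re.push_back(call_end + 1);
    rdir.push_back(d);
    rz.push_back(bestz);
    j = call_end + 1;
  }
  return DataFrame::create(_["start"] = rs, _["end"] = re,
                           _["dir"] = rdir, _["z"] = rz);
}
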