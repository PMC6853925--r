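#include <Rcpp.h>
using namespace Rcpp;

// Per-core XP-EHH kernel.
//
// For one core SNP and one direction, haplotypes are extended marker by
// marker; group identity is the allele string from the core outward (core
// allele included). Only markers at which the POOLED EHH drops are decay
// points; between decay points the curves are linear (trapezoid rule).
// Integration of the two population curves stops at the distance where the
// pooled EHH crosses `cutoff` (linear interpolation); if the contig end is
// reached first the side is flagged truncated.

static inline double pair_frac(const std::vector<int> &cnt, double denom) {
  double s = 0.0;
  for (size_t i = 0; i < cnt.size(); ++i)
    s += (double)cnt[i] * (cnt[i] - 1);
  return s / 2.0 / denom;
}

// [[Rcpp::export(name = ".xpehh_scan_cpp")]]
NumericMatrix xpehh_scan_cpp(const IntegerMatrix hap,
                             const NumericVector pos,
                             const IntegerVector cores,   // 1-based
                             const IntegerVector obs_rows, // 1-based
                             const IntegerVector ref_rows, // 1-based
                             const double cutoff) {
  const int n = hap.nrow();
  const int S = hap.ncol();
  const int n_obs = obs_rows.size();
  const int n_ref = ref_rows.size();
  const double d_all = (double)n * (n - 1) / 2.0;
  const double d_obs = (double)n_obs * (n_obs - 1) / 2.0;
  const double d_ref = (double)n_ref * (n_ref - 1) / 2.0;

  NumericMatrix out(cores.size(), 3); // ihh_obs, ihh_ref, truncated
  std::vector<int> g(n), newid, cnt, cnt_pop;

  for (int ci = 0; ci < cores.size(); ++ci) {
    const int core = cores[ci] - 1;
    double area_obs = 0.0, area_ref = 0.0;
    bool truncated = false;

    for (int dir = -1; dir <= 1; dir += 2) {
      // groups start as the core allele
      for (int i = 0; i < n; ++i) g[i] = hap(i, core);
      int n_groups = 2;
      double d_prev = 0.0, ea_prev = 1.0, eo_prev = 1.0, er_prev = 1.0;
      bool crossed = false;

      for (int m = core + dir; m >= 0 && m < S; m += dir) {
        // refine groups by the allele at marker m, relabel densely
        newid.assign(2 * n_groups + 2, -1);
        int next = 0;
        for (int i = 0; i < n; ++i) {
          int key = 2 * g[i] + hap(i, m);
          if (newid[key] < 0) newid[key] = next++;
          g[i] = newid[key];
        }
        n_groups = next;

        cnt.assign(n_groups, 0);
        for (int i = 0; i < n; ++i) cnt[g[i]]++;
        double e_all = pair_frac(cnt, d_all);
        if (e_all < ea_prev) {
          double d = std::abs(pos[m] - pos[core]);
          cnt_pop.assign(n_groups, 0);
          for (int i = 0; i < n_obs; ++i) cnt_pop[g[obs_rows[i] - 1]]++;
          double e_obs = pair_frac(cnt_pop, d_obs);
          cnt_pop.assign(n_groups, 0);
          for (int i = 0; i < n_ref; ++i) cnt_pop[g[ref_rows[i] - 1]]++;
          double e_ref = pair_frac(cnt_pop, d_ref);

          if (e_all >= cutoff) {
            area_obs += (eo_prev + e_obs) / 2.0 * (d - d_prev);
            area_ref += (er_prev + e_ref) / 2.0 * (d - d_prev);
            d_prev = d; ea_prev = e_all; eo_prev = e_obs; er_prev = e_ref;
          } else {
            // pooled curve crosses the cutoff between d_prev and d
            double frac = (ea_prev - cutoff) / (ea_prev - e_all);
            double bound = d_prev + frac * (d - d_prev);
            double eo_at = eo_prev + frac * (e_obs - eo_prev);
            double er_at = er_prev + frac * (e_ref - er_prev);
            area_obs += (eo_prev + eo_at) / 2.0 * (bound - d_prev);
            area_ref += (er_prev + er_at) / 2.0 * (bound - d_prev);
            crossed = true;
            break;
          }
        } else if (e_all < cutoff) { // can only happen when already below
          crossed = true;
          break;
        }
      }
      if (!crossed) truncated = true;
    }
    out(ci, 0) = area_obs;
    out(ci, 1) = area_ref;
    out(ci, 2) = truncated ? 1.0 : 0.0;
  }
  return out;
}
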