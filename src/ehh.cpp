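// Integrated EHH scan.
//
// EHH at marker x for a core allele is the probability that two random
// carrier haplotypes are identical over every marker between the core and
// x inclusive: sum_g C(e_g,2) / C(c,2) over the identity groups g.  iHH is
// the trapezoid integral of (EHH - cutoff)+ against physical position,
// walked outward from the core on each side, truncated where EHH drops
// below the cutoff, at an inter-marker gap larger than max_gap, or at the
// chromosome end.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// one-sided integral for the haplotypes in `rows` at core column `core`,
// stepping by `dir` (+1 right, -1 left)
static double side_ihh(const IntegerMatrix& haps, const NumericVector& pos,
                       const std::vector<int>& rows, int core, int dir,
                       double cutoff, double max_gap) {
  const int c = rows.size();
  const int m = haps.ncol();
  const double denom = 0.5 * c * (c - 1);
  std::vector<int> grp(c, 0);
  std::vector<int> remap;
  int n_grp = 1;
  double ehh_prev = 1.0, pos_prev = pos[core], ihh = 0.0;
  for (int k = core + dir; k >= 0 && k < m; k += dir) {
    double gap = std::fabs(pos[k] - pos_prev);
    if (gap > max_gap) break;
    // split groups by the allele at marker k
    remap.assign(2 * n_grp, -1);
    int nxt = 0;
    std::vector<int> cnt;
    for (int i = 0; i < c; ++i) {
      int key = 2 * grp[i] + haps(rows[i], k);
      if (remap[key] < 0) {
        remap[key] = nxt++;
        cnt.push_back(0);
      }
      grp[i] = remap[key];
      cnt[grp[i]]++;
    }
    n_grp = nxt;
    double hom = 0.0;
    for (int g = 0; g < n_grp; ++g) hom += 0.5 * cnt[g] * (cnt[g] - 1);
    double ehh = hom / denom;
    double a = ehh_prev - cutoff, b = ehh - cutoff;
    if (a < 0) a = 0;
    if (b < 0) b = 0;
    ihh += 0.5 * (a + b) * gap;
    if (ehh < cutoff || ehh <= 0.0) break;
    ehh_prev = ehh;
    pos_prev = pos[k];
  }
  return ihh;
}

// [[Rcpp::export(name = ".ihh_scan_cpp")]]
NumericMatrix ihh_scan_cpp(IntegerMatrix haps, NumericVector pos,
                           double min_maf, double cutoff, double max_gap) {
  const int n = haps.nrow(), m = haps.ncol();
  NumericMatrix out(m, 3); // derived_freq, ihh_a, ihh_d
  std::vector<int> anc, der;
  for (int j = 0; j < m; ++j) {
    anc.clear();
    der.clear();
    for (int i = 0; i < n; ++i) {
      if (haps(i, j) == 1) der.push_back(i); else anc.push_back(i);
    }
    double q = (double)der.size() / n;
    out(j, 0) = q;
    out(j, 1) = NA_REAL;
    out(j, 2) = NA_REAL;
    if (q < min_maf || q > 1.0 - min_maf) continue;
    if (der.size() < 2 || anc.size() < 2) continue;
    out(j, 1) = side_ihh(haps, pos, anc, j, -1, cutoff, max_gap) +
                side_ihh(haps, pos, anc, j, +1, cutoff, max_gap);
    out(j, 2) = side_ihh(haps, pos, der, j, -1, cutoff, max_gap) +
                side_ihh(haps, pos, der, j, +1, cutoff, max_gap);
  }
  return out;
}
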