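#include <Rcpp.h>
#include <algorithm>
#include <cfloat>
#include <vector>

using namespace Rcpp;

// Rank one statistic column: rank 1 = largest d.  Ties and excluded
// peptides (d replaced by -DBL_MAX upstream) are broken by row index.
// (d, index) pairs are sorted contiguously for cache locality; the explicit
// index tie-break reproduces a stable sort.
static void rank_column(std::vector<std::pair<double, int> >& di,
                        std::vector<int>& rank) {
  const int F = (int)di.size();
  std::sort(di.begin(), di.end(),
            [](const std::pair<double, int>& a,
               const std::pair<double, int>& b) {
              return a.first > b.first ||
                     (a.first == b.first && a.second < b.second);
            });
  for (int i = 0; i < F; ++i) rank[di[i].second] = i + 1;
}

// Mean and SD of top-k overlaps over disjoint consecutive pairs of resample
// columns, for every statistic in the family and every k in kgrid.
//
// absdiff, se: F x C matrices of |group mean difference| and pooled SE per
// peptide and resampled dataset; NA marks a peptide untestable in that
// resample (it ranks last).  C must be even; columns (0,1), (2,3), ... form
// the pairs.  The statistic family is: |diff| (fold change, alpha2 = 0,
// included when include_fc) followed by |diff| / (alpha1 + se) for each
// alpha1.  A non-positive denominator excludes the peptide (ranks last).
//
// Overlap at k is computed via the identity
//   |top_k(a) /\ top_k(b)| = #{ i : max(rank_a(i), rank_b(i)) <= k },
// one O(F) tabulation per pair serving every k at once.
// [[Rcpp::export]]
List rots_profile_cpp(NumericMatrix absdiff, NumericMatrix se,
                      NumericVector alpha1, bool include_fc,
                      IntegerVector kgrid) {
  const int F = absdiff.nrow(), C = absdiff.ncol();
  if (C % 2 != 0) stop("resample column count must be even");
  const int P = C / 2;
  const int A = alpha1.size();
  const int S = A + (include_fc ? 1 : 0);
  const int K = kgrid.size();
  for (int j = 0; j < K; ++j) {
    if (kgrid[j] < 1 || kgrid[j] > F) stop("k out of range 1..F");
    if (j > 0 && kgrid[j] <= kgrid[j - 1])
      stop("k grid must be strictly increasing");
  }

  NumericMatrix Rmean(S, K), Rsd(S, K);
  std::vector<std::pair<double, int> > di(F);
  std::vector<int> rank1(F), rank2(F), cnt(F + 1);

  for (int s = 0; s < S; ++s) {
    const bool fc = include_fc && s == 0;
    const double a1 = fc ? 0.0 : alpha1[s - (include_fc ? 1 : 0)];
    std::vector<double> sum(K, 0.0), sumsq(K, 0.0);
    for (int p = 0; p < P; ++p) {
      for (int half = 0; half < 2; ++half) {
        const int c = 2 * p + half;
        const double* ad_col = &absdiff(0, c);
        const double* se_col = &se(0, c);
        for (int i = 0; i < F; ++i) {
          const double ad = ad_col[i];
          double d;
          if (!R_finite(ad)) d = -DBL_MAX;
          else if (fc) d = ad;
          else {
            const double denom = a1 + se_col[i];
            d = (R_finite(denom) && denom > 0.0) ? ad / denom : -DBL_MAX;
          }
          di[i] = std::make_pair(d, i);
        }
        rank_column(di, half ? rank2 : rank1);
      }
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int i = 0; i < F; ++i) {
        const int m = std::max(rank1[i], rank2[i]);
        cnt[m]++;
      }
      int cum = 0, j = 0;
      for (int k = 1; k <= F && j < K; ++k) {
        cum += cnt[k];
        while (j < K && kgrid[j] == k) {
          const double ov = (double)cum / (double)k;
          sum[j] += ov;
          sumsq[j] += ov * ov;
          ++j;
        }
      }
    }
    for (int j = 0; j < K; ++j) {
      const double mean = sum[j] / P;
      double sd = 0.0;
      if (P > 1) {
        double var = (sumsq[j] - P * mean * mean) / (P - 1);
        if (var < 0) var = 0;
        sd = std::sqrt(var);
      }
      Rmean(s, j) = mean;
      Rsd(s, j) = sd;
    }
  }
  return List::create(_["R"] = Rmean, _["sd"] = Rsd);
}
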