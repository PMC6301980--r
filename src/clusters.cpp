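#include <Rcpp.h>
using namespace Rcpp;

// Max summed statistic over runs of supra-threshold bins, per row.
// Runs never span a segment boundary; `seg_ends` are 1-based last bins.
// [[Rcpp::export]]
NumericVector max_cluster_sums(NumericMatrix F, double thresh,
                               IntegerVector seg_ends) {
  int nr = F.nrow(), nc = F.ncol();
  NumericVector out(nr);
  std::vector<bool> boundary(nc, false);
  for (int k = 0; k < seg_ends.size(); ++k) {
    int e = seg_ends[k];
    if (e >= 1 && e < nc) boundary[e - 1] = true;  // break after this bin
  }
  for (int i = 0; i < nr; ++i) {
    double best = 0.0, cur = 0.0;
    for (int j = 0; j < nc; ++j) {
      double v = F(i, j);
      if (v > thresh) {
        cur += v;
        if (cur > best) best = cur;
      } else {
        cur = 0.0;
      }
      if (boundary[j]) cur = 0.0;
    }
    out[i] = best;
  }
  return out;
}

// Enumerate clusters (start, end, summed F) of one statistic series.
// [[Rcpp::export]]
DataFrame find_clusters(NumericVector f, double thresh,
                        IntegerVector seg_ends) {
  int nc = f.size();
  std::vector<bool> boundary(nc, false);
  for (int k = 0; k < seg_ends.size(); ++k) {
    int e = seg_ends[k];
    if (e >= 1 && e < nc) boundary[e - 1] = true;
  }
  std::vector<int> start, end;
  std::vector<double> sum;
  int cs = -1;
  double acc = 0.0;
  for (int j = 0; j < nc; ++j) {
    if (f[j] > thresh) {
      if (cs < 0) { cs = j; acc = 0.0; }
      acc += f[j];
    }
    bool close = (cs >= 0) && (f[j] <= thresh || boundary[j] || j == nc - 1);
    if (close) {
      int ce = (f[j] > thresh) ? j : j - 1;
      start.push_back(cs + 1);
      end.push_back(ce + 1);
      sum.push_back(acc);
      cs = -1;
    }
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["sum_F"] = sum);
}
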