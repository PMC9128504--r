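#include <Rcpp.h>
using namespace Rcpp;

// Pairwise between-community mean nearest taxon distance for one pool.
// fw: k x t row-normalized weights (zero for absent taxa); pres: k x t
// presence; dis: t x t patristic distances. Returns the symmetric k x k
// matrix of averaged directional weighted means, zero diagonal.
// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix fw, LogicalMatrix pres,
                        NumericMatrix dis) {
  const int k = fw.nrow(), t = fw.ncol();
  NumericMatrix md(t, k);
  std::fill(md.begin(), md.end(), R_PosInf);
  for (int s = 0; s < k; s++) {
    double *mcol = &md(0, s);
    for (int j = 0; j < t; j++) {
      if (!pres(s, j)) continue;
      const double *dcol = &dis(0, j);
      for (int i = 0; i < t; i++)
        if (dcol[i] < mcol[i]) mcol[i] = dcol[i];
    }
  }
  NumericMatrix dd(k, k);
  for (int b = 0; b < k; b++) {
    const double *mcol = &md(0, b);
    for (int a = 0; a < k; a++) {
      double acc = 0.0;
      for (int i = 0; i < t; i++) {
        const double w = fw(a, i);
        if (w > 0) acc += w * mcol[i];
      }
      dd(a, b) = acc;
    }
  }
  NumericMatrix out(k, k);
  for (int a = 0; a < k; a++)
    for (int b = 0; b < k; b++)
      out(a, b) = (dd(a, b) + dd(b, a)) / 2.0;
  for (int a = 0; a < k; a++) out(a, a) = 0.0;
  return out;
}

// Per-sample mean nearest taxon distance for a pool. comm: k x t
// abundances; returns NA for samples with fewer than two taxa.
// [[Rcpp::export]]
NumericVector cpp_pool_mntd(NumericMatrix comm, NumericMatrix dis,
                            bool weighted) {
  const int k = comm.nrow(), t = comm.ncol();
  NumericVector out(k);
  std::vector<int> idx;
  for (int s = 0; s < k; s++) {
    idx.clear();
    for (int j = 0; j < t; j++)
      if (comm(s, j) > 0) idx.push_back(j);
    const int n = (int) idx.size();
    if (n < 2) { out[s] = NA_REAL; continue; }
    double num = 0.0, den = 0.0;
    for (int ii = 0; ii < n; ii++) {
      const int i = idx[ii];
      double m = R_PosInf;
      for (int jj = 0; jj < n; jj++) {
        if (jj == ii) continue;
        const double v = dis(i, idx[jj]);
        if (v < m) m = v;
      }
      const double w = weighted ? comm(s, i) : 1.0;
      num += w * m;
      den += w;
    }
    out[s] = num / den;
  }
  return out;
}
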