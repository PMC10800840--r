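#include <Rcpp.h>
using namespace Rcpp;

// Pairwise beta mean nearest taxon distance.
//
// relab: samples x taxa relative abundances (rows sum to 1 over present taxa
//        when weighted; presence/absence handled by the caller for the
//        unweighted case by passing equal weights).
// dmat:  taxa x taxa cophenetic distances, in the table's taxon order.
// perm:  0-based permutation of taxa (the taxa-shuffle null relabels tips,
//        i.e. taxon i takes the phylogenetic position perm[i]); identity for
//        the observed matrix.
//
// For samples k,l: 0.5 * [ sum_i f_ik * min_{j in l} d_ij
//                        + sum_j f_jl * min_{i in k} d_ij ],
// minima over taxa present (abundance > 0) in the other sample; a taxon
// present in both contributes its self-distance 0.
// [[Rcpp::export]]
NumericMatrix bmntd_pairwise(NumericMatrix relab, NumericMatrix dmat,
                             IntegerVector perm) {
  const int ns = relab.nrow();
  const int nt = relab.ncol();
  if (dmat.nrow() != nt || dmat.ncol() != nt)
    stop("distance matrix does not match taxon count");
  if (perm.size() != nt) stop("permutation length mismatch");

  // present taxa per sample
  std::vector< std::vector<int> > pres(ns);
  for (int s = 0; s < ns; ++s) {
    pres[s].reserve(nt);
    for (int t = 0; t < nt; ++t)
      if (relab(s, t) > 0.0) pres[s].push_back(t);
  }

  NumericMatrix out(ns, ns);
  for (int k = 0; k < ns; ++k) {
    const std::vector<int>& pk = pres[k];
    if (pk.empty()) stop("sample with no taxa present");
    for (int l = k + 1; l < ns; ++l) {
      const std::vector<int>& pl = pres[l];
      if (pl.empty()) stop("sample with no taxa present");
      double s1 = 0.0, s2 = 0.0;
      for (size_t a = 0; a < pk.size(); ++a) {
        const int i = perm[pk[a]];
        double dmin = R_PosInf;
        for (size_t b = 0; b < pl.size(); ++b) {
          const double d = dmat(i, perm[pl[b]]);
          if (d < dmin) dmin = d;
        }
        s1 += relab(k, pk[a]) * dmin;
      }
      for (size_t b = 0; b < pl.size(); ++b) {
        const int j = perm[pl[b]];
        double dmin = R_PosInf;
        for (size_t a = 0; a < pk.size(); ++a) {
          const double d = dmat(j, perm[pk[a]]);
          if (d < dmin) dmin = d;
        }
        s2 += relab(l, pl[b]) * dmin;
      }
      const double v = 0.5 * (s1 + s2);
      out(k, l) = v;
      out(l, k) = v;
    }
  }
  return out;
}

// Accumulate null moments for the taxa-shuffle null: given a matrix of
// permutations (n_null x n_taxa, 0-based), return per-pair running sums,
// sums of squares, and the global max null value (used by pNST scaling).
// [[Rcpp::export]]
List bmntd_null_moments(NumericMatrix relab, NumericMatrix dmat,
                        IntegerMatrix perms) {
  const int ns = relab.nrow();
  const int nrep = perms.nrow();
  NumericMatrix sum(ns, ns), sumsq(ns, ns);
  double maxval = R_NegInf;
  for (int r = 0; r < nrep; ++r) {
    IntegerVector perm = perms(r, _);
    NumericMatrix b = bmntd_pairwise(relab, dmat, perm);
    for (int k = 0; k < ns; ++k)
      for (int l = k + 1; l < ns; ++l) {
        const double v = b(k, l);
        sum(k, l) += v;
        sumsq(k, l) += v * v;
        if (v > maxval) maxval = v;
      }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["n"] = nrep, _["max"] = maxval);
}
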