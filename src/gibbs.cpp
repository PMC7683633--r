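#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the biterm topic model over event pairs.
// wi, wj: 0-based event-vocabulary ids per biterm (wi <= wj).
// Counts: nk[k] biterms assigned to topic k; nek(w,k) occurrences of event
// w in topic k (each biterm contributes two).  The conditional for biterm
// b is  P(z_b = k | z_-b, B)  proportional to
//   (n_k + alpha) * (n_i|k + beta)(n_j|k + beta + [i==j])
//     / ((2 n_k + W beta)(2 n_k + 1 + W beta)),
// the [i==j] correction making the chain exact when a biterm repeats one
// event token.  Post-burn-in iterations accumulate count sums and
// per-biterm topic frequencies (the sampled assignment marginals).

// [[Rcpp::export]]
List gibbs_btm_cpp(IntegerVector wi, IntegerVector wj, int K, double alpha,
                   double beta, int W, int iterations, int burn_in) {
  const int B = wi.size();
  IntegerVector z(B);
  std::vector<double> nk(K, 0.0);
  NumericMatrix nek(W, K);
  RNGScope scope;

  for (int b = 0; b < B; ++b) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[b] = k;
    nk[k] += 1.0;
    nek(wi[b], k) += 1.0;
    nek(wj[b], k) += 1.0;
  }

  std::vector<double> p(K);
  NumericVector nk_sum(K);
  NumericMatrix nek_sum(W, K);
  NumericMatrix zfreq(B, K);
  int nsamples = 0;

  for (int it = 0; it < iterations; ++it) {
    for (int b = 0; b < B; ++b) {
      const int i = wi[b], j = wj[b];
      int k = z[b];
      nk[k] -= 1.0;
      nek(i, k) -= 1.0;
      nek(j, k) -= 1.0;
      const double self = (i == j) ? 1.0 : 0.0;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        const double denom = 2.0 * nk[kk] + W * beta;
        const double val = (nk[kk] + alpha) *
          (nek(i, kk) + beta) * (nek(j, kk) + beta + self) /
          (denom * (denom + 1.0));
        p[kk] = val;
        tot += val;
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double cum = p[0];
      while (u > cum && knew < K - 1) {
        ++knew;
        cum += p[knew];
      }
      z[b] = knew;
      nk[knew] += 1.0;
      nek(i, knew) += 1.0;
      nek(j, knew) += 1.0;
    }
    if (it >= burn_in) {
      ++nsamples;
      for (int k = 0; k < K; ++k) nk_sum[k] += nk[k];
      for (int w = 0; w < W; ++w)
        for (int k = 0; k < K; ++k) nek_sum(w, k) += nek(w, k);
      for (int b = 0; b < B; ++b) zfreq(b, z[b]) += 1.0;
    }
  }

  return List::create(_["z"] = z, _["nk_sum"] = nk_sum,
                      _["nek_sum"] = nek_sum, _["zfreq"] = zfreq,
                      _["n_samples"] = nsamples);
}
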