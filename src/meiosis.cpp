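#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete sampler: one gamete per entry of `parent`.
//
// Recombination follows Haldane's model: per chromosome the crossover count
// is Poisson(map length in Morgan), crossover positions are uniform and
// there is no interference. The starting strand is chosen at random per
// chromosome. Mutation is a symmetric 0<->1 flip applied per transmitted
// allele with probability mut_rate (drawn as a Binomial(L, mut_rate) count
// with uniformly chosen loci).
//
// hapA/hapB are locus-major (L x N) so a haplotype is a contiguous column.
// All randomness comes from R's RNG (RNGScope via Rcpp attributes), so
// set.seed() makes gametes reproducible.
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& hapA, const IntegerMatrix& hapB,
                          const IntegerVector& parent,  // 0-based column indices
                          const NumericVector& pos,     // within-chromosome position, Morgan
                          const IntegerVector& chr_start,  // 0-based first locus per chromosome
                          const IntegerVector& chr_nloci,
                          const NumericVector& chr_len,    // Morgan
                          double mut_rate) {
  const int L = hapA.nrow();
  const int n = parent.size();
  const int nchr = chr_start.size();
  if (mut_rate < 0) stop("mutation rate must be non-negative");
  IntegerMatrix out(L, n);
  std::vector<double> bp;
  for (int g = 0; g < n; ++g) {
    const int pc = parent[g];
    if (pc < 0 || pc >= hapA.ncol()) stop("parent index out of range");
    const int* A = &hapA(0, pc);
    const int* B = &hapB(0, pc);
    int* O = &out(0, g);
    for (int c = 0; c < nchr; ++c) {
      const int s = chr_start[c], m = chr_nloci[c];
      const int k = (int) R::rpois(chr_len[c]);
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      if (k == 0) {
        const int* src = strand ? B : A;
        std::copy(src + s, src + s + m, O + s);
      } else {
        bp.resize(k);
        for (int i = 0; i < k; ++i) bp[i] = unif_rand() * chr_len[c];
        std::sort(bp.begin(), bp.end());
        int bi = 0;
        for (int j = s; j < s + m; ++j) {
          while (bi < k && bp[bi] <= pos[j]) { strand ^= 1; ++bi; }
          O[j] = strand ? B[j] : A[j];
        }
      }
    }
    if (mut_rate > 0) {
      const int nm = (int) R::rbinom((double) L, mut_rate);
      for (int i = 0; i < nm; ++i) {
        int j = (int) (unif_rand() * L);
        if (j >= L) j = L - 1;
        O[j] = 1 - O[j];
      }
    }
  }
  return out;
}
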