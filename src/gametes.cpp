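#include <Rcpp.h>
using namespace Rcpp;

// Gamete dropping over a marker map.
//
// rec[j] is the probability that the copied parental haplotype switches
// between locus j-1 and locus j (Haldane recombination fraction within a
// chromosome, 0.5 across a chromosome boundary).  rec[0] is ignored: the
// starting haplotype is chosen at random.  Uses R's RNG so results are
// reproducible through set.seed().

// [[Rcpp::export]]
IntegerMatrix cpp_drop_gametes(const IntegerMatrix& hapA,
                               const IntegerMatrix& hapB,
                               const IntegerVector& parent,
                               const NumericVector& rec) {
  const int nloci = hapA.ncol();
  const int ng = parent.size();
  if (hapB.ncol() != nloci)
    stop("haplotype matrices have different numbers of loci");
  IntegerMatrix out(ng, nloci);
  for (int g = 0; g < ng; ++g) {
    const int p = parent[g] - 1;
    if (p < 0 || p >= hapA.nrow()) stop("parent index out of range");
    bool useA = unif_rand() < 0.5;
    for (int j = 0; j < nloci; ++j) {
      if (j > 0 && unif_rand() < rec[j]) useA = !useA;
      out(g, j) = useA ? hapA(p, j) : hapB(p, j);
    }
  }
  return out;
}
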