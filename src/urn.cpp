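#include <Rcpp.h>
using namespace Rcpp;

// Sequential weighted-urn growth of a two-type mtDNA pool.
//
// Starting from `functional` + `dysfunctional` molecules, copies are added
// one at a time until the pool holds `target` molecules. Each addition
// duplicates an existing molecule chosen with per-copy weight 1
// (functional) versus 1 + delta (dysfunctional), so the sampling
// probabilities shift as the pool grows (a Polya-type urn). Uses R's RNG
// so results are governed by set.seed().

// [[Rcpp::export]]
IntegerVector urn_fill(int functional, int dysfunctional, double delta,
                       int target) {
  double f = functional, d = dysfunctional;
  if (f + d <= 0) stop("empty pool cannot replicate");
  if (target < f + d) stop("target below current pool size");
  while (f + d < target) {
    double pd = d * (1.0 + delta) / (f + d * (1.0 + delta));
    if (unif_rand() < pd) d += 1.0; else f += 1.0;
  }
  return IntegerVector::create((int)f, (int)d);
}

// Vectorised variant: grow many pools (one per row) to a shared target.
// [[Rcpp::export]]
IntegerMatrix urn_fill_many(IntegerVector functional,
                            IntegerVector dysfunctional, double delta,
                            int target) {
  int n = functional.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double f = functional[i], d = dysfunctional[i];
    if (f + d <= 0) stop("empty pool cannot replicate");
    if (target < f + d) stop("target below current pool size");
    while (f + d < target) {
      double pd = d * (1.0 + delta) / (f + d * (1.0 + delta));
      if (unif_rand() < pd) d += 1.0; else f += 1.0;
    }
    out(i, 0) = (int)f;
    out(i, 1) = (int)d;
  }
  return out;
}

// Weighted sampling without replacement of `draw` molecules from a pool,
// functional molecules having relative weight 1 + bias (selective import
// at the oocyte boundary). bias = 0 reduces to a hypergeometric draw.
// Returns c(functional_drawn, dysfunctional_drawn).

// [[Rcpp::export]]
IntegerVector biased_draw(int functional, int dysfunctional, double bias,
                          int draw) {
  if (draw > functional + dysfunctional)
    stop("draw exceeds pool size");
  double f = functional, d = dysfunctional, wf = 1.0 + bias;
  int gf = 0, gd = 0;
  for (int i = 0; i < draw; ++i) {
    double pf = f * wf / (f * wf + d);
    if (unif_rand() < pf) { f -= 1.0; ++gf; } else { d -= 1.0; ++gd; }
  }
  return IntegerVector::create(gf, gd);
}
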