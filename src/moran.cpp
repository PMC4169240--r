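#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Neutral Moran chain for one locus in a population of N mtDNA copies.
// Per event one copy (drawn with replacement) is duplicated and one is
// destroyed, so the mutant count k moves +1 with probability p(1-p),
// -1 with probability p(1-p) and stays otherwise, p = k/N.  We simulate
// the embedded jump chain: waiting times between changes are geometric
// with success probability c = 2 p (1-p); conditional on a change the
// step is +1 or -1 with probability 1/2.  Distribution-identical to
// per-event simulation, but O(number of changes) instead of O(events).
// States 0 and N are absorbing.  Uses R's RNG (deterministic under
// set.seed()).
static int locus_advance(int k, int N, double n_events) {
  double remaining = n_events;
  while (remaining >= 1.0 && k > 0 && k < N) {
    double p = (double)k / (double)N;
    double c = 2.0 * p * (1.0 - p);
    double u = unif_rand();
    if (u <= 0.0) u = DBL_MIN;
    // events consumed up to and including the next change (support 1, 2, ...)
    double g = std::floor(std::log(u) / std::log1p(-c)) + 1.0;
    if (g > remaining) return k;  // no further change within the horizon
    remaining -= g;
    k += (unif_rand() < 0.5) ? 1 : -1;
  }
  return k;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector moran_locus_cpp(IntegerVector k0, int N, double n_events) {
  if (N < 2) stop("N must be >= 2");
  if (n_events < 0) stop("n_events must be >= 0");
  R_xlen_t n = k0.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int k = k0[i];
    if (k < 0 || k > N) stop("copy count outside [0, N]");
    out[i] = locus_advance(k, N, n_events);
  }
  return out;
}

// Full crypt lifetime: new mutations arise at rate mut_rate per event
// (on the replicated copy), each starting at one copy and drifting
// independently (free-recombination approximation) until the horizon.
// Returns the copy counts of mutations surviving at the horizon plus the
// total number that ever arose.
// [[Rcpp::export]]
List moran_crypt_cpp(double n_events, int N, double mut_rate) {
  if (N < 2) stop("N must be >= 2");
  if (mut_rate < 0 || mut_rate > 1) stop("mut_rate must be in [0, 1]");
  if (n_events < 0) stop("n_events must be >= 0");
  double n_mut = ::Rf_rbinom(n_events, mut_rate);
  std::vector<double> arrival((size_t)n_mut);
  for (size_t i = 0; i < arrival.size(); ++i)
    arrival[i] = std::floor(unif_rand() * n_events);
  std::sort(arrival.begin(), arrival.end());
  std::vector<int> surv;
  for (size_t i = 0; i < arrival.size(); ++i) {
    int k = locus_advance(1, N, n_events - arrival[i] - 1.0);
    if (k > 0) surv.push_back(k);
  }
  return List::create(_["counts"] = wrap(surv),
                      _["n_arising"] = (double)arrival.size());
}
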