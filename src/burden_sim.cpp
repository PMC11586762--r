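// Monte-Carlo core: per-variant hypergeometric allele draws.
//
// Each simulated control cohort of N individuals draws 2N alleles without
// replacement from the AN_pop alleles of the population database, of which
// AC_pop are alternate; per-iteration totals are summed over variants.
// Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".sim_burden_totals")]]
IntegerVector sim_burden_totals(IntegerVector ac, IntegerVector an,
                                int n_draws, int iterations) {
  int V = ac.size();
  if (an.size() != V) stop("ac and an must have equal length");
  if (iterations < 1) stop("iterations must be >= 1");
  for (int v = 0; v < V; v++) {
    if (ac[v] < 0 || an[v] < 0 || ac[v] > an[v])
      stop("require 0 <= AC <= AN for every variant");
    if (an[v] < n_draws)
      stop("AN (%d) smaller than the 2*N = %d alleles to draw: population smaller than simulated cohort", an[v], n_draws);
  }
  IntegerVector totals(iterations, 0);
  RNGScope scope;
  for (int v = 0; v < V; v++) {
    if (ac[v] == 0) continue;
    double m = ac[v], n = an[v] - ac[v], k = n_draws;
    for (int i = 0; i < iterations; i++)
      totals[i] += (int)::Rf_rhyper(m, n, k);
  }
  return totals;
}

// Simulated collapsed genotype scores for control cohorts: per iteration the
// drawn alt alleles of each variant are assigned uniformly without replacement
// to the 2N allele slots of N individuals; an individual scores 2 if any
// variant occupies both of its slots, 1 if it carries any alt allele but no
// homozygous variant, 0 otherwise.
// Returns an iterations x 3 matrix of counts (n_score0, n_score1, n_score2).
// [[Rcpp::export(name = ".sim_control_scores")]]
IntegerMatrix sim_control_scores(IntegerVector ac, IntegerVector an,
                                 int n_individuals, int iterations) {
  int V = ac.size();
  int n_slots = 2 * n_individuals;
  for (int v = 0; v < V; v++) {
    if (ac[v] < 0 || an[v] < ac[v]) stop("require 0 <= AC <= AN");
    if (an[v] < n_slots) stop("AN smaller than 2*N");
  }
  IntegerMatrix out(iterations, 3);
  std::vector<int> slots(n_slots);
  std::vector<int> het(n_individuals), hom(n_individuals);
  RNGScope scope;
  for (int i = 0; i < iterations; i++) {
    std::fill(het.begin(), het.end(), 0);
    std::fill(hom.begin(), hom.end(), 0);
    for (int v = 0; v < V; v++) {
      if (ac[v] == 0) continue;
      int x = (int)::Rf_rhyper((double)ac[v], (double)(an[v] - ac[v]), (double)n_slots);
      if (x == 0) continue;
      // partial Fisher-Yates: sample x distinct slots out of n_slots
      for (int s = 0; s < n_slots; s++) slots[s] = s;
      std::vector<int> dose(n_individuals, 0);
      for (int d = 0; d < x; d++) {
        int r = d + (int)(unif_rand() * (n_slots - d));
        if (r >= n_slots) r = n_slots - 1;
        std::swap(slots[d], slots[r]);
        dose[slots[d] / 2]++;
      }
      for (int s = 0; s < n_individuals; s++) {
        if (dose[s] == 2) hom[s] = 1;
        else if (dose[s] == 1) het[s] = 1;
      }
    }
    int n2 = 0, n1 = 0;
    for (int s = 0; s < n_individuals; s++) {
      if (hom[s]) n2++;
      else if (het[s]) n1++;
    }
    out(i, 0) = n_individuals - n1 - n2;
    out(i, 1) = n1;
    out(i, 2) = n2;
  }
  return out;
}
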