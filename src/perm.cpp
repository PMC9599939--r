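#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// max |t| over admissible splits of x into x[0..i) / x[i..n); both sides
// must keep at least min_probes values. ss_tot = sum(x^2), tot = sum(x).
static double best_split_stat(const double* x, int n, int min_probes,
                              double tot, double ss_tot) {
  double best = R_NegInf;
  double s1 = 0.0;
  for (int i = 1; i < n; ++i) {
    s1 += x[i - 1];
    if (i < min_probes || (n - i) < min_probes) continue;
    double m1 = s1 / i;
    double m2 = (tot - s1) / (n - i);
    double ss_within = ss_tot - i * m1 * m1 - (n - i) * m2 * m2;
    if (ss_within < 0) ss_within = 0;
    double se2 = ss_within / (n - 2) * (1.0 / i + 1.0 / (n - i));
    double diff = std::fabs(m1 - m2);
    double stat;
    if (se2 <= 0) {
      stat = (diff > 0) ? R_PosInf : 0.0;
    } else {
      stat = diff / std::sqrt(se2);
    }
    if (stat > best) best = stat;
  }
  return best;
}

// Permutation exceedance count for the observed max-|t| split statistic,
// with early stop once the count exceeds `allow` (the largest count still
// compatible with acceptance). Uses R's RNG so results follow set.seed().
// [[Rcpp::export(.perm_exceed)]]
List perm_exceed(NumericVector x, double observed, int n_perm, int allow,
                 int min_probes) {
  int n = x.size();
  std::vector<double> buf(x.begin(), x.end());
  double tot = 0.0, ss_tot = 0.0;
  for (int i = 0; i < n; ++i) {
    tot += buf[i];
    ss_tot += buf[i] * buf[i];
  }
  RNGScope scope;
  int exceed = 0, done = 0;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(buf[i], buf[j]);
    }
    double stat = best_split_stat(buf.data(), n, min_probes, tot, ss_tot);
    ++done;
    if (stat >= observed) {
      ++exceed;
      if (exceed > allow) break;
    }
  }
  return List::create(_["exceed"] = exceed, _["done"] = done);
}
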