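#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact jackknife pseudo-observations of the Aalen-Johansen CIF at tau.
// Subjects sharing an observed (time, event) pattern share the same
// leave-one-out estimate, and every subject observed beyond tau perturbs
// only the at-risk counts, identically; so one recomputation per distinct
// pattern (plus one for the beyond-tau class) reproduces the naive
// per-subject jackknife exactly.
// [[Rcpp::export]]
NumericVector pseudo_cif_cpp(NumericVector time, IntegerVector event,
                             int cause, double tau) {
  int n = time.size();
  if (n < 2) stop("pseudo-values need at least 2 subjects");

  std::vector<double> ut(time.begin(), time.end());
  std::sort(ut.begin(), ut.end());
  ut.erase(std::unique(ut.begin(), ut.end()), ut.end());
  int m = ut.size();

  std::vector<int> idx(n);
  std::vector<int> cnt(m, 0), dall(m, 0), dc(m, 0);
  for (int i = 0; i < n; ++i) {
    int j = std::lower_bound(ut.begin(), ut.end(), time[i]) - ut.begin();
    idx[i] = j;
    cnt[j]++;
    if (event[i] > 0) dall[j]++;
    if (event[i] == cause) dc[j]++;
  }
  std::vector<int> nat(m);
  int left = n;
  for (int j = 0; j < m; ++j) { nat[j] = left; left -= cnt[j]; }

  int mtau = std::upper_bound(ut.begin(), ut.end(), tau) - ut.begin();

  // F(tau) with one subject of class (jrm, erm) removed; jrm = -1 and
  // erm = -1 encode the beyond-tau class; jrm = -2 removes nobody.
  auto F_loo = [&](int jrm, int erm) -> double {
    double S = 1.0, F = 0.0;
    for (int j = 0; j < mtau; ++j) {
      double natj = nat[j];
      if (jrm == -1 || (jrm >= 0 && j <= jrm)) natj -= 1.0;
      double dallj = dall[j], dcj = dc[j];
      if (j == jrm) {
        if (erm > 0) dallj -= 1.0;
        if (erm == cause) dcj -= 1.0;
      }
      if (natj <= 0.0) continue;
      F += S * dcj / natj;
      S *= 1.0 - dallj / natj;
    }
    return F;
  };

  double Ffull = F_loo(-2, 0);

  // distinct (time index <= tau, event) classes
  double loo_beyond = NA_REAL;
  std::vector<std::vector<double>> loo(m);  // per time index, per code 0..2
  NumericVector theta(n);
  for (int i = 0; i < n; ++i) {
    double Fm;
    if (time[i] > tau) {
      if (!R_finite(loo_beyond)) loo_beyond = F_loo(-1, -1);
      Fm = loo_beyond;
    } else {
      int j = idx[i], e = event[i];
      if (e < 0 || e > 8) stop("event codes must lie in 0..8");
      if (loo[j].empty()) loo[j].assign(9, NA_REAL);
      if (!R_finite(loo[j][e])) loo[j][e] = F_loo(j, e);
      Fm = loo[j][e];
    }
    theta[i] = n * Ffull - (n - 1.0) * Fm;
  }
  return theta;
}

// IPCW concordance for cause-1 events before tau_max. Index subjects i
// (event 1, T_i < tau_max) carry weight w_i = 1/G(T_i-)^2, precomputed in
// R; comparable partners j have T_j > T_i, or T_j == T_i while j is free
// of the cause-1 event at that time. Score ties count one half.
// [[Rcpp::export]]
List ipcw_cindex_cpp(NumericVector score, NumericVector time,
                     IntegerVector event, NumericVector w, double tau_max) {
  int n = score.size();
  double num = 0.0, den = 0.0;
  long pairs = 0;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1 || !(time[i] < tau_max) || w[i] <= 0.0) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      bool comparable = time[j] > time[i] ||
        (time[j] == time[i] && event[j] != 1);
      if (!comparable) continue;
      den += w[i];
      pairs++;
      if (score[i] > score[j]) num += w[i];
      else if (score[i] == score[j]) num += 0.5 * w[i];
    }
  }
  return List::create(_["num"] = num, _["den"] = den,
                      _["pairs"] = (double)pairs);
}
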