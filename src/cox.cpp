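#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted Cox partial log-likelihood on the age timescale with delayed entry
// (left truncation) and Efron handling of tied event ages.  Risk set at event
// age t is {i : entry_i < t <= exit_i}.  Subjects enter and leave risk sets
// monotonically when event ages are processed in decreasing order, so the
// risk-set sums S0, S1, S2 are maintained incrementally: O((n + k) p^2).
//
// With case weights the convention matches survival::coxph(ties = "efron"):
// each tie group of size d contributes
//   sum_{i in D} w_i eta_i - (sum_{i in D} w_i / d) *
//     sum_{j=0}^{d-1} log(S0_R - (j/d) S0_D).
// [[Rcpp::export]]
List cox_loglik_cpp(NumericVector entry, NumericVector exit,
                    IntegerVector event, NumericVector weight,
                    NumericVector eta, NumericMatrix X, bool derivs) {
  const int n = entry.size();
  const int p = derivs ? X.ncol() : 0;

  // centre eta for overflow safety; the partial likelihood is invariant
  double etamax = 0.0;
  for (int i = 0; i < n; i++) if (eta[i] > etamax) etamax = eta[i];
  std::vector<double> risk(n);
  for (int i = 0; i < n; i++) risk[i] = weight[i] * std::exp(eta[i] - etamax);

  std::vector<int> by_exit(n), by_entry(n);
  for (int i = 0; i < n; i++) by_exit[i] = by_entry[i] = i;
  std::sort(by_exit.begin(), by_exit.end(),
            [&](int a, int b) { return exit[a] > exit[b]; });
  std::sort(by_entry.begin(), by_entry.end(),
            [&](int a, int b) { return entry[a] > entry[b]; });

  // distinct event ages, decreasing
  std::vector<double> etimes;
  for (int i = 0; i < n; i++) if (event[i] == 1) etimes.push_back(exit[i]);
  std::sort(etimes.begin(), etimes.end(), std::greater<double>());
  etimes.erase(std::unique(etimes.begin(), etimes.end()), etimes.end());

  double S0 = 0.0, loglik = 0.0;
  std::vector<double> S1(p, 0.0), S2(p * p, 0.0);
  NumericVector grad(p);
  NumericMatrix info(p, p);
  std::vector<double> s1d(p), a(p);
  double nevent_w = 0.0;
  int nevent = 0;

  size_t pe = 0, pn = 0;
  for (size_t ti = 0; ti < etimes.size(); ti++) {
    const double t = etimes[ti];
    while (pe < by_exit.size() && exit[by_exit[pe]] >= t) {
      const int i = by_exit[pe++];
      S0 += risk[i];
      for (int u = 0; u < p; u++) {
        const double xu = risk[i] * X(i, u);
        S1[u] += xu;
        for (int v = 0; v <= u; v++) S2[u * p + v] += xu * X(i, v);
      }
    }
    while (pn < by_entry.size() && entry[by_entry[pn]] >= t) {
      const int i = by_entry[pn++];
      S0 -= risk[i];
      for (int u = 0; u < p; u++) {
        const double xu = risk[i] * X(i, u);
        S1[u] -= xu;
        for (int v = 0; v <= u; v++) S2[u * p + v] -= xu * X(i, v);
      }
    }

    // tie set D at this event age: entries of by_exit just behind pe
    double s0d = 0.0, wd = 0.0;
    int d = 0;
    std::fill(s1d.begin(), s1d.end(), 0.0);
    std::vector<double> s2d(p * p, 0.0);
    // tied events have exit == t: scan by_exit backwards from pe
    // (all subjects with exit >= t sit in [0, pe))
    for (size_t q = pe; q-- > 0;) {
      const int i = by_exit[q];
      if (exit[i] > t) break;
      if (event[i] != 1) continue;
      d++;
      wd += weight[i];
      s0d += risk[i];
      loglik += weight[i] * (eta[i] - etamax);
      for (int u = 0; u < p; u++) {
        const double xu = risk[i] * X(i, u);
        s1d[u] += xu;
        for (int v = 0; v <= u; v++) s2d[u * p + v] += xu * X(i, v);
        grad[u] += weight[i] * X(i, u);
      }
    }
    nevent += d;
    nevent_w += wd;
    const double mw = wd / d;
    for (int j = 0; j < d; j++) {
      const double frac = (double)j / d;
      const double d0 = S0 - frac * s0d;
      loglik -= mw * std::log(d0);
      if (p > 0) {
        for (int u = 0; u < p; u++) a[u] = (S1[u] - frac * s1d[u]) / d0;
        for (int u = 0; u < p; u++) {
          grad[u] -= mw * a[u];
          for (int v = 0; v <= u; v++)
            info(u, v) += mw * ((S2[u * p + v] - frac * s2d[u * p + v]) / d0 -
                                a[u] * a[v]);
        }
      }
    }
    if (ti % 256 == 0) Rcpp::checkUserInterrupt();
  }
  // log(exp(eta - etamax)) terms: each event contributed w*(eta-etamax) and
  // each denominator log lost mw*etamax implicitly; they cancel exactly, so
  // loglik above is already on the original eta scale.
  for (int u = 0; u < p; u++)
    for (int v = u + 1; v < p; v++) info(u, v) = info(v, u);

  return List::create(_["loglik"] = loglik, _["grad"] = grad,
                      _["info"] = info, _["n_events"] = nevent,
                      _["n_events_weighted"] = nevent_w);
}

// Weight-sum Fenwick (binary indexed) tree over predictor ranks.
struct Fenwick {
  std::vector<double> tree;
  explicit Fenwick(int n) : tree(n + 1, 0.0) {}
  void add(int i, double w) {            // 1-based rank
    for (; i < (int)tree.size(); i += i & (-i)) tree[i] += w;
  }
  double prefix(int i) const {           // sum of ranks 1..i
    double s = 0.0;
    for (; i > 0; i -= i & (-i)) s += tree[i];
    return s;
  }
};

// Harrell-type concordance with delayed entry.  A pair (i, j) is comparable
// when i has an event at t = exit_i and j is at risk past t: entry_j < t and
// (exit_j > t, or exit_j == t with j censored).  Tied predictions count 1/2;
// pairs are weighted by w_i * w_j.  Event ages are processed in decreasing
// order with a Fenwick tree over predictor ranks holding the current risk
// set, so the total cost is O(n log n) rather than O(n * events).
// [[Rcpp::export]]
List concordance_cpp(NumericVector entry, NumericVector exit,
                     IntegerVector event, NumericVector weight,
                     NumericVector lp) {
  const int n = entry.size();

  // dense ranks of lp (1-based)
  std::vector<int> idx(n), rank(n);
  for (int i = 0; i < n; i++) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return lp[a] < lp[b]; });
  int r = 0;
  for (int k = 0; k < n; k++) {
    if (k > 0 && lp[idx[k]] != lp[idx[k - 1]]) r++;
    rank[idx[k]] = r + 1;
  }
  const int nrank = r + 1;

  std::vector<int> by_exit(n), by_entry(n);
  for (int i = 0; i < n; i++) by_exit[i] = by_entry[i] = i;
  std::sort(by_exit.begin(), by_exit.end(),
            [&](int a, int b) { return exit[a] > exit[b]; });
  std::sort(by_entry.begin(), by_entry.end(),
            [&](int a, int b) { return entry[a] > entry[b]; });

  std::vector<double> etimes;
  for (int i = 0; i < n; i++) if (event[i] == 1) etimes.push_back(exit[i]);
  std::sort(etimes.begin(), etimes.end(), std::greater<double>());
  etimes.erase(std::unique(etimes.begin(), etimes.end()), etimes.end());

  Fenwick fw(nrank);
  double in_tree = 0.0;                  // total weight currently held
  double conc = 0.0, ties = 0.0, total = 0.0;
  size_t pe = 0, pn = 0;
  for (size_t ti = 0; ti < etimes.size(); ti++) {
    const double t = etimes[ti];
    while (pe < by_exit.size() && exit[by_exit[pe]] >= t) {
      const int i = by_exit[pe++];
      fw.add(rank[i], weight[i]);
      in_tree += weight[i];
    }
    while (pn < by_entry.size() && entry[by_entry[pn]] >= t) {
      const int i = by_entry[pn++];
      fw.add(rank[i], -weight[i]);
      in_tree -= weight[i];
    }
    // subjects dying at t are not comparable with each other: lift them out
    std::vector<int> died;
    for (size_t q = pe; q-- > 0;) {
      const int i = by_exit[q];
      if (exit[i] > t) break;
      if (event[i] != 1) continue;
      died.push_back(i);
      fw.add(rank[i], -weight[i]);
      in_tree -= weight[i];
    }
    for (int i : died) {
      const double below = fw.prefix(rank[i] - 1);
      const double at = fw.prefix(rank[i]) - below;
      conc += weight[i] * below;
      ties += weight[i] * at;
      total += weight[i] * in_tree;
    }
    for (int i : died) {                 // restore: still at risk for later
      fw.add(rank[i], weight[i]);        // (i.e. earlier-age) events
      in_tree += weight[i];
    }
    if (ti % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["concordant"] = conc, _["tied"] = ties,
                      _["comparable"] = total);
}
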