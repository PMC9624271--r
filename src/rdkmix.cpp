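#include <Rcpp.h>
using namespace Rcpp;

// von Mises density per degree, overflow-safe for large kappa:
// exp(kappa * (cos(d) - 1)) / (360 * I0(kappa) * exp(-kappa))
static inline double vm_pdf_deg(double delta_rad, double kappa, double i0e) {
  return std::exp(kappa * (std::cos(delta_rad) - 1.0)) / (360.0 * i0e);
}

// EM over mixture weights at fixed component densities.
// d1, d2 may be empty (component absent). Weights are passed in as the
// starting point (the weight log-likelihood is concave with a unique fixed
// point, so warm starts from a neighboring grid node are safe) and the
// converged values are written back. Returns the log-likelihood.
static double em_weights(const std::vector<double>& d1,
                         const std::vector<double>& d2,
                         int n, bool use_det, bool use_rood,
                         double tol, int max_iter,
                         double& r1, double& r2, double& r3) {
  const double u = 1.0 / 360.0;
  for (int it = 0; it < max_iter; ++it) {
    double s1 = 0.0, s2 = 0.0, s3 = 0.0;
    for (int i = 0; i < n; ++i) {
      double a1 = use_det ? r1 * d1[i] : 0.0;
      double a2 = use_rood ? r2 * d2[i] : 0.0;
      double a3 = r3 * u;
      double mix = a1 + a2 + a3;
      s1 += a1 / mix;
      s2 += a2 / mix;
      s3 += a3 / mix;
    }
    double n1 = s1 / n, n2 = s2 / n, n3 = s3 / n;
    double delta = std::max(std::fabs(n1 - r1),
                   std::max(std::fabs(n2 - r2), std::fabs(n3 - r3)));
    r1 = n1; r2 = n2; r3 = n3;
    if (delta < tol) break;
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double mix = (use_det ? r1 * d1[i] : 0.0) +
                 (use_rood ? r2 * d2[i] : 0.0) + r3 * u;
    ll += std::log(mix);
  }
  return ll;
}

// Stage-1 grid search for the von Mises mixture: for every (mu, kappa1,
// kappa2) node, mixture weights are optimized by EM; the best node is kept,
// ties broken toward smallest |mu|, then smallest kappa1, then kappa2
// (guaranteed by visiting nodes in that priority order).
// [[Rcpp::export(name = ".grid_fit_cpp")]]
List grid_fit_cpp(NumericVector theta_rad, NumericVector mu_grid_rad,
                  NumericVector kappa1_grid, NumericVector kappa2_grid,
                  bool use_det, bool use_rood,
                  double tol, int max_iter) {
  const int n = theta_rad.size();
  const double pi = M_PI;

  // visit mu in order of increasing |mu|
  std::vector<int> mu_order(mu_grid_rad.size());
  for (int i = 0; i < (int)mu_order.size(); ++i) mu_order[i] = i;
  std::sort(mu_order.begin(), mu_order.end(), [&](int a, int b) {
    double fa = std::fabs(mu_grid_rad[a]), fb = std::fabs(mu_grid_rad[b]);
    if (fa != fb) return fa < fb;
    return mu_grid_rad[a] < mu_grid_rad[b];
  });

  int nk1 = use_det ? kappa1_grid.size() : 1;
  int nk2 = use_rood ? kappa2_grid.size() : 1;

  std::vector<double> i0e1(nk1, 1.0), i0e2(nk2, 1.0);
  if (use_det)
    for (int a = 0; a < nk1; ++a)
      i0e1[a] = R::bessel_i(kappa1_grid[a], 0.0, 2.0);
  if (use_rood)
    for (int b = 0; b < nk2; ++b)
      i0e2[b] = R::bessel_i(kappa2_grid[b], 0.0, 2.0);

  // screening pass over every node in tie-break priority order: EM with a
  // capped iteration count, warm-started from the previous node (floored
  // away from the absorbing zero boundary of the EM weight update)
  const int screen_iter = std::min(max_iter, 100);
  const int n_nodes = (int)mu_order.size() * nk1 * nk2;
  std::vector<double> s_ll(n_nodes), s_mu(n_nodes), s_k1(n_nodes),
      s_k2(n_nodes), s_r1(n_nodes), s_r2(n_nodes), s_r3(n_nodes);
  double warm_r1 = 1.0 / 3, warm_r2 = 1.0 / 3, warm_r3 = 1.0 / 3;

  std::vector<double> d1(use_det ? n : 0), d2(use_rood ? n : 0);
  std::vector<std::vector<double>> D1(nk1), D2(nk2);

  int node = 0;
  for (int mo = 0; mo < (int)mu_order.size(); ++mo) {
    double mu = mu_grid_rad[mu_order[mo]];
    if (use_det)
      for (int a = 0; a < nk1; ++a) {
        D1[a].resize(n);
        for (int i = 0; i < n; ++i)
          D1[a][i] = vm_pdf_deg(theta_rad[i] - mu, kappa1_grid[a], i0e1[a]);
      }
    if (use_rood)
      for (int b = 0; b < nk2; ++b) {
        D2[b].resize(n);
        for (int i = 0; i < n; ++i)
          D2[b][i] = vm_pdf_deg(theta_rad[i] - mu - pi, kappa2_grid[b], i0e2[b]);
      }
    for (int a = 0; a < nk1; ++a) {
      for (int b = 0; b < nk2; ++b) {
        double r1 = use_det ? std::max(warm_r1, 0.05) : 0.0;
        double r2 = use_rood ? std::max(warm_r2, 0.05) : 0.0;
        double r3 = std::max(warm_r3, 0.05);
        double tot = r1 + r2 + r3;
        r1 /= tot; r2 /= tot; r3 /= tot;
        double ll = em_weights(use_det ? D1[a] : d1, use_rood ? D2[b] : d2,
                               n, use_det, use_rood, tol, screen_iter,
                               r1, r2, r3);
        warm_r1 = r1; warm_r2 = r2; warm_r3 = r3;
        s_ll[node] = ll;
        s_mu[node] = mu;
        s_k1[node] = use_det ? kappa1_grid[a] : 0.0;
        s_k2[node] = use_rood ? kappa2_grid[b] : 0.0;
        s_r1[node] = r1; s_r2[node] = r2; s_r3[node] = r3;
        ++node;
      }
    }
  }

  // polish the leading candidates to full tolerance, keeping priority order
  // so that exact log-likelihood ties resolve toward smallest |mu|, then
  // smallest kappas
  const int n_polish = std::min(n_nodes, 20);
  std::vector<int> cand(n_nodes);
  for (int i = 0; i < n_nodes; ++i) cand[i] = i;
  std::partial_sort(cand.begin(), cand.begin() + n_polish, cand.end(),
                    [&](int a, int b) { return s_ll[a] > s_ll[b]; });
  cand.resize(n_polish);
  std::sort(cand.begin(), cand.end());

  double best_ll = R_NegInf, best_mu = 0.0, best_k1 = 0.0, best_k2 = 0.0;
  double best_r1 = 0.0, best_r2 = 0.0, best_r3 = 1.0;
  std::vector<double> pd1(use_det ? n : 0), pd2(use_rood ? n : 0);
  for (int ci = 0; ci < n_polish; ++ci) {
    int j = cand[ci];
    if (use_det) {
      double i0e = R::bessel_i(s_k1[j], 0.0, 2.0);
      for (int i = 0; i < n; ++i)
        pd1[i] = vm_pdf_deg(theta_rad[i] - s_mu[j], s_k1[j], i0e);
    }
    if (use_rood) {
      double i0e = R::bessel_i(s_k2[j], 0.0, 2.0);
      for (int i = 0; i < n; ++i)
        pd2[i] = vm_pdf_deg(theta_rad[i] - s_mu[j] - pi, s_k2[j], i0e);
    }
    double r1 = s_r1[j], r2 = s_r2[j], r3 = s_r3[j];
    double ll = em_weights(pd1, pd2, n, use_det, use_rood, tol, max_iter,
                           r1, r2, r3);
    if (ll > best_ll + 1e-9) {
      best_ll = ll;
      best_mu = s_mu[j];
      best_k1 = s_k1[j];
      best_k2 = s_k2[j];
      best_r1 = r1; best_r2 = r2; best_r3 = r3;
    }
  }

  return List::create(_["mu_rad"] = best_mu,
                      _["kappa1"] = best_k1,
                      _["kappa2"] = best_k2,
                      _["r1"] = best_r1,
                      _["r2"] = best_r2,
                      _["r3"] = best_r3,
                      _["log_likelihood"] = best_ll);
}

// Two-sample Cramer-von Mises statistic on sorted pooled values:
// T = n*m/N^2 * sum over pooled observations of (Fn - Fm)^2, with the ECDFs
// evaluated at the observation's value (tie-aware, so T = 0 iff the samples
// are identical multisets).
static double cvm_from_sorted(const std::vector<double>& val,
                              const std::vector<int>& grp, int n, int m) {
  const int N = n + m;
  double cn = 0.0, cm = 0.0, s = 0.0;
  int i = 0;
  while (i < N) {
    int j = i;
    while (j < N && val[j] == val[i]) {
      if (grp[j] == 0) cn += 1.0; else cm += 1.0;
      ++j;
    }
    double d = cn / n - cm / m;
    s += (j - i) * d * d;
    i = j;
  }
  return (double)n * m / ((double)N * N) * s;
}

// [[Rcpp::export(name = ".cvm_stat_cpp")]]
double cvm_stat_cpp(NumericVector pooled_sorted, IntegerVector group, int n, int m) {
  std::vector<double> val(pooled_sorted.begin(), pooled_sorted.end());
  std::vector<int> grp(group.begin(), group.end());
  return cvm_from_sorted(val, grp, n, m);
}

// Permutation null distribution: group labels are shuffled over the sorted
// pooled sample (values fixed), using R's RNG so results respect set.seed().
// [[Rcpp::export(name = ".cvm_perm_cpp")]]
NumericVector cvm_perm_cpp(NumericVector pooled_sorted, int n, int m, int n_perm) {
  const int N = n + m;
  std::vector<double> val(pooled_sorted.begin(), pooled_sorted.end());
  std::vector<int> grp(N);
  NumericVector out(n_perm);
  GetRNGstate();
  for (int p = 0; p < n_perm; ++p) {
    std::fill(grp.begin(), grp.end(), 1);
    // sample n of N positions for group A by partial Fisher-Yates
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < n; ++i) {
      int j = i + (int)(unif_rand() * (N - i));
      if (j >= N) j = N - 1;
      std::swap(idx[i], idx[j]);
      grp[idx[i]] = 0;
    }
    out[p] = cvm_from_sorted(val, grp, n, m);
  }
  PutRNGstate();
  return out;
}
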