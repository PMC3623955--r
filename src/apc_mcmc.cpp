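#include <Rcpp.h>
using namespace Rcpp;

// Adaptive single-site Metropolis-within-Gibbs sampler for the Poisson
// age-period-cohort model with RW2 priors:
//
//   D[a,p] ~ Poisson(N[a,p] * exp(eta)),  eta = mu + alpha[a] + beta[p] + gamma[c]
//   c = (A - a) + p  (1-based anti-diagonal index)
//
// RW2 prior on each included effect vector (flat on its first two elements),
// Gamma(shape, rate) hyperprior on each RW2 precision (Gibbs update), diffuse
// normal prior on mu. Identifiability constraints are enforced by a
// deterministic affine transform after every iteration; the transform leaves
// every fitted log-rate unchanged. All randomness comes from R's RNG, so runs
// are reproducible from set.seed() on the R side.

// sum of squared second differences
static double ss_second_diff(const std::vector<double>& x) {
  double s = 0.0;
  for (size_t k = 2; k < x.size(); ++k) {
    double d = x[k] - 2.0 * x[k - 1] + x[k - 2];
    s += d * d;
  }
  return s;
}

struct APCState {
  double mu;
  std::vector<double> alpha, beta, gamma;
  double tau_a, tau_b, tau_g;
};

// constraint transform; mirrors apply_constraints() in R. Operates in place.
static void apply_constraints_cpp(APCState& st, int A, int P, int C,
                                  bool inc_a, bool inc_b, bool inc_g,
                                  int r1, int r2, int rc) {
  if (inc_a && inc_b && inc_g) {
    // detilt beta at the two reference periods (1-based r1 < r2)
    double v = (st.beta[r2 - 1] - st.beta[r1 - 1]) / double(r2 - r1);
    double u = st.beta[r1 - 1] - v * r1;
    for (int p = 0; p < P; ++p) st.beta[p] -= u + v * (p + 1);
    // compensation via p = c - A + a: mu += u - v*A, alpha += v*a, gamma += v*c
    st.mu += u - v * A;
    for (int a = 0; a < A; ++a) st.alpha[a] += v * (a + 1);
    for (int c = 0; c < C; ++c) st.gamma[c] += v * (c + 1);
    // level of gamma at the reference cohort
    double g0 = st.gamma[rc - 1];
    for (int c = 0; c < C; ++c) st.gamma[c] -= g0;
    st.mu += g0;
    // level of alpha (mean zero)
    double m = 0.0;
    for (int a = 0; a < A; ++a) m += st.alpha[a];
    m /= A;
    for (int a = 0; a < A; ++a) st.alpha[a] -= m;
    st.mu += m;
  } else {
    // submodels: centre each included effect (level only)
    if (inc_a) {
      double m = 0.0;
      for (int a = 0; a < A; ++a) m += st.alpha[a];
      m /= A;
      for (int a = 0; a < A; ++a) st.alpha[a] -= m;
      st.mu += m;
    }
    if (inc_b) {
      double m = 0.0;
      for (int p = 0; p < P; ++p) m += st.beta[p];
      m /= P;
      for (int p = 0; p < P; ++p) st.beta[p] -= m;
      st.mu += m;
    }
    if (inc_g) {
      double g0 = st.gamma[rc - 1];
      for (int c = 0; c < C; ++c) st.gamma[c] -= g0;
      st.mu += g0;
    }
  }
}

// [[Rcpp::export(name = ".apc_mcmc_chain")]]
List apc_mcmc_chain(IntegerVector D, NumericVector N, int A, int P,
                    bool inc_age, bool inc_period, bool inc_cohort,
                    int ref_p1, int ref_p2, int ref_cohort,
                    double hyper_shape, double hyper_rate, double mu_prior_var,
                    List init, NumericVector log_scales_in,
                    bool adapt, int adapt_offset,
                    int n_iter, int thin, bool store) {
  const int C = A + P - 1;
  const int ncell = A * P;
  if (D.size() != ncell || N.size() != ncell)
    stop("D and N must have A*P cells");

  APCState st;
  st.mu = as<double>(init["mu"]);
  st.alpha = as<std::vector<double> >(init["alpha"]);
  st.beta = as<std::vector<double> >(init["beta"]);
  st.gamma = as<std::vector<double> >(init["gamma"]);
  st.tau_a = as<double>(init["tau_age"]);
  st.tau_b = as<double>(init["tau_period"]);
  st.tau_g = as<double>(init["tau_cohort"]);
  if ((int)st.alpha.size() != A || (int)st.beta.size() != P ||
      (int)st.gamma.size() != C)
    stop("init effect lengths inconsistent with grid");

  const int n_coord = 1 + A + P + C;  // mu, alpha, beta, gamma
  std::vector<double> ls(log_scales_in.begin(), log_scales_in.end());
  if ((int)ls.size() != n_coord) stop("log_scales must have 1+A+P+C entries");
  std::vector<double> acc(n_coord, 0.0), tries(n_coord, 0.0);

  // cell bookkeeping: row/col/diagonal membership, cohort of cell (0-based)
  std::vector<int> coh(ncell);
  for (int p = 0; p < P; ++p)
    for (int a = 0; a < A; ++a)
      coh[p * A + a] = (A - (a + 1)) + (p + 1) - 1;
  std::vector<std::vector<int> > cells_of_coh(C);
  for (int i = 0; i < ncell; ++i) cells_of_coh[coh[i]].push_back(i);

  // maintained state: eta and N*exp(eta) per cell
  std::vector<double> eta(ncell), lamN(ncell);
  double totD = 0.0;
  std::vector<double> Drow(A, 0.0), Dcol(P, 0.0), Dcoh(C, 0.0);
  for (int p = 0; p < P; ++p)
    for (int a = 0; a < A; ++a) {
      int i = p * A + a;
      totD += D[i];
      Drow[a] += D[i];
      Dcol[p] += D[i];
      Dcoh[coh[i]] += D[i];
    }
  auto recompute_eta = [&]() {
    for (int p = 0; p < P; ++p)
      for (int a = 0; a < A; ++a) {
        int i = p * A + a;
        double e = st.mu;
        if (inc_age) e += st.alpha[a];
        if (inc_period) e += st.beta[p];
        if (inc_cohort) e += st.gamma[coh[i]];
        eta[i] = e;
        lamN[i] = N[i] * std::exp(e);
      }
  };
  recompute_eta();

  int n_keep = store ? (n_iter / thin) : 0;
  int n_par = 1 + A + P + C + 3;
  NumericMatrix draws(n_keep, n_par);
  int kept = 0;

  // single-site Metropolis step on one coordinate of an effect vector.
  // cells: the cells that coordinate touches; Dsum: their total deaths.
  auto mh_effect = [&](std::vector<double>& x, int k, double tau,
                       const std::vector<int>& cells, double Dsum,
                       int ls_idx, int t_adapt) {
    double s = std::exp(ls[ls_idx]);
    double delta = R::rnorm(0.0, s);
    double lamsum = 0.0;
    for (size_t j = 0; j < cells.size(); ++j) lamsum += lamN[cells[j]];
    double dll = delta * Dsum - (std::expm1(delta)) * lamsum;
    double s_old = ss_second_diff(x);
    x[k] += delta;
    double s_new = ss_second_diff(x);
    x[k] -= delta;
    double dlp = -0.5 * tau * (s_new - s_old);
    double logr = dll + dlp;
    double a_prob = (logr >= 0.0) ? 1.0 : std::exp(logr);
    bool accept = (R::unif_rand() < a_prob);
    if (accept) {
      x[k] += delta;
      double f = std::exp(delta);
      for (size_t j = 0; j < cells.size(); ++j) {
        eta[cells[j]] += delta;
        lamN[cells[j]] *= f;
      }
    }
    tries[ls_idx] += 1.0;
    if (accept) acc[ls_idx] += 1.0;
    if (adapt) {
      double step = std::pow((double)(t_adapt + adapt_offset + 1), -0.6);
      ls[ls_idx] += step * (a_prob - 0.44);
      if (ls[ls_idx] < -10.0) ls[ls_idx] = -10.0;
      if (ls[ls_idx] > 5.0) ls[ls_idx] = 5.0;
    }
  };

  std::vector<int> all_cells(ncell);
  for (int i = 0; i < ncell; ++i) all_cells[i] = i;
  std::vector<std::vector<int> > row_cells(A), col_cells(P);
  for (int a = 0; a < A; ++a)
    for (int p = 0; p < P; ++p) row_cells[a].push_back(p * A + a);
  for (int p = 0; p < P; ++p)
    for (int a = 0; a < A; ++a) col_cells[p].push_back(p * A + a);

  for (int t = 0; t < n_iter; ++t) {
    // mu (diffuse normal prior)
    {
      double s = std::exp(ls[0]);
      double delta = R::rnorm(0.0, s);
      double lamsum = 0.0;
      for (int i = 0; i < ncell; ++i) lamsum += lamN[i];
      double dll = delta * totD - std::expm1(delta) * lamsum;
      double mu_new = st.mu + delta;
      double dlp = -(mu_new * mu_new - st.mu * st.mu) / (2.0 * mu_prior_var);
      double logr = dll + dlp;
      double a_prob = (logr >= 0.0) ? 1.0 : std::exp(logr);
      bool accept = (R::unif_rand() < a_prob);
      if (accept) {
        st.mu = mu_new;
        double f = std::exp(delta);
        for (int i = 0; i < ncell; ++i) { eta[i] += delta; lamN[i] *= f; }
      }
      tries[0] += 1.0;
      if (accept) acc[0] += 1.0;
      if (adapt) {
        double step = std::pow((double)(t + adapt_offset + 1), -0.6);
        ls[0] += step * (a_prob - 0.44);
        if (ls[0] < -10.0) ls[0] = -10.0;
        if (ls[0] > 5.0) ls[0] = 5.0;
      }
    }
    if (inc_age)
      for (int a = 0; a < A; ++a)
        mh_effect(st.alpha, a, st.tau_a, row_cells[a], Drow[a], 1 + a, t);
    if (inc_period)
      for (int p = 0; p < P; ++p)
        mh_effect(st.beta, p, st.tau_b, col_cells[p], Dcol[p], 1 + A + p, t);
    if (inc_cohort)
      for (int c = 0; c < C; ++c)
        mh_effect(st.gamma, c, st.tau_g, cells_of_coh[c], Dcoh[c],
                  1 + A + P + c, t);

    // Gibbs updates for the RW2 precisions
    if (inc_age) {
      double S = ss_second_diff(st.alpha);
      st.tau_a = R::rgamma(hyper_shape + 0.5 * (A - 2),
                           1.0 / (hyper_rate + 0.5 * S));
    }
    if (inc_period) {
      double S = ss_second_diff(st.beta);
      st.tau_b = R::rgamma(hyper_shape + 0.5 * (P - 2),
                           1.0 / (hyper_rate + 0.5 * S));
    }
    if (inc_cohort) {
      double S = ss_second_diff(st.gamma);
      st.tau_g = R::rgamma(hyper_shape + 0.5 * (C - 2),
                           1.0 / (hyper_rate + 0.5 * S));
    }

    // identifiability constraints (fitted rates invariant, eta untouched)
    apply_constraints_cpp(st, A, P, C, inc_age, inc_period, inc_cohort,
                          ref_p1, ref_p2, ref_cohort);

    // guard against slow numerical drift of the maintained eta
    if ((t + 1) % 512 == 0) recompute_eta();

    if (store && ((t + 1) % thin == 0) && kept < n_keep) {
      int j = 0;
      draws(kept, j++) = st.mu;
      for (int a = 0; a < A; ++a) draws(kept, j++) = inc_age ? st.alpha[a] : 0.0;
      for (int p = 0; p < P; ++p) draws(kept, j++) = inc_period ? st.beta[p] : 0.0;
      for (int c = 0; c < C; ++c) draws(kept, j++) = inc_cohort ? st.gamma[c] : 0.0;
      draws(kept, j++) = inc_age ? 1.0 / st.tau_a : NA_REAL;
      draws(kept, j++) = inc_period ? 1.0 / st.tau_b : NA_REAL;
      draws(kept, j++) = inc_cohort ? 1.0 / st.tau_g : NA_REAL;
      ++kept;
    }
  }

  List state = List::create(
    _["mu"] = st.mu, _["alpha"] = st.alpha, _["beta"] = st.beta,
    _["gamma"] = st.gamma, _["tau_age"] = st.tau_a,
    _["tau_period"] = st.tau_b, _["tau_cohort"] = st.tau_g);
  NumericVector rate(n_coord);
  for (int j = 0; j < n_coord; ++j)
    rate[j] = tries[j] > 0 ? acc[j] / tries[j] : NA_REAL;
  return List::create(_["draws"] = draws, _["state"] = state,
                      _["log_scales"] = NumericVector(ls.begin(), ls.end()),
                      _["accept_rate"] = rate);
}
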