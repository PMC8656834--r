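#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the BYM convolution Poisson model:
//   y_i ~ Poisson(E_i * exp(alpha + u_i + v_i))
//   u   ~ ICAR(tau_u) on the adjacency graph (sum-to-zero, islands fixed at 0)
//   v_i ~ N(0, 1/tau_v),  alpha ~ flat
//   tau_u, tau_v ~ Gamma(a, b)  (shape, rate)
//
// alpha, u_i, v_i use adaptive random-walk Metropolis (target acceptance
// 0.44), tuned during burn-in only. The likelihood identifies only the sum
// w = u + v, so the u/v split and the two precisions are updated in the
// eigenbasis of the graph Laplacian on the non-island nodes, where both the
// ICAR prior and the iid prior are diagonal:
//   * the precisions move by random-walk MH on the log scale against the
//     MARGINAL density p(w | tau_u, tau_v) with the split integrated out
//     (w-component k has variance 1/(tau_u*lambda_k) + 1/tau_v), so they do
//     not random-walk along the ridge of any particular split; these are
//     interleaved with a joint rescaling move w -> c*w that traverses the
//     (|w|, tau) funnel directly;
//   * random eigencomponents of w are refreshed by independence proposals
//     from their prior, accepted by the bare likelihood ratio — effective
//     exactly in sparse-data strata where coordinate-wise updates are slow;
//   * the split is then redrawn EXACTLY from its Gaussian full conditional
//     given w and the precisions (component k of u has mean
//     w_k * tau_v/(tau_u*lambda_k + tau_v) and that same denominator as
//     precision), a pure Gibbs step that leaves the likelihood untouched;
//   * a conjugate Gibbs refresh of both precisions follows.
// Uses R's RNG, so set.seed() on the R side governs reproducibility.

static inline double rw_step(double ls) { return R::rnorm(0.0, exp(ls)); }

// [[Rcpp::export(name = ".bym_mcmc")]]
List bym_mcmc(IntegerVector y, NumericVector E,
              List nbr,                 // per-node integer vectors, 0-based
              IntegerVector edge_i, IntegerVector edge_j,  // 0-based edges
              LogicalVector island, int icar_rank,
              NumericMatrix Vt,         // rows: Laplacian eigenvectors (free nodes)
              NumericVector lambda,     // matching eigenvalues, >= 0
              int n_iter, int n_burnin, int thin,
              double a, double b,
              double alpha_init, NumericVector u_init, NumericVector v_init,
              double tau_u_init, double tau_v_init) {
  RNGScope scope;
  const int n = y.size();
  const int n_edge = edge_i.size();
  const double target = 0.44;
  const double lam_eps = 1e-9;

  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ni = nbr[i];
    adj[i].assign(ni.begin(), ni.end());
  }

  double alpha = alpha_init, tau_u = tau_u_init, tau_v = tau_v_init;
  std::vector<double> u(u_init.begin(), u_init.end());
  std::vector<double> v(v_init.begin(), v_init.end());

  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i) if (!island[i]) free_idx.push_back(i);
  const int m = free_idx.size();
  const bool any_island = (m < n);

  double sumy = 0.0;
  for (int i = 0; i < n; ++i) sumy += y[i];

  // adaptive proposal log-sds
  double ls_alpha = log(0.1), ls_tu = log(0.5), ls_tv = log(0.5);
  double ls_w = log(0.2);
  std::vector<double> ls_u(n, log(0.5)), ls_v(n, log(0.5));
  double acc_alpha = 0.0;
  std::vector<double> acc_u(n, 0.0), acc_v(n, 0.0);
  int n_after = 0;

  std::vector<double> wt(m), ut(m);  // w and u in the eigenbasis

  // marginal log-density of w (eigen components) + priors, as a function of
  // the precisions; island v-terms are added for tau_v only
  auto marginal_lp = [&](double tu, double tv, double island_ss,
                         int n_island) -> double {
    double lp = a * log(tu) - b * tu + a * log(tv) - b * tv;
    for (int k = 0; k < m; ++k) {
      const double s = (lambda[k] > lam_eps ? 1.0 / (tu * lambda[k]) : 0.0) +
        1.0 / tv;
      lp += -0.5 * log(s) - wt[k] * wt[k] / (2.0 * s);
    }
    lp += 0.5 * n_island * log(tv) - 0.5 * tv * island_ss;
    return lp;
  };

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericVector alpha_draws(n_keep), tau_u_draws(n_keep), tau_v_draws(n_keep);
  NumericMatrix u_draws(n_keep, n), v_draws(n_keep, n);

  int keep = 0;
  for (int t = 1; t <= n_iter; ++t) {
    const bool adapting = (t <= n_burnin);
    const double delta = std::min(0.25, 2.0 / sqrt((double)t));

    // --- alpha (random-walk Metropolis, flat prior) ---
    {
      double sumw = 0.0;
      for (int i = 0; i < n; ++i) sumw += E[i] * exp(u[i] + v[i]);
      double prop = alpha + rw_step(ls_alpha);
      double lr = sumy * (prop - alpha) - sumw * (exp(prop) - exp(alpha));
      bool acc = log(R::runif(0.0, 1.0)) < lr;
      if (acc) alpha = prop;
      if (adapting) ls_alpha += delta * ((acc ? 1.0 : 0.0) - target);
      else if (acc) acc_alpha += 1.0;
    }

    // --- u_i (ICAR conditional prior, Poisson likelihood) ---
    const double ea = exp(alpha);
    for (int i = 0; i < n; ++i) {
      if (island[i]) continue;
      const int d = adj[i].size();
      double nbsum = 0.0;
      for (int k = 0; k < d; ++k) nbsum += u[adj[i][k]];
      const double mbar = nbsum / d;
      const double cur = u[i];
      const double prop = cur + rw_step(ls_u[i]);
      const double lik = y[i] * (prop - cur) -
        ea * E[i] * exp(v[i]) * (exp(prop) - exp(cur));
      const double pri = -0.5 * tau_u * d *
        ((prop - mbar) * (prop - mbar) - (cur - mbar) * (cur - mbar));
      bool acc = log(R::runif(0.0, 1.0)) < lik + pri;
      if (acc) u[i] = prop;
      if (adapting) ls_u[i] += delta * ((acc ? 1.0 : 0.0) - target);
      else if (acc) acc_u[i] += 1.0;
    }

    // sum-to-zero recentring of u. Without islands this is an exact
    // measure-preserving move (alpha absorbs the mean along the flat
    // direction of the posterior); with islands the mean is removed from
    // the free components only (on-the-fly centering).
    if (m > 0) {
      double mean_u = 0.0;
      for (int k = 0; k < m; ++k) mean_u += u[free_idx[k]];
      mean_u /= m;
      for (int k = 0; k < m; ++k) u[free_idx[k]] -= mean_u;
      if (!any_island) alpha += mean_u;
    }

    // --- v_i (iid normal prior) ---
    const double ea2 = exp(alpha);
    for (int i = 0; i < n; ++i) {
      const double cur = v[i];
      const double prop = cur + rw_step(ls_v[i]);
      const double lik = y[i] * (prop - cur) -
        ea2 * E[i] * exp(u[i]) * (exp(prop) - exp(cur));
      const double pri = -0.5 * tau_v * (prop * prop - cur * cur);
      bool acc = log(R::runif(0.0, 1.0)) < lik + pri;
      if (acc) v[i] = prop;
      if (adapting) ls_v[i] += delta * ((acc ? 1.0 : 0.0) - target);
      else if (acc) acc_v[i] += 1.0;
    }

    // --- precisions and u/v split in the Laplacian eigenbasis ---
    if (m > 0 && icar_rank > 0) {
      // w in the eigenbasis
      for (int k = 0; k < m; ++k) {
        double s = 0.0;
        for (int j = 0; j < m; ++j) {
          const int i2 = free_idx[j];
          s += Vt(k, j) * (u[i2] + v[i2]);
        }
        wt[k] = s;
      }
      double island_ss = 0.0;
      int n_island = 0;
      for (int i = 0; i < n; ++i) if (island[i]) {
        island_ss += v[i] * v[i];
        ++n_island;
      }
      // marginal MH on log(tau_u), then log(tau_v); the a*log(tau) prior
      // terms in marginal_lp already fold in the log-scale Jacobian
      // ((a-1)*log(tau) + log(tau)). Each evaluation is O(m), so the pair
      // is iterated many times per sweep: the precision posterior given w
      // is typically very wide and a single random-walk step per sweep
      // would traverse it slowly.
      for (int outer = 0; outer < 5; ++outer) {
        for (int rep = 0; rep < 8; ++rep) {
          {
            const double prop = tau_u * exp(rw_step(ls_tu));
            const double lr = marginal_lp(prop, tau_v, island_ss, n_island) -
              marginal_lp(tau_u, tau_v, island_ss, n_island);
            bool acc = log(R::runif(0.0, 1.0)) < lr;
            if (acc) tau_u = prop;
            if (adapting) ls_tu += delta * ((acc ? 1.0 : 0.0) - target);
          }
          {
            const double prop = tau_v * exp(rw_step(ls_tv));
            const double lr = marginal_lp(tau_u, prop, island_ss, n_island) -
              marginal_lp(tau_u, tau_v, island_ss, n_island);
            bool acc = log(R::runif(0.0, 1.0)) < lr;
            if (acc) tau_v = prop;
            if (adapting) ls_tv += delta * ((acc ? 1.0 : 0.0) - target);
          }
        }
        // joint scale move w -> c*w on the free nodes (c = exp(step), MH
        // with Jacobian m*log(c)). The site updates change the field's
        // overall magnitude one coordinate at a time, which is the slow
        // direction when the data are sparse and the prior dominates;
        // interleaving this move with the precision updates traverses the
        // (|w|, tau) funnel directly.
        {
          const double c = exp(rw_step(ls_w));
          double quad = 0.0;
          for (int k = 0; k < m; ++k) {
            const double s = (lambda[k] > lam_eps ? 1.0 / (tau_u * lambda[k])
                                                  : 0.0) + 1.0 / tau_v;
            quad += wt[k] * wt[k] / s;
          }
          double lik = 0.0;
          const double ea3 = exp(alpha);
          for (int j = 0; j < m; ++j) {
            const int i2 = free_idx[j];
            const double w0 = u[i2] + v[i2];
            lik += y[i2] * (c - 1.0) * w0 -
              ea3 * E[i2] * (exp(c * w0) - exp(w0));
          }
          const double lr = lik - 0.5 * (c * c - 1.0) * quad + m * log(c);
          bool acc = log(R::runif(0.0, 1.0)) < lr;
          if (acc) {
            for (int k = 0; k < m; ++k) wt[k] *= c;
            for (int j = 0; j < m; ++j) {
              const int i2 = free_idx[j];
              u[i2] *= c;
              v[i2] *= c;
            }
          }
          if (adapting) ls_w += delta * ((acc ? 1.0 : 0.0) - target);
        }
      }
      // independence refresh of random eigencomponents of w, proposing from
      // the prior N(0, s_k): the acceptance probability is the bare
      // likelihood ratio, close to one exactly in the sparse-data regime
      // where the coordinate-wise site updates decorrelate w most slowly.
      {
        const double ea4 = exp(alpha);
        const int n_try = m < 16 ? m : 16;
        for (int trial = 0; trial < n_try; ++trial) {
          const int k = (int)(R::unif_rand() * m);
          if (k >= m) continue;
          const double s = (lambda[k] > lam_eps ? 1.0 / (tau_u * lambda[k])
                                                : 0.0) + 1.0 / tau_v;
          const double propk = R::rnorm(0.0, sqrt(s));
          const double dk = propk - wt[k];
          double lik = 0.0;
          for (int j = 0; j < m; ++j) {
            const int i2 = free_idx[j];
            const double d = dk * Vt(k, j);
            const double w0 = u[i2] + v[i2];
            lik += y[i2] * d - ea4 * E[i2] * (exp(w0 + d) - exp(w0));
          }
          if (log(R::unif_rand()) < lik) {
            wt[k] = propk;
            for (int j = 0; j < m; ++j) v[free_idx[j]] += dk * Vt(k, j);
          }
        }
      }
      // exact Gibbs redraw of the split given w and the precisions; the
      // null components of the Laplacian stay at zero in u (sum-to-zero
      // convention), so their share of w remains in v
      for (int k = 0; k < m; ++k) {
        if (lambda[k] <= lam_eps) { ut[k] = 0.0; continue; }
        const double prec = tau_u * lambda[k] + tau_v;
        const double mean = wt[k] * tau_v / prec;
        ut[k] = mean + R::rnorm(0.0, 1.0) / sqrt(prec);
      }
      for (int j = 0; j < m; ++j) {
        const int i2 = free_idx[j];
        double s = 0.0;
        for (int k = 0; k < m; ++k) s += Vt(k, j) * ut[k];
        const double w = u[i2] + v[i2];
        u[i2] = s;
        v[i2] = w - s;
      }
    }

    // --- precisions (conjugate Gibbs refresh) ---
    {
      double ss = 0.0;
      for (int e = 0; e < n_edge; ++e) {
        const double diff = u[edge_i[e]] - u[edge_j[e]];
        ss += diff * diff;
      }
      if (icar_rank > 0)
        tau_u = R::rgamma(a + 0.5 * icar_rank, 1.0 / (b + 0.5 * ss));
      else
        tau_u = R::rgamma(a, 1.0 / b);
      double sv = 0.0;
      for (int i = 0; i < n; ++i) sv += v[i] * v[i];
      tau_v = R::rgamma(a + 0.5 * n, 1.0 / (b + 0.5 * sv));
    }

    if (!adapting) ++n_after;
    if (t > n_burnin && ((t - n_burnin) % thin == 0) && keep < n_keep) {
      alpha_draws[keep] = alpha;
      tau_u_draws[keep] = tau_u;
      tau_v_draws[keep] = tau_v;
      for (int i = 0; i < n; ++i) {
        u_draws(keep, i) = u[i];
        v_draws(keep, i) = v[i];
      }
      ++keep;
    }
  }

  NumericVector au(n), av(n);
  for (int i = 0; i < n; ++i) {
    au[i] = n_after > 0 ? acc_u[i] / n_after : NA_REAL;
    av[i] = n_after > 0 ? acc_v[i] / n_after : NA_REAL;
  }
  return List::create(
    _["alpha"] = alpha_draws, _["tau_u"] = tau_u_draws,
    _["tau_v"] = tau_v_draws, _["u"] = u_draws, _["v"] = v_draws,
    _["accept"] = List::create(
      _["alpha"] = n_after > 0 ? acc_alpha / n_after : NA_REAL,
      _["u"] = au, _["v"] = av));
}
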