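// Metropolis-within-Gibbs sampler for the BYM spatio-temporal Poisson model:
//   y_c ~ Poisson(n_c * exp(mu + alpha[age_c] + u[area_c] + v[area_c] + gamma[year_c]))
//   u ~ ICAR(tau_u) per graph component, v_i ~ N(0, 1/tau_v),
//   gamma ~ RW1(tau_g), mu/alpha ~ N(0, fe_sd^2), precisions ~ Gamma(a0, b0).
//
// The likelihood is evaluated incrementally: E_c = n_c * exp(eta_c) is cached
// per cell together with its totals by area / age / year, so a component-wise
// random-walk update touches only the cells its parameter enters.  Cells with
// n_c = 0 never reach this file (they contribute nothing to the likelihood).
//
// All randomness comes from R's RNG, so set.seed() at the R level makes a
// chain bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Cache {
  std::vector<double> E;             // n_c * exp(eta_c)
  double sumE;
  std::vector<double> byArea, byAge, byYear;
};

void rebuild_cache(Cache &cc,
                   const IntegerVector &y, const NumericVector &n,
                   const IntegerVector &area, const IntegerVector &age,
                   const IntegerVector &yr,
                   double mu, const NumericVector &alpha,
                   const NumericVector &u, const NumericVector &v,
                   const NumericVector &gamma) {
  const int N = y.size();
  std::fill(cc.byArea.begin(), cc.byArea.end(), 0.0);
  std::fill(cc.byAge.begin(), cc.byAge.end(), 0.0);
  std::fill(cc.byYear.begin(), cc.byYear.end(), 0.0);
  cc.sumE = 0.0;
  for (int c = 0; c < N; ++c) {
    double eta = mu + alpha[age[c]] + u[area[c]] + v[area[c]] + gamma[yr[c]];
    double e = n[c] * std::exp(eta);
    cc.E[c] = e;
    cc.sumE += e;
    cc.byArea[area[c]] += e;
    cc.byAge[age[c]] += e;
    cc.byYear[yr[c]] += e;
  }
}

inline double norm_prior_delta(double x, double d, double sd) {
  return -((x + d) * (x + d) - x * x) / (2.0 * sd * sd);
}

}  // namespace

// [[Rcpp::export]]
List cpp_bym_chain(IntegerVector y, NumericVector n,
                   IntegerVector area, IntegerVector age, IntegerVector yr,
                   int I, int A, int T,
                   List nbr0, IntegerMatrix edges0,
                   IntegerVector comp0, int C,
                   List init, NumericVector prop,
                   double a0, double b0, double fe_sd,
                   int iterations, int burn_in, int thin,
                   bool use_temporal, bool do_gibbs, bool adapt,
                   bool recenter) {
  const int N = y.size();
  NumericVector alpha = clone(as<NumericVector>(init["alpha"]));
  NumericVector u = clone(as<NumericVector>(init["u"]));
  NumericVector v = clone(as<NumericVector>(init["v"]));
  NumericVector gamma = clone(as<NumericVector>(init["gamma"]));
  double mu = as<double>(init["mu"]);
  double tau_u = as<double>(init["tau_u"]);
  double tau_v = as<double>(init["tau_v"]);
  double tau_g = as<double>(init["tau_g"]);

  // proposal SDs per block: mu, alpha, u, v, gamma
  double sd_mu = prop["mu"], sd_al = prop["alpha"], sd_u = prop["u"],
         sd_v = prop["v"], sd_g = prop["gamma"];
  double sd_us = prop.containsElementNamed("u_scale") ? (double)prop["u_scale"] : 0.1;

  // per-parameter cell lists
  std::vector<std::vector<int>> cellsArea(I), cellsAge(A), cellsYear(T);
  std::vector<double> sumY_area(I, 0.0), sumY_age(A, 0.0), sumY_year(T, 0.0);
  double sumY = 0.0;
  for (int c = 0; c < N; ++c) {
    cellsArea[area[c]].push_back(c);
    cellsAge[age[c]].push_back(c);
    cellsYear[yr[c]].push_back(c);
    sumY += y[c];
    sumY_area[area[c]] += y[c];
    sumY_age[age[c]] += y[c];
    sumY_year[yr[c]] += y[c];
  }
  std::vector<std::vector<int>> nbr(I);
  for (int i = 0; i < I; ++i) nbr[i] = as<std::vector<int>>(nbr0[i]);
  std::vector<int> compSize(C, 0);
  for (int i = 0; i < I; ++i) compSize[comp0[i]]++;

  Cache cc;
  cc.E.assign(N, 0.0);
  cc.byArea.assign(I, 0.0);
  cc.byAge.assign(A, 0.0);
  cc.byYear.assign(T, 0.0);
  rebuild_cache(cc, y, n, area, age, yr, mu, alpha, u, v, gamma);

  const int M = (thin > 0) ? (iterations - burn_in) / thin : 0;
  NumericVector d_mu(std::max(M, 0)), d_tu(std::max(M, 0)),
      d_tv(std::max(M, 0)), d_tg(std::max(M, 0));
  NumericMatrix d_alpha(std::max(M, 0), A), d_u(std::max(M, 0), I),
      d_v(std::max(M, 0), I), d_gamma(std::max(M, 0), T);

  // acceptance bookkeeping: [0] post-burn-in totals, batch counters for
  // Roberts–Rosenthal adaptation toward 0.44 during burn-in
  double acc[6] = {0, 0, 0, 0, 0, 0}, att[6] = {0, 0, 0, 0, 0, 0};
  double bacc[6] = {0, 0, 0, 0, 0, 0}, batt[6] = {0, 0, 0, 0, 0, 0};
  int batch = 0;
  const int batch_len = 50;

  auto scale_cells = [&](const std::vector<int> &cells, double g) {
    for (int c : cells) {
      double e = cc.E[c];
      cc.sumE -= e;
      cc.byArea[area[c]] -= e;
      cc.byAge[age[c]] -= e;
      cc.byYear[yr[c]] -= e;
      e *= g;
      cc.E[c] = e;
      cc.sumE += e;
      cc.byArea[area[c]] += e;
      cc.byAge[age[c]] += e;
      cc.byYear[yr[c]] += e;
    }
  };

  int rec = 0;
  for (int iter = 1; iter <= iterations; ++iter) {
    bool tracking = iter > burn_in;

    // --- mu ---
    {
      double d = R::rnorm(0.0, sd_mu);
      double g = std::exp(d);
      double lp = d * sumY - (g - 1.0) * cc.sumE + norm_prior_delta(mu, d, fe_sd);
      att[0] += 1; batt[0] += 1;
      if (std::log(unif_rand()) < lp) {
        mu += d;
        for (int c = 0; c < N; ++c) cc.E[c] *= g;
        cc.sumE *= g;
        for (int i = 0; i < I; ++i) cc.byArea[i] *= g;
        for (int a = 0; a < A; ++a) cc.byAge[a] *= g;
        for (int t = 0; t < T; ++t) cc.byYear[t] *= g;
        acc[0] += tracking; bacc[0] += 1;
      }
    }

    // --- alpha (skip when a single age group: pinned at 0 by the constraint) ---
    if (A > 1) {
      for (int a = 0; a < A; ++a) {
        double d = R::rnorm(0.0, sd_al);
        double g = std::exp(d);
        double lp = d * sumY_age[a] - (g - 1.0) * cc.byAge[a] +
                    norm_prior_delta(alpha[a], d, fe_sd);
        att[1] += 1; batt[1] += 1;
        if (std::log(unif_rand()) < lp) {
          alpha[a] += d;
          scale_cells(cellsAge[a], g);
          acc[1] += tracking; bacc[1] += 1;
        }
      }
      if (recenter) {  // mu absorbs the mean; eta is exactly unchanged
        double m = mean(alpha);
        for (int a = 0; a < A; ++a) alpha[a] -= m;
        mu += m;
      }
    }

    // --- u (spatially structured) ---
    for (int i = 0; i < I; ++i) {
      double d = R::rnorm(0.0, sd_u);
      double g = std::exp(d);
      double s = 0.0;
      for (int j : nbr[i]) s += (u[i] - u[j]);
      double deg = (double)nbr[i].size();
      double lp = d * sumY_area[i] - (g - 1.0) * cc.byArea[i]
                  - 0.5 * tau_u * (deg * d * d + 2.0 * d * s);
      att[2] += 1; batt[2] += 1;
      if (std::log(unif_rand()) < lp) {
        u[i] += d;
        scale_cells(cellsArea[i], g);
        acc[2] += tracking; bacc[2] += 1;
      }
    }
    if (recenter) {
      std::vector<double> m(C, 0.0);
      for (int i = 0; i < I; ++i) m[comp0[i]] += u[i];
      for (int c2 = 0; c2 < C; ++c2) m[c2] /= compSize[c2];
      double grand = 0.0;
      for (int i = 0; i < I; ++i) { grand += m[comp0[i]]; u[i] -= m[comp0[i]]; }
      mu += grand / I;
      if (C > 1) {
        // per-component shifts are not a global constant: refresh the cache
        rebuild_cache(cc, y, n, area, age, yr, mu, alpha, u, v, gamma);
      }
    }

    // --- joint rescale of u: u' = s u, s = exp(d) ---
    // Moves along the prior's scale direction, decoupling u from tau_u
    // (the classic slow-mixing pair for ICAR models).  The move stays in the
    // per-component sum-to-zero subspace of dimension I - C, hence the
    // Jacobian term (I - C) * d.
    if (sd_us > 0.0) {
      double d = R::rnorm(0.0, sd_us);
      double s = std::exp(d);
      double qf0 = 0.0;
      for (int e = 0; e < edges0.nrow(); ++e) {
        double diff = u[edges0(e, 0)] - u[edges0(e, 1)];
        qf0 += diff * diff;
      }
      double lp = (I - C) * d - 0.5 * tau_u * (s * s - 1.0) * qf0;
      for (int i = 0; i < I; ++i) {
        double du = (s - 1.0) * u[i];
        lp += du * sumY_area[i] - (std::exp(du) - 1.0) * cc.byArea[i];
      }
      att[5] += 1; batt[5] += 1;
      if (std::isfinite(lp) && std::log(unif_rand()) < lp) {
        for (int i = 0; i < I; ++i) {
          double g = std::exp((s - 1.0) * u[i]);
          u[i] *= s;
          scale_cells(cellsArea[i], g);
        }
        acc[5] += tracking; bacc[5] += 1;
      }
    }

    // --- v (unstructured) ---
    for (int i = 0; i < I; ++i) {
      double d = R::rnorm(0.0, sd_v);
      double g = std::exp(d);
      double lp = d * sumY_area[i] - (g - 1.0) * cc.byArea[i]
                  - 0.5 * tau_v * ((v[i] + d) * (v[i] + d) - v[i] * v[i]);
      att[3] += 1; batt[3] += 1;
      if (std::log(unif_rand()) < lp) {
        v[i] += d;
        scale_cells(cellsArea[i], g);
        acc[3] += tracking; bacc[3] += 1;
      }
    }

    // --- gamma (RW1 year effect) ---
    if (use_temporal && T > 1) {
      for (int t = 0; t < T; ++t) {
        double d = R::rnorm(0.0, sd_g);
        double g = std::exp(d);
        double pr = 0.0;
        if (t > 0) {
          double a1 = gamma[t] - gamma[t - 1];
          pr += (a1 + d) * (a1 + d) - a1 * a1;
        }
        if (t < T - 1) {
          double a2 = gamma[t + 1] - gamma[t];
          pr += (a2 - d) * (a2 - d) - a2 * a2;
        }
        double lp = d * sumY_year[t] - (g - 1.0) * cc.byYear[t] - 0.5 * tau_g * pr;
        att[4] += 1; batt[4] += 1;
        if (std::log(unif_rand()) < lp) {
          gamma[t] += d;
          scale_cells(cellsYear[t], g);
          acc[4] += tracking; bacc[4] += 1;
        }
      }
      if (recenter) {
        double m = mean(gamma);
        for (int t = 0; t < T; ++t) gamma[t] -= m;
        mu += m;
      }
    }

    // --- conjugate Gibbs draws for the precisions ---
    if (do_gibbs) {
      double qf = 0.0;
      for (int e = 0; e < edges0.nrow(); ++e) {
        double diff = u[edges0(e, 0)] - u[edges0(e, 1)];
        qf += diff * diff;
      }
      tau_u = R::rgamma(a0 + 0.5 * (I - C), 1.0 / (b0 + 0.5 * qf));
      double sv = 0.0;
      for (int i = 0; i < I; ++i) sv += v[i] * v[i];
      tau_v = R::rgamma(a0 + 0.5 * I, 1.0 / (b0 + 0.5 * sv));
      if (use_temporal && T > 1) {
        double sg = 0.0;
        for (int t = 1; t < T; ++t) {
          double diff = gamma[t] - gamma[t - 1];
          sg += diff * diff;
        }
        tau_g = R::rgamma(a0 + 0.5 * (T - 1), 1.0 / (b0 + 0.5 * sg));
      }
    }

    // --- proposal adaptation during burn-in, frozen afterwards ---
    if (adapt && iter <= burn_in && iter % batch_len == 0) {
      batch++;
      double step = std::min(0.05, 1.0 / std::sqrt((double)batch));
      double *sds[6] = {&sd_mu, &sd_al, &sd_u, &sd_v, &sd_g, &sd_us};
      for (int b = 0; b < 6; ++b) {
        if (batt[b] > 0) {
          double rate = bacc[b] / batt[b];
          *sds[b] *= std::exp(rate > 0.44 ? step : -step);
        }
        bacc[b] = 0; batt[b] = 0;
      }
    }

    // periodic refresh kills float drift in the incremental cache
    if (iter % 500 == 0) {
      rebuild_cache(cc, y, n, area, age, yr, mu, alpha, u, v, gamma);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && rec < M) {
      d_mu[rec] = mu; d_tu[rec] = tau_u; d_tv[rec] = tau_v; d_tg[rec] = tau_g;
      for (int a = 0; a < A; ++a) d_alpha(rec, a) = alpha[a];
      for (int i = 0; i < I; ++i) { d_u(rec, i) = u[i]; d_v(rec, i) = v[i]; }
      for (int t = 0; t < T; ++t) d_gamma(rec, t) = gamma[t];
      rec++;
    }
  }

  NumericVector acc_rate(6), final_prop = NumericVector::create(
      _["mu"] = sd_mu, _["alpha"] = sd_al, _["u"] = sd_u, _["v"] = sd_v,
      _["gamma"] = sd_g, _["u_scale"] = sd_us);
  for (int b = 0; b < 6; ++b) {
    double post_att = att[b] - (att[b] / iterations) * burn_in;
    acc_rate[b] = post_att > 0 ? acc[b] / post_att : NA_REAL;
  }
  acc_rate.names() = CharacterVector::create("mu", "alpha", "u", "v", "gamma", "u_scale");

  return List::create(
      _["mu"] = d_mu, _["alpha"] = d_alpha, _["u"] = d_u, _["v"] = d_v,
      _["gamma"] = d_gamma, _["tau_u"] = d_tu, _["tau_v"] = d_tv,
      _["tau_g"] = d_tg,
      _["acceptance"] = acc_rate, _["proposal_sd"] = final_prop,
      _["final_state"] = List::create(
          _["mu"] = mu, _["alpha"] = alpha, _["u"] = u, _["v"] = v,
          _["gamma"] = gamma, _["tau_u"] = tau_u, _["tau_v"] = tau_v,
          _["tau_g"] = tau_g));
}
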