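#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gene dropping: batched meiosis under the Haldane (no-interference) model.
// Crossovers per chromosome are Poisson(L) at Uniform(0, L) positions; the
// starting parental strand is a fair coin per chromosome.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_drop_gametes(const IntegerMatrix& hap_a,
                               const IntegerMatrix& hap_b,
                               const IntegerVector& parent_row,
                               const NumericVector& pos,
                               const IntegerVector& chrom,
                               const NumericVector& chrom_len) {
  const int m = pos.size();
  const int g = parent_row.size();
  IntegerMatrix out(g, m);
  const int n_chrom = chrom_len.size();

  // locus index ranges per chromosome (loci grouped, positions nondecreasing)
  std::vector<int> c_start(n_chrom, -1), c_end(n_chrom, -1);
  for (int j = 0; j < m; ++j) {
    int c = chrom[j] - 1;
    if (c_start[c] < 0) c_start[c] = j;
    c_end[c] = j;
  }

  std::vector<double> bp;
  for (int i = 0; i < g; ++i) {
    const int p = parent_row[i] - 1;
    for (int cc = 0; cc < n_chrom; ++cc) {
      if (c_start[cc] < 0) continue;
      double L = chrom_len[cc];
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      int k = (int) R::rpois(L);
      bp.clear();
      for (int b = 0; b < k; ++b) bp.push_back(unif_rand() * L);
      std::sort(bp.begin(), bp.end());
      size_t next = 0;
      for (int j = c_start[cc]; j <= c_end[cc]; ++j) {
        while (next < bp.size() && bp[next] <= pos[j]) { cur = 1 - cur; ++next; }
        out(i, j) = (cur == 0) ? hap_a(p, j) : hap_b(p, j);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Distributional helpers for the whole-genome regression samplers.  Exposed
// individually so each conditional can be exercised against closed forms.
// ---------------------------------------------------------------------------

static double rinvgauss1(double mu, double lambda) {
  // Michael, Schucany & Haas
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
double cpp_rinvgauss(double mu, double lambda) { return rinvgauss1(mu, lambda); }

// pi | indicators ~ Beta(1 + m1, 1 + m - m1)  (flat prior on pi)
// [[Rcpp::export]]
double cpp_draw_pi(int m1, int m) {
  return R::rbeta(1.0 + m1, 1.0 + (m - m1));
}

// Laplace rate: flat prior on lambda^2, exponential mixing variances tau2:
// lambda^2 | tau2 ~ Gamma(m + 1, rate = sum(tau2)/2); returns lambda
// [[Rcpp::export]]
double cpp_draw_lasso_rate(const NumericVector& tau2) {
  double s = 0.0;
  for (double t : tau2) s += t;
  double l2 = R::rgamma(tau2.size() + 1.0, 2.0 / s);
  return std::sqrt(l2);
}

// t-prior scale S: flat prior, sigma2_j ~ scaled-inv-chisq(df, S):
// S | sigma2, df ~ Gamma(m*df/2 + 1, rate = (df/2) * sum(1/sigma2_j))
// [[Rcpp::export]]
double cpp_draw_t_scale(const NumericVector& sigma2, double df) {
  double s = 0.0;
  for (double v : sigma2) s += 1.0 / v;
  return R::rgamma(sigma2.size() * df / 2.0 + 1.0, 1.0 / (df / 2.0 * s));
}

// log conditional density of df given per-SNP variances (flat prior on df)
// [[Rcpp::export]]
double cpp_df_logpost(double df, double S, const NumericVector& sigma2) {
  double lp = 0.0;
  double ld = df / 2.0 * std::log(df * S / 2.0) - R::lgammafn(df / 2.0);
  for (double v : sigma2) {
    lp += ld - (df / 2.0 + 1.0) * std::log(v) - df * S / (2.0 * v);
  }
  return lp;
}

// one random-walk Metropolis step on log(df) with reflection at [lo, hi]
// [[Rcpp::export]]
List cpp_df_mh_step(double df, double S, const NumericVector& sigma2,
                    double step, double lo, double hi) {
  double llo = std::log(lo), lhi = std::log(hi);
  double prop = std::log(df) + step * norm_rand();
  // reflect into [llo, lhi]
  for (int it = 0; it < 64 && (prop < llo || prop > lhi); ++it) {
    if (prop < llo) prop = 2.0 * llo - prop;
    if (prop > lhi) prop = 2.0 * lhi - prop;
  }
  double dfp = std::exp(prop);
  // flat prior on df, log-scale proposal => Jacobian log(df)
  double la = cpp_df_logpost(dfp, S, sigma2) + std::log(dfp) -
              cpp_df_logpost(df, S, sigma2) - std::log(df);
  bool acc = std::log(unif_rand()) < la;
  return List::create(_["df"] = acc ? dfp : df, _["accepted"] = acc);
}

// ---------------------------------------------------------------------------
// Single-site Gibbs sampler for y = mu + Z beta + e under four prior families
// method: 0 = LASSO (Laplace), 1 = Bayes A (scaled-t), 2 = BBn (spike +
// normal slab), 3 = BBt (spike + t slab).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_wgr_chain(const NumericVector& y,
                   const NumericMatrix& Zp,
                   const NumericMatrix& Zall,
                   int method,
                   double lambda0, bool est_lambda,
                   double df0, bool est_df, double df_lo, double df_hi,
                   double pi0, bool est_pi,
                   double s2snp0,
                   int burn_in, int n_samples, int thin,
                   bool mu_fixed, double mu_fix_value,
                   bool s2e_fixed, double s2e_fix_value,
                   int verbose) {
  const int n = Zp.nrow(), m = Zp.ncol(), N = Zall.nrow();
  const bool spike = (method == 2 || method == 3);
  const bool has_persnp_var = (method == 1 || method == 3); // scaled-t slab
  const int total_cycles = burn_in + n_samples * thin;

  std::vector<double> zz(m);
  for (int j = 0; j < m; ++j) {
    const double* z = &Zp(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += z[i] * z[i];
    zz[j] = s;
  }

  // state
  double mu = mu_fixed ? mu_fix_value : mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e;
  {
    double vy = 0.0, my = mean(y);
    for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
    vy /= (n - 1);
    s2e = s2e_fixed ? s2e_fix_value : vy;
  }
  std::vector<double> beta(m, 0.0), s2j(m, s2snp0), tau2(m, s2snp0);
  std::vector<int> delta(m, 1);
  double lambda = lambda0;   // Laplace rate (LASSO) or t scale S (BayesA/BBt)
  double s2snp = s2snp0;     // shared normal slab variance (BBn)
  double df = df0, pi = pi0;
  if (spike) {
    for (int j = 0; j < m; ++j) delta[j] = (unif_rand() < pi) ? 1 : 0;
  }

  // df adaptation
  double df_step = 0.5;
  int df_try = 0, df_acc = 0, df_acc_total = 0, df_try_total = 0;

  // accumulators
  std::vector<double> beta_sum(m, 0.0), delta_sum(m, 0.0);
  std::vector<double> u(N), u_sum(N, 0.0), u_ss(N, 0.0);
  NumericMatrix trace(n_samples, 7); // mu s2e lambda pi df s2snp m1
  CharacterVector trace_names =
    CharacterVector::create("mu", "sigma2_e", "lambda", "pi", "df",
                            "sigma2_snp", "n_included");
  int kept = 0;

  for (int cyc = 1; cyc <= total_cycles; ++cyc) {
    // mean
    if (!mu_fixed) {
      double me = 0.0;
      for (int i = 0; i < n; ++i) me += e[i];
      me /= n;
      double mu_new = mu + me + norm_rand() * std::sqrt(s2e / n);
      double d = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= d;
      mu = mu_new;
    }

    // SNP effects (single site, residual maintained incrementally)
    for (int j = 0; j < m; ++j) {
      const double* z = &Zp(0, j);
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += z[i] * e[i];
      r += zz[j] * beta[j];
      double v1 = spike ? (method == 2 ? s2snp : s2j[j])
                        : (method == 0 ? tau2[j] : s2j[j]);
      if (spike) {
        int d_new;
        if (pi >= 1.0) d_new = 1;
        else if (pi <= 0.0) d_new = 0;
        else {
          double lbf = 0.5 * std::log(s2e / (s2e + v1 * zz[j])) +
            0.5 * r * r * v1 / (s2e * (s2e + v1 * zz[j]));
          double logit = std::log(pi / (1.0 - pi)) + lbf;
          double p1 = 1.0 / (1.0 + std::exp(-logit));
          d_new = (unif_rand() < p1) ? 1 : 0;
        }
        delta[j] = d_new;
        if (d_new == 0) {
          if (beta[j] != 0.0) {
            double d = -beta[j];
            for (int i = 0; i < n; ++i) e[i] -= z[i] * d;
            beta[j] = 0.0;
          }
          continue;
        }
      }
      double denom = zz[j] + s2e / v1;
      double b_new = r / denom + norm_rand() * std::sqrt(s2e / denom);
      double d = b_new - beta[j];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= z[i] * d;
      beta[j] = b_new;
    }

    // per-SNP prior scales
    if (method == 0) {
      for (int j = 0; j < m; ++j) {
        double ab = std::fabs(beta[j]);
        double mu_ig = (ab > 1e-10) ? lambda / ab : 1e10;
        if (mu_ig > 1e10) mu_ig = 1e10;
        double x = rinvgauss1(mu_ig, lambda * lambda);
        tau2[j] = 1.0 / x;
        if (tau2[j] < 1e-12) tau2[j] = 1e-12;
      }
    } else if (has_persnp_var) {
      for (int j = 0; j < m; ++j) {
        if (method == 1 || delta[j] == 1) {
          s2j[j] = (df * lambda + beta[j] * beta[j]) / R::rchisq(df + 1.0);
        } else {
          s2j[j] = df * lambda / R::rchisq(df); // prior draw for excluded SNP
        }
        if (s2j[j] < 1e-12) s2j[j] = 1e-12;
      }
    }

    // hyperparameters
    int m1 = 0;
    if (spike) for (int j = 0; j < m; ++j) m1 += delta[j];
    if (est_lambda) {
      if (method == 0) {
        lambda = cpp_draw_lasso_rate(NumericVector(tau2.begin(), tau2.end()));
      } else if (has_persnp_var) {
        lambda = cpp_draw_t_scale(NumericVector(s2j.begin(), s2j.end()), df);
      }
      if (lambda < 1e-8) lambda = 1e-8;
      if (lambda > 1e8) lambda = 1e8;
    }
    if (method == 2 && est_lambda) {
      // shared slab variance, flat prior; the conditional is proper only
      // with >= 3 included SNP -- otherwise a reference scaled-inv-chisq
      // draw around the initial scale keeps the chain mobile
      if (m1 >= 3) {
        double bb = 0.0;
        for (int j = 0; j < m; ++j) if (delta[j]) bb += beta[j] * beta[j];
        s2snp = (bb / 2.0) / R::rgamma(m1 / 2.0 - 1.0, 1.0);
      } else {
        s2snp = 4.0 * s2snp0 / R::rchisq(4.0);
      }
      if (s2snp < 1e-8) s2snp = 1e-8;
      if (s2snp > 1e8) s2snp = 1e8;
    }
    if (spike && est_pi) pi = cpp_draw_pi(m1, m);
    if (has_persnp_var && est_df) {
      NumericVector sv(s2j.begin(), s2j.end());
      List st = cpp_df_mh_step(df, lambda, sv, df_step, df_lo, df_hi);
      df = as<double>(st["df"]);
      bool acc = as<bool>(st["accepted"]);
      ++df_try; ++df_try_total;
      if (acc) { ++df_acc; ++df_acc_total; }
      if (cyc <= burn_in && df_try >= 100) { // adapt toward 20-40% acceptance
        double rate = (double) df_acc / df_try;
        if (rate > 0.40) df_step *= 1.2;
        else if (rate < 0.20) df_step /= 1.2;
        df_try = 0; df_acc = 0;
      }
    }

    // residual variance (flat prior on the variance)
    if (!s2e_fixed) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (n > 4) s2e = sse / R::rchisq(n - 2.0);
      if (s2e < 1e-12) s2e = 1e-12;
    }

    // periodic full residual recomputation to cap incremental drift
    if (cyc % 100 == 0) {
      for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
      for (int j = 0; j < m; ++j) {
        if (beta[j] != 0.0) {
          const double* z = &Zp(0, j);
          for (int i = 0; i < n; ++i) e[i] -= z[i] * beta[j];
        }
      }
    }

    // retention
    if (cyc > burn_in && (cyc - burn_in) % thin == 0) {
      std::fill(u.begin(), u.end(), 0.0);
      for (int j = 0; j < m; ++j) {
        if (beta[j] != 0.0) {
          const double* za = &Zall(0, j);
          for (int i = 0; i < N; ++i) u[i] += za[i] * beta[j];
        }
      }
      for (int i = 0; i < N; ++i) { u_sum[i] += u[i]; u_ss[i] += u[i] * u[i]; }
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        delta_sum[j] += spike ? delta[j] : 1.0;
      }
      trace(kept, 0) = mu; trace(kept, 1) = s2e;
      trace(kept, 2) = (method == 2) ? s2snp : lambda;
      trace(kept, 3) = spike ? pi : NA_REAL;
      trace(kept, 4) = has_persnp_var ? df : NA_REAL;
      trace(kept, 5) = (method == 2) ? s2snp : NA_REAL;
      trace(kept, 6) = spike ? (double) m1 : (double) m;
      ++kept;
    }
    if (verbose > 0 && cyc % 10000 == 0) {
      Rcpp::Rcout << "cycle " << cyc << "/" << total_cycles;
      if (est_df && df_try_total > 0)
        Rcpp::Rcout << " (df acceptance "
                    << (double) df_acc_total / df_try_total << ")";
      Rcpp::Rcout << std::endl;
    }
    if (cyc % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector beta_hat(m), incl(m), gebv(N), pev(N);
  for (int j = 0; j < m; ++j) {
    beta_hat[j] = beta_sum[j] / kept;
    incl[j] = delta_sum[j] / kept;
  }
  for (int i = 0; i < N; ++i) {
    gebv[i] = u_sum[i] / kept;
    double v = u_ss[i] / kept - gebv[i] * gebv[i];
    pev[i] = v > 0 ? v * kept / std::max(1, kept - 1) : 0.0;
  }
  colnames(trace) = trace_names;
  return List::create(
    _["beta"] = beta_hat, _["inclusion_prob"] = incl,
    _["gebv"] = gebv, _["pev"] = pev,
    _["trace"] = trace, _["n_cycles"] = total_cycles,
    _["df_acceptance"] = df_try_total > 0 ?
        (double) df_acc_total / df_try_total : NA_REAL);
}
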