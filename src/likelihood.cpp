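#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---- dropout-configuration bookkeeping -------------------------------------
// One admissible amplification configuration (k REF copies, l ALT copies
// amplified, (k,l) != (0,0)) of a genotype with allele copies (cr, ca).
struct DropTerm {
  double log_w;       // log binomial weight of the configuration
  double f;           // error-adjusted expected ALT fraction
  bool hom;           // amplified copies single-allele?
  double lbeta_const; // log B(omega f, omega (1-f))
  int n_drop;         // copies dropped = cr + ca - k - l
};

static std::vector<DropTerm> drop_terms(int cr, int ca, double mu, double eps,
                                        double om_hom, double om_het) {
  std::vector<DropTerm> terms;
  int c_tot = cr + ca;
  double lmu = (mu > 0) ? std::log(mu) : NEG_INF;
  double l1mu = std::log1p(-mu);
  for (int k = 0; k <= cr; ++k) {
    for (int l = 0; l <= ca; ++l) {
      if (k + l == 0) continue;
      int nd = c_tot - k - l;
      double lw;
      if (nd == 0) lw = (k + l) * l1mu;
      else if (mu <= 0) continue; // zero-probability configuration
      else lw = nd * lmu + (k + l) * l1mu;
      lw += R::lchoose(cr, k) + R::lchoose(ca, l);
      DropTerm t;
      t.log_w = lw;
      t.f = (l * (1.0 - eps) + k * eps) / (k + l);
      t.hom = (k == 0 || l == 0);
      double om = t.hom ? om_hom : om_het;
      t.lbeta_const = R::lbeta(om * t.f, om * (1.0 - t.f));
      t.n_drop = nd;
      terms.push_back(t);
    }
  }
  return terms;
}

// Allelic log-likelihood column for one variant under one genotype (cr, ca),
// over all cells; optionally also the posterior mean number of dropped
// copies per cell (for the EM M-step).  Zero-depth cells contribute
// log-probability 0 but still carry the prior dropout posterior.
static void allelic_column(int n_cells, const IntegerMatrix& alt,
                           const IntegerMatrix& dp, int i, int cr, int ca,
                           double mu, double eps, double om_hom,
                           double om_het, bool renorm,
                           const NumericMatrix& lchoose_da,
                           const NumericMatrix& lg_d_omhom,
                           const NumericMatrix& lg_d_omhet,
                           double* ll_out, double* edrop_out) {
  int c_tot = cr + ca;
  if (c_tot == 0) {
    // locus fully deleted: reads can only be sequencing error
    double f = eps;
    double lbc = R::lbeta(om_hom * f, om_hom * (1.0 - f));
    double lg_om = std::lgamma(om_hom);
    for (int j = 0; j < n_cells; ++j) {
      int d = dp(j, i), a = alt(j, i);
      if (d == 0) { ll_out[j] = 0.0; }
      else {
        ll_out[j] = lchoose_da(j, i) + std::lgamma(a + om_hom * f) +
          std::lgamma(d - a + om_hom * (1.0 - f)) - lg_d_omhom(j, i) - lbc;
      }
      if (edrop_out) edrop_out[j] = 0.0;
    }
    return;
  }
  std::vector<DropTerm> terms = drop_terms(cr, ca, mu, eps, om_hom, om_het);
  int nt = terms.size();
  double lg_om_hom = std::lgamma(om_hom), lg_om_het = std::lgamma(om_het);
  double lnorm = 0.0;
  if (renorm && mu > 0) lnorm = std::log1p(-std::pow(mu, c_tot));

  // prior-only posterior (zero-depth cells): same for every such cell
  double prior_edrop = 0.0;
  {
    double mx = NEG_INF;
    for (int t = 0; t < nt; ++t) mx = std::max(mx, terms[t].log_w);
    double s = 0.0, sd = 0.0;
    for (int t = 0; t < nt; ++t) {
      double w = std::exp(terms[t].log_w - mx);
      s += w; sd += w * terms[t].n_drop;
    }
    prior_edrop = sd / s;
  }

  std::vector<double> buf(nt);
  for (int j = 0; j < n_cells; ++j) {
    int d = dp(j, i), a = alt(j, i);
    if (d == 0) {
      ll_out[j] = 0.0;
      if (edrop_out) edrop_out[j] = prior_edrop;
      continue;
    }
    double mx = NEG_INF;
    for (int t = 0; t < nt; ++t) {
      const DropTerm& tt = terms[t];
      double om = tt.hom ? om_hom : om_het;
      double lg_d_om = tt.hom ? lg_d_omhom(j, i) : lg_d_omhet(j, i);
      double lg_om = tt.hom ? lg_om_hom : lg_om_het;
      double bb = lchoose_da(j, i) + std::lgamma(a + om * tt.f) +
        std::lgamma(d - a + om * (1.0 - tt.f)) - lg_d_om - tt.lbeta_const;
      buf[t] = tt.log_w + bb;
      if (buf[t] > mx) mx = buf[t];
    }
    double s = 0.0, sd = 0.0;
    for (int t = 0; t < nt; ++t) {
      double w = std::exp(buf[t] - mx);
      s += w; sd += w * terms[t].n_drop;
    }
    ll_out[j] = mx + std::log(s) - lnorm;
    if (edrop_out) edrop_out[j] = sd / s;
  }
}

// Region-depth log-likelihood matrix (cells x attachments); negative
// binomial with mean D_j c_k rho_k / sum_l c_l rho_l and inverse
// dispersion theta.  lgamma caches are precomputed in R.
static NumericMatrix region_ll_matrix(const IntegerMatrix& region_depth,
                                      const NumericVector& cell_total,
                                      const NumericMatrix& region_cn,
                                      const NumericVector& rho, double theta,
                                      const NumericMatrix& lg_d_theta,
                                      const NumericMatrix& lg_d1) {
  int n_cells = region_depth.nrow(), n_regions = region_depth.ncol();
  int n_attach = region_cn.nrow();
  NumericMatrix out(n_cells, n_attach);
  double lg_theta = std::lgamma(theta), ltheta = std::log(theta);
  // attachments sharing a copy-number profile share their column
  std::vector<int> share(n_attach, -1);
  for (int a = 1; a < n_attach; ++a) {
    for (int b = 0; b < a; ++b) {
      bool same = true;
      for (int k = 0; k < n_regions && same; ++k)
        if (region_cn(a, k) != region_cn(b, k)) same = false;
      if (same) { share[a] = b; break; }
    }
  }
  for (int a = 0; a < n_attach; ++a) {
    if (share[a] >= 0) {
      for (int j = 0; j < n_cells; ++j) out(j, a) = out(j, share[a]);
      continue;
    }
    double denom = 0.0;
    for (int k = 0; k < n_regions; ++k) denom += region_cn(a, k) * rho[k];
    if (denom <= 0) {
      for (int j = 0; j < n_cells; ++j) out(j, a) = NEG_INF;
      continue;
    }
    for (int k = 0; k < n_regions; ++k) {
      double coef = region_cn(a, k) * rho[k] / denom;
      if (coef <= 0) {
        for (int j = 0; j < n_cells; ++j)
          if (region_depth(j, k) > 0) out(j, a) = NEG_INF;
        continue;
      }
      for (int j = 0; j < n_cells; ++j) {
        double m = cell_total[j] * coef;
        double lm_t = std::log(theta + m);
        int d = region_depth(j, k);
        double ll = lg_d_theta(j, k) - lg_d1(j, k) - lg_theta +
          theta * (ltheta - lm_t);
        if (d > 0) ll += d * (std::log(m) - lm_t);
        out(j, a) += ll;
      }
    }
  }
  return out;
}

// genotype key for deduplication (allele copies are small non-negatives)
static inline int geno_key(int cr, int ca) { return cr * 32 + ca; }

// [[Rcpp::export]]
NumericMatrix cpp_attach_loglik(IntegerMatrix region_depth,
                                NumericVector cell_total, IntegerMatrix alt,
                                IntegerMatrix dp, NumericMatrix region_cn,
                                NumericMatrix cr_m, NumericMatrix ca_m,
                                NumericVector mu, NumericVector rho,
                                double theta, double eps, double om_hom,
                                double om_het, bool renorm,
                                NumericMatrix lg_d_theta, NumericMatrix lg_d1,
                                NumericMatrix lchoose_da,
                                NumericMatrix lg_d_omhom,
                                NumericMatrix lg_d_omhet) {
  int n_cells = region_depth.nrow();
  int n_attach = region_cn.nrow();
  int n_variants = cr_m.ncol();
  NumericMatrix out = region_ll_matrix(region_depth, cell_total, region_cn,
                                       rho, theta, lg_d_theta, lg_d1);
  std::vector<double> col(n_cells);
  for (int i = 0; i < n_variants; ++i) {
    std::vector<int> key_of(256, -1);
    std::vector<std::vector<double> > uniq_ll;
    std::vector<int> map_a(n_attach);
    for (int a = 0; a < n_attach; ++a) {
      int cr = (int)std::lround(cr_m(a, i)), ca = (int)std::lround(ca_m(a, i));
      int key = geno_key(cr, ca);
      if (key_of[key] < 0) {
        allelic_column(n_cells, alt, dp, i, cr, ca, mu[i], eps, om_hom,
                       om_het, renorm, lchoose_da, lg_d_omhom, lg_d_omhet,
                       col.data(), NULL);
        key_of[key] = uniq_ll.size();
        uniq_ll.push_back(col);
      }
      map_a[a] = key_of[key];
    }
    for (int a = 0; a < n_attach; ++a) {
      const std::vector<double>& v = uniq_ll[map_a[a]];
      for (int j = 0; j < n_cells; ++j) out(j, a) += v[j];
    }
  }
  return out;
}

// expected complete-data log-posterior in mu for one variant under the
// amplification-conditioned (renormalised) dropout model
static double mu_objective(double mu, double s_drop, double s_amp,
                           double alpha, double beta,
                           const std::vector<double>& w_c) {
  double g = (alpha - 1.0 + s_drop) * std::log(mu) +
    (beta - 1.0 + s_amp) * std::log1p(-mu);
  for (size_t c = 1; c < w_c.size(); ++c)
    if (w_c[c] > 0)
      g -= w_c[c] * std::log1p(-std::pow(mu, (double)c));
  return g;
}

static double maximize_mu(double s_drop, double s_amp, double alpha,
                          double beta, const std::vector<double>& w_c,
                          double lo, double hi) {
  // coarse grid to bracket, then golden-section refinement
  const int ngrid = 33;
  double best_x = lo, best_g = NEG_INF;
  for (int t = 0; t < ngrid; ++t) {
    double x = lo + (hi - lo) * t / (ngrid - 1.0);
    double g = mu_objective(x, s_drop, s_amp, alpha, beta, w_c);
    if (g > best_g) { best_g = g; best_x = x; }
  }
  double step = (hi - lo) / (ngrid - 1.0);
  double a = std::max(lo, best_x - step), b = std::min(hi, best_x + step);
  const double gr = 0.6180339887498949;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double g1 = mu_objective(x1, s_drop, s_amp, alpha, beta, w_c);
  double g2 = mu_objective(x2, s_drop, s_amp, alpha, beta, w_c);
  for (int it = 0; it < 80 && (b - a) > 1e-12; ++it) {
    if (g1 < g2) {
      a = x1; x1 = x2; g1 = g2;
      x2 = a + gr * (b - a);
      g2 = mu_objective(x2, s_drop, s_amp, alpha, beta, w_c);
    } else {
      b = x2; x2 = x1; g2 = g1;
      x1 = b - gr * (b - a);
      g1 = mu_objective(x1, s_drop, s_amp, alpha, beta, w_c);
    }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export]]
List cpp_fit_em(IntegerMatrix region_depth, NumericVector cell_total,
                IntegerMatrix alt, IntegerMatrix dp, NumericMatrix region_cn,
                NumericMatrix cr_m, NumericMatrix ca_m,
                IntegerVector pair_a, IntegerVector pair_b, int n_nodes,
                double delta, NumericVector pi0, NumericVector mu0,
                NumericVector rho, double theta, double eps, double om_hom,
                double om_het, bool renorm, double alpha, double beta,
                int max_iter, double tol, NumericMatrix lg_d_theta,
                NumericMatrix lg_d1, NumericMatrix lchoose_da,
                NumericMatrix lg_d_omhom, NumericMatrix lg_d_omhet) {
  const double MU_MIN = 1e-4, MU_MAX = 0.5;
  int n_cells = region_depth.nrow();
  int n_attach = region_cn.nrow();
  int n_variants = cr_m.ncol();

  NumericMatrix region_ll = region_ll_matrix(region_depth, cell_total,
                                             region_cn, rho, theta,
                                             lg_d_theta, lg_d1);
  NumericVector pi = clone(pi0), mu = clone(mu0);
  NumericMatrix resp(n_cells, n_attach);
  std::vector<double> trace;
  double loglik = NEG_INF;

  // per-variant unique-genotype tables (shapes do not change across iters)
  std::vector<std::vector<int> > map_a(n_variants,
                                       std::vector<int>(n_attach));
  std::vector<std::vector<std::pair<int,int> > > uniq_geno(n_variants);
  for (int i = 0; i < n_variants; ++i) {
    std::vector<int> key_of(256, -1);
    for (int a = 0; a < n_attach; ++a) {
      int cr = (int)std::lround(cr_m(a, i)), ca = (int)std::lround(ca_m(a, i));
      int key = geno_key(cr, ca);
      if (key_of[key] < 0) {
        key_of[key] = uniq_geno[i].size();
        uniq_geno[i].push_back(std::make_pair(cr, ca));
      }
      map_a[i][a] = key_of[key];
    }
  }

  std::vector<std::vector<std::vector<double> > > uniq_ll(n_variants),
    uniq_edrop(n_variants);
  for (int i = 0; i < n_variants; ++i) {
    uniq_ll[i].resize(uniq_geno[i].size(), std::vector<double>(n_cells));
    uniq_edrop[i].resize(uniq_geno[i].size(), std::vector<double>(n_cells));
  }

  NumericMatrix M(n_cells, n_attach);
  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step pieces: allelic columns at current mu
    for (int i = 0; i < n_variants; ++i)
      for (size_t u = 0; u < uniq_geno[i].size(); ++u)
        allelic_column(n_cells, alt, dp, i, uniq_geno[i][u].first,
                       uniq_geno[i][u].second, mu[i], eps, om_hom, om_het,
                       renorm, lchoose_da, lg_d_omhom, lg_d_omhet,
                       uniq_ll[i][u].data(), uniq_edrop[i][u].data());

    for (int a = 0; a < n_attach; ++a)
      for (int j = 0; j < n_cells; ++j) M(j, a) = region_ll(j, a);
    for (int i = 0; i < n_variants; ++i)
      for (int a = 0; a < n_attach; ++a) {
        const std::vector<double>& v = uniq_ll[i][map_a[i][a]];
        for (int j = 0; j < n_cells; ++j) M(j, a) += v[j];
      }

    // attachment log-weights
    std::vector<double> lw(n_attach);
    for (int a = 0; a < n_attach; ++a) {
      if (pair_a[a] == 0) { // singlet (column a = node a)
        double w = pi[a];
        if (delta > 0) w *= (1.0 - delta);
        lw[a] = (w > 0) ? std::log(w) : NEG_INF;
      } else {
        int na = pair_a[a] - 1, nb = pair_b[a] - 1;
        double w = delta * pi[na] * pi[nb] * (na == nb ? 1.0 : 2.0);
        lw[a] = (w > 0) ? std::log(w) : NEG_INF;
      }
    }

    // responsibilities and observed log-likelihood
    loglik = 0.0;
    for (int j = 0; j < n_cells; ++j) {
      double mx = NEG_INF;
      for (int a = 0; a < n_attach; ++a) {
        double v = M(j, a) + lw[a];
        resp(j, a) = v;
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int a = 0; a < n_attach; ++a) {
        double w = std::exp(resp(j, a) - mx);
        resp(j, a) = w; s += w;
      }
      for (int a = 0; a < n_attach; ++a) resp(j, a) /= s;
      loglik += mx + std::log(s);
    }
    double logpost = loglik;
    for (int i = 0; i < n_variants; ++i)
      logpost += (alpha - 1.0) * std::log(mu[i]) +
        (beta - 1.0) * std::log1p(-mu[i]);
    trace.push_back(logpost);
    if (trace.size() >= 2 &&
        logpost - trace[trace.size() - 2] < tol) break;
    if (iter == max_iter - 1) break; // no point updating params unused

    // M-step: node weights (pairs credit half a cell to each member)
    std::vector<double> pin(n_nodes, 0.0), col_r(n_attach, 0.0);
    for (int a = 0; a < n_attach; ++a) {
      double s = 0.0;
      for (int j = 0; j < n_cells; ++j) s += resp(j, a);
      col_r[a] = s;
      if (pair_a[a] == 0) pin[a] += s;
      else if (pair_a[a] == pair_b[a]) pin[pair_a[a] - 1] += s;
      else {
        pin[pair_a[a] - 1] += 0.5 * s;
        pin[pair_b[a] - 1] += 0.5 * s;
      }
    }
    for (int n = 0; n < n_nodes; ++n) pi[n] = pin[n] / n_cells;

    // M-step: dropout rates
    for (int i = 0; i < n_variants; ++i) {
      double s_drop = 0.0, c_tot = 0.0;
      std::vector<double> w_c(13, 0.0);
      for (int a = 0; a < n_attach; ++a) {
        int u = map_a[i][a];
        int c = uniq_geno[i][u].first + uniq_geno[i][u].second;
        if (c == 0) continue; // deleted locus: no dropout information
        const std::vector<double>& ed = uniq_edrop[i][u];
        double sd = 0.0;
        for (int j = 0; j < n_cells; ++j) sd += resp(j, a) * ed[j];
        s_drop += sd;
        c_tot += col_r[a] * c;
        w_c[c] += col_r[a];
      }
      double mui;
      if (c_tot <= 0) {
        mui = mu[i]; // variant absent from all attached genotypes
      } else if (renorm) {
        mui = maximize_mu(s_drop, c_tot - s_drop, alpha, beta, w_c,
                          MU_MIN, MU_MAX);
      } else {
        mui = (alpha - 1.0 + s_drop) / (alpha + beta - 2.0 + c_tot);
      }
      if (mui < MU_MIN) mui = MU_MIN;
      if (mui > MU_MAX) mui = MU_MAX;
      mu[i] = mui;
    }
  }

  return List::create(_["pi"] = pi, _["mu"] = mu,
                      _["responsibilities"] = resp,
                      _["loglik"] = loglik,
                      _["log_post_trace"] = NumericVector(trace.begin(),
                                                          trace.end()));
}
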