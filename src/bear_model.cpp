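// Core numerics for the age-at-harvest state-space model:
//  * joint log-posterior (priors + projection + two-part harvest likelihood)
//  * adaptive random-walk Metropolis-within-Gibbs sampler (singleton blocks,
//    batch step-size adaptation during burn-in only)
//  * per-draw derivation of the latent abundance trajectory
// Parameter vector layout (Y data years, A age classes, K free age offsets):
//   [0..3]   log LS (fecundity groups 2.5/3.5/4.5/5.5+)
//   [4..7]   logit PR
//   [8]      logit SP_f
//   [9]      eta CubSa           (cloglog-mortality link)
//   [10]     eta CubSb
//   [11,12]  eta Rep F, M
//   [13,14]  mu HS F, M          (link-scale long-term means)
//   [15..15+Y-1]        eps HS F by year
//   [15+Y..15+2Y-1]     eps HS M by year
//   [15+2Y, 16+2Y]      log tau HS F, M
//   [17+2Y]             mu NS
//   [18+2Y..18+3Y-1]    eps NS by year
//   [18+3Y]             log tau NS
//   [19+3Y..19+3Y+K-1]  LHR age offsets (classes 1.5, 2.5, 3.5; 4.5+ ref 0)
//   [19+3Y+K]           log N0 total
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct BearModel {
  int A, Y, K;
  std::vector<double> O, nAged;   // length Y
  std::vector<double> C;          // A*2*Y, a fastest, then sex (F=0,M=1), year
  std::vector<double> lgamC;      // precomputed lgamma(C+1) sums per year
  std::vector<double> lgamN;      // lgamma(nAged+1) per year
  std::vector<double> lgamO;      // lgamma(O+1) per year
  // prior hyperparameters
  double ls_shape[4], ls_rate[4], pr_a[4], pr_b[4], sp_a, sp_b;
  double cubsa_mu, cubsa_sd, cubsb_mu, cubsb_sd, rep_mu, rep_sd;
  double hsf_mu0, hsf_sd, hsm_mu0, hsm_sd, ns_mu0, ns_sd;
  double tauhs_shape, tauhs_rate, taun_shape, taun_rate;
  double lhr_sd, logn0_mu, logn0_sd;
  std::vector<double> props;      // A*2 initial allocation proportions

  int dim() const { return 20 + 3 * Y + K; }

  int fec_group(int a) const {    // 0-based class -> fecundity group, -1 none
    if (a == 0) return -1;
    return a - 1 < 3 ? a - 1 : 3;
  }
  double lhr_of(const std::vector<double>& th, int a) const {
    return a < K ? th[19 + 3 * Y + a] : 0.0;
  }

  double logpost(const std::vector<double>& th) const {
    const double NEG = -std::numeric_limits<double>::infinity();
    double lp = 0.0;
    double LS[4], PR[4];
    for (int i = 0; i < 4; ++i) {
      LS[i] = std::exp(th[i]);
      lp += R::dgamma(LS[i], ls_shape[i], 1.0 / ls_rate[i], 1) + th[i];
      double z = th[4 + i];
      PR[i] = 1.0 / (1.0 + std::exp(-z));
      lp += R::dbeta(PR[i], pr_a[i], pr_b[i], 1)
          + std::log(PR[i]) + std::log1p(-PR[i]);
    }
    double SPf = 1.0 / (1.0 + std::exp(-th[8]));
    lp += R::dbeta(SPf, sp_a, sp_b, 1) + std::log(SPf) + std::log1p(-SPf);
    lp += R::dnorm(th[9], cubsa_mu, cubsa_sd, 1);
    lp += R::dnorm(th[10], cubsb_mu, cubsb_sd, 1);
    lp += R::dnorm(th[11], rep_mu, rep_sd, 1);
    lp += R::dnorm(th[12], rep_mu, rep_sd, 1);
    lp += R::dnorm(th[13], hsf_mu0, hsf_sd, 1);
    lp += R::dnorm(th[14], hsm_mu0, hsm_sd, 1);
    double tauF = std::exp(th[15 + 2 * Y]), tauM = std::exp(th[16 + 2 * Y]);
    lp += R::dgamma(tauF, tauhs_shape, 1.0 / tauhs_rate, 1) + th[15 + 2 * Y];
    lp += R::dgamma(tauM, tauhs_shape, 1.0 / tauhs_rate, 1) + th[16 + 2 * Y];
    double sdF = 1.0 / std::sqrt(tauF), sdM = 1.0 / std::sqrt(tauM);
    for (int y = 0; y < Y; ++y) {
      lp += R::dnorm(th[15 + y], 0.0, sdF, 1);
      lp += R::dnorm(th[15 + Y + y], 0.0, sdM, 1);
    }
    double tauN = std::exp(th[18 + 3 * Y]);
    lp += R::dgamma(tauN, taun_shape, 1.0 / taun_rate, 1) + th[18 + 3 * Y];
    double sdN = 1.0 / std::sqrt(tauN);
    for (int y = 0; y < Y; ++y)
      lp += R::dnorm(th[18 + 2 * Y + y], 0.0, sdN, 1);
    for (int k = 0; k < K; ++k)
      lp += R::dnorm(th[19 + 3 * Y + k], 0.0, lhr_sd, 1);
    lp += R::dnorm(th[19 + 3 * Y + K], logn0_mu, logn0_sd, 1);
    if (!std::isfinite(lp)) return NEG;

    double CubSa = std::exp(-std::exp(th[9]));
    double CubSb = std::exp(-std::exp(th[10]));
    double RepF = std::exp(-std::exp(th[11]));
    double RepM = std::exp(-std::exp(th[12]));
    double N0 = std::exp(th[19 + 3 * Y + K]);

    std::vector<double> N(A * 2), Nprev(A * 2), Nlag2F(A), Nlag1F(A);
    for (int i = 0; i < A * 2; ++i) N[i] = N0 * props[i];
    double fec[64];
    for (int a = 0; a < A; ++a) {
      int g = fec_group(a);
      fec[a] = g < 0 ? 0.0 : LS[g] * PR[g];
    }
    std::vector<double> Nn(A * 2);
    double hs_a[64];                       // per-class HS, reused both parts
    for (int y = 0; y < Y; ++y) {
      // observation likelihood at pre-season abundance of year y
      double Htot = 0.0, lmult = 0.0;
      bool bad = false;
      double ns = (y + 1 < Y)
        ? std::exp(-std::exp(th[17 + 2 * Y] + th[18 + 2 * Y + y])) : 0.0;
      if (y + 1 < Y) {
        for (int a = 0; a < A; ++a) Nlag1F[a] = N[a];  // female slice
        std::fill(Nn.begin(), Nn.end(), 0.0);
      }
      for (int s = 0; s < 2; ++s) {
        double base = (s == 0 ? th[13] : th[14]) +
                      (s == 0 ? th[15 + y] : th[15 + Y + y]);
        double rep = s == 0 ? RepF : RepM;
        double hs_ref = std::exp(-std::exp(base));    // classes >= K share it
        for (int a = 0; a < A; ++a)
          hs_a[a] = a < K ? std::exp(-std::exp(base + th[19 + 3 * Y + a]))
                          : hs_ref;
        for (int a = 0; a < A; ++a) {
          double H = N[s * A + a] * (1.0 - hs_a[a]) * rep;
          Htot += H;
          double c = C[y * A * 2 + s * A + a];
          if (c > 0) {
            if (H <= 0) { bad = true; break; }
            lmult += c * std::log(H);
          }
        }
        if (bad) break;
        if (y + 1 < Y) {                              // project to year y+1
          for (int a = 0; a < A - 1; ++a)
            Nn[s * A + a + 1] += N[s * A + a] * hs_a[a] * ns;
          Nn[s * A + A - 1] += N[s * A + A - 1] * hs_a[A - 1] * ns;
        }
      }
      if (bad || !(Htot > 0) || !std::isfinite(Htot)) return NEG;
      lp += O[y] * std::log(Htot) - Htot - lgamO[y];            // Poisson O_y
      lp += lgamN[y] - lgamC[y] + lmult - nAged[y] * std::log(Htot); // multinomial
      if (!std::isfinite(lp)) return NEG;
      if (y + 1 < Y) {
        const std::vector<double>& lagF = (y == 0) ? Nlag1F : Nlag2F;
        double prod = 0.0;
        for (int a = 0; a < A; ++a) prod += lagF[a] * fec[a];
        double rec = CubSa * CubSb * prod;
        Nn[0] = SPf * rec;
        Nn[A] = (1.0 - SPf) * rec;
        Nlag2F = Nlag1F;
        N = Nn;
      }
    }
    return std::isfinite(lp) ? lp : NEG;
  }

  // deterministic projection over Y+1 years for one parameter vector
  std::vector<double> project(const std::vector<double>& th) const {
    double LS[4], PR[4];
    for (int i = 0; i < 4; ++i) {
      LS[i] = std::exp(th[i]);
      PR[i] = 1.0 / (1.0 + std::exp(-th[4 + i]));
    }
    double SPf = 1.0 / (1.0 + std::exp(-th[8]));
    double CubSa = std::exp(-std::exp(th[9]));
    double CubSb = std::exp(-std::exp(th[10]));
    double N0 = std::exp(th[19 + 3 * Y + K]);
    double fec[64];
    for (int a = 0; a < A; ++a) {
      int g = fec_group(a);
      fec[a] = g < 0 ? 0.0 : LS[g] * PR[g];
    }
    int YY = Y + 1;
    std::vector<double> out(A * 2 * YY);
    std::vector<double> N(A * 2), Nlag2F(A), Nlag1F(A);
    for (int i = 0; i < A * 2; ++i) N[i] = N0 * props[i];
    for (int y = 0; y < YY; ++y) {
      for (int i = 0; i < A * 2; ++i) out[y * A * 2 + i] = N[i];
      if (y + 1 == YY) break;
      double ns = std::exp(-std::exp(th[17 + 2 * Y] + th[18 + 2 * Y + y]));
      for (int a = 0; a < A; ++a) Nlag1F[a] = N[a];
      std::vector<double> Nn(A * 2, 0.0);
      for (int s = 0; s < 2; ++s) {
        double mu = s == 0 ? th[13] : th[14];
        double eps = s == 0 ? th[15 + y] : th[15 + Y + y];
        for (int a = 0; a < A - 1; ++a) {
          double S = std::exp(-std::exp(mu + eps + lhr_of(th, a))) * ns;
          Nn[s * A + a + 1] += N[s * A + a] * S;
        }
        double Sterm = std::exp(-std::exp(mu + eps + lhr_of(th, A - 1))) * ns;
        Nn[s * A + A - 1] += N[s * A + A - 1] * Sterm;
      }
      const std::vector<double>& lagF = (y == 0) ? Nlag1F : Nlag2F;
      double prod = 0.0;
      for (int a = 0; a < A; ++a) prod += lagF[a] * fec[a];
      double rec = CubSa * CubSb * prod;
      Nn[0] = SPf * rec;
      Nn[A] = (1.0 - SPf) * rec;
      Nlag2F = Nlag1F;
      N = Nn;
    }
    return out;
  }
};

static BearModel build_model(const List& m) {
  BearModel b;
  b.A = as<int>(m["A"]); b.Y = as<int>(m["Y"]); b.K = as<int>(m["K"]);
  NumericVector O = m["O"], nAged = m["n_aged"], C = m["C"], props = m["props"];
  b.O.assign(O.begin(), O.end());
  b.nAged.assign(nAged.begin(), nAged.end());
  b.C.assign(C.begin(), C.end());
  b.props.assign(props.begin(), props.end());
  NumericVector lss = m["ls_shape"], lsr = m["ls_rate"],
                pra = m["pr_a"], prb = m["pr_b"];
  for (int i = 0; i < 4; ++i) {
    b.ls_shape[i] = lss[i]; b.ls_rate[i] = lsr[i];
    b.pr_a[i] = pra[i]; b.pr_b[i] = prb[i];
  }
  b.sp_a = as<double>(m["sp_a"]); b.sp_b = as<double>(m["sp_b"]);
  b.cubsa_mu = as<double>(m["cubsa_mu"]); b.cubsa_sd = as<double>(m["cubsa_sd"]);
  b.cubsb_mu = as<double>(m["cubsb_mu"]); b.cubsb_sd = as<double>(m["cubsb_sd"]);
  b.rep_mu = as<double>(m["rep_mu"]); b.rep_sd = as<double>(m["rep_sd"]);
  b.hsf_mu0 = as<double>(m["hsf_mu0"]); b.hsf_sd = as<double>(m["hsf_sd"]);
  b.hsm_mu0 = as<double>(m["hsm_mu0"]); b.hsm_sd = as<double>(m["hsm_sd"]);
  b.ns_mu0 = as<double>(m["ns_mu0"]); b.ns_sd = as<double>(m["ns_sd"]);
  b.tauhs_shape = as<double>(m["tauhs_shape"]);
  b.tauhs_rate = as<double>(m["tauhs_rate"]);
  b.taun_shape = as<double>(m["taun_shape"]);
  b.taun_rate = as<double>(m["taun_rate"]);
  b.lhr_sd = as<double>(m["lhr_sd"]);
  b.logn0_mu = as<double>(m["logn0_mu"]); b.logn0_sd = as<double>(m["logn0_sd"]);
  // NS prior mean enters through mu NS prior
  b.lgamO.resize(b.Y); b.lgamN.resize(b.Y); b.lgamC.resize(b.Y);
  for (int y = 0; y < b.Y; ++y) {
    b.lgamO[y] = std::lgamma(b.O[y] + 1.0);
    b.lgamN[y] = std::lgamma(b.nAged[y] + 1.0);
    double s = 0.0;
    for (int i = 0; i < b.A * 2; ++i)
      s += std::lgamma(b.C[y * b.A * 2 + i] + 1.0);
    b.lgamC[y] = s;
  }
  return b;
}

// NS long-term mean prior: th[17+2Y] ~ N(ns_mu0, ns_sd). Applied inside
// logpost via the generic normal block below (kept out of the loop above for
// clarity it is added here):
struct BearPosterior {
  BearModel m;
  double operator()(const std::vector<double>& th) const {
    double lp = m.logpost(th);
    if (!std::isfinite(lp)) return lp;
    return lp + R::dnorm(th[17 + 2 * m.Y], m.ns_mu0, m.ns_sd, 1);
  }
};

// Per-coordinate adaptive random-walk Metropolis-within-Gibbs, optionally
// followed each sweep by 1-D proposals along fixed directions ("dirs",
// one column per direction) that track known posterior ridges; each
// direction carries its own adaptive step size.
template <typename F>
List amwg_run(const F& logpost, std::vector<double> cur,
              int n_iter, int burn, int thin,
              std::vector<double> lstep, double target, bool adapt,
              const NumericMatrix& dirs, std::vector<double> lstep_dir,
              int batch = 50) {
  const int d = cur.size();
  const int ndir = dirs.ncol();
  double lp_cur = logpost(cur);
  if (!std::isfinite(lp_cur))
    stop("initial value has non-finite log-posterior");
  int n_keep = (n_iter - burn) / thin;
  NumericMatrix draws(n_keep, d);
  std::vector<long> acc(d + ndir, 0), tries(d + ndir, 0);
  std::vector<int> bacc(d + ndir, 0);
  std::vector<double> prop(d);
  int kept = 0, nbatch = 0;
  for (int t = 1; t <= n_iter; ++t) {
    for (int j = 0; j < d; ++j) {
      double old = cur[j];
      cur[j] = old + norm_rand() * std::exp(lstep[j]);
      double lp_prop = logpost(cur);
      ++tries[j];
      if (std::isfinite(lp_prop) &&
          std::log(unif_rand()) < lp_prop - lp_cur) {
        lp_cur = lp_prop; ++acc[j]; ++bacc[j];
      } else {
        cur[j] = old;
      }
    }
    for (int k = 0; k < ndir; ++k) {
      double delta = norm_rand() * std::exp(lstep_dir[k]);
      for (int j = 0; j < d; ++j) prop[j] = cur[j] + delta * dirs(j, k);
      double lp_prop = logpost(prop);
      ++tries[d + k];
      if (std::isfinite(lp_prop) &&
          std::log(unif_rand()) < lp_prop - lp_cur) {
        lp_cur = lp_prop; cur = prop; ++acc[d + k]; ++bacc[d + k];
      }
    }
    if (adapt && t <= burn && t % batch == 0) {
      ++nbatch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)nbatch));
      for (int j = 0; j < d; ++j) {
        lstep[j] += (bacc[j] > target * batch) ? delta : -delta;
        bacc[j] = 0;
      }
      for (int k = 0; k < ndir; ++k) {
        lstep_dir[k] += (bacc[d + k] > target * batch) ? delta : -delta;
        bacc[d + k] = 0;
      }
    }
    if (t > burn && (t - burn) % thin == 0) {
      for (int j = 0; j < d; ++j) draws(kept, j) = cur[j];
      ++kept;
    }
    if (t % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector arate(d + ndir), steps(d + ndir);
  for (int j = 0; j < d + ndir; ++j) {
    arate[j] = tries[j] ? (double)acc[j] / tries[j] : NA_REAL;
    steps[j] = std::exp(j < d ? lstep[j] : lstep_dir[j - d]);
  }
  return List::create(_["draws"] = draws, _["accept"] = arate,
                      _["step"] = steps, _["lp_last"] = lp_cur);
}

// [[Rcpp::export]]
double bear_logpost_cpp(NumericVector theta, List model) {
  BearPosterior post{build_model(model)};
  std::vector<double> th(theta.begin(), theta.end());
  if ((int)th.size() != post.m.dim())
    stop("theta has length %d, expected %d", (int)th.size(), post.m.dim());
  return post(th);
}

// [[Rcpp::export]]
List bear_mcmc_cpp(List model, NumericVector init, int n_iter, int burn,
                   int thin, NumericVector step_init, double target_accept,
                   bool adapt, NumericMatrix dirs, NumericVector dir_step) {
  BearPosterior post{build_model(model)};
  if ((int)init.size() != post.m.dim())
    stop("init has length %d, expected %d", (int)init.size(), post.m.dim());
  if (dirs.ncol() > 0 && dirs.nrow() != post.m.dim())
    stop("direction matrix must have one row per parameter");
  std::vector<double> cur(init.begin(), init.end());
  std::vector<double> lstep(step_init.size());
  for (int j = 0; j < (int)lstep.size(); ++j)
    lstep[j] = std::log(step_init[j]);
  std::vector<double> ldir(dir_step.size());
  for (int k = 0; k < (int)ldir.size(); ++k)
    ldir[k] = std::log(dir_step[k]);
  RNGScope scope;
  return amwg_run(post, cur, n_iter, burn, thin, lstep, target_accept, adapt,
                  dirs, ldir);
}

// [[Rcpp::export]]
NumericMatrix bear_project_draws_cpp(List model, NumericMatrix draws) {
  BearModel m = build_model(model);
  int n = draws.nrow(), YY = m.Y + 1;
  NumericMatrix out(n, m.A * 2 * YY);
  std::vector<double> th(m.dim());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m.dim(); ++j) th[j] = draws(i, j);
    std::vector<double> N = m.project(th);
    for (int k = 0; k < (int)N.size(); ++k) out(i, k) = N[k];
  }
  return out;
}

struct RFunctor {
  Function f;
  double operator()(const std::vector<double>& th) const {
    NumericVector v(th.begin(), th.end());
    return as<double>(f(v));
  }
};

// [[Rcpp::export]]
List amwg_generic_cpp(Function logpost, NumericVector init, int n_iter,
                      int burn, int thin, NumericVector step_init,
                      double target_accept, bool adapt) {
  RFunctor post{logpost};
  std::vector<double> cur(init.begin(), init.end());
  std::vector<double> lstep(step_init.size());
  for (int j = 0; j < (int)lstep.size(); ++j)
    lstep[j] = std::log(step_init[j]);
  RNGScope scope;
  NumericMatrix nodirs(init.size(), 0);
  return amwg_run(post, cur, n_iter, burn, thin, lstep, target_accept, adapt,
                  nodirs, std::vector<double>());
}
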