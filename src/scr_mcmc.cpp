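// Metropolis-within-Gibbs sampler for the data-augmented SCR model with a
// cloglog observation model and (half-)normal distance kernel.
//
// Key algebraic device: with rate lambda_{ijk} = lam0 * exp(bsex*sex) *
// g(d_{s_i,j}) * E_{jk}, the log-probability of an all-zero history for
// individual i collapses over occasions to -lam0s_i * sum_j g_ij * cumE_j,
// where cumE_j = sum_k E_jk. Only the (sparse) observed detections need
// per-cell-occasion treatment, so one likelihood evaluation costs
// O(n_traps) per individual rather than O(n_traps * n_occasions).
//
// Kernel values with exponent > CUTOFF are treated as zero in the summed
// miss-mass (relative error < 5e-18); detection cells are always exact.

#include <Rcpp.h>
using namespace Rcpp;

static const double CUTOFF = 40.0;

struct Model {
  bool lambda0_sex, sigma_sex, include_pb;
  double theta;
};

static inline double kern(double dd2, double sig2two, double theta, bool cut) {
  double e = dd2 / sig2two;
  if (theta != 1.0) e = std::pow(e, theta);
  if (cut && e > CUTOFF) return 0.0;
  return std::exp(-e);
}

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

class Sampler {
public:
  // data
  NumericMatrix d2;            // n_hab x n_traps squared distances
  // per-pixel traps sorted by distance, for early exit at the kernel cutoff
  std::vector<std::vector<int> > ord;
  std::vector<std::vector<double> > d2s;
  IntegerVector act_trap;      // active cell-occasions -> trap (0-based)
  NumericVector act_logeff, act_pb;
  IntegerVector det_t;         // detections -> active cell-occasion index
  IntegerVector det_ptr;       // offsets per observed individual (n_obs+1)
  IntegerVector sex_obs;       // length M, 0/1/-1
  int n_obs, M, n_hab, n_traps, n_act, n_det;
  // lattice for s proposals
  IntegerVector hab_gx, hab_gy, gmap; // gmap: nx*ny -> hab index or -1
  int nx, ny, s_window;
  Model mod;
  // priors
  double lpl_lo, lpl_hi, sigma_max, beta_sd;

  // state
  double lam0, sigF, sigM, beff, beff2, bsex, psi, psisex;
  IntegerVector z, s, sex;
  NumericVector cumE, E;       // per trap / per active cell-occasion
  NumericMatrix G;             // M x n_traps kernel values (cutoff)
  NumericVector H;             // per individual: dot(G_i, cumE)
  NumericVector gdet;          // per detection: exact kernel value at s_i

  // proposals / adaptation
  NumericVector prop_sd;       // 6 blocks
  IntegerVector acc, tries;    // per block + s-moves (index 6)
  IntegerVector bacc, btries;  // batch counters for adaptation
  bool adapt, update_params;
  int batch_len = 50, batch_no = 0;

  double sig2two(int sx) const {
    double s_ = (mod.sigma_sex && sx == 1) ? sigM : sigF;
    return 2.0 * s_ * s_;
  }
  // squared-distance threshold beyond which the kernel is treated as zero
  double d2thr(double s2two) const {
    return mod.theta == 1.0 ? s2two * CUTOFF
                            : s2two * std::pow(CUTOFF, 1.0 / mod.theta);
  }

  void buildOrder() {
    ord.assign(n_hab, std::vector<int>());
    d2s.assign(n_hab, std::vector<double>());
    std::vector<int> idx(n_traps);
    for (int p = 0; p < n_hab; ++p) {
      for (int j = 0; j < n_traps; ++j) idx[j] = j;
      const double *row0 = &d2(p, 0);
      // column-major: d2(p, j) strided; copy first
      std::vector<double> dr(n_traps);
      for (int j = 0; j < n_traps; ++j) dr[j] = d2(p, j);
      std::sort(idx.begin(), idx.end(),
                [&dr](int a, int b) { return dr[a] < dr[b]; });
      ord[p].resize(n_traps); d2s[p].resize(n_traps);
      for (int j = 0; j < n_traps; ++j) {
        ord[p][j] = idx[j]; d2s[p][j] = dr[idx[j]];
      }
      (void)row0;
    }
  }
  double lam0s(int sx) const {
    return lam0 * ((mod.lambda0_sex && sx == 1) ? std::exp(bsex) : 1.0);
  }

  void computeE() {
    double bpb = mod.include_pb ? beff2 : 0.0;
    std::fill(cumE.begin(), cumE.end(), 0.0);
    for (int t = 0; t < n_act; ++t) {
      E[t] = std::exp(beff * act_logeff[t] + bpb * act_pb[t]);
      cumE[act_trap[t]] += E[t];
    }
  }

  // refresh kernel row + H for individual i at its current s/sex
  void refreshG(int i) {
    double s2 = sig2two(sex[i]), thr = d2thr(s2);
    double h = 0.0;
    int si = s[i];
    for (int j = 0; j < n_traps; ++j) G(i, j) = 0.0;
    const std::vector<int> &od = ord[si];
    const std::vector<double> &dd = d2s[si];
    for (int k = 0; k < n_traps; ++k) {
      if (dd[k] > thr) break;
      double e = dd[k] / s2;
      if (mod.theta != 1.0) e = std::pow(e, mod.theta);
      double g = std::exp(-e);
      G(i, od[k]) = g;
      h += g * cumE[od[k]];
    }
    H[i] = h;
    if (i < n_obs)
      for (int t = det_ptr[i]; t < det_ptr[i + 1]; ++t)
        gdet[t] = kern(d2(si, act_trap[det_t[t]]), s2, mod.theta, false);
  }

  // H at an arbitrary pixel for a given sex (no caching)
  double Hat(int pix, int sx) const {
    double s2 = sig2two(sx), thr = d2thr(s2), h = 0.0;
    const std::vector<int> &od = ord[pix];
    const std::vector<double> &dd = d2s[pix];
    for (int k = 0; k < n_traps; ++k) {
      if (dd[k] > thr) break;
      double e = dd[k] / s2;
      if (mod.theta != 1.0) e = std::pow(e, mod.theta);
      h += std::exp(-e) * cumE[od[k]];
    }
    return h;
  }
  // H at a pixel for given sigma (parameter proposals)
  double HatSig(int pix, double sig) const {
    double s2 = 2.0 * sig * sig, thr = d2thr(s2), h = 0.0;
    const std::vector<int> &od = ord[pix];
    const std::vector<double> &dd = d2s[pix];
    for (int k = 0; k < n_traps; ++k) {
      if (dd[k] > thr) break;
      double e = dd[k] / s2;
      if (mod.theta != 1.0) e = std::pow(e, mod.theta);
      h += std::exp(-e) * cumE[od[k]];
    }
    return h;
  }

  // detection-correction term log(pi) + lam summed over detections of i,
  // at pixel pix and sex sx with rate scale l0s
  double corr(int i, int pix, int sx, double l0s) const {
    if (i >= n_obs) return 0.0;
    double s2 = sig2two(sx), c = 0.0;
    for (int t = det_ptr[i]; t < det_ptr[i + 1]; ++t) {
      double g = kern(d2(pix, act_trap[det_t[t]]), s2, mod.theta, false);
      double lam = l0s * g * E[det_t[t]];
      if (lam <= 0) return R_NegInf;
      c += std::log(-std::expm1(-lam)) + lam;
    }
    return c;
  }
  // same but using cached gdet (current state, current E)
  double corrCached(int i, double l0s) const {
    if (i >= n_obs) return 0.0;
    double c = 0.0;
    for (int t = det_ptr[i]; t < det_ptr[i + 1]; ++t) {
      double lam = l0s * gdet[t] * E[det_t[t]];
      if (lam <= 0) return R_NegInf;
      c += std::log(-std::expm1(-lam)) + lam;
    }
    return c;
  }

  // full detection log-likelihood of included individuals at current state
  double detLoglik() const {
    double ll = 0.0;
    for (int i = 0; i < M; ++i) {
      if (!z[i]) continue;
      double l0s = lam0s(sex[i]);
      ll += -l0s * H[i];
      if (i < n_obs) ll += corrCached(i, l0s);
    }
    return ll;
  }

  // ---- latent updates ------------------------------------------------

  void updateS() {
    std::vector<double> gtmp(n_traps);
    std::vector<int> touched;
    touched.reserve(n_traps);
    for (int i = 0; i < M; ++i) {
      if (!z[i]) {                       // prior (uniform-habitat) draw
        s[i] = runif_int(n_hab);
        refreshG(i);
        continue;
      }
      int gx = hab_gx[s[i]] + runif_int(2 * s_window + 1) - s_window;
      int gy = hab_gy[s[i]] + runif_int(2 * s_window + 1) - s_window;
      tries[6]++;
      if (gx < 0 || gx >= nx || gy < 0 || gy >= ny) continue;
      int cand = gmap[gy * nx + gx];
      if (cand < 0) continue;           // non-habitat: reject outright
      double l0s = lam0s(sex[i]);
      // kernel row at the candidate pixel, kept for reuse on acceptance
      double s2 = sig2two(sex[i]), thr = d2thr(s2), hcand = 0.0;
      touched.clear();
      const std::vector<int> &od = ord[cand];
      const std::vector<double> &dd = d2s[cand];
      for (int k = 0; k < n_traps; ++k) {
        if (dd[k] > thr) break;
        double e = dd[k] / s2;
        if (mod.theta != 1.0) e = std::pow(e, mod.theta);
        double g = std::exp(-e);
        gtmp[od[k]] = g;
        touched.push_back(od[k]);
        hcand += g * cumE[od[k]];
      }
      double lr = (-l0s * hcand + corr(i, cand, sex[i], l0s)) -
                  (-l0s * H[i] + corrCached(i, l0s));
      if (std::log(unif_rand()) < lr) {
        s[i] = cand;
        for (int j = 0; j < n_traps; ++j) G(i, j) = 0.0;
        for (int k = 0; k < (int)touched.size(); ++k)
          G(i, touched[k]) = gtmp[touched[k]];
        H[i] = hcand;
        if (i < n_obs)
          for (int t = det_ptr[i]; t < det_ptr[i + 1]; ++t)
            gdet[t] = kern(d2(cand, act_trap[det_t[t]]), s2, mod.theta, false);
        acc[6]++;
      }
    }
  }

  void updateSex(int it) {
    for (int i = 0; i < M; ++i) {
      if (sex_obs[i] >= 0) { continue; }
      // undetected individuals' sex is nearly prior-distributed; a
      // round-robin subsample keeps the Gibbs scan cheap without changing
      // the stationary distribution
      if (i >= n_obs && z[i] && (it + i) % 3 != 0) continue;
      if (!z[i]) {                       // prior draw
        int nsx = (unif_rand() < psisex) ? 1 : 0;
        if (nsx != sex[i]) { sex[i] = nsx; refreshG(i); }
        continue;
      }
      // Gibbs: p(male) proportional to psisex * L(male)
      double llF = -lam0s(0) * (mod.sigma_sex ? Hat(s[i], 0) : H[i]) +
                   corr(i, s[i], 0, lam0s(0));
      double llM = -lam0s(1) * (mod.sigma_sex ? Hat(s[i], 1) : H[i]) +
                   corr(i, s[i], 1, lam0s(1));
      double a = std::log(psisex) + llM, b = std::log(1.0 - psisex) + llF;
      double pm = 1.0 / (1.0 + std::exp(b - a));
      int nsx = (unif_rand() < pm) ? 1 : 0;
      if (nsx != sex[i]) { sex[i] = nsx; refreshG(i); }
    }
  }

  void updateZ() {
    for (int i = n_obs; i < M; ++i) {
      double p0 = std::exp(-lam0s(sex[i]) * H[i]);
      double pstar = psi * p0 / (psi * p0 + 1.0 - psi);
      z[i] = (unif_rand() < pstar) ? 1 : 0;
    }
  }

  void updatePsi() {
    int n1 = std::accumulate(z.begin(), z.end(), 0);
    psi = R::rbeta(1.0 + n1, 1.0 + M - n1);
    int nm = 0;
    for (int i = 0; i < M; ++i) nm += sex[i];
    psisex = R::rbeta(1.0 + nm, 1.0 + M - nm);
  }

  // ---- parameter updates ---------------------------------------------

  void refreshAllIncluded() {
    for (int i = 0; i < M; ++i) if (z[i] || i < n_obs) refreshG(i);
  }

  void tryBlock(int b) {
    tries[b]++; btries[b]++;
    double cur_ll = detLoglik();
    double nlam0 = lam0, nsigF = sigF, nsigM = sigM,
           nbeff = beff, nbeff2 = beff2, nbsex = bsex;
    double lpratio = 0.0;           // prior + Jacobian log-ratio
    double step = norm_rand() * prop_sd[b];
    switch (b) {
    case 0: {                        // log lambda0, flat prior on log scale
      double u = std::log(lam0) + step;
      if (u < lpl_lo || u > lpl_hi) return;
      nlam0 = std::exp(u);
      break; }
    case 1: {                        // log sigma_F, Unif(0, sigma_max) + Jacobian
      nsigF = sigF * std::exp(step);
      if (nsigF >= sigma_max) return;
      if (!mod.sigma_sex) nsigM = nsigF;
      lpratio = std::log(nsigF) - std::log(sigF);
      break; }
    case 2: {
      nsigM = sigM * std::exp(step);
      if (nsigM >= sigma_max) return;
      lpratio = std::log(nsigM) - std::log(sigM);
      break; }
    case 3: nbeff = beff + step;
      lpratio = R::dnorm(nbeff, 0, beta_sd, 1) - R::dnorm(beff, 0, beta_sd, 1);
      break;
    case 4: nbeff2 = beff2 + step;
      lpratio = R::dnorm(nbeff2, 0, beta_sd, 1) - R::dnorm(beff2, 0, beta_sd, 1);
      break;
    case 5: nbsex = bsex + step;
      lpratio = R::dnorm(nbsex, 0, beta_sd, 1) - R::dnorm(bsex, 0, beta_sd, 1);
      break;
    }

    // proposal log-likelihood
    double prop_ll = 0.0;
    bool newE = (b == 3 || b == 4);
    std::vector<double> ncumE, nE;
    if (newE) {
      ncumE.assign(n_traps, 0.0); nE.assign(n_act, 0.0);
      double bpb = mod.include_pb ? nbeff2 : 0.0;
      for (int t = 0; t < n_act; ++t) {
        nE[t] = std::exp(nbeff * act_logeff[t] + bpb * act_pb[t]);
        ncumE[act_trap[t]] += nE[t];
      }
    }
    for (int i = 0; i < M; ++i) {
      if (!z[i]) continue;
      double l0s = nlam0 * ((mod.lambda0_sex && sex[i] == 1) ? std::exp(nbsex) : 1.0);
      double hi;
      if (b == 1 && (!mod.sigma_sex || sex[i] == 0)) {
        hi = HatSig(s[i], nsigF);
      } else if (b == 2 && mod.sigma_sex && sex[i] == 1) {
        hi = HatSig(s[i], nsigM);
      } else if (newE) {
        double h = 0.0;
        for (int j = 0; j < n_traps; ++j) h += G(i, j) * ncumE[j];
        hi = h;
      } else hi = H[i];
      prop_ll += -l0s * hi;
      if (i < n_obs) {
        double sF = nsigF, sM = nsigM;
        double s_ = (mod.sigma_sex && sex[i] == 1) ? sM : sF;
        double s2 = 2.0 * s_ * s_, c = 0.0;
        for (int t = det_ptr[i]; t < det_ptr[i + 1]; ++t) {
          double g = kern(d2(s[i], act_trap[det_t[t]]), s2, mod.theta, false);
          double Et = newE ? nE[det_t[t]] : E[det_t[t]];
          double lam = l0s * g * Et;
          if (lam <= 0) { c = R_NegInf; break; }
          c += std::log(-std::expm1(-lam)) + lam;
        }
        prop_ll += c;
      }
    }

    if (std::log(unif_rand()) < prop_ll - cur_ll + lpratio) {
      lam0 = nlam0; sigF = nsigF; sigM = nsigM;
      beff = nbeff; beff2 = nbeff2; bsex = nbsex;
      if (newE) {
        std::copy(ncumE.begin(), ncumE.end(), cumE.begin());
        std::copy(nE.begin(), nE.end(), E.begin());
        refreshAllIncluded();
      } else if (b == 1 || b == 2) {
        refreshAllIncluded();
      }
      acc[b]++; bacc[b]++;
    }
  }

  void adaptScales() {
    batch_no++;
    double kappa = 1.0 / std::sqrt((double)batch_no);
    for (int b = 0; b < 6; ++b) {
      if (btries[b] == 0) continue;
      double rate = (double)bacc[b] / btries[b];
      prop_sd[b] *= std::exp(kappa * (rate - 0.35));
      prop_sd[b] = std::min(std::max(prop_sd[b], 1e-4), 10.0);
      bacc[b] = 0; btries[b] = 0;
    }
  }

  // ---- bookkeeping ----------------------------------------------------

  // complete-data log likelihood (sex and s mass for included only)
  double completeLoglik() const {
    double ll = detLoglik();
    int n1 = 0;
    for (int i = 0; i < M; ++i) {
      if (!z[i]) continue;
      n1++;
      ll += (sex[i] == 1 ? std::log(psisex) : std::log(1.0 - psisex)) -
            std::log((double)n_hab);
    }
    ll += n1 * std::log(psi) + (M - n1) * std::log(1.0 - psi);
    return ll;
  }

  // Freeman-Tukey discrepancy for observed and a replicate draw
  void ppc(double &Tobs, double &Trep) {
    Tobs = 0.0; Trep = 0.0;
    for (int i = 0; i < M; ++i) {
      if (!z[i]) continue;
      double l0s = lam0s(sex[i]);
      double ei = 0.0; int nrep = 0;
      for (int t = 0; t < n_act; ++t) {
        double g = G(i, act_trap[t]);
        if (g <= 0) continue;
        double lam = l0s * g * E[t];
        double p = (lam < 1e-5) ? lam : -std::expm1(-lam);
        ei += p;
        if (unif_rand() < p) nrep++;
      }
      int nobs = (i < n_obs) ? det_ptr[i + 1] - det_ptr[i] : 0;
      double se = std::sqrt(ei);
      Tobs += std::pow(std::sqrt((double)nobs) - se, 2);
      Trep += std::pow(std::sqrt((double)nrep) - se, 2);
    }
  }
};

// [[Rcpp::export(name = ".scr_mcmc_cpp")]]
List scr_mcmc_cpp(NumericMatrix d2, IntegerVector act_trap,
                  NumericVector act_logeff, NumericVector act_pb,
                  IntegerVector det_t, IntegerVector det_ptr,
                  IntegerVector sex_obs, int n_obs,
                  IntegerVector hab_gx, IntegerVector hab_gy,
                  IntegerVector gmap, int nx, int ny,
                  List spec, List priors, List init, List control) {
  Sampler S;
  S.d2 = d2; S.act_trap = act_trap; S.act_logeff = act_logeff; S.act_pb = act_pb;
  S.det_t = det_t; S.det_ptr = det_ptr; S.sex_obs = sex_obs; S.n_obs = n_obs;
  S.hab_gx = hab_gx; S.hab_gy = hab_gy; S.gmap = gmap; S.nx = nx; S.ny = ny;
  S.n_hab = d2.nrow(); S.n_traps = d2.ncol(); S.n_act = act_trap.size();
  S.n_det = det_t.size();
  S.mod.lambda0_sex = as<bool>(spec["lambda0_sex_specific"]);
  S.mod.sigma_sex = as<bool>(spec["sigma_sex_specific"]);
  S.mod.include_pb = as<bool>(spec["include_playback"]);
  S.mod.theta = as<double>(spec["theta"]);
  S.M = as<int>(spec["M"]);
  NumericVector lpl = priors["log_lambda0"];
  S.lpl_lo = lpl[0]; S.lpl_hi = lpl[1];
  S.sigma_max = as<double>(priors["sigma_max"]);
  S.beta_sd = as<double>(priors["beta_sd"]);

  NumericVector p0 = init["params"]; // lam0 sigF sigM beff beff2 bsex psi psisex
  S.lam0 = p0[0]; S.sigF = p0[1]; S.sigM = p0[2]; S.beff = p0[3];
  S.beff2 = p0[4]; S.bsex = p0[5]; S.psi = p0[6]; S.psisex = p0[7];
  S.z = clone(as<IntegerVector>(init["z"]));
  S.s = clone(as<IntegerVector>(init["s"]));
  S.sex = clone(as<IntegerVector>(init["sex"]));

  int n_iter = as<int>(control["n_iter"]);
  int burn_in = as<int>(control["burn_in"]);
  int thin = as<int>(control["thin"]);
  int latent_thin = as<int>(control["latent_thin"]);
  S.s_window = as<int>(control["s_window"]);
  S.adapt = as<bool>(control["adapt"]);
  S.update_params = as<bool>(control["update_params"]);
  S.prop_sd = clone(as<NumericVector>(control["prop_sd"]));
  S.acc = IntegerVector(7); S.tries = IntegerVector(7);
  S.bacc = IntegerVector(6); S.btries = IntegerVector(6);

  S.cumE = NumericVector(S.n_traps);
  S.E = NumericVector(S.n_act);
  S.G = NumericMatrix(S.M, S.n_traps);
  S.H = NumericVector(S.M);
  S.gdet = NumericVector(S.n_det);

  RNGScope scope;
  S.buildOrder();
  S.computeE();
  for (int i = 0; i < S.M; ++i) S.refreshG(i);

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, 10);
  colnames(out) = CharacterVector::create("lambda0", "sigma_F", "sigma_M",
    "beta_eff", "beta_eff2", "beta_sex", "psi", "psi_sex", "N_super", "loglik");
  int n_lat = (n_iter - burn_in) / latent_thin;
  IntegerMatrix lat_s(n_lat, S.M), lat_z(n_lat, S.M), lat_sex(n_lat, S.M);
  NumericVector Tobs(n_lat), Trep(n_lat);

  bool trace = control.containsElementNamed("trace") && as<bool>(control["trace"]);
  int keep = 0, lat = 0;
  for (int it = 1; it <= n_iter; ++it) {
    if (trace) Rprintf("it %d sex\n", it);
    S.updateSex(it);
    if (trace) Rprintf("it %d s\n", it);
    S.updateS();
    if (trace) Rprintf("it %d z\n", it);
    S.updateZ();
    if (S.update_params) {
      S.updatePsi();
      S.tryBlock(0);
      S.tryBlock(1);
      if (S.mod.sigma_sex) S.tryBlock(2);
      S.tryBlock(3);
      if (S.mod.include_pb) S.tryBlock(4);
      if (S.mod.lambda0_sex) S.tryBlock(5);
      if (S.adapt && it <= burn_in && it % S.batch_len == 0) S.adaptScales();
    }
    if (trace) Rprintf("it %d store\n", it);
    if (it > burn_in) {
      int po = it - burn_in;
      if (po % thin == 0 && keep < n_keep) {
        int n1 = std::accumulate(S.z.begin(), S.z.end(), 0);
        out(keep, 0) = S.lam0; out(keep, 1) = S.sigF; out(keep, 2) = S.sigM;
        out(keep, 3) = S.beff; out(keep, 4) = S.beff2; out(keep, 5) = S.bsex;
        out(keep, 6) = S.psi; out(keep, 7) = S.psisex;
        out(keep, 8) = n1; out(keep, 9) = S.completeLoglik();
        keep++;
      }
      if (po % latent_thin == 0 && lat < n_lat) {
        for (int i = 0; i < S.M; ++i) {
          lat_s(lat, i) = S.s[i]; lat_z(lat, i) = S.z[i]; lat_sex(lat, i) = S.sex[i];
        }
        S.ppc(Tobs[lat], Trep[lat]);
        lat++;
      }
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(7);
  for (int b = 0; b < 7; ++b)
    acc_rate[b] = S.tries[b] > 0 ? (double)S.acc[b] / S.tries[b] : NA_REAL;
  acc_rate.names() = CharacterVector::create("log_lambda0", "log_sigma_F",
    "log_sigma_M", "beta_eff", "beta_eff2", "beta_sex", "s_move");

  return List::create(_["samples"] = out,
                      _["s"] = lat_s, _["z"] = lat_z, _["sex"] = lat_sex,
                      _["T_obs"] = Tobs, _["T_rep"] = Trep,
                      _["acceptance"] = acc_rate,
                      _["prop_sd"] = S.prop_sd);
}

// Exact detection log-likelihood evaluator (for cross-checks against the R
// reference implementation); no cutoff is applied.
// [[Rcpp::export(name = ".scr_detloglik_cpp")]]
double scr_detloglik_cpp(NumericMatrix d2, IntegerVector act_trap,
                         NumericVector act_logeff, NumericVector act_pb,
                         IntegerVector det_t, IntegerVector det_ptr,
                         int n_obs, List spec, NumericVector params,
                         IntegerVector z, IntegerVector s, IntegerVector sex) {
  bool lam0sex = as<bool>(spec["lambda0_sex_specific"]);
  bool sigsex = as<bool>(spec["sigma_sex_specific"]);
  bool incpb = as<bool>(spec["include_playback"]);
  double theta = as<double>(spec["theta"]);
  double lam0 = params[0], sigF = params[1], sigM = params[2],
         beff = params[3], beff2 = params[4], bsex = params[5];
  int n_act = act_trap.size(), M = z.size();
  std::vector<double> E(n_act);
  double bpb = incpb ? beff2 : 0.0;
  for (int t = 0; t < n_act; ++t)
    E[t] = std::exp(beff * act_logeff[t] + bpb * act_pb[t]);
  double ll = 0.0;
  for (int i = 0; i < M; ++i) {
    if (!z[i]) continue;
    double sg = (sigsex && sex[i] == 1) ? sigM : sigF;
    double s2 = 2.0 * sg * sg;
    double l0s = lam0 * ((lam0sex && sex[i] == 1) ? std::exp(bsex) : 1.0);
    for (int t = 0; t < n_act; ++t) {
      double e = d2(s[i], act_trap[t]) / s2;
      if (theta != 1.0) e = std::pow(e, theta);
      ll += -l0s * std::exp(-e) * E[t];
    }
    if (i < n_obs) {
      for (int t = det_ptr[i]; t < det_ptr[i + 1]; ++t) {
        double e = d2(s[i], act_trap[det_t[t]]) / s2;
        if (theta != 1.0) e = std::pow(e, theta);
        double lam = l0s * std::exp(-e) * E[det_t[t]];
        ll += std::log(-std::expm1(-lam)) + lam;
      }
    }
  }
  return ll;
}
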