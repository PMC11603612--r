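// Integrator core for adiabatic constant-pH lambda dynamics.
//
// Coordinates:
//   - lambda coordinates: titration coordinates of every site (1 per acid,
//     3 per multisite His) plus titratable buffer coordinates (flat potential,
//     constraint participation only).
//   - environment coordinates: one harmonic coordinate per site whose minimum
//     and curvature interpolate linearly in lambda between the protonated (A)
//     and deprotonated (B) wells.
//   - gate coordinates: optional double-well conformational coordinate per
//     site; its position multiplicatively switches the A<->B offset (the
//     buried-residue toy landscape).
//   - s: optional d-AFED extended variable harmonically tethered to a gate,
//     propagated by BAOAB Langevin at its own high temperature.
//
// Thermostats: per-degree-of-freedom ("massive") Nose-Hoover chains with
// Suzuki-Yoshida factorization in the velocity-Verlet "side" scheme, or a
// single stochastic velocity-rescaling (CSVR) thermostat in standard mode.
// A SHAKE-like position projection plus RATTLE-like velocity projection
// enforces the linear charge-neutrality constraint each step.
//
// All randomness goes through R's RNG so set.seed() fully determines a run.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0083144621;     // kJ mol^-1 K^-1
static const double GATE_SWITCH_W = 0.2;   // width of the gate switching fn
static const double GATE_MIN = 0.5;        // gate well positions (+/-)

// ---------------------------------------------------------------------------
// System description (flattened by the R side)
// ---------------------------------------------------------------------------

struct Sys {
  // lambda coordinates
  int nl = 0;
  std::vector<double> lmass, lT, lbar, lslope, alpha;
  // tanh restraint groups (triples of lambda indices)
  int ng = 0;
  std::vector<int> gidx;                    // 3 * ng, 0-based
  std::vector<double> gamp, gflat, gsw;
  // environment coordinates
  int ne = 0;
  std::vector<double> emass, eminA, ekA, eminB, ekB, eoff;
  std::vector<int> elam;                    // attached lambda index
  // gate coordinates
  int ngt = 0;
  std::vector<double> gmass, gheight, goff;
  std::vector<int> glam;                    // lambda index whose offset is gated
  double Tphys = 300.0;
  // d-AFED extended variable
  bool dafed = false;
  int dgate = 0;
  double dk = 1000.0, dmass = 20.0, dTs = 1000.0, dgamma = 5.0;
  // charge constraint
  bool constr = false;
  double target = 0.0;
  // thermostat: 0 = none, 1 = massive NHC, 2 = global CSVR
  int tmode = 1;
  int M = 4, nsy = 4, nmts = 5;
  double tau = 0.5;
};

static Sys parse_sys(const List& L) {
  Sys S;
  S.lmass  = as<std::vector<double>>(L["lam_mass"]);
  S.lT     = as<std::vector<double>>(L["lam_T"]);
  S.lbar   = as<std::vector<double>>(L["lam_barrier"]);
  S.lslope = as<std::vector<double>>(L["lam_ph_slope"]);
  S.alpha  = as<std::vector<double>>(L["alpha"]);
  S.nl = (int)S.lmass.size();
  S.gidx  = as<std::vector<int>>(L["restraint_idx"]);
  S.gamp  = as<std::vector<double>>(L["restraint_amp"]);
  S.gflat = as<std::vector<double>>(L["restraint_flat"]);
  S.gsw   = as<std::vector<double>>(L["restraint_sw"]);
  S.ng = (int)S.gamp.size();
  S.emass = as<std::vector<double>>(L["env_mass"]);
  S.eminA = as<std::vector<double>>(L["env_minA"]);
  S.ekA   = as<std::vector<double>>(L["env_kA"]);
  S.eminB = as<std::vector<double>>(L["env_minB"]);
  S.ekB   = as<std::vector<double>>(L["env_kB"]);
  S.eoff  = as<std::vector<double>>(L["env_off"]);
  S.elam  = as<std::vector<int>>(L["env_lam"]);
  S.ne = (int)S.emass.size();
  S.gmass   = as<std::vector<double>>(L["gate_mass"]);
  S.gheight = as<std::vector<double>>(L["gate_height"]);
  S.goff    = as<std::vector<double>>(L["gate_off"]);
  S.glam    = as<std::vector<int>>(L["gate_lam"]);
  S.ngt = (int)S.gmass.size();
  S.Tphys = as<double>(L["T_physical"]);
  S.dafed = as<bool>(L["dafed"]);
  if (S.dafed) {
    S.dgate  = as<int>(L["dafed_gate"]);
    S.dk     = as<double>(L["dafed_k"]);
    S.dmass  = as<double>(L["dafed_mass"]);
    S.dTs    = as<double>(L["dafed_Ts"]);
    S.dgamma = as<double>(L["dafed_gamma"]);
  }
  S.constr = as<bool>(L["constraint"]);
  S.target = as<double>(L["constraint_target"]);
  S.tmode  = as<int>(L["thermo_mode"]);
  S.M      = as<int>(L["nhc_length"]);
  S.nsy    = as<int>(L["nhc_sy_order"]);
  S.nmts   = as<int>(L["nhc_n_mts"]);
  S.tau    = as<double>(L["nhc_tau"]);
  return S;
}

// ---------------------------------------------------------------------------
// Potential energy and analytic forces
// ---------------------------------------------------------------------------

// Step-like pH potential profile: quintic smoothstep rising from 0 to 1
// between the frame-classification thresholds (0.2, 0.8), exactly flat in
// both end-state basins so the basin count ratio obeys the two-state
// tempered-reweighting relation.
static inline double ph_step(double l) {
  if (l <= 0.2) return 0.0;
  if (l >= 0.8) return 1.0;
  const double t = (l - 0.2) / 0.6;
  return t * t * t * (10.0 + t * (-15.0 + 6.0 * t));
}
static inline double ph_step_d(double l) {
  if (l <= 0.2 || l >= 0.8) return 0.0;
  const double t = (l - 0.2) / 0.6;
  const double u = t * (1.0 - t);
  return 30.0 * u * u / 0.6;
}

// energy terms: 0 pH, 1 barrier, 2 restraint, 3 env, 4 gate, 5 dafed coupling
static void eval_forces(const Sys& S,
                        const double* xl, const double* xe, const double* xg,
                        double s,
                        double* fl, double* fe, double* fg, double& fs,
                        double E[6]) {
  for (int t = 0; t < 6; ++t) E[t] = 0.0;
  for (int i = 0; i < S.nl; ++i) fl[i] = 0.0;
  for (int i = 0; i < S.ne; ++i) fe[i] = 0.0;
  for (int i = 0; i < S.ngt; ++i) fg[i] = 0.0;
  fs = 0.0;

  for (int i = 0; i < S.nl; ++i) {
    const double l = xl[i];
    if (S.lslope[i] != 0.0) {
      E[0] += S.lslope[i] * ph_step(l);
      fl[i] -= S.lslope[i] * ph_step_d(l);
    }
    const double h = S.lbar[i];
    if (h > 0.0) {
      const double om = 1.0 - l;
      E[1] += 16.0 * h * l * l * om * om;
      fl[i] -= 32.0 * h * l * om * (1.0 - 2.0 * l);
    }
  }

  for (int g = 0; g < S.ng; ++g) {
    const int i0 = S.gidx[3 * g], i1 = S.gidx[3 * g + 1], i2 = S.gidx[3 * g + 2];
    const double d = xl[i0] + xl[i1] + xl[i2] - 1.0;
    const double ad = std::fabs(d);
    const double u = (ad - S.gflat[g]) / S.gsw[g];
    const double th = std::tanh(u);
    E[2] += 0.5 * S.gamp[g] * (th + 1.0);
    if (d != 0.0) {
      const double sech2 = 1.0 - th * th;
      const double dv = 0.5 * S.gamp[g] * sech2 / S.gsw[g] * (d > 0 ? 1.0 : -1.0);
      fl[i0] -= dv; fl[i1] -= dv; fl[i2] -= dv;
    }
  }

  for (int e = 0; e < S.ne; ++e) {
    const double r = xe[e];
    const double l = xl[S.elam[e]];
    const double dA = r - S.eminA[e], dB = r - S.eminB[e];
    const double vA = 0.5 * S.ekA[e] * dA * dA;
    const double vB = 0.5 * S.ekB[e] * dB * dB + S.eoff[e];
    E[3] += (1.0 - l) * vA + l * vB;
    fe[e] -= (1.0 - l) * S.ekA[e] * dA + l * S.ekB[e] * dB;
    fl[S.elam[e]] -= vB - vA;
  }

  for (int g = 0; g < S.ngt; ++g) {
    const double x = xg[g] / GATE_MIN;
    const double q = x * x - 1.0;
    E[4] += S.gheight[g] * q * q;
    fg[g] -= 4.0 * S.gheight[g] * x * q / GATE_MIN;
    if (S.goff[g] != 0.0) {
      const double th = std::tanh(xg[g] / GATE_SWITCH_W);
      const double sw = 0.5 * (1.0 - th);          // 1 closed (x<0), 0 open
      const double l = xl[S.glam[g]];
      E[4] += l * S.goff[g] * sw;
      fl[S.glam[g]] -= S.goff[g] * sw;
      fg[g] -= l * S.goff[g] * (-0.5) * (1.0 - th * th) / GATE_SWITCH_W;
    }
  }

  if (S.dafed) {
    const double d = xg[S.dgate] - s;
    E[5] += 0.5 * S.dk * d * d;
    fg[S.dgate] -= S.dk * d;
    fs += S.dk * d;
  }
}

// ---------------------------------------------------------------------------
// Nose-Hoover chain (single degree of freedom, all chain masses equal)
// ---------------------------------------------------------------------------

static void sy_weights(int order, std::vector<double>& w) {
  if (order == 4) {
    const double w1 = 1.0 / (2.0 - std::pow(2.0, 1.0 / 3.0));
    w = {w1, 1.0 - 2.0 * w1, w1};
  } else if (order == 6) {
    const double w1 = 0.784513610477560;
    const double w2 = 0.235573213359357;
    const double w3 = -1.17767998417887;
    w = {w1, w2, w3, 1.0 - 2.0 * (w1 + w2 + w3), w3, w2, w1};
  } else {
    w = {1.0};
  }
}

// exp() with a cubic fast path: chain sub-step arguments are O(1e-4), where
// the 3rd-order Taylor series is exact to double precision.
static inline double fexp(double x) {
  if (std::fabs(x) < 1e-3)
    return 1.0 + x * (1.0 + x * (0.5 + x / 6.0));
  return std::exp(x);
}

// Applies the factorized NHC update for time `dt` to one dof with kinetic
// energy (m v^2) = kin2, target kB*T = kT.  Returns the velocity scale
// factor; updates chain positions xi and velocities vxi in place.
static double nhc_update(double kin2, double kT, double Q,
                         double* xi, double* vxi, int M,
                         double dt, const std::vector<double>& w, int nmts) {
  double scale = 1.0;
  std::vector<double> G(M);
  for (size_t iw = 0; iw < w.size(); ++iw) {
    const double dts = w[iw] * dt / nmts;
    for (int it = 0; it < nmts; ++it) {
      G[0] = (kin2 - kT) / Q;
      for (int j = 1; j < M; ++j) G[j] = (Q * vxi[j - 1] * vxi[j - 1] - kT) / Q;
      vxi[M - 1] += G[M - 1] * dts / 4.0;
      for (int j = M - 2; j >= 0; --j) {
        const double ef = fexp(-vxi[j + 1] * dts / 8.0);
        vxi[j] = (vxi[j] * ef + G[j] * dts / 4.0) * ef;
      }
      const double sc = fexp(-vxi[0] * dts / 2.0);
      scale *= sc;
      kin2 *= sc * sc;
      for (int j = 0; j < M; ++j) xi[j] += vxi[j] * dts / 2.0;
      G[0] = (kin2 - kT) / Q;
      for (int j = 0; j < M - 1; ++j) {
        const double ef = fexp(-vxi[j + 1] * dts / 8.0);
        vxi[j] = (vxi[j] * ef + G[j] * dts / 4.0) * ef;
        G[j + 1] = (Q * vxi[j] * vxi[j] - kT) / Q;
      }
      vxi[M - 1] += G[M - 1] * dts / 4.0;
    }
  }
  return scale;
}

// [[Rcpp::export]]
List nhc_half_step_core(NumericMatrix xi, NumericMatrix vxi,
                        NumericVector v, NumericVector mass,
                        NumericVector target_T, double dt, double tau,
                        int sy_order, int n_mts) {
  const int n = v.size(), M = xi.ncol();
  std::vector<double> w;
  sy_weights(sy_order, w);
  NumericMatrix xio = clone(xi), vxio = clone(vxi);
  NumericVector vo = clone(v);
  for (int i = 0; i < n; ++i) {
    const double kT = KB * target_T[i];
    const double Q = kT * tau * tau;
    std::vector<double> cx(M), cv(M);
    for (int j = 0; j < M; ++j) { cx[j] = xio(i, j); cv[j] = vxio(i, j); }
    const double sc = nhc_update(mass[i] * v[i] * v[i], kT, Q,
                                 cx.data(), cv.data(), M, dt, w, n_mts);
    vo[i] = v[i] * sc;
    for (int j = 0; j < M; ++j) { xio(i, j) = cx[j]; vxio(i, j) = cv[j]; }
  }
  return List::create(_["xi"] = xio, _["vxi"] = vxio, _["v"] = vo);
}

// ---------------------------------------------------------------------------
// Stochastic velocity rescaling (CSVR)
// ---------------------------------------------------------------------------

static double csvr_scale(double K, double Kbar, int Nf, double cexp) {
  const double R1 = norm_rand();
  const double SS = (Nf > 1) ? ::Rf_rchisq((double)(Nf - 1)) : 0.0;
  const double t = (1.0 - cexp) * Kbar / (Nf * K);
  double a2 = cexp + t * (R1 * R1 + SS) + 2.0 * R1 * std::sqrt(cexp * t);
  if (a2 < 0.0) a2 = 0.0;
  return std::sqrt(a2);
}

// ---------------------------------------------------------------------------
// Charge constraint (SHAKE positions / RATTLE velocities)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List charge_constraint_core(NumericVector lambda_u, NumericVector velocity_u,
                            NumericVector alpha, NumericVector mass,
                            double target) {
  const int n = lambda_u.size();
  double denom = 0.0, viol = 0.0, vviol = 0.0;
  for (int i = 0; i < n; ++i) {
    denom += alpha[i] * alpha[i] / mass[i];
    viol += alpha[i] * lambda_u[i];
    vviol += alpha[i] * velocity_u[i];
  }
  if (denom == 0.0) stop("charge constraint undefined: all alpha are zero");
  const double zeta = (viol - target) / denom;
  const double zeta_v = vviol / denom;
  NumericVector l(n), v(n);
  for (int i = 0; i < n; ++i) {
    l[i] = lambda_u[i] - zeta * alpha[i] / mass[i];
    v[i] = velocity_u[i] - zeta_v * alpha[i] / mass[i];
  }
  return List::create(_["lambda"] = l, _["velocity"] = v,
                      _["zeta"] = zeta, _["zeta_v"] = zeta_v);
}

// ---------------------------------------------------------------------------
// Energy / force evaluation entry point for the R wrappers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List energy_forces_core(List sys, NumericVector xl, NumericVector xe,
                        NumericVector xg, double s) {
  Sys S = parse_sys(sys);
  if ((int)xl.size() != S.nl) stop("lambda vector length mismatch");
  if ((int)xe.size() != S.ne) stop("environment vector length mismatch");
  if ((int)xg.size() != S.ngt) stop("gate vector length mismatch");
  std::vector<double> fl(S.nl), fe(std::max(S.ne, 1)), fg(std::max(S.ngt, 1));
  double fs = 0.0, E[6];
  eval_forces(S, REAL(xl), S.ne ? REAL(xe) : nullptr,
              S.ngt ? REAL(xg) : nullptr, s,
              fl.data(), fe.data(), fg.data(), fs, E);
  double tot = 0.0;
  for (int t = 0; t < 6; ++t) tot += E[t];
  NumericVector terms = NumericVector::create(
      _["pH"] = E[0], _["barrier"] = E[1], _["restraint"] = E[2],
      _["env"] = E[3], _["gate"] = E[4], _["coupling"] = E[5]);
  return List::create(
      _["total"] = tot, _["terms"] = terms,
      _["f_lambda"] = NumericVector(fl.begin(), fl.begin() + S.nl),
      _["f_env"] = NumericVector(fe.begin(), fe.begin() + S.ne),
      _["f_gate"] = NumericVector(fg.begin(), fg.begin() + S.ngt),
      _["f_s"] = fs);
}

// ---------------------------------------------------------------------------
// d-AFED Langevin propagator for the extended variable (free-standing,
// used by the langevin_ou_step() wrapper and its property tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List langevin_run_core(double s, double vs, double mass, double Ts,
                       double gamma, double k, double cv, bool has_cv,
                       double dt, int n_steps) {
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(KB * Ts / mass * (1.0 - c1 * c1));
  NumericVector svec(n_steps), vvec(n_steps);
  double f = has_cv ? k * (cv - s) : 0.0;
  for (int i = 0; i < n_steps; ++i) {
    vs += 0.5 * dt * f / mass;           // B
    s += 0.5 * dt * vs;                  // A
    vs = c1 * vs + c2 * norm_rand();     // O (exact OU)
    s += 0.5 * dt * vs;                  // A
    f = has_cv ? k * (cv - s) : 0.0;
    vs += 0.5 * dt * f / mass;           // B
    svec[i] = s;
    vvec[i] = vs;
  }
  return List::create(_["s"] = svec, _["v_s"] = vvec);
}

// ---------------------------------------------------------------------------
// Main propagation loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_core(List sys, List state, int n_steps, double dt, int stride,
              bool record_conserved) {
  Sys S = parse_sys(sys);
  std::vector<double> xl = as<std::vector<double>>(state["lambda"]);
  std::vector<double> vl = as<std::vector<double>>(state["lambda_velocity"]);
  std::vector<double> xe = as<std::vector<double>>(state["env"]);
  std::vector<double> ve = as<std::vector<double>>(state["env_velocity"]);
  std::vector<double> xg = as<std::vector<double>>(state["gate"]);
  std::vector<double> vg = as<std::vector<double>>(state["gate_velocity"]);
  double s = as<double>(state["s"]);
  double vs = as<double>(state["s_velocity"]);
  int step0 = as<int>(state["step"]);

  const int nth = S.nl + S.ne + S.ngt;  // NHC-thermostatted dofs
  NumericMatrix xi_in = state["nhc_xi"], vxi_in = state["nhc_vxi"];
  const int M = S.M;
  std::vector<double> xi(nth * M, 0.0), vxi(nth * M, 0.0);
  if (xi_in.nrow() == nth && xi_in.ncol() == M)
    for (int i = 0; i < nth; ++i)
      for (int j = 0; j < M; ++j) { xi[i * M + j] = xi_in(i, j); vxi[i * M + j] = vxi_in(i, j); }

  // per-dof thermostat targets and masses
  std::vector<double> dof_T(nth), dof_m(nth);
  std::vector<double*> dof_x(nth), dof_v(nth);
  for (int i = 0; i < S.nl; ++i) {
    dof_T[i] = S.lT[i]; dof_m[i] = S.lmass[i];
    dof_x[i] = &xl[i]; dof_v[i] = &vl[i];
  }
  for (int i = 0; i < S.ne; ++i) {
    dof_T[S.nl + i] = S.Tphys; dof_m[S.nl + i] = S.emass[i];
    dof_x[S.nl + i] = &xe[i]; dof_v[S.nl + i] = &ve[i];
  }
  for (int i = 0; i < S.ngt; ++i) {
    dof_T[S.nl + S.ne + i] = S.Tphys; dof_m[S.nl + S.ne + i] = S.gmass[i];
    dof_x[S.nl + S.ne + i] = &xg[i]; dof_v[S.nl + S.ne + i] = &vg[i];
  }

  std::vector<double> w;
  sy_weights(S.nsy, w);
  const double dth = dt / 2.0;
  const double csvr_c = std::exp(-dth / S.tau);
  const double lc1 = std::exp(-S.dgamma * dt);
  const double lc2 = S.dafed ? std::sqrt(KB * S.dTs / S.dmass * (1.0 - lc1 * lc1)) : 0.0;

  std::vector<double> fl(S.nl), fe(std::max(S.ne, 1)), fg(std::max(S.ngt, 1));
  double fs = 0.0, E[6];
  eval_forces(S, xl.data(), xe.data(), xg.data(), s, fl.data(), fe.data(), fg.data(), fs, E);

  const int nsamp = n_steps / stride;
  NumericMatrix out_l(nsamp, S.nl), out_e(nsamp, std::max(S.ne, 0)),
      out_g(nsamp, std::max(S.ngt, 0)), out_T(nsamp, nth + (S.dafed ? 1 : 0)),
      out_E(nsamp, 6);
  NumericVector out_s(S.dafed ? nsamp : 0);
  IntegerVector out_step(nsamp);
  NumericVector out_cons(record_conserved ? nsamp : 0);
  int isamp = 0;

  auto thermo_half = [&]() {
    if (S.tmode == 1) {
      // massive NHC per lambda coordinate at its fictitious temperature;
      // the physical (env + gate) coordinates share a CSVR thermostat at
      // T_physical, as a molecular system would
      for (int i = 0; i < S.nl; ++i) {
        const double kT = KB * dof_T[i];
        const double Q = kT * S.tau * S.tau;
        const double v = *dof_v[i];
        const double sc = nhc_update(dof_m[i] * v * v, kT, Q,
                                     &xi[i * M], &vxi[i * M], M, dth, w, S.nmts);
        *dof_v[i] = v * sc;
      }
      const int nphys = S.ne + S.ngt;
      if (nphys > 0) {
        double K = 0.0;
        for (int i = S.nl; i < nth; ++i)
          K += 0.5 * dof_m[i] * (*dof_v[i]) * (*dof_v[i]);
        if (K > 0.0) {
          const double Kbar = nphys * KB * S.Tphys / 2.0;
          const double sc = csvr_scale(K, Kbar, nphys, csvr_c);
          for (int i = S.nl; i < nth; ++i) *dof_v[i] *= sc;
        }
      }
    } else if (S.tmode == 2) {
      double K = 0.0;
      for (int i = 0; i < nth; ++i) K += 0.5 * dof_m[i] * (*dof_v[i]) * (*dof_v[i]);
      if (K > 0.0) {
        const double Kbar = nth * KB * S.Tphys / 2.0;
        const double sc = csvr_scale(K, Kbar, nth, csvr_c);
        for (int i = 0; i < nth; ++i) *dof_v[i] *= sc;
      }
    }
  };

  for (int step = 1; step <= n_steps; ++step) {
    thermo_half();

    for (int i = 0; i < S.nl; ++i) vl[i] += dth * fl[i] / S.lmass[i];
    for (int i = 0; i < S.ne; ++i) ve[i] += dth * fe[i] / S.emass[i];
    for (int i = 0; i < S.ngt; ++i) vg[i] += dth * fg[i] / S.gmass[i];
    if (S.dafed) vs += dth * fs / S.dmass;

    for (int i = 0; i < S.nl; ++i) xl[i] += dt * vl[i];
    for (int i = 0; i < S.ne; ++i) xe[i] += dt * ve[i];
    for (int i = 0; i < S.ngt; ++i) xg[i] += dt * vg[i];
    if (S.dafed) {                       // A-O-A around the exact OU update
      s += dth * vs;
      vs = lc1 * vs + lc2 * norm_rand();
      s += dth * vs;
    }

    if (S.constr) {                      // SHAKE-like position projection
      double denom = 0.0, viol = -S.target;
      for (int i = 0; i < S.nl; ++i) {
        denom += S.alpha[i] * S.alpha[i] / S.lmass[i];
        viol += S.alpha[i] * xl[i];
      }
      const double zeta = viol / denom;
      for (int i = 0; i < S.nl; ++i) xl[i] -= zeta * S.alpha[i] / S.lmass[i];
    }

    eval_forces(S, xl.data(), xe.data(), xg.data(), s, fl.data(), fe.data(), fg.data(), fs, E);
    if (!std::isfinite(E[0] + E[1] + E[2] + E[3] + E[4] + E[5]))
      stop("non-finite energy at step %d", step0 + step);

    for (int i = 0; i < S.nl; ++i) vl[i] += dth * fl[i] / S.lmass[i];
    for (int i = 0; i < S.ne; ++i) ve[i] += dth * fe[i] / S.emass[i];
    for (int i = 0; i < S.ngt; ++i) vg[i] += dth * fg[i] / S.gmass[i];
    if (S.dafed) vs += dth * fs / S.dmass;

    if (S.constr) {                      // RATTLE-like velocity projection
      double denom = 0.0, vviol = 0.0;
      for (int i = 0; i < S.nl; ++i) {
        denom += S.alpha[i] * S.alpha[i] / S.lmass[i];
        vviol += S.alpha[i] * vl[i];
      }
      const double zeta_v = vviol / denom;
      for (int i = 0; i < S.nl; ++i) vl[i] -= zeta_v * S.alpha[i] / S.lmass[i];
    }

    thermo_half();

    if (step % stride == 0) {
      for (int i = 0; i < S.nl; ++i) out_l(isamp, i) = xl[i];
      for (int i = 0; i < S.ne; ++i) out_e(isamp, i) = xe[i];
      for (int i = 0; i < S.ngt; ++i) out_g(isamp, i) = xg[i];
      for (int i = 0; i < nth; ++i)
        out_T(isamp, i) = dof_m[i] * (*dof_v[i]) * (*dof_v[i]) / KB;
      if (S.dafed) {
        out_s[isamp] = s;
        out_T(isamp, nth) = S.dmass * vs * vs / KB;
      }
      for (int t = 0; t < 6; ++t) out_E(isamp, t) = E[t];
      out_step[isamp] = step0 + step;
      if (record_conserved) {
        double K = 0.0;
        for (int i = 0; i < nth; ++i) K += 0.5 * dof_m[i] * (*dof_v[i]) * (*dof_v[i]);
        if (S.dafed) K += 0.5 * S.dmass * vs * vs;
        double cons = K + E[0] + E[1] + E[2] + E[3] + E[4] + E[5];
        if (S.tmode == 1) {
          for (int i = 0; i < S.nl; ++i) {
            const double kT = KB * dof_T[i];
            const double Q = kT * S.tau * S.tau;
            for (int j = 0; j < M; ++j)
              cons += 0.5 * Q * vxi[i * M + j] * vxi[i * M + j] + kT * xi[i * M + j];
          }
        }
        out_cons[isamp] = cons;
      }
      ++isamp;
    }
  }

  NumericMatrix xi_out(nth, M), vxi_out(nth, M);
  for (int i = 0; i < nth; ++i)
    for (int j = 0; j < M; ++j) { xi_out(i, j) = xi[i * M + j]; vxi_out(i, j) = vxi[i * M + j]; }

  List fin = List::create(
      _["lambda"] = NumericVector(xl.begin(), xl.end()),
      _["lambda_velocity"] = NumericVector(vl.begin(), vl.end()),
      _["env"] = NumericVector(xe.begin(), xe.end()),
      _["env_velocity"] = NumericVector(ve.begin(), ve.end()),
      _["gate"] = NumericVector(xg.begin(), xg.end()),
      _["gate_velocity"] = NumericVector(vg.begin(), vg.end()),
      _["s"] = s, _["s_velocity"] = vs,
      _["step"] = step0 + n_steps,
      _["nhc_xi"] = xi_out, _["nhc_vxi"] = vxi_out);

  return List::create(
      _["step"] = out_step, _["lambda"] = out_l, _["env"] = out_e,
      _["gate"] = out_g, _["s"] = out_s, _["temps"] = out_T,
      _["energies"] = out_E, _["conserved"] = out_cons,
      _["final_state"] = fin);
}
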