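// Operator-split finite-volume stepper for the four-field
// phage/bacteria/nutrient system on a masked disk.
//
// Scheme per step of size dt (Strang arrangement):
//   transport(dt/2) -> reaction(dt) -> transport(dt/2)
// Transport: explicit central diffusion + first-order upwind chemotactic
// drift, conservative flux form, zero flux across mask faces.
// Reaction: per-cell adaptive exponential-Euler with Richardson
// extrapolation; the stiff linear decays (adsorption losses of B and P,
// lysis of L, consumption of n) are integrated exactly for frozen
// coefficients, so the step size is limited only by coefficient drift.
//
// Fluxes are accumulated into separate x- and y-divergence buffers which
// are combined as (divx + divy); this keeps mirror-symmetric initial data
// bitwise mirror-symmetric for all times.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Model {
  double DB, DP, Dn;        // cm^2/h
  double Kv, Kc, alpha, eta, beta, kl, gmax, Kn, lam, Kb, n0;
  bool abl_nut, abl_den;
  // Discreteness cutoff (um^-2): reaction source terms act only where the
  // participating densities exceed this level (about one particle per grid
  // cell). Without it, sub-particle lattice tails of B and L seed the
  // phage amplification loop (local growth rate ~ k_l n (beta-1)) far
  // ahead of and behind the physical fronts.
  double cut;
};

static Model model_from_list(const List& par) {
  Model m;
  m.DB = as<double>(par["D_Bmax"]);
  m.DP = as<double>(par["D_P"]);
  m.Dn = as<double>(par["D_n"]);
  m.Kv = as<double>(par["K_v"]);
  m.Kc = as<double>(par["K_c"]);
  m.alpha = as<double>(par["alpha_c"]);
  m.eta = as<double>(par["eta"]);
  m.beta = as<double>(par["beta"]);
  m.kl = as<double>(par["k_l"]);
  m.gmax = as<double>(par["g_max"]);
  m.Kn = as<double>(par["K_n"]);
  m.lam = as<double>(par["lam"]);
  m.Kb = as<double>(par["K_b"]);
  m.n0 = as<double>(par["n0"]);
  m.abl_nut = as<bool>(par["ablate_nutrient_gating"]);
  m.abl_den = as<bool>(par["ablate_density_inhibition"]);
  m.cut = 0.0;
  return m;
}

struct Work {
  int nx, ny;
  double h;
  std::vector<char> mask;
  std::vector<double> nu, cnu;            // motility factor, chi*nu
  std::vector<double> dxB, dyB, dxL, dyL, dxP, dyP, dxN, dyN;
  double umax;       // max |drift velocity| seen in last transport pass
  double clamped;    // accumulated clamped (negative) mass, density*cm^2
  Work(int nx_, int ny_, double h_)
      : nx(nx_), ny(ny_), h(h_), mask(nx_ * ny_),
        nu(nx_ * ny_), cnu(nx_ * ny_),
        dxB(nx_ * ny_), dyB(nx_ * ny_), dxL(nx_ * ny_), dyL(nx_ * ny_),
        dxP(nx_ * ny_), dyP(nx_ * ny_), dxN(nx_ * ny_), dyN(nx_ * ny_),
        umax(0), clamped(0) {}
};

static inline double sqr(double x) { return x * x; }

// (1 - exp(-a)) / a, stable near a = 0
static inline double phi1(double a) {
  if (std::fabs(a) < 1e-8) return 1.0 - 0.5 * a;
  return -std::expm1(-a) / a;
}

// One explicit transport substep of size dt on all four fields.
static void transport(std::vector<double>& B, std::vector<double>& L,
                      std::vector<double>& P, std::vector<double>& N,
                      const Model& m, Work& w, double dt) {
  const int nx = w.nx, ny = w.ny;
  const double h = w.h;
  // cell coefficients from current nutrient
  for (int k = 0; k < nx * ny; ++k) {
    if (!w.mask[k]) { w.nu[k] = 0; w.cnu[k] = 0; continue; }
    double n = N[k];
    double nu = m.abl_nut ? 1.0 : sqr(n / (n + m.Kv));
    w.nu[k] = nu;
    w.cnu[k] = m.DB * m.alpha * nu * m.Kc / sqr(n + m.Kc);
  }
  std::fill(w.dxB.begin(), w.dxB.end(), 0.0);
  std::fill(w.dyB.begin(), w.dyB.end(), 0.0);
  std::fill(w.dxL.begin(), w.dxL.end(), 0.0);
  std::fill(w.dyL.begin(), w.dyL.end(), 0.0);
  std::fill(w.dxP.begin(), w.dxP.end(), 0.0);
  std::fill(w.dyP.begin(), w.dyP.end(), 0.0);
  std::fill(w.dxN.begin(), w.dxN.end(), 0.0);
  std::fill(w.dyN.begin(), w.dyN.end(), 0.0);
  double umax = 0;

  // faces along a given stride (1 for x faces, nx for y faces)
  auto do_faces = [&](int stride, std::vector<double>& dB,
                      std::vector<double>& dL, std::vector<double>& dP,
                      std::vector<double>& dN) {
    const int ni = (stride == 1) ? nx - 1 : nx;
    const int nj = (stride == 1) ? ny : ny - 1;
    for (int j = 0; j < nj; ++j) {
      for (int i = 0; i < ni; ++i) {
        int a = i + j * nx;
        int b = a + stride;
        if (!w.mask[a] || !w.mask[b]) continue;
        double nuf = 0.5 * (w.nu[a] + w.nu[b]);
        double dn = (N[b] - N[a]) / h;
        double u = 0.5 * (w.cnu[a] + w.cnu[b]) * dn;  // drift velocity
        if (std::fabs(u) > umax) umax = std::fabs(u);
        double Bu = (u > 0) ? B[a] : B[b];
        double Lu = (u > 0) ? L[a] : L[b];
        double JB = -m.DB * nuf * (B[b] - B[a]) / h + u * Bu;
        double JL = -m.DB * nuf * (L[b] - L[a]) / h + u * Lu;
        double JP = -m.DP * (P[b] - P[a]) / h;
        double JN = -m.Dn * (N[b] - N[a]) / h;
        dB[a] -= JB; dB[b] += JB;
        dL[a] -= JL; dL[b] += JL;
        dP[a] -= JP; dP[b] += JP;
        dN[a] -= JN; dN[b] += JN;
      }
    }
  };
  do_faces(1, w.dxB, w.dxL, w.dxP, w.dxN);
  do_faces(nx, w.dyB, w.dyL, w.dyP, w.dyN);
  w.umax = umax;

  const double c = dt / h;
  for (int k = 0; k < nx * ny; ++k) {
    if (!w.mask[k]) continue;
    B[k] += c * (w.dxB[k] + w.dyB[k]);
    L[k] += c * (w.dxL[k] + w.dyL[k]);
    P[k] += c * (w.dxP[k] + w.dyP[k]);
    N[k] += c * (w.dxN[k] + w.dyN[k]);
    if (B[k] < 0) { w.clamped -= B[k] * h * h; B[k] = 0; }
    if (L[k] < 0) { w.clamped -= L[k] * h * h; L[k] = 0; }
    if (P[k] < 0) { w.clamped -= P[k] * h * h; P[k] = 0; }
    if (N[k] < 0) { w.clamped -= N[k] * h * h; N[k] = 0; }
  }
}

// One exponential-Euler reaction step with coefficients frozen at the
// start of the step. Exact for the linear-in-own-variable parts.
// Discreteness gates: a source term switches off when any density it
// needs is below the one-particle-per-cell level m.cut. Gates are frozen
// over one reaction step so the substep error estimate stays smooth.
struct Gates {
  bool grow, infect, padsorb, burst, consume;
};

static inline Gates eval_gates(const double y[4], const Model& m) {
  Gates gt;
  gt.grow = y[0] >= m.cut;
  gt.infect = (y[0] >= m.cut) && (y[2] >= m.cut);
  gt.padsorb = (y[0] + y[1] >= m.cut) && (y[2] >= m.cut);
  gt.burst = y[1] >= m.cut;
  gt.consume = y[0] + y[1] >= m.cut;
  return gt;
}

static inline void expo_step(const double y[4], double dt, const Model& m,
                             const Gates& gt, double out[4]) {
  double b = y[0], l = y[1], p = y[2], n = y[3];
  double af = m.abl_den ? 1.0 : m.Kb / (b + l + m.Kb);
  double a = m.eta * af;
  double g = m.gmax * n / (n + m.Kn);
  double d = m.kl * (m.abl_nut ? m.n0 : n);
  // B' = (g - a p) B
  out[0] = b * std::exp(((gt.grow ? g : 0.0) -
                         (gt.infect ? a * p : 0.0)) * dt);
  // L' = a b p - d L
  double src = gt.infect ? a * b * p : 0.0;
  out[1] = l * std::exp(-d * dt) + src * dt * phi1(d * dt);
  // P' = -a (b+l) P + beta d L
  double cdec = gt.padsorb ? a * (b + l) : 0.0;
  double q = gt.burst ? m.beta * d * l : 0.0;
  out[2] = p * std::exp(-cdec * dt) + q * dt * phi1(cdec * dt);
  // n' = -lam g (b+l) = -[lam gmax (b+l)/(n+Kn)] n
  double rho = gt.consume ? m.lam * m.gmax * (b + l) / (n + m.Kn) : 0.0;
  out[3] = n * std::exp(-rho * dt);
}

// Adaptive reaction integration over [0, dt] for one cell, using step
// doubling + Richardson extrapolation (2nd order) with relative error
// control on coefficient drift.
static void react_cell(double y[4], double dt, const Model& m,
                       double rtol, double atol, double& clamped,
                       double cellarea) {
  double t = 0.0;
  double hstep = dt;
  const Gates gt = eval_gates(y, m);
  int guard = 0;
  while (t < dt * (1.0 - 1e-14)) {
    if (++guard > 2000000) Rcpp::stop("reaction integration stalled");
    if (hstep > dt - t) hstep = dt - t;
    double y1[4], ym[4], y2[4];
    expo_step(y, hstep, m, gt, y1);
    expo_step(y, 0.5 * hstep, m, gt, ym);
    expo_step(ym, 0.5 * hstep, m, gt, y2);
    double err = 0.0;
    for (int c = 0; c < 4; ++c) {
      double sc = atol + rtol * std::max(std::fabs(y2[c]), std::fabs(y[c]));
      double e = std::fabs(y2[c] - y1[c]) / sc;
      if (e > err) err = e;
    }
    if (!std::isfinite(err)) { hstep *= 0.1; continue; }
    if (err <= 1.0) {
      t += hstep;
      for (int c = 0; c < 4; ++c) {
        double v = 2.0 * y2[c] - y1[c];  // Richardson
        if (v < 0) { clamped -= v * cellarea; v = 0; }
        y[c] = v;
      }
      double f = (err > 0) ? 0.9 / std::sqrt(err) : 5.0;
      if (f > 5.0) f = 5.0;
      if (f < 0.2) f = 0.2;
      hstep *= f;
    } else {
      double f = 0.9 / std::sqrt(err);
      if (f < 0.1) f = 0.1;
      hstep *= f;
      if (hstep < 1e-12) Rcpp::stop("reaction step underflow");
    }
  }
}

static void reaction(std::vector<double>& B, std::vector<double>& L,
                     std::vector<double>& P, std::vector<double>& N,
                     const Model& m, Work& w, double dt, double rtol) {
  const double atol = 1e-16;
  const double trace = 1e-10;  // um^-2; far below one particle per cell
  const double cellarea = w.h * w.h;
  for (int k = 0; k < w.nx * w.ny; ++k) {
    if (!w.mask[k]) continue;
    if (B[k] == 0.0 && L[k] == 0.0) continue;  // inert cell
    double y[4] = {B[k], L[k], P[k], N[k]};
    if (B[k] + L[k] < trace && P[k] < trace) {
      // diffusion tail: densities far below one particle per cell; a
      // single frozen-coefficient exponential step is ample there
      double y1[4];
      expo_step(y, dt, m, eval_gates(y, m), y1);
      for (int c = 0; c < 4; ++c) y[c] = y1[c];
    } else {
      react_cell(y, dt, m, rtol, atol, w.clamped, cellarea);
    }
    B[k] = y[0]; L[k] = y[1]; P[k] = y[2]; N[k] = y[3];
  }
}

static void check_finite(const std::vector<double>& v, const char* nm,
                         double t) {
  for (size_t k = 0; k < v.size(); ++k)
    if (!std::isfinite(v[k]))
      Rcpp::stop("non-finite value in field %s at t = %g", nm, t);
}

// Full Strang step: transport(dt/2), reaction(dt), transport(dt/2).
static void strang_step(std::vector<double>& B, std::vector<double>& L,
                        std::vector<double>& P, std::vector<double>& N,
                        const Model& m, Work& w, double dt, double rtol) {
  transport(B, L, P, N, m, w, 0.5 * dt);
  reaction(B, L, P, N, m, w, dt, rtol);
  transport(B, L, P, N, m, w, 0.5 * dt);
}

static std::vector<double> mat_to_vec(const NumericMatrix& M) {
  return std::vector<double>(M.begin(), M.end());
}

static NumericMatrix vec_to_mat(const std::vector<double>& v, int nx, int ny) {
  NumericMatrix M(nx, ny);
  std::copy(v.begin(), v.end(), M.begin());
  return M;
}

// [[Rcpp::export(name = ".step_core")]]
List step_core(NumericMatrix B0, NumericMatrix L0, NumericMatrix P0,
               NumericMatrix N0, LogicalMatrix maskM, double h,
               List par, double dt, double rxn_rtol, double cut_density) {
  const int nx = B0.nrow(), ny = B0.ncol();
  Model m = model_from_list(par);
  m.cut = cut_density;
  Work w(nx, ny, h);
  for (int k = 0; k < nx * ny; ++k) w.mask[k] = maskM[k];
  std::vector<double> B = mat_to_vec(B0), L = mat_to_vec(L0),
                      P = mat_to_vec(P0), N = mat_to_vec(N0);
  strang_step(B, L, P, N, m, w, dt, rxn_rtol);
  check_finite(B, "B", dt); check_finite(L, "L", dt);
  check_finite(P, "P", dt); check_finite(N, "N", dt);
  return List::create(_["B"] = vec_to_mat(B, nx, ny),
                      _["L"] = vec_to_mat(L, nx, ny),
                      _["P"] = vec_to_mat(P, nx, ny),
                      _["n"] = vec_to_mat(N, nx, ny),
                      _["clamped_mass"] = w.clamped,
                      _["umax"] = w.umax);
}

// [[Rcpp::export(name = ".run_core")]]
List run_core(NumericMatrix B0, NumericMatrix L0, NumericMatrix P0,
              NumericMatrix N0, LogicalMatrix maskM, double h,
              List par, double t0, double Tend, NumericVector snap_times,
              double safety, double dt_max, double rxn_rtol,
              double cut_density, IntegerVector probe, double stop_frac,
              int max_steps) {
  const int nx = B0.nrow(), ny = B0.ncol();
  Model m = model_from_list(par);
  m.cut = cut_density;
  Work w(nx, ny, h);
  for (int k = 0; k < nx * ny; ++k) w.mask[k] = maskM[k];
  std::vector<double> B = mat_to_vec(B0), L = mat_to_vec(L0),
                      P = mat_to_vec(P0), N = mat_to_vec(N0);

  const bool have_probe = probe.size() == 2;
  int probe_idx = -1;
  double n_probe0 = NA_REAL;
  if (have_probe) {
    probe_idx = (probe[0] - 1) + (probe[1] - 1) * nx;
    n_probe0 = N[probe_idx];
  }

  // diffusive stability bound: strongest diffusivity among n, B (gated),
  // P; the motility factor is bounded by its value at the current max n.
  auto diff_bound = [&]() {
    double nmax = 0;
    for (int k = 0; k < nx * ny; ++k)
      if (w.mask[k] && N[k] > nmax) nmax = N[k];
    double numax = m.abl_nut ? 1.0 : sqr(nmax / (nmax + m.Kv));
    double D = std::max(m.Dn, std::max(m.DB * numax, m.DP));
    return (D > 0) ? h * h / (4.0 * D) : R_PosInf;
  };

  std::vector<double> snaps_sorted(snap_times.begin(), snap_times.end());
  std::sort(snaps_sorted.begin(), snaps_sorted.end());
  size_t next_snap = 0;
  while (next_snap < snaps_sorted.size() &&
         snaps_sorted[next_snap] <= t0 + 1e-12)
    ++next_snap;

  List out_fields;
  std::vector<double> out_times;
  auto emit = [&](double t) {
    out_fields.push_back(List::create(
        _["B"] = vec_to_mat(B, nx, ny), _["L"] = vec_to_mat(L, nx, ny),
        _["P"] = vec_to_mat(P, nx, ny), _["n"] = vec_to_mat(N, nx, ny)));
    out_times.push_back(t);
  };
  if (!snaps_sorted.empty() && std::fabs(snaps_sorted[0] - t0) <= 1e-12)
    emit(t0);

  std::vector<double> probe_t, probe_n, dt_hist;
  double t = t0;
  double umax_prev = 0.0;
  bool stopped_depleted = false;
  int steps = 0;

  while (t < Tend - 1e-12) {
    double dt = safety * diff_bound();
    if (umax_prev > 0) dt = std::min(dt, safety * h / umax_prev);
    dt = std::min(dt, dt_max);
    double t_event = (next_snap < snaps_sorted.size())
                         ? std::min(Tend, snaps_sorted[next_snap])
                         : Tend;
    if (t + dt > t_event) dt = t_event - t;
    strang_step(B, L, P, N, m, w, dt, rxn_rtol);
    t += dt;
    umax_prev = w.umax;
    dt_hist.push_back(dt);
    if (++steps % 200 == 0) {
      check_finite(B, "B", t); check_finite(L, "L", t);
      check_finite(P, "P", t); check_finite(N, "N", t);
      Rcpp::checkUserInterrupt();
    }
    if (have_probe) {
      probe_t.push_back(t);
      probe_n.push_back(N[probe_idx]);
    }
    if (next_snap < snaps_sorted.size() &&
        std::fabs(t - snaps_sorted[next_snap]) <= 1e-12) {
      emit(snaps_sorted[next_snap]);
      ++next_snap;
    }
    if (have_probe && stop_frac > 0 && N[probe_idx] < stop_frac * n_probe0) {
      stopped_depleted = true;
      if (out_times.empty() || std::fabs(out_times.back() - t) > 1e-12)
        emit(t);
      break;
    }
    if (steps >= max_steps)
      Rcpp::stop("exceeded max_steps (%d) at t = %g h", max_steps, t);
  }
  check_finite(B, "B", t); check_finite(L, "L", t);
  check_finite(P, "P", t); check_finite(N, "N", t);
  if (!stopped_depleted &&
      (out_times.empty() || std::fabs(out_times.back() - t) > 1e-12))
    emit(t);

  return List::create(
      _["fields"] = out_fields, _["times"] = wrap(out_times),
      _["probe_t"] = wrap(probe_t), _["probe_n"] = wrap(probe_n),
      _["dt_history"] = wrap(dt_hist), _["clamped_mass"] = w.clamped,
      _["stopped_depleted"] = stopped_depleted, _["t_end"] = t,
      _["n_steps"] = steps);
}
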