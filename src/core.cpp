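// Explicit finite-difference core for the multicellular phase-field model.
//
// Layout: every field is a nx x ny column-major matrix, index i along x
// (anterior->posterior), j along y (ventral->dorsal). Interior nodes live at
// (x0 + i*h, y0 + j*h); the zero-flux (Neumann) boundary is closed by
// mirrored ghost values (ghost = nearest interior node), which makes the
// discrete Laplacian conservative: sum(lap(f))*h^2 == 0 exactly.
//
// The energy uses face (forward) differences for all gradient-square terms,
// so the 5-point Laplacian RHS below is the exact discrete functional
// derivative of the discrete energy -- energy descent and the
// directional-derivative oracle then hold to roundoff, not just O(h^2).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static inline int mir(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// smoothstep indicator, clamped outside [0,1]: the cubic is non-monotone
// there and would make the overlap energy unbounded below under overshoots
static inline double h_interp(double p) {
  if (p <= 0.0) return 0.0;
  if (p >= 1.0) return 1.0;
  return p * p * (3.0 - 2.0 * p);
}
static inline double h_prime(double p) {
  if (p <= 0.0 || p >= 1.0) return 0.0;
  return 6.0 * p * (1.0 - p);
}
static inline double dwell(double p) { double q = p * (1.0 - p); return 0.25 * q * q; }
static inline double dwell_prime(double p) { return 0.5 * p * (1.0 - p) * (1.0 - 2.0 * p); }

// C1 containment barrier outside [0,1]: with the indicator clamped, only the
// (weak) double well restores overshoots, so strong guidance forces could
// pile phase mass without bound; the barrier keeps excursions small while
// leaving the energy untouched on [0,1].
static inline double contain(double p, double B) {
  if (p < 0.0) return 0.5 * B * p * p;
  if (p > 1.0) return 0.5 * B * (p - 1.0) * (p - 1.0);
  return 0.0;
}
static inline double contain_prime(double p, double B) {
  if (p < 0.0) return B * p;
  if (p > 1.0) return B * (p - 1.0);
  return 0.0;
}

typedef std::vector<double> vec;

static void lap_into(const double* f, double* out, int nx, int ny, double h) {
  const double h2i = 1.0 / (h * h);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double c = f[i + (size_t)nx * j];
      double w = f[mir(i - 1, nx) + (size_t)nx * j];
      double e = f[mir(i + 1, nx) + (size_t)nx * j];
      double s = f[i + (size_t)nx * mir(j - 1, ny)];
      double n = f[i + (size_t)nx * mir(j + 1, ny)];
      out[i + (size_t)nx * j] = (w + e + s + n - 4.0 * c) * h2i;
    }
  }
}

static void gradx_into(const double* f, double* out, int nx, int ny, double h) {
  const double s = 1.0 / (2.0 * h);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      out[i + (size_t)nx * j] =
        (f[mir(i + 1, nx) + (size_t)nx * j] - f[mir(i - 1, nx) + (size_t)nx * j]) * s;
}

static void grady_into(const double* f, double* out, int nx, int ny, double h) {
  const double s = 1.0 / (2.0 * h);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      out[i + (size_t)nx * j] =
        (f[i + (size_t)nx * mir(j + 1, ny)] - f[i + (size_t)nx * mir(j - 1, ny)]) * s;
}

// sum over interior faces of (df/h)*(dg/h); boundary faces carry zero flux
static double face_dot(const double* f, const double* g, int nx, int ny, double h) {
  const double h2i = 1.0 / (h * h);
  double acc = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i + 1 < nx; ++i) {
      size_t k = i + (size_t)nx * j;
      acc += (f[k + 1] - f[k]) * (g[k + 1] - g[k]);
    }
  for (int j = 0; j + 1 < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t k = i + (size_t)nx * j;
      acc += (f[k + nx] - f[k]) * (g[k + nx] - g[k]);
    }
  return acc * h2i;
}

struct Pars {
  int N, nx, ny;
  double h, mu, beta0, gamma0, alpha0, barrier;
  std::vector<double> eps2, alpha, Vbar;
  std::vector<double> beta, gamma;  // N x N, column-major
};

static Pars unpack_pars(List pars, int nx, int ny, int N) {
  Pars p;
  p.N = N; p.nx = nx; p.ny = ny;
  p.h = as<double>(pars["h"]);
  p.mu = as<double>(pars["mu"]);
  p.beta0 = as<double>(pars["beta0"]);
  p.gamma0 = as<double>(pars["gamma0"]);
  p.alpha0 = as<double>(pars["alpha0"]);
  p.barrier = as<double>(pars["barrier"]);
  p.eps2 = as<std::vector<double> >(pars["eps2"]);
  p.alpha = as<std::vector<double> >(pars["alpha"]);
  p.Vbar = as<std::vector<double> >(pars["Vbar"]);
  NumericMatrix b = pars["beta"], g = pars["gamma"];
  p.beta.assign(b.begin(), b.end());
  p.gamma.assign(g.begin(), g.end());
  if ((int)p.eps2.size() != N || (int)p.alpha.size() != N || (int)p.Vbar.size() != N)
    stop("parameter vectors must have one entry per dynamic cell");
  if (b.nrow() != N || b.ncol() != N || g.nrow() != N || g.ncol() != N)
    stop("beta/gamma must be N x N per-cell matrices");
  return p;
}

// Workspace shared by rhs/energy/step computations
struct Work {
  int nx, ny, N;
  size_t nn;
  vec h0, lap_h0;            // static epithelium pieces
  double A_in;               // interior area integral(1 - h(phi0))
  std::vector<vec> hphi, lap_hphi;
  vec lap_phi, bsum, gsum, tmp1, tmp2, tmp3, tmp4, tmp5, tmp6;
  std::vector<double> V;

  Work(int nx_, int ny_, int N_, const double* phi0, double h)
    : nx(nx_), ny(ny_), N(N_), nn((size_t)nx_ * ny_) {
    h0.resize(nn); lap_h0.resize(nn);
    for (size_t k = 0; k < nn; ++k) h0[k] = h_interp(phi0[k]);
    lap_into(h0.data(), lap_h0.data(), nx, ny, h);
    A_in = 0.0;
    for (size_t k = 0; k < nn; ++k) A_in += 1.0 - h0[k];
    A_in *= h * h;
    hphi.assign(N, vec(nn));
    lap_hphi.assign(N, vec(nn));
    lap_phi.resize(nn); bsum.resize(nn); gsum.resize(nn);
    tmp1.resize(nn); tmp2.resize(nn); tmp3.resize(nn);
    tmp4.resize(nn); tmp5.resize(nn); tmp6.resize(nn);
    V.assign(N, 0.0);
  }

  // refresh h(phi_m), their Laplacians and volumes from the current state
  void update(const double* phi, const Pars& p) {
    const double h2 = p.h * p.h;
    for (int m = 0; m < N; ++m) {
      const double* pm = phi + nn * m;
      double v = 0.0;
      for (size_t k = 0; k < nn; ++k) { hphi[m][k] = h_interp(pm[k]); v += hphi[m][k]; }
      V[m] = v * h2;
      lap_into(hphi[m].data(), lap_hphi[m].data(), nx, ny, p.h);
    }
  }

  double deficit() const {
    double s = 0.0;
    for (int m = 0; m < N; ++m) s += V[m];
    return A_in - s;
  }
};

// dphi_m/dt for all m (no external force), writing into out
static void rhs_into(const double* phi, double* out, const Pars& p, Work& w) {
  w.update(phi, p);
  const double D = w.deficit();
  for (int m = 0; m < p.N; ++m) {
    const double* pm = phi + w.nn * m;
    lap_into(pm, w.lap_phi.data(), p.nx, p.ny, p.h);
    std::fill(w.bsum.begin(), w.bsum.end(), 0.0);
    std::fill(w.gsum.begin(), w.gsum.end(), 0.0);
    for (int n = 0; n < p.N; ++n) {
      if (n == m) continue;
      double bmn = p.beta[m + (size_t)p.N * n], gmn = p.gamma[m + (size_t)p.N * n];
      if (bmn != 0.0)
        for (size_t k = 0; k < w.nn; ++k) w.bsum[k] += bmn * w.hphi[n][k];
      if (gmn != 0.0)
        for (size_t k = 0; k < w.nn; ++k) w.gsum[k] += gmn * w.lap_hphi[n][k];
    }
    const double volp = 2.0 * p.alpha[m] * (w.V[m] - p.Vbar[m]);
    double* om = out + w.nn * m;
    for (size_t k = 0; k < w.nn; ++k) {
      double ph = pm[k];
      double bracket = volp + p.beta0 * w.h0[k] + 2.0 * w.bsum[k]
        - 2.0 * p.alpha0 * D - p.gamma0 * w.lap_h0[k] - 2.0 * w.gsum[k];
      om[k] = p.mu * (p.eps2[m] * w.lap_phi[k] - dwell_prime(ph)
                      - contain_prime(ph, p.barrier) - h_prime(ph) * bracket);
    }
  }
}

// energy breakdown: E0, E1, E2, E3, total (face-difference gradient terms)
static void energy_into(const double* phi, const Pars& p, Work& w, double* E) {
  w.update(phi, p);
  const double h2 = p.h * p.h;
  double E0 = 0.0, E1 = 0.0, E3 = 0.0;
  for (int m = 0; m < p.N; ++m) {
    const double* pm = phi + w.nn * m;
    double bulk = 0.0;
    for (size_t k = 0; k < w.nn; ++k) bulk += dwell(pm[k]) + contain(pm[k], p.barrier);
    E0 += (0.5 * p.eps2[m] * face_dot(pm, pm, p.nx, p.ny, p.h) + bulk) * h2;
    E0 += p.alpha[m] * (w.V[m] - p.Vbar[m]) * (w.V[m] - p.Vbar[m]);
    double s01 = 0.0;
    for (size_t k = 0; k < w.nn; ++k) s01 += w.h0[k] * w.hphi[m][k];
    E1 += p.beta0 * s01 * h2;
    E3 += p.gamma0 * face_dot(w.h0.data(), w.hphi[m].data(), p.nx, p.ny, p.h) * h2;
  }
  for (int m = 0; m < p.N; ++m)
    for (int n = m + 1; n < p.N; ++n) {
      double bmn = p.beta[m + (size_t)p.N * n], gmn = p.gamma[m + (size_t)p.N * n];
      if (bmn != 0.0) {
        double s = 0.0;
        for (size_t k = 0; k < w.nn; ++k) s += w.hphi[m][k] * w.hphi[n][k];
        E1 += 2.0 * bmn * s * h2;  // double sum counts each unordered pair twice
      }
      if (gmn != 0.0)
        E3 += 2.0 * gmn * face_dot(w.hphi[m].data(), w.hphi[n].data(), p.nx, p.ny, p.h) * h2;
    }
  double D = w.deficit();
  double E2 = p.alpha0 * D * D;
  E[0] = E0; E[1] = E1; E[2] = E2; E[3] = E3; E[4] = E0 + E1 + E2 + E3;
}

static void force_chem_into(const double* phic, const double* gcx, const double* gcy,
                            double mu_c, double h, int nx, int ny,
                            vec& wx, vec& wy, vec& t1, vec& t2, double* out) {
  size_t nn = (size_t)nx * ny;
  for (size_t k = 0; k < nn; ++k) { wx[k] = phic[k] * gcx[k]; wy[k] = phic[k] * gcy[k]; }
  gradx_into(wx.data(), t1.data(), nx, ny, h);
  grady_into(wy.data(), t2.data(), nx, ny, h);
  for (size_t k = 0; k < nn; ++k) out[k] = -mu_c * (t1[k] + t2[k]);
}

// TIM traction: -mubar * div( rho(c) * phic * phisub * sgn(grad c . perp) * perp )
// with perp = rotation of grad(phic); sgn(0) := 0 so a uniform c gives an
// exactly zero force, and the support is confined to phic*phisub > 0.
// support_floor zeroes the traction where the overlap product is below a
// small threshold: the exponential tails of phic otherwise act as a surface
// conveyor that ratchets stray mass far ahead of the cluster body.
static void force_tim_into(const double* phic, const double* phisub, const double* rho,
                           const double* gcx, const double* gcy,
                           double mubar, double h, int nx, int ny,
                           double perp_sign, double sgn_width, double support_floor,
                           vec& gx, vec& gy, vec& wx, vec& wy, vec& t1, vec& t2,
                           double* out) {
  size_t nn = (size_t)nx * ny;
  gradx_into(phic, gx.data(), nx, ny, h);
  grady_into(phic, gy.data(), nx, ny, h);
  for (size_t k = 0; k < nn; ++k) {
    double px = -perp_sign * gy[k], py = perp_sign * gx[k];
    double dot = gcx[k] * px + gcy[k] * py;
    double s;
    if (sgn_width > 0.0) s = std::tanh(dot / sgn_width);
    else s = (dot > 0.0) - (dot < 0.0);
    double ov = phic[k] * phisub[k];
    double a = (ov > support_floor) ? rho[k] * ov * s : 0.0;
    wx[k] = a * px; wy[k] = a * py;
  }
  gradx_into(wx.data(), t1.data(), nx, ny, h);
  grady_into(wy.data(), t2.data(), nx, ny, h);
  for (size_t k = 0; k < nn; ++k) out[k] = -mubar * (t1[k] + t2[k]);
}

static inline double clamp01(double p) { return p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p); }

// Expanded (transport + jump) formulation of the TIM traction used by the
// integrator. Writing the Eq-13 divergence out, with a = rho * Phi_sub * phic
// and t = perp(grad phic):
//   div(a s t) = s (grad a . t) + a (grad s . t)     [div t = 0 discretely]
// and the self-gradient part of grad(a) . t vanishes identically
// (grad phic . perp grad phic = 0), leaving
//   F = -mubar * phic * [ s (grad(rho Phi) . t) + rho Phi (grad s . t) ].
// The first term transports the cluster skin along the contact arc; the
// second is the flip-line (delta-layer) contribution where the sign factor
// reverses -- the tangential flux from both arc halves converges at the
// up-gradient pole, which is the propulsive protrusion. Discretizing the
// expansion instead of div(a s t) directly avoids the product-rule error
// that amplifies grid-scale roughness of phic. Amplitude factors are
// clamped to [0,1], where the overlap density is meaningful.
static void force_tim_transport_into(const double* phic, const double* phisub,
                                     const double* rho,
                                     const double* gcx, const double* gcy,
                                     double mubar, double h, int nx, int ny,
                                     double perp_sign, double sgn_width,
                                     double support_floor,
                                     vec& gx, vec& gy, vec& amp, vec& sf,
                                     vec& t1, vec& t2, vec& s1, vec& s2,
                                     double* out) {
  size_t nn = (size_t)nx * ny;
  gradx_into(phic, gx.data(), nx, ny, h);
  grady_into(phic, gy.data(), nx, ny, h);
  for (size_t k = 0; k < nn; ++k) {
    double px = -perp_sign * gy[k], py = perp_sign * gx[k];
    double dot = gcx[k] * px + gcy[k] * py;
    if (sgn_width > 0.0) sf[k] = std::tanh(dot / sgn_width);
    else sf[k] = (double)((dot > 0.0) - (dot < 0.0));
    amp[k] = rho[k] * clamp01(phisub[k]);
  }
  gradx_into(amp.data(), t1.data(), nx, ny, h);
  grady_into(amp.data(), t2.data(), nx, ny, h);
  gradx_into(sf.data(), s1.data(), nx, ny, h);
  grady_into(sf.data(), s2.data(), nx, ny, h);
  for (size_t k = 0; k < nn; ++k) {
    double px = -perp_sign * gy[k], py = perp_sign * gx[k];
    double pc = clamp01(phic[k]);
    double ov = pc * clamp01(phisub[k]);
    if (ov <= support_floor) { out[k] = 0.0; continue; }
    double transport = sf[k] * (t1[k] * px + t2[k] * py);
    double jump = amp[k] * (s1[k] * px + s2[k] * py);
    out[k] = -mubar * pc * (transport + jump);
  }
}

// ---------------------------------------------------------------- exports --

// [[Rcpp::export]]
NumericMatrix cpp_laplacian(NumericMatrix f, double h) {
  NumericMatrix out(f.nrow(), f.ncol());
  lap_into(f.begin(), out.begin(), f.nrow(), f.ncol(), h);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gradx(NumericMatrix f, double h) {
  NumericMatrix out(f.nrow(), f.ncol());
  gradx_into(f.begin(), out.begin(), f.nrow(), f.ncol(), h);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_grady(NumericMatrix f, double h) {
  NumericMatrix out(f.nrow(), f.ncol());
  grady_into(f.begin(), out.begin(), f.nrow(), f.ncol(), h);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rhs_all(NumericVector phi, NumericMatrix phi0, List pars) {
  IntegerVector dm = phi.attr("dim");
  if (dm.size() != 3) stop("phi must be a 3-d array (nx, ny, N)");
  int nx = dm[0], ny = dm[1], N = dm[2];
  Pars p = unpack_pars(pars, nx, ny, N);
  Work w(nx, ny, N, phi0.begin(), p.h);
  NumericVector out(phi.size());
  out.attr("dim") = dm;
  rhs_into(phi.begin(), out.begin(), p, w);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericVector phi, NumericMatrix phi0, List pars) {
  IntegerVector dm = phi.attr("dim");
  int nx = dm[0], ny = dm[1], N = dm[2];
  Pars p = unpack_pars(pars, nx, ny, N);
  Work w(nx, ny, N, phi0.begin(), p.h);
  double E[5];
  energy_into(phi.begin(), p, w, E);
  return NumericVector::create(_["E0"] = E[0], _["E1"] = E[1], _["E2"] = E[2],
                               _["E3"] = E[3], _["total"] = E[4]);
}

// [[Rcpp::export]]
NumericMatrix cpp_force_chem(NumericMatrix phic, NumericMatrix gcx, NumericMatrix gcy,
                             double mu_c, double h) {
  int nx = phic.nrow(), ny = phic.ncol();
  size_t nn = (size_t)nx * ny;
  vec wx(nn), wy(nn), t1(nn), t2(nn);
  NumericMatrix out(nx, ny);
  force_chem_into(phic.begin(), gcx.begin(), gcy.begin(), mu_c, h, nx, ny,
                  wx, wy, t1, t2, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_force_tim(NumericMatrix phic, NumericMatrix phisub, NumericMatrix rho,
                            NumericMatrix gcx, NumericMatrix gcy,
                            double mubar, double h, double perp_sign, double sgn_width,
                            double support_floor) {
  int nx = phic.nrow(), ny = phic.ncol();
  size_t nn = (size_t)nx * ny;
  vec gx(nn), gy(nn), wx(nn), wy(nn), t1(nn), t2(nn);
  NumericMatrix out(nx, ny);
  force_tim_into(phic.begin(), phisub.begin(), rho.begin(), gcx.begin(), gcy.begin(),
                 mubar, h, nx, ny, perp_sign, sgn_width, support_floor,
                 gx, gy, wx, wy, t1, t2, out.begin());
  return out;
}

// Forward-Euler integration of the full system with trajectory logging.
// ctrl: dt, nsteps, record_every, t0, force_mode (0 none / 1 chem / 2 tim),
//       force_cell, mu_c, mubar_c, rho, gcx, gcy, substrate (0-based),
//       perp_sign, sgn_width, cluster, oocyte, x, y
// [[Rcpp::export]]
List cpp_run(NumericVector phi_in, NumericMatrix phi0, List pars, List ctrl) {
  IntegerVector dm = phi_in.attr("dim");
  int nx = dm[0], ny = dm[1], N = dm[2];
  size_t nn = (size_t)nx * ny;
  Pars p = unpack_pars(pars, nx, ny, N);
  Work w(nx, ny, N, phi0.begin(), p.h);

  double dt = as<double>(ctrl["dt"]);
  int nsteps = as<int>(ctrl["nsteps"]);
  int record_every = as<int>(ctrl["record_every"]);
  double t0 = as<double>(ctrl["t0"]);
  int force_mode = as<int>(ctrl["force_mode"]);
  int force_cell = as<int>(ctrl["force_cell"]);       // 0-based, -1 none
  double mu_c = as<double>(ctrl["mu_c"]);
  double mubar_c = as<double>(ctrl["mubar_c"]);
  double perp_sign = as<double>(ctrl["perp_sign"]);
  double sgn_width = as<double>(ctrl["sgn_width"]);
  double support_floor = as<double>(ctrl["support_floor"]);
  int cluster = as<int>(ctrl["cluster"]);             // 0-based
  int oocyte = as<int>(ctrl["oocyte"]);               // -1 if absent
  IntegerVector substrate = ctrl["substrate"];        // 0-based, TIM force
  IntegerVector nurse = ctrl["nurse"];                // 0-based, overlap log
  NumericVector xs = ctrl["x"], ys = ctrl["y"];

  vec rho(nn, 0.0), gcx(nn, 0.0), gcy(nn, 0.0);
  if (force_mode != 0) {
    NumericMatrix r = ctrl["rho"], gx = ctrl["gcx"], gy = ctrl["gcy"];
    std::copy(r.begin(), r.end(), rho.begin());
    std::copy(gx.begin(), gx.end(), gcx.begin());
    std::copy(gy.begin(), gy.end(), gcy.begin());
  }

  vec phi(phi_in.begin(), phi_in.end());
  vec rhs(phi.size()), force(nn, 0.0), phisub(nn, 0.0);
  vec backup(phi);

  int nrec = nsteps / record_every + 1;
  int ncol = 3 + N + 5 + 2;
  NumericMatrix traj(nrec, ncol);
  double over_lo = 0.0, over_hi = 0.0;
  bool ok = true;
  std::string msg = "";
  int irec = 0, done_steps = 0, last_rec_step = 0;
  const double h2 = p.h * p.h;

  // record current state into row irec (updates w)
  auto record = [&](double tnow) {
    double E[5];
    energy_into(phi.data(), p, w, E);
    const double* hc = w.hphi[cluster].data();
    double sx = 0.0, sy = 0.0, sm = 0.0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = hc[i + (size_t)nx * j];
        sm += v; sx += v * xs[i]; sy += v * ys[j];
      }
    double xc = sm > 0 ? sx / sm : NA_REAL, yc = sm > 0 ? sy / sm : NA_REAL;
    double ovs = 0.0, ovo = 0.0;
    const double* pc = phi.data() + nn * cluster;
    for (int s = 0; s < nurse.size(); ++s) {
      const double* pj = phi.data() + nn * nurse[s];
      for (size_t k = 0; k < nn; ++k) ovs += pc[k] * pj[k];
    }
    if (oocyte >= 0) {
      const double* po = phi.data() + nn * oocyte;
      for (size_t k = 0; k < nn; ++k) ovo += pc[k] * po[k];
    }
    traj(irec, 0) = tnow; traj(irec, 1) = xc; traj(irec, 2) = yc;
    for (int m = 0; m < N; ++m) traj(irec, 3 + m) = w.V[m];
    for (int q = 0; q < 5; ++q) traj(irec, 3 + N + q) = E[q];
    traj(irec, 3 + N + 5) = ovs * h2;
    traj(irec, 3 + N + 6) = ovo * h2;
    ++irec;
  };

  record(t0);

  for (int step = 1; step <= nsteps; ++step) {
    rhs_into(phi.data(), rhs.data(), p, w);
    if (force_mode == 1) {
      force_chem_into(phi.data() + nn * force_cell, gcx.data(), gcy.data(),
                      mu_c, p.h, nx, ny, w.tmp1, w.tmp2, w.tmp3, w.tmp4, force.data());
      double* rf = rhs.data() + nn * force_cell;
      for (size_t k = 0; k < nn; ++k) rf[k] += force[k];
    } else if (force_mode == 2) {
      std::fill(phisub.begin(), phisub.end(), 0.0);
      for (int s = 0; s < substrate.size(); ++s) {
        const double* pj = phi.data() + nn * substrate[s];
        for (size_t k = 0; k < nn; ++k) phisub[k] += pj[k];
      }
      force_tim_transport_into(phi.data() + nn * force_cell, phisub.data(),
                               rho.data(), gcx.data(), gcy.data(), mubar_c,
                               p.h, nx, ny, perp_sign, sgn_width, support_floor,
                               w.tmp1, w.tmp2, w.tmp3, w.bsum, w.tmp4, w.tmp5,
                               w.tmp6, w.gsum, force.data());
      double* rf = rhs.data() + nn * force_cell;
      for (size_t k = 0; k < nn; ++k) rf[k] += force[k];
    }
    for (size_t k = 0; k < phi.size(); ++k) phi[k] += dt * rhs[k];

    if (step % record_every == 0) {
      bool finite = true;
      double lo = 0.0, hi = 1.0;
      for (size_t k = 0; k < phi.size(); ++k) {
        double v = phi[k];
        if (!std::isfinite(v)) { finite = false; break; }
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (!finite) {
        ok = false;
        msg = "non-finite field values detected; returning last recorded state";
        phi = backup;
        done_steps = last_rec_step;
        break;
      }
      if (-lo > over_lo) over_lo = -lo;
      if (hi - 1.0 > over_hi) over_hi = hi - 1.0;
      record(t0 + step * dt);
      backup = phi;
      last_rec_step = step;
    }
    done_steps = ok ? step : done_steps;
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector phi_out(phi.begin(), phi.end());
  phi_out.attr("dim") = dm;
  return List::create(
    _["phi"] = phi_out,
    _["traj"] = traj(Range(0, irec - 1), Range(0, ncol - 1)),
    _["time"] = t0 + done_steps * dt,
    _["steps_done"] = done_steps,
    _["ok"] = ok,
    _["message"] = msg,
    _["overshoot"] = NumericVector::create(_["below"] = over_lo, _["above"] = over_hi));
}
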