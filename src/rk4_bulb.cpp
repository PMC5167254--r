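// Fixed-step RK4 integrator for the coupled mitral-granule rate dynamics,
// optionally co-integrating the Hebbian ODE on the stored support of H.
//
//   dx = -H gy(y) - x/tau_x + c * L gx(x) + I(t)
//   dy =  W gx(x) - y/tau_y + I_c
//   dH_ij = -eta1 H_ij^2 + eta2 gx(x_i) gy(y_j)   (on stored entries only)
//
// H, W, L arrive as dgCMatrix slots (CSC). H's values are carried in a
// working copy so the input matrix is never modified in place. The
// glomerular drive I(t) is interpolated linearly on its sample grid.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// two-branch tanh membrane-potential function; unit slope at the threshold
static inline double act(double v, double zeta, double s_lo, double s_hi) {
  if (v < zeta) return s_lo + s_lo * std::tanh((v - zeta) / s_lo);
  return s_lo + s_hi * std::tanh((v - zeta) / s_hi);
}

// out = A %*% v for CSC arrays (n x n)
static inline void spmv(const int* Ai, const int* Ap, const double* Ax,
                        int n, const double* v, double* out) {
  for (int i = 0; i < n; ++i) out[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    const double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) out[Ai[k]] += Ax[k] * vj;
  }
}

struct Deriv {
  int n, nnzH;
  const int *Hi, *Hp, *Hj;        // Hj: column index per stored H entry
  const int *Wi, *Wp, *Li, *Lp;
  const double *Wx, *Lx;
  double tau_x, tau_y, zeta, sx_lo, sx_hi, sy_lo, sy_hi, c_gain;
  double i_background, i_cortex;
  bool learn;
  double eta1, eta2;
  std::vector<double> gx, gy, hgy, lgx, wgx;

  void operator()(const double* x, const double* y, const double* Hx,
                  const double* drive_t,
                  double* dx, double* dy, double* dHx) {
    for (int i = 0; i < n; ++i) {
      gx[i] = act(x[i], zeta, sx_lo, sx_hi);
      gy[i] = act(y[i], zeta, sy_lo, sy_hi);
    }
    spmv(Hi, Hp, Hx, n, gy.data(), hgy.data());
    spmv(Li, Lp, Lx, n, gx.data(), lgx.data());
    spmv(Wi, Wp, Wx, n, gx.data(), wgx.data());
    for (int i = 0; i < n; ++i) {
      dx[i] = -hgy[i] - x[i] / tau_x + c_gain * lgx[i] + drive_t[i] + i_background;
      dy[i] = wgx[i] - y[i] / tau_y + i_cortex;
    }
    if (learn) {
      for (int k = 0; k < nnzH; ++k) {
        dHx[k] = -eta1 * Hx[k] * Hx[k] + eta2 * gx[Hi[k]] * gy[Hj[k]];
      }
    }
  }
};

// [[Rcpp::export]]
List rk4_bulb_cpp(S4 H, S4 W, S4 L, NumericMatrix drive, double drive_t0,
                  double drive_dt, List par, double t0, double dt,
                  int n_steps, int record_stride,
                  NumericVector x0, NumericVector y0,
                  bool learn, double eta1, double eta2, bool record_y,
                  double diverge_bound) {
  const int n = x0.size();
  IntegerVector Hi = H.slot("i"), Hp = H.slot("p");
  IntegerVector Wi = W.slot("i"), Wp = W.slot("p");
  IntegerVector Li = L.slot("i"), Lp = L.slot("p");
  NumericVector Hx0 = H.slot("x"), Wx = W.slot("x"), Lx = L.slot("x");
  const int nnzH = Hx0.size();

  // column index per stored H entry
  std::vector<int> Hj(nnzH);
  for (int j = 0; j < n; ++j)
    for (int k = Hp[j]; k < Hp[j + 1]; ++k) Hj[k] = j;

  Deriv f;
  f.n = n; f.nnzH = nnzH;
  f.Hi = Hi.begin(); f.Hp = Hp.begin(); f.Hj = Hj.data();
  f.Wi = Wi.begin(); f.Wp = Wp.begin(); f.Wx = Wx.begin();
  f.Li = Li.begin(); f.Lp = Lp.begin(); f.Lx = Lx.begin();
  f.tau_x = par["tau_x"]; f.tau_y = par["tau_y"];
  f.zeta = par["zeta_thresh"];
  f.sx_lo = par["sx_lo"]; f.sx_hi = par["sx_hi"];
  f.sy_lo = par["sy_lo"]; f.sy_hi = par["sy_hi"];
  f.c_gain = par["c_gain"];
  f.i_background = par["i_background"]; f.i_cortex = par["i_cortex"];
  f.learn = learn; f.eta1 = eta1; f.eta2 = eta2;
  f.gx.resize(n); f.gy.resize(n); f.hgy.resize(n); f.lgx.resize(n); f.wgx.resize(n);

  const int n_drive = drive.ncol();
  std::vector<double> dr(n);
  auto drive_at = [&](double t) {
    double u = (t - drive_t0) / drive_dt;
    int k0 = (int)std::floor(u);
    if (k0 < 0) k0 = 0;
    if (k0 > n_drive - 2) k0 = n_drive - 2;
    double w = u - k0;
    if (w < 0) w = 0;
    if (w > 1) w = 1;
    const double* a = &drive(0, k0);
    const double* b = &drive(0, k0 + 1);
    for (int i = 0; i < n; ++i) dr[i] = (1.0 - w) * a[i] + w * b[i];
  };

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> Hx(Hx0.begin(), Hx0.end());
  std::vector<double> k1x(n), k1y(n), k2x(n), k2y(n), k3x(n), k3y(n), k4x(n), k4y(n);
  std::vector<double> tx(n), ty(n);
  std::vector<double> k1h, k2h, k3h, k4h, th;
  if (learn) {
    k1h.resize(nnzH); k2h.resize(nnzH); k3h.resize(nnzH); k4h.resize(nnzH);
    th.resize(nnzH);
  }
  double* thp = learn ? th.data() : Hx.data();

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix x_trace(n, n_rec);
  NumericMatrix y_trace(record_y ? n : 1, record_y ? n_rec : 1);
  NumericVector rec_times(n_rec);
  int rec = 0;
  auto record = [&](double t) {
    rec_times[rec] = t;
    for (int i = 0; i < n; ++i) x_trace(i, rec) = x[i];
    if (record_y) for (int i = 0; i < n; ++i) y_trace(i, rec) = y[i];
    ++rec;
  };
  record(t0);

  for (int step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;

    drive_at(t);
    f(x.data(), y.data(), Hx.data(), dr.data(),
      k1x.data(), k1y.data(), learn ? k1h.data() : nullptr);

    drive_at(t + 0.5 * dt);
    for (int i = 0; i < n; ++i) { tx[i] = x[i] + 0.5 * dt * k1x[i]; ty[i] = y[i] + 0.5 * dt * k1y[i]; }
    if (learn) for (int k = 0; k < nnzH; ++k) th[k] = Hx[k] + 0.5 * dt * k1h[k];
    f(tx.data(), ty.data(), thp, dr.data(),
      k2x.data(), k2y.data(), learn ? k2h.data() : nullptr);

    for (int i = 0; i < n; ++i) { tx[i] = x[i] + 0.5 * dt * k2x[i]; ty[i] = y[i] + 0.5 * dt * k2y[i]; }
    if (learn) for (int k = 0; k < nnzH; ++k) th[k] = Hx[k] + 0.5 * dt * k2h[k];
    f(tx.data(), ty.data(), thp, dr.data(),
      k3x.data(), k3y.data(), learn ? k3h.data() : nullptr);

    drive_at(t + dt);
    for (int i = 0; i < n; ++i) { tx[i] = x[i] + dt * k3x[i]; ty[i] = y[i] + dt * k3y[i]; }
    if (learn) for (int k = 0; k < nnzH; ++k) th[k] = Hx[k] + dt * k3h[k];
    f(tx.data(), ty.data(), thp, dr.data(),
      k4x.data(), k4y.data(), learn ? k4h.data() : nullptr);

    const double h6 = dt / 6.0;
    double amax = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += h6 * (k1x[i] + 2.0 * k2x[i] + 2.0 * k3x[i] + k4x[i]);
      y[i] += h6 * (k1y[i] + 2.0 * k2y[i] + 2.0 * k3y[i] + k4y[i]);
      double a = std::fabs(x[i]); if (a > amax) amax = a;
      a = std::fabs(y[i]); if (a > amax) amax = a;
    }
    if (learn) for (int k = 0; k < nnzH; ++k) {
      Hx[k] += h6 * (k1h[k] + 2.0 * k2h[k] + 2.0 * k3h[k] + k4h[k]);
    }
    if (!(amax < diverge_bound)) {
      stop("state diverged (|state| >= %g) at t = %g ms", diverge_bound,
           t0 + (step + 1) * dt);
    }
    if ((step + 1) % record_stride == 0) record(t0 + (step + 1) * dt);
    if (step % 2000 == 0) checkUserInterrupt();
  }

  return List::create(_["times"] = rec_times,
                      _["x_trace"] = x_trace,
                      _["y_trace"] = record_y ? SEXP(y_trace) : R_NilValue,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["h_values"] = NumericVector(Hx.begin(), Hx.end()));
}
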