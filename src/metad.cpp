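// Well-tempered metadynamics on a 2D collective-variable space with an
// overdamped Langevin sampler.
//
// Per-step bias forces are interpolated bilinearly from gradient grids that
// are updated locally whenever a hill is deposited; deposited hill heights
// are computed from the EXACT sum over all previously deposited hills at
// the new center, so the hills log is self-consistent: re-evaluating the
// logged bias reproduces every height bit-for-bit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// potential kinds: 0 = flat, 1 = harmonic (k1,c1,k2,c2),
// 2 = double Gaussian well (A1,c1x,c1y,w1x,w1y, A2,c2x,c2y,w2x,w2y)
static inline void pot_eval(int kind, const double* p,
                            double x, double y,
                            double& U, double& gx, double& gy) {
  U = 0.0; gx = 0.0; gy = 0.0;
  if (kind == 1) {
    const double dx = x - p[1], dy = y - p[3];
    U = 0.5 * p[0] * dx * dx + 0.5 * p[2] * dy * dy;
    gx = p[0] * dx;
    gy = p[2] * dy;
  } else if (kind == 2) {
    for (int w = 0; w < 2; ++w) {
      const double A = p[5 * w], cx = p[5 * w + 1], cy = p[5 * w + 2];
      const double wx = p[5 * w + 3], wy = p[5 * w + 4];
      const double dx = (x - cx) / wx, dy = (y - cy) / wy;
      const double e = -A * std::exp(-0.5 * (dx * dx + dy * dy));
      U += e;
      gx += -e * dx / wx;
      gy += -e * dy / wy;
    }
  }
}

// quartic confining walls outside [lo, hi], per dimension
static inline void wall_eval(double v, double lo, double hi, double scale,
                             double k, double& U, double& g) {
  if (v < lo) {
    const double t = (lo - v) / scale;
    U += k * t * t * t * t;
    g += -4.0 * k * t * t * t / scale;
  } else if (v > hi) {
    const double t = (v - hi) / scale;
    U += k * t * t * t * t;
    g += 4.0 * k * t * t * t / scale;
  }
}

struct BiasGrid {
  int n1, n2;
  double lo1, lo2, h1, h2;
  std::vector<double> V, Gx, Gy;
  BiasGrid(int n1_, int n2_, double lo1_, double hi1, double lo2_, double hi2)
      : n1(n1_), n2(n2_), lo1(lo1_), lo2(lo2_),
        h1((hi1 - lo1_) / (n1_ - 1)), h2((hi2 - lo2_) / (n2_ - 1)),
        V(n1_ * n2_, 0.0), Gx(n1_ * n2_, 0.0), Gy(n1_ * n2_, 0.0) {}

  void add_hill(double cx, double cy, double s1, double s2, double h) {
    const int a0 = std::max(0, (int)std::floor((cx - 6 * s1 - lo1) / h1));
    const int a1 = std::min(n1 - 1, (int)std::ceil((cx + 6 * s1 - lo1) / h1));
    const int b0 = std::max(0, (int)std::floor((cy - 6 * s2 - lo2) / h2));
    const int b1 = std::min(n2 - 1, (int)std::ceil((cy + 6 * s2 - lo2) / h2));
    for (int b = b0; b <= b1; ++b) {
      const double dy = (lo2 + b * h2 - cy);
      const double ey = std::exp(-0.5 * dy * dy / (s2 * s2));
      for (int a = a0; a <= a1; ++a) {
        const double dx = (lo1 + a * h1 - cx);
        const double g = h * std::exp(-0.5 * dx * dx / (s1 * s1)) * ey;
        const int id = a + n1 * b;
        V[id] += g;
        Gx[id] += -g * dx / (s1 * s1);
        Gy[id] += -g * dy / (s2 * s2);
      }
    }
  }

  void grad(double x, double y, double& bx, double& by) const {
    double u = (x - lo1) / h1, v = (y - lo2) / h2;
    int i = (int)std::floor(u), j = (int)std::floor(v);
    if (i < 0) i = 0; if (i > n1 - 2) i = n1 - 2;
    if (j < 0) j = 0; if (j > n2 - 2) j = n2 - 2;
    double fx = u - i, fy = v - j;
    if (fx < 0) fx = 0; if (fx > 1) fx = 1;
    if (fy < 0) fy = 0; if (fy > 1) fy = 1;
    const int id = i + n1 * j;
    const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
    const double w01 = (1 - fx) * fy, w11 = fx * fy;
    bx = w00 * Gx[id] + w10 * Gx[id + 1] + w01 * Gx[id + n1] +
         w11 * Gx[id + n1 + 1];
    by = w00 * Gy[id] + w10 * Gy[id + 1] + w01 * Gy[id + n1] +
         w11 * Gy[id + n1 + 1];
  }
};

// [[Rcpp::export]]
List metad_run_cpp(int pot_kind, NumericVector pot_params,
                   NumericVector box, double wall_k, NumericVector wall_scale,
                   NumericVector x0, int n_steps, NumericVector mobility,
                   double kT, double w0, int pace, NumericVector sigma,
                   double bias_factor, double kB_dT, double dt_ps, double t0,
                   NumericMatrix hills0, int trace_stride,
                   NumericVector grid_lo, NumericVector grid_hi,
                   IntegerVector grid_n) {
  const double lo1 = box[0], hi1 = box[1], lo2 = box[2], hi2 = box[3];
  BiasGrid grid(grid_n[0], grid_n[1], grid_lo[0], grid_hi[0], grid_lo[1],
                grid_hi[1]);

  // resumed hills: stored centers/sigmas/heights, grid pre-loaded
  std::vector<double> hc1, hc2, hs1, hs2, hh;
  const int n_old = hills0.nrow();
  hc1.reserve(n_old + n_steps / std::max(pace, 1) + 1);
  for (int k = 0; k < n_old; ++k) {
    hc1.push_back(hills0(k, 1)); hc2.push_back(hills0(k, 2));
    hs1.push_back(hills0(k, 3)); hs2.push_back(hills0(k, 4));
    hh.push_back(hills0(k, 5));
    grid.add_hill(hills0(k, 1), hills0(k, 2), hills0(k, 3), hills0(k, 4),
                  hills0(k, 5));
  }

  const bool deposit = pace > 0 && pace <= n_steps && w0 > 0;
  const int n_new = deposit ? n_steps / pace : 0;
  NumericMatrix hills_new(n_new, 7);
  const int n_trace = n_steps / trace_stride + 1;
  NumericMatrix trace(n_trace, 4);

  double x = x0[0], y = x0[1];
  const double mu1 = mobility[0], mu2 = mobility[1];
  const double a1 = std::sqrt(2.0 * mu1 * kT), a2 = std::sqrt(2.0 * mu2 * kT);
  // per-step drift cap: keeps the stiff confining walls from making the
  // explicit overdamped update overshoot; inactive in the landscape interior
  const double lim1 = std::max(10.0 * a1, 0.1 * sigma[0]);
  const double lim2 = std::max(10.0 * a2, 0.1 * sigma[1]);
  bool diverged = false;
  int n_dep = 0, n_tr = 0;
  RNGScope rng;

  for (int step = 0; step <= n_steps; ++step) {
    if (step % trace_stride == 0 && n_tr < n_trace) {
      double U, gx, gy;
      pot_eval(pot_kind, pot_params.begin(), x, y, U, gx, gy);
      wall_eval(x, lo1, hi1, wall_scale[0], wall_k, U, gx);
      wall_eval(y, lo2, hi2, wall_scale[1], wall_k, U, gy);
      trace(n_tr, 0) = t0 + step * dt_ps;
      trace(n_tr, 1) = x;
      trace(n_tr, 2) = y;
      trace(n_tr, 3) = U;
      ++n_tr;
    }
    if (step == n_steps) break;

    double U, gx, gy;
    pot_eval(pot_kind, pot_params.begin(), x, y, U, gx, gy);
    wall_eval(x, lo1, hi1, wall_scale[0], wall_k, U, gx);
    wall_eval(y, lo2, hi2, wall_scale[1], wall_k, U, gy);
    double bx = 0.0, by = 0.0;
    grid.grad(x, y, bx, by);
    gx += bx; gy += by;

    double drift1 = -mu1 * gx, drift2 = -mu2 * gy;
    if (drift1 > lim1) drift1 = lim1; else if (drift1 < -lim1) drift1 = -lim1;
    if (drift2 > lim2) drift2 = lim2; else if (drift2 < -lim2) drift2 = -lim2;
    x += drift1 + (kT > 0 ? a1 * R::norm_rand() : 0.0);
    y += drift2 + (kT > 0 ? a2 * R::norm_rand() : 0.0);

    if (x < lo1 - 10 * sigma[0] || x > hi1 + 10 * sigma[0] ||
        y < lo2 - 10 * sigma[1] || y > hi2 + 10 * sigma[1]) {
      diverged = true;
      break;
    }

    if (deposit && (step + 1) % pace == 0) {
      // exact bias at the new center from all hills deposited so far
      double Vc = 0.0;
      for (size_t k = 0; k < hh.size(); ++k) {
        const double dx = (x - hc1[k]) / hs1[k];
        const double dy = (y - hc2[k]) / hs2[k];
        Vc += hh[k] * std::exp(-0.5 * (dx * dx + dy * dy));
      }
      const double h = w0 * std::exp(-Vc / kB_dT);
      hills_new(n_dep, 0) = t0 + (step + 1) * dt_ps;
      hills_new(n_dep, 1) = x;
      hills_new(n_dep, 2) = y;
      hills_new(n_dep, 3) = sigma[0];
      hills_new(n_dep, 4) = sigma[1];
      hills_new(n_dep, 5) = h;
      hills_new(n_dep, 6) = bias_factor;
      hc1.push_back(x); hc2.push_back(y);
      hs1.push_back(sigma[0]); hs2.push_back(sigma[1]);
      hh.push_back(h);
      grid.add_hill(x, y, sigma[0], sigma[1], h);
      ++n_dep;
    }
  }

  return List::create(_["hills"] = hills_new, _["trace"] = trace,
                      _["n_hills"] = n_dep, _["n_trace"] = n_tr,
                      _["diverged"] = diverged,
                      _["x_final"] = NumericVector::create(x, y));
}
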