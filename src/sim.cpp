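// Monte Carlo core for lateral diffusion in a periodic 2D membrane with
// circular trapping domains, plus the virtual confocal detector.
//
// The stepper and the intensity sampler share one particle-update routine:
// an isotropic Gaussian step whose standard deviation per axis is
// sqrt(2 * D_local * dt), with D_local = d_in inside a domain and d_out
// outside. A proposed step that crosses a domain boundary is accepted with
// probability p_enter (outside -> inside) or p_escape (inside -> outside);
// a refused crossing is reflected off the circular boundary. All distances
// use the minimum-image convention.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// Static spatial index over the (non-overlapping) trapping disks so that
// point-in-domain queries touch only a handful of candidate disks.
struct DomainGrid {
  int ncell;
  double cellsize, box, radius, radius2;
  std::vector<double> cx, cy;
  std::vector<std::vector<int> > cells;

  DomainGrid(const NumericMatrix& centers, double radius_, double box_)
      : box(box_), radius(radius_), radius2(radius_ * radius_) {
    int nd = centers.nrow();
    for (int d = 0; d < nd; ++d) {
      cx.push_back(centers(d, 0));
      cy.push_back(centers(d, 1));
    }
    ncell = 1;
    if (nd > 0 && radius > 0) {
      ncell = (int)std::floor(box / (2.0 * radius));
      if (ncell < 1) ncell = 1;
      if (ncell > 64) ncell = 64;
    }
    cellsize = box / ncell;
    cells.resize((size_t)ncell * ncell);
    for (int d = 0; d < nd; ++d) {
      int i0 = (int)std::floor((cx[d] - radius) / cellsize);
      int i1 = (int)std::floor((cx[d] + radius) / cellsize);
      int j0 = (int)std::floor((cy[d] - radius) / cellsize);
      int j1 = (int)std::floor((cy[d] + radius) / cellsize);
      for (int i = i0; i <= i1; ++i) {
        for (int j = j0; j <= j1; ++j) {
          int ii = ((i % ncell) + ncell) % ncell;
          int jj = ((j % ncell) + ncell) % ncell;
          std::vector<int>& v = cells[(size_t)ii * ncell + jj];
          if (std::find(v.begin(), v.end(), d) == v.end()) v.push_back(d);
        }
      }
    }
  }

  inline double mindist2(double x, double y, int d) const {
    double dx = x - cx[d];
    dx -= box * std::round(dx / box);
    double dy = y - cy[d];
    dy -= box * std::round(dy / box);
    return dx * dx + dy * dy;
  }

  // index of the disk containing (x, y), or -1
  inline int locate(double x, double y) const {
    if (cx.empty()) return -1;
    int i = (int)(x / cellsize);
    if (i >= ncell) i = ncell - 1;
    if (i < 0) i = 0;
    int j = (int)(y / cellsize);
    if (j >= ncell) j = ncell - 1;
    if (j < 0) j = 0;
    const std::vector<int>& v = cells[(size_t)i * ncell + j];
    for (size_t k = 0; k < v.size(); ++k)
      if (mindist2(x, y, v[k]) <= radius2) return v[k];
    return -1;
  }
};

struct Stepper {
  double box, sig_out, sig_in, p_enter, p_escape;
  const DomainGrid* grid;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;
  std::uniform_real_distribution<double> unif;

  Stepper(double box_, double d_out, double d_in, double dt, double p_enter_,
          double p_escape_, const DomainGrid* grid_, uint64_t seed)
      : box(box_),
        sig_out(std::sqrt(2.0 * d_out * dt)),
        sig_in(std::sqrt(2.0 * d_in * dt)),
        p_enter(p_enter_),
        p_escape(p_escape_),
        grid(grid_),
        rng(seed),
        gauss(0.0, 1.0),
        unif(0.0, 1.0) {}

  inline double wrap(double v) {
    v -= box * std::floor(v / box);
    if (v >= box) v -= box;  // guard against rounding at the upper edge
    return v;
  }

  inline void step(double& x, double& y, int& dom) {
    double sig = (dom >= 0) ? sig_in : sig_out;
    double qx = wrap(x + sig * gauss(rng));
    double qy = wrap(y + sig * gauss(rng));
    int dnew = grid->locate(qx, qy);
    if (dnew == dom) {
      x = qx;
      y = qy;
      return;
    }
    // boundary crossing: accept, or reflect off the circle
    double pacc = (dom < 0) ? p_enter
                            : ((dnew < 0) ? p_escape : p_escape * p_enter);
    if (pacc >= 1.0 || unif(rng) < pacc) {
      x = qx;
      y = qy;
      dom = dnew;
      return;
    }
    int dref = (dom >= 0) ? dom : dnew;  // disk whose boundary was hit
    double dx = qx - grid->cx[dref];
    dx -= box * std::round(dx / box);
    double dy = qy - grid->cy[dref];
    dy -= box * std::round(dy / box);
    double rho = std::sqrt(dx * dx + dy * dy);
    if (rho < 1e-12) return;  // degenerate proposal: stay put
    double rho2 = 2.0 * grid->radius - rho;
    if (rho2 < 0) rho2 = 0;
    double s = rho2 / rho;
    double rx = wrap(grid->cx[dref] + dx * s);
    double ry = wrap(grid->cy[dref] + dy * s);
    int dr = grid->locate(rx, ry);
    // keep the reflected point only if it lands on the original side;
    // otherwise (large step near several disks) the particle waits a step
    if ((dom >= 0 && dr == dom) || (dom < 0 && dr < 0)) {
      x = rx;
      y = ry;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".locate_domains_cpp")]]
IntegerVector locate_domains_cpp(NumericVector x, NumericVector y,
                                 NumericMatrix centers, double radius,
                                 double box) {
  DomainGrid grid(centers, radius, box);
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = grid.locate(x[i], y[i]) + 1;  // 0 = outside
  return out;
}

// Full-resolution trajectories: positions and domain occupancy per frame.
// x0/y0 give the initial frame; dom0 uses 0 = outside, 1..n = disk index.
// [[Rcpp::export(name = ".sim_trajectories_cpp")]]
List sim_trajectories_cpp(NumericVector x0, NumericVector y0,
                          IntegerVector dom0, int n_frames, double dt,
                          double box, double d_out, double d_in,
                          double p_enter, double p_escape,
                          NumericMatrix centers, double radius, double seed) {
  int np = x0.size();
  DomainGrid grid(centers, radius, box);
  Stepper st(box, d_out, d_in, dt, p_enter, p_escape, &grid, (uint64_t)seed);

  NumericMatrix X(n_frames, np), Y(n_frames, np);
  LogicalMatrix IN(n_frames, np);
  std::vector<double> x(np), y(np);
  std::vector<int> dom(np);
  for (int i = 0; i < np; ++i) {
    x[i] = x0[i];
    y[i] = y0[i];
    dom[i] = dom0[i] - 1;
  }
  for (int f = 0; f < n_frames; ++f) {
    if (f > 0)
      for (int i = 0; i < np; ++i) st.step(x[i], y[i], dom[i]);
    for (int i = 0; i < np; ++i) {
      X(f, i) = x[i];
      Y(f, i) = y[i];
      IN(f, i) = dom[i] >= 0;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["in_domain"] = IN);
}

// Simulate and record only the expected fluorescence per sampling bin for a
// set of Gaussian spots (waist = 1/e^2 radius). The position entering bin b
// is the state after b * steps_per_bin updates; warmup_steps updates run
// before recording starts. Returns an n_bins x n_spots matrix of expected
// counts (Poisson noise, if wanted, is applied by the caller).
// [[Rcpp::export(name = ".sim_intensity_cpp")]]
NumericMatrix sim_intensity_cpp(NumericVector x0, NumericVector y0,
                                IntegerVector dom0, double n_bins_,
                                int steps_per_bin, int warmup_steps, double dt,
                                double box, double d_out, double d_in,
                                double p_enter, double p_escape,
                                NumericMatrix centers, double radius,
                                NumericVector spot_x, NumericVector spot_y,
                                NumericVector waist, double brightness,
                                double background, double seed) {
  int np = x0.size();
  int ns = waist.size();
  R_xlen_t n_bins = (R_xlen_t)n_bins_;
  DomainGrid grid(centers, radius, box);
  Stepper st(box, d_out, d_in, dt, p_enter, p_escape, &grid, (uint64_t)seed);

  std::vector<double> x(np), y(np);
  std::vector<int> dom(np);
  for (int i = 0; i < np; ++i) {
    x[i] = x0[i];
    y[i] = y0[i];
    dom[i] = dom0[i] - 1;
  }
  for (int w = 0; w < warmup_steps; ++w)
    for (int i = 0; i < np; ++i) st.step(x[i], y[i], dom[i]);

  std::vector<double> inv_w2(ns), cutoff(ns);
  for (int s = 0; s < ns; ++s) {
    inv_w2[s] = 2.0 / (waist[s] * waist[s]);
    cutoff[s] = 8.0 * waist[s] * waist[s];  // exp(-16) ~ 1e-7: negligible
  }

  NumericMatrix out(n_bins, ns);
  for (R_xlen_t b = 0; b < n_bins; ++b) {
    // the first recorded bin is the (possibly warmed-up) initial state
    if (b > 0)
      for (int q = 0; q < steps_per_bin; ++q)
        for (int i = 0; i < np; ++i) st.step(x[i], y[i], dom[i]);
    for (int s = 0; s < ns; ++s) {
      double acc = 0.0;
      double sx = spot_x[s], sy = spot_y[s];
      for (int i = 0; i < np; ++i) {
        double dx = x[i] - sx;
        dx -= box * std::round(dx / box);
        double dy = y[i] - sy;
        dy -= box * std::round(dy / box);
        double d2 = dx * dx + dy * dy;
        if (d2 < cutoff[s]) acc += std::exp(-d2 * inv_w2[s]);
      }
      out(b, s) = background + brightness * acc;
    }
    if ((b & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
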