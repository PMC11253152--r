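#include <Rcpp.h>
#include <set>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform grid for fixed-radius neighbour queries on a strip that is
// periodic in y (period W, origin ymin) and open in x.
struct NeighbourGrid {
  double xmin, cw, ymin, W, ch, rc;
  int nbx, nby;
  std::vector< std::vector<int> > bins;

  NeighbourGrid(const NumericVector& x, const NumericVector& y,
                double rcut, double ymin_, double W_)
    : ymin(ymin_), W(W_), rc(rcut) {
    double xlo = R_PosInf, xhi = R_NegInf;
    for (int i = 0; i < x.size(); ++i) {
      if (x[i] < xlo) xlo = x[i];
      if (x[i] > xhi) xhi = x[i];
    }
    if (!R_FINITE(xlo)) { xlo = 0.0; xhi = 0.0; }
    xmin = xlo;
    double span = std::max(xhi - xlo, rcut);
    nbx = std::max(1, (int)std::floor(span / rcut));
    cw = span / nbx * (1.0 + 1e-12);
    nby = std::max(1, (int)std::floor(W / rcut));
    ch = W / nby;
    bins.assign((size_t)nbx * nby, std::vector<int>());
    for (int i = 0; i < x.size(); ++i) bins[index(x[i], y[i])].push_back(i);
  }

  int ixof(double x) const {
    int ix = (int)std::floor((x - xmin) / cw);
    if (ix < 0) ix = 0;
    if (ix >= nbx) ix = nbx - 1;
    return ix;
  }
  int iyof(double y) const {
    double v = (y - ymin) / W;
    double u = (v - std::floor(v)) * W;
    int iy = (int)std::floor(u / ch);
    if (iy >= nby) iy = nby - 1;
    return iy;
  }
  size_t index(double x, double y) const {
    return (size_t)ixof(x) + (size_t)nbx * iyof(y);
  }

  // visit candidate neighbours of (x, y); F(int j)
  template <typename F>
  void visit(double x, double y, F f) const {
    int ix = ixof(x), iy = iyof(y);
    int seen[3]; int nseen = 0;
    for (int d = -1; d <= 1; ++d) {
      int jy = iy + d;
      if (jy < 0) jy += nby;
      if (jy >= nby) jy -= nby;
      bool dup = false;
      for (int s = 0; s < nseen; ++s) if (seen[s] == jy) dup = true;
      if (dup) continue;
      seen[nseen++] = jy;
      for (int dx = -1; dx <= 1; ++dx) {
        int jx = ix + dx;
        if (jx < 0 || jx >= nbx) continue;
        const std::vector<int>& b = bins[(size_t)jx + (size_t)nbx * jy];
        for (size_t t = 0; t < b.size(); ++t) f(b[t]);
      }
    }
  }
};

static inline double wrap_dy(double dy, double W) {
  return dy - W * std::nearbyint(dy / W);
}

// SPH (Poly6) density, density gradient and neighbour count at query
// points, given particles of uniform mass m. Periodic in y.
// [[Rcpp::export]]
List sph_eval_cpp(NumericVector px, NumericVector py,
                  NumericVector qx, NumericVector qy,
                  double m, double h, double ymin, double W) {
  int nq = qx.size();
  NumericVector rho(nq), gx(nq), gy(nq);
  IntegerVector cnt(nq);
  if (px.size() == 0) return List::create(_["rho"] = rho, _["gx"] = gx,
                                          _["gy"] = gy, _["count"] = cnt);
  double h2 = h * h, h8 = std::pow(h, 8);
  double cW = 4.0 / (M_PI * h8), cG = -24.0 / (M_PI * h8);
  NeighbourGrid grid(px, py, h, ymin, W);
  for (int i = 0; i < nq; ++i) {
    double r = 0, ggx = 0, ggy = 0; int c = 0;
    double xi = qx[i], yi = qy[i];
    grid.visit(xi, yi, [&](int j) {
      double dx = xi - px[j];
      double dy = wrap_dy(yi - py[j], W);
      double d2 = dx * dx + dy * dy;
      if (d2 < h2) {
        double u = h2 - d2;
        r += cW * u * u * u;
        double g = cG * u * u;
        ggx += g * dx;
        ggy += g * dy;
        ++c;
      }
    });
    rho[i] = m * r; gx[i] = m * ggx; gy[i] = m * ggy; cnt[i] = c;
  }
  return List::create(_["rho"] = rho, _["gx"] = gx, _["gy"] = gy,
                      _["count"] = cnt);
}

// Explicit-Euler descent on the pairwise repulsion potential
// Phi(r) = 2*kappa*R^2*(r-1)^2 for r = dist/(2R) < 1, until the maximum
// pair overlap falls below eps*2R. Anterior wall: x clamped >= 0.
// [[Rcpp::export]]
List relax_cpp(NumericVector x0, NumericVector y0, double R, double kappa,
               double ymin, double W, double eps, int maxit,
               bool track_energy, double eps_accept = 0.1) {
  int n = x0.size();
  NumericVector x = clone(x0), y = clone(y0);
  NumericVector fx(n), fy(n);
  std::vector<double> energy;
  double two_r = 2.0 * R;
  // pair stiffness is kappa (Phi'' in overlap units), so explicit Euler is
  // contractive for dt < 0.5/kappa; the displacement cap below still
  // bounds each move by 0.25 R
  double dt0 = 0.2 / kappa;
  double max_ov = 0.0;
  int it = 0;
  bool converged = false;
  // stall detection: in a pressurized packing the descent can reach a
  // force equilibrium with small residual overlaps; accept it once the
  // best overlap has stopped improving, provided it is below eps_accept
  double best_ov = R_PosInf;
  int last_improve = 0;
  for (it = 0; it <= maxit; ++it) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    max_ov = 0.0;
    double epot = 0.0;
    NeighbourGrid grid(x, y, two_r, ymin, W);
    for (int i = 0; i < n; ++i) {
      double xi = x[i], yi = y[i];
      grid.visit(xi, yi, [&](int j) {
        if (j == i) return;
        double dx = xi - x[j];
        double dy = wrap_dy(yi - y[j], W);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < two_r) {
          double ov = two_r - d;
          if (ov > max_ov) max_ov = ov;
          double r = d / two_r;
          if (track_energy) epot += kappa * R * R * (r - 1.0) * (r - 1.0); // half of 2*kappa.. per ordered pair
          double mag;
          if (d > 1e-12) {
            mag = 2.0 * kappa * R * (1.0 - r) / d; // -dPhi/dd / d
            fx[i] += mag * dx;
            fy[i] += mag * dy;
          } else {
            // coincident centres: deterministic tiny split along x by index order
            fx[i] += (i < j ? -1.0 : 1.0) * 2.0 * kappa * R * 1e-3;
          }
        }
      });
    }
    if (track_energy) energy.push_back(epot);
    if (max_ov < eps * two_r) { converged = true; break; }
    if (max_ov < best_ov * 0.99) { best_ov = max_ov; last_improve = it; }
    if (it - last_improve > 2000) {
      if (max_ov < eps_accept * two_r) break; // force equilibrium, accept
      // wedged pairs: gradient descent cannot shear past a packing
      // barrier, so project offending pairs apart to exact contact
      // (deterministic position-based overlap resolution) and continue
      NeighbourGrid g2(x, y, two_r, ymin, W);
      for (int i = 0; i < n; ++i) {
        double xi = x[i], yi = y[i];
        g2.visit(xi, yi, [&](int j) {
          if (j <= i) return;
          double dx = x[i] - x[j];
          double dy = wrap_dy(yi - y[j], W);
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < (1.0 - eps_accept) * two_r && d > 1e-12) {
            if (x[i] <= 0.0 && x[j] <= 0.0) {
              // an over-full wall row cannot resolve laterally: eject the
              // younger (higher-index) cell posteriorly to exact contact
              double need2 = two_r * two_r - dy * dy;
              x[j] = (need2 > 0) ? std::sqrt(need2) : two_r;
              return;
            }
            // split the separation between the pair, but hand any part
            // the anterior wall would absorb to the free partner
            double ux = dx / d, uy = dy / d;
            double need = two_r - d;
            double si = 0.5 * need, sj = 0.5 * need;
            if (ux < 0 && x[i] + si * ux < 0) {
              double si2 = -x[i] / ux;
              sj += si - si2; si = si2;
            } else if (ux > 0 && x[j] - sj * ux < 0) {
              double sj2 = x[j] / ux;
              si += sj - sj2; sj = sj2;
            }
            x[i] += si * ux; y[i] += si * uy;
            x[j] -= sj * ux; y[j] -= sj * uy;
            if (x[i] < 0) x[i] = 0;
            if (x[j] < 0) x[j] = 0;
          }
        });
      }
      best_ov = R_PosInf;
      last_improve = it;
    }
    if (it == maxit) break;
    double fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i]);
      if (f > fmax) fmax = f;
    }
    double dt = dt0;
    if (fmax * dt > 0.25 * R) dt = 0.25 * R / fmax;
    for (int i = 0; i < n; ++i) {
      x[i] += dt * fx[i];
      y[i] += dt * fy[i];
      if (x[i] < 0.0) x[i] = 0.0;
      double v = (y[i] - ymin) / W;
      y[i] = ymin + (v - std::floor(v)) * W;
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["iterations"] = it,
                      _["max_overlap"] = max_ov, _["converged"] = converged,
                      _["energy"] = wrap(energy));
}

// Front cells: cell i is a front cell iff there is no cell j with
// x_j > x_i and wrapped |y_j - y_i| < R.
// [[Rcpp::export]]
LogicalVector front_cells_cpp(NumericVector x, NumericVector y, double R,
                              double ymin, double W) {
  int n = x.size();
  LogicalVector front(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] > x[b]; });
  std::multiset<double> ys; // y, y-W, y+W of all strictly-posterior cells
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[ord[j]] == x[ord[i]]) ++j; // tie group: equal x never blocks
    for (int t = i; t < j; ++t) {
      int c = ord[t];
      // blocked iff some posterior y lies in the open interval (y-R, y+R)
      auto lo = ys.upper_bound(y[c] - R);
      front[c] = !(lo != ys.end() && *lo < y[c] + R);
    }
    for (int t = i; t < j; ++t) {
      int c = ord[t];
      ys.insert(y[c]);
      ys.insert(y[c] - W);
      ys.insert(y[c] + W);
    }
    i = j;
  }
  return front;
}
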