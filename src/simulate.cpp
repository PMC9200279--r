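#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Agent motility states
static const int MOTILE = 0, TRAPPED = 1, EPS_IMMOTILE = 2;

// Truncated Pareto (tail exponent a) on [tmin, tmax] by inverse CDF.
static double rtrunc_pareto(double a, double tmin, double tmax) {
  double u = R::runif(0.0, 1.0);
  if (std::fabs(a - 1.0) < 1e-12) return tmin * std::pow(tmax / tmin, u);
  double p = 1.0 - a;
  double v = std::pow(tmin, p) + u * (std::pow(tmax, p) - std::pow(tmin, p));
  return std::pow(v, 1.0 / p);
}

static inline double wrap_coord(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against x/L rounding to exactly 1
  return x;
}

// minimum-image displacement on the periodic box
static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

struct CellList {
  int nx;
  double cell, L;
  std::vector<std::vector<int>> bins;
  CellList(double L_, double r) : L(L_) {
    nx = std::max(1, (int)std::floor(L_ / r));
    cell = L_ / nx;
    bins.assign((size_t)nx * nx, {});
  }
  void build(const std::vector<double>& x, const std::vector<double>& y) {
    for (auto& b : bins) b.clear();
    for (int i = 0; i < (int)x.size(); ++i) {
      int ix = std::min(nx - 1, (int)(x[i] / cell));
      int iy = std::min(nx - 1, (int)(y[i] / cell));
      bins[(size_t)iy * nx + ix].push_back(i);
    }
  }
  template <class F>
  void neighbors(double xi, double yi, F f) const {
    int ix = std::min(nx - 1, (int)(xi / cell));
    int iy = std::min(nx - 1, (int)(yi / cell));
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int jx = (ix + dx + nx) % nx, jy = (iy + dy + nx) % nx;
        for (int j : bins[(size_t)jy * nx + jx]) f(j);
      }
  }
};

// [[Rcpp::export(name = ".sim_colony_cpp")]]
List sim_colony_cpp(NumericVector x0, NumericVector y0, NumericVector h0,
                    IntegerVector state0, double box_side, double dt,
                    int n_steps, int burn_in,
                    double speed_motile, double run_time_exponent,
                    double run_time_min, double run_time_max,
                    double trap_radius, int trap_min_neighbors,
                    double p_trap, double p_escape,
                    double align_radius, double align_strength,
                    double cohesion_strength,
                    double rep_semi_l, double rep_semi_w,
                    double repulsion_push,
                    double rot_noise, double speed_base_frac, double n_sat,
                    bool eps_drift, double eps_drift_speed) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      h(h0.begin(), h0.end());
  std::vector<int> st(state0.begin(), state0.end());
  std::vector<double> clock(n);
  for (int i = 0; i < n; ++i)
    clock[i] = rtrunc_pareto(run_time_exponent, run_time_min, run_time_max);

  int total = burn_in + n_steps;
  NumericVector X((size_t)n * n_steps), Y((size_t)n * n_steps),
      H((size_t)n * n_steps);
  IntegerVector S((size_t)n * n_steps);

  double r_nb = std::max(trap_radius, align_radius);
  double r2_trap = trap_radius * trap_radius;
  double r2_align = align_radius * align_radius;
  double r2_rep = rep_semi_l * rep_semi_l; // widest reach of the ellipse
  CellList cl(box_side, std::max(r_nb, box_side / 64.0));

  std::vector<int> newst(n);
  std::vector<int> bounces(n, 0); // consecutive blocked moves (jamming)
  for (int step = 0; step < total; ++step) {
    cl.build(x, y);
    for (int i = 0; i < n; ++i) newst[i] = st[i];
    for (int i = 0; i < n; ++i) {
      if (st[i] == EPS_IMMOTILE) {
        if (eps_drift) {
          // rearrangement by the surrounding swarm: slow drift along the mean
          // heading of >= 3 adjacent motile cells (off by default)
          double sx = 0, sy = 0; int nm = 0;
          cl.neighbors(x[i], y[i], [&](int j) {
            if (j == i || st[j] != MOTILE) return;
            double ddx = min_image(x[j] - x[i], box_side);
            double ddy = min_image(y[j] - y[i], box_side);
            if (ddx * ddx + ddy * ddy <= r2_trap) {
              sx += std::cos(h[j]); sy += std::sin(h[j]); ++nm;
            }
          });
          if (nm >= 3) {
            double nrm = std::sqrt(sx * sx + sy * sy);
            if (nrm > 0) {
              x[i] = wrap_coord(x[i] + eps_drift_speed * dt * sx / nrm, box_side);
              y[i] = wrap_coord(y[i] + eps_drift_speed * dt * sy / nrm, box_side);
            }
          }
        }
        continue;
      }
      if (st[i] == TRAPPED) {
        if (R::runif(0.0, 1.0) < p_escape) {
          newst[i] = MOTILE;
          h[i] = R::runif(0.0, 2.0 * M_PI);
          clock[i] = rtrunc_pareto(run_time_exponent, run_time_min, run_time_max);
        }
        continue;
      }
      // MOTILE: gather neighborhood statistics
      int n_loc = 0, n_nm_here = 0;
      double ax = 0, ay = 0, gx = 0, gy = 0, rx = 0, ry = 0;
      cl.neighbors(x[i], y[i], [&](int j) {
        if (j == i) return;
        double ddx = min_image(x[j] - x[i], box_side);
        double ddy = min_image(y[j] - y[i], box_side);
        double d2 = ddx * ddx + ddy * ddy;
        if (d2 <= r2_align) {
          ++n_loc;
          if (st[j] == MOTILE) {
            ax += std::cos(h[j]); ay += std::sin(h[j]);
            gx += ddx; gy += ddy;
          }
        }
        if (d2 <= r2_rep && d2 > 0) {
          // soft excluded volume: elliptical metric in the cell frame so
          // rods exclude ~a body length along the axis and ~a width across
          double uu = std::cos(h[i]) * ddx + std::sin(h[i]) * ddy;
          double vv = -std::sin(h[i]) * ddx + std::cos(h[i]) * ddy;
          double q = std::sqrt(uu * uu / (rep_semi_l * rep_semi_l) +
                               vv * vv / (rep_semi_w * rep_semi_w));
          if (q < 1.0 && q > 0) {
            double d = std::sqrt(d2);
            double ov = 1.0 - q;
            rx -= ov * ddx / d;
            ry -= ov * ddy / d;
          }
        }
        if (d2 <= r2_trap && st[j] != MOTILE) ++n_nm_here;
      });
      // already in a trap neighborhood (e.g. inside an aggregate pocket):
      // same per-step trapping probability applies in place
      if (n_nm_here >= trap_min_neighbors && R::runif(0.0, 1.0) < p_trap) {
        newst[i] = TRAPPED;
        continue;
      }
      // local alignment toward the mean heading of motile neighbors (raft
      // coherence), plus rotational noise
      if (align_strength > 0 && (ax != 0 || ay != 0)) {
        double hm = std::atan2(ay, ax);
        h[i] += align_strength * std::sin(hm - h[i]);
      }
      // mild cohesion: steer toward the local motile center of mass, so the
      // swarm organises into dense fast rafts rather than a uniform gas
      if (cohesion_strength > 0 && (gx != 0 || gy != 0)) {
        double hg = std::atan2(gy, gx);
        h[i] += cohesion_strength * std::sin(hg - h[i]);
      }
      if (rot_noise > 0) h[i] += rot_noise * std::sqrt(dt) * R::rnorm(0.0, 1.0);
      clock[i] -= dt;
      if (clock[i] <= 0) {
        h[i] = R::runif(0.0, 2.0 * M_PI);
        clock[i] = rtrunc_pareto(run_time_exponent, run_time_min, run_time_max);
      }
      // cooperative speed-up: speed rises with local crowding up to saturation
      double v = speed_motile *
        (speed_base_frac + (1.0 - speed_base_frac) *
         std::min(1.0, n_sat > 0 ? n_loc / n_sat : 1.0));
      double pushx = 0, pushy = 0;
      if (repulsion_push > 0 && (rx != 0 || ry != 0)) {
        double rn = std::sqrt(rx * rx + ry * ry);
        double mag = std::min(repulsion_push * rn, 0.5 * rep_semi_w);
        pushx = mag * rx / rn;
        pushy = mag * ry / rn;
      }
      double nx2 = wrap_coord(x[i] + v * dt * std::cos(h[i]) + pushx, box_side);
      double ny2 = wrap_coord(y[i] + v * dt * std::sin(h[i]) + pushy, box_side);
      // stationary aggregates are obstacles: moving into the neighborhood of
      // enough non-motile cells either traps the swarmer there or deflects it
      int n_nm_new = 0;
      double cmx = 0, cmy = 0;
      cl.neighbors(nx2, ny2, [&](int j) {
        if (j == i || st[j] == MOTILE) return;
        double ddx = min_image(x[j] - nx2, box_side);
        double ddy = min_image(y[j] - ny2, box_side);
        if (ddx * ddx + ddy * ddy <= r2_trap) {
          ++n_nm_new; cmx += ddx; cmy += ddy;
        }
      });
      if (n_nm_new >= trap_min_neighbors) {
        if (R::runif(0.0, 1.0) < p_trap || ++bounces[i] >= 15) {
          // trapped outright, or jammed after repeated blocked moves
          x[i] = nx2; y[i] = ny2;
          newst[i] = TRAPPED;
          bounces[i] = 0;
          continue;
        }
        // slide along the aggregate boundary: remove the velocity component
        // pointing into the local cluster (toward its center of mass)
        double nn = std::sqrt(cmx * cmx + cmy * cmy);
        bool moved = false;
        if (nn > 0) {
          double nxu = cmx / nn, nyu = cmy / nn;
          double dxs = std::cos(h[i]), dys = std::sin(h[i]);
          double dot = dxs * nxu + dys * nyu;
          double tx = dxs - dot * nxu, ty = dys - dot * nyu;
          double tn = std::sqrt(tx * tx + ty * ty);
          if (tn > 0.1) {
            double nx3 = wrap_coord(x[i] + v * dt * tx / tn, box_side);
            double ny3 = wrap_coord(y[i] + v * dt * ty / tn, box_side);
            int n_nm3 = 0;
            cl.neighbors(nx3, ny3, [&](int j) {
              if (j == i || st[j] == MOTILE) return;
              double ddx = min_image(x[j] - nx3, box_side);
              double ddy = min_image(y[j] - ny3, box_side);
              if (ddx * ddx + ddy * ddy <= r2_trap) ++n_nm3;
            });
            if (n_nm3 < trap_min_neighbors) {
              x[i] = nx3; y[i] = ny3;
              h[i] = std::atan2(ty / tn, tx / tn);
              moved = true;
            }
          }
        }
        if (!moved) { // cornered: tumble in place
          h[i] = R::runif(0.0, 2.0 * M_PI);
          clock[i] = rtrunc_pareto(run_time_exponent, run_time_min,
                                   run_time_max);
        }
        continue;
      }
      bounces[i] = 0;
      x[i] = nx2;
      y[i] = ny2;
    }
    st = newst;
    if (step >= burn_in) {
      int f = step - burn_in;
      for (int i = 0; i < n; ++i) {
        size_t k = (size_t)f * n + i;
        X[k] = x[i]; Y[k] = y[i]; H[k] = h[i]; S[k] = st[i];
      }
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["heading"] = H,
                      _["state"] = S, _["n_agents"] = n,
                      _["n_frames"] = n_steps);
}

// Stamp anisotropic intensity kernels (cells) into one frame.
// sigma_l/sigma_w in um; positions in um; periodic wrapping. Kernels are
// composited with per-pixel max so that dense regions keep cell-to-cell
// texture (per-agent amplitude) instead of saturating uniformly.
// [[Rcpp::export(name = ".render_frame_cpp")]]
NumericMatrix render_frame_cpp(NumericVector x, NumericVector y,
                               NumericVector heading, LogicalVector keep,
                               NumericVector amp, int npix,
                               double pixel_size, double box_side,
                               double sigma_l, double sigma_w) {
  NumericMatrix img(npix, npix); // rows = y, cols = x
  int half = (int)std::ceil(3.0 * sigma_l / pixel_size);
  for (int i = 0; i < x.size(); ++i) {
    if (!keep[i]) continue;
    double c = std::cos(heading[i]), s = std::sin(heading[i]);
    int pc = (int)std::floor(x[i] / pixel_size);
    int pr = (int)std::floor(y[i] / pixel_size);
    for (int dr = -half; dr <= half; ++dr) {
      int r = pr + dr;
      double py = (r + 0.5) * pixel_size;
      r = ((r % npix) + npix) % npix;
      for (int dc = -half; dc <= half; ++dc) {
        int col = pc + dc;
        double px = (col + 0.5) * pixel_size;
        col = ((col % npix) + npix) % npix;
        double ddx = min_image(px - x[i], box_side);
        double ddy = min_image(py - y[i], box_side);
        double u = c * ddx + s * ddy;   // along the cell axis
        double v = -s * ddx + c * ddy;  // across
        // flat-top (super-Gaussian) anisotropic kernel: sharp cell edges so
        // the thresholded footprint is insensitive to the exact threshold
        double q = u * u / (sigma_l * sigma_l) + v * v / (sigma_w * sigma_w);
        double val = amp[i] * std::exp(-0.5 * q * q * q);
        if (val > img(r, col)) img(r, col) = val;
      }
    }
  }
  return img;
}

// Binary footprint mask: oriented ellipses with semi-axes (L/2 + m, W/2 + m)
// for the selected agents (m = dilation margin).
// [[Rcpp::export(name = ".render_mask_cpp")]]
LogicalMatrix render_mask_cpp(NumericVector x, NumericVector y,
                              NumericVector heading, LogicalVector keep,
                              int npix, double pixel_size, double box_side,
                              double semi_l, double semi_w) {
  LogicalMatrix msk(npix, npix);
  int half = (int)std::ceil(semi_l / pixel_size) + 1;
  for (int i = 0; i < x.size(); ++i) {
    if (!keep[i]) continue;
    double c = std::cos(heading[i]), s = std::sin(heading[i]);
    int pc = (int)std::floor(x[i] / pixel_size);
    int pr = (int)std::floor(y[i] / pixel_size);
    for (int dr = -half; dr <= half; ++dr) {
      int r = pr + dr;
      double py = (r + 0.5) * pixel_size;
      r = ((r % npix) + npix) % npix;
      for (int dc = -half; dc <= half; ++dc) {
        int col = pc + dc;
        double px = (col + 0.5) * pixel_size;
        col = ((col % npix) + npix) % npix;
        double ddx = min_image(px - x[i], box_side);
        double ddy = min_image(py - y[i], box_side);
        double u = c * ddx + s * ddy, v = -s * ddx + c * ddy;
        if (u * u / (semi_l * semi_l) + v * v / (semi_w * semi_w) <= 1.0)
          msk(r, col) = true;
      }
    }
  }
  return msk;
}

// 8-connected component labeling of a logical matrix (BFS flood fill).
// Returns an integer matrix of labels (0 = background), labels 1..K.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      q.push({r0, c0});
      while (!q.empty()) {
        auto [r, c] = q.front();
        q.pop();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push({rr, cc});
            }
          }
      }
    }
  return lab;
}

// For each agent and frame, TRUE when no non-motile agent lies within
// `clearance` (used to select freely swarming track segments).
// [[Rcpp::export(name = ".clearance_cpp")]]
LogicalMatrix clearance_cpp(NumericVector x, NumericVector y,
                            IntegerVector state, int n, int nf,
                            double box_side, double clearance) {
  LogicalMatrix clear(n, nf);
  double r2 = clearance * clearance;
  for (int f = 0; f < nf; ++f) {
    CellList cl(box_side, std::max(clearance, box_side / 64.0));
    std::vector<double> xf(n), yf(n);
    std::vector<int> st(n);
    for (int i = 0; i < n; ++i) {
      xf[i] = x[(size_t)f * n + i];
      yf[i] = y[(size_t)f * n + i];
      st[i] = state[(size_t)f * n + i];
    }
    cl.build(xf, yf);
    for (int i = 0; i < n; ++i) {
      bool ok = true;
      cl.neighbors(xf[i], yf[i], [&](int j) {
        if (!ok || j == i || st[j] == MOTILE) return;
        double ddx = min_image(xf[j] - xf[i], box_side);
        double ddy = min_image(yf[j] - yf[i], box_side);
        if (ddx * ddx + ddy * ddy <= r2) ok = false;
      });
      clear(i, f) = ok;
    }
  }
  return clear;
}
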