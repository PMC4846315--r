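// Core evaluation kernels for the ring-of-quadrilaterals model:
// tension + cavity + contact energy with analytic gradient, and the
// area-constraint residuals/Jacobian products used by the constrained
// minimizer.  Layout of the flat coordinate vector x (length 4n):
// (apical x, apical y, basal x, basal y).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double cav_U(double r, double rv, double p0) {
  if (r < rv) return 0.0;
  double s = (r - rv) / rv;
  return p0 * rv * (std::exp(s) - 1.0) - p0 * (r - rv);
}
static inline double cav_p(double r, double rv, double p0) {
  if (r < rv) return 0.0;
  return p0 * (std::exp((r - rv) / rv) - 1.0);
}

// [[Rcpp::export(name = ".energy_core_cpp")]]
List energy_core_cpp(NumericVector x, int n,
                     NumericVector Ga, NumericVector Gb, NumericVector Gl,
                     bool has_cavity, double rv, double p0,
                     bool has_contact, double range, double kc,
                     double hinge, double hinge_margin,
                     double max_ext, double max_edge, double ext_k,
                     bool want_grad) {
  const double *ax = &x[0], *ay = &x[n], *bx = &x[2 * n], *by = &x[3 * n];
  std::vector<double> gax(n, 0.0), gay(n, 0.0), gbx(n, 0.0), gby(n, 0.0);
  double W = 0.0;

  std::vector<double> La(n), Hax(n), Hay(n);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double dx = ax[j] - ax[i], dy = ay[j] - ay[i];
    double L = std::sqrt(dx * dx + dy * dy);
    La[i] = L; Hax[i] = dx / L; Hay[i] = dy / L;
    W += Ga[i] * L;
    double dWdL = Ga[i];
    if (has_contact && ext_k > 0.0 && L > max_edge) {
      W += 0.5 * ext_k * (L - max_edge) * (L - max_edge);
      dWdL += ext_k * (L - max_edge);
    }
    if (want_grad) {
      gax[i] -= dWdL * Hax[i]; gay[i] -= dWdL * Hay[i];
      gax[j] += dWdL * Hax[i]; gay[j] += dWdL * Hay[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double dx = bx[j] - bx[i], dy = by[j] - by[i];
    double L = std::sqrt(dx * dx + dy * dy);
    W += Gb[i] * L;
    double dWdL = Gb[i];
    if (has_contact && ext_k > 0.0 && L > max_edge) {
      W += 0.5 * ext_k * (L - max_edge) * (L - max_edge);
      dWdL += ext_k * (L - max_edge);
    }
    if (want_grad) {
      double hx = dx / L, hy = dy / L;
      gbx[i] -= dWdL * hx; gby[i] -= dWdL * hy;
      gbx[j] += dWdL * hx; gby[j] += dWdL * hy;
    }
  }
  // lateral edge i joins apical i and basal i, shared by cells i-1, i;
  // the extension ceiling (one-sided quadratic above max_ext) rides on
  // the same edges
  for (int i = 0; i < n; ++i) {
    int p = (i + n - 1) % n;
    double w = 0.5 * (Gl[i] + Gl[p]);
    double dx = ax[i] - bx[i], dy = ay[i] - by[i];
    double L = std::sqrt(dx * dx + dy * dy);
    W += w * L;
    double dWdL = w;
    if (has_contact && ext_k > 0.0 && L > max_ext) {
      W += 0.5 * ext_k * (L - max_ext) * (L - max_ext);
      dWdL += ext_k * (L - max_ext);
    }
    if (want_grad) {
      double hx = dx / L, hy = dy / L;
      gax[i] += dWdL * hx; gay[i] += dWdL * hy;
      gbx[i] -= dWdL * hx; gby[i] -= dWdL * hy;
    }
  }

  // vitelline wall: Simpson sampling (vertex, midpoint, vertex) per edge
  if (has_cavity) {
    std::vector<double> rva(n), Uv(n);
    for (int i = 0; i < n; ++i) {
      rva[i] = std::sqrt(ax[i] * ax[i] + ay[i] * ay[i]);
      Uv[i] = cav_U(rva[i], rv, p0);
    }
    std::vector<double> wv(n, 0.0);
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double mx = 0.5 * (ax[i] + ax[j]), my = 0.5 * (ay[i] + ay[j]);
      double rm = std::sqrt(mx * mx + my * my);
      double Um = cav_U(rm, rv, p0);
      double Uavg = (Uv[i] + 4.0 * Um + Uv[j]) / 6.0;
      if (Uavg > 0.0) {
        W += La[i] * Uavg;
        if (want_grad) {
          gax[i] -= Uavg * Hax[i]; gay[i] -= Uavg * Hay[i];
          gax[j] += Uavg * Hax[i]; gay[j] += Uavg * Hay[i];
          double pm = cav_p(rm, rv, p0);
          if (pm > 0.0) {
            double c = (4.0 / 6.0) * La[i] * pm / rm * 0.5;
            gax[i] += c * mx; gay[i] += c * my;
            gax[j] += c * mx; gay[j] += c * my;
          }
        }
      }
      if (want_grad) { wv[i] += La[i] / 6.0; wv[j] += La[i] / 6.0; }
    }
    if (want_grad) {
      for (int i = 0; i < n; ++i) {
        double pv = cav_p(rva[i], rv, p0);
        if (pv > 0.0) {
          double c = wv[i] * pv / rva[i];
          gax[i] += c * ax[i]; gay[i] += c * ay[i];
        }
      }
    }
  }

  // short-range contact repulsion between non-adjacent apical points
  // (vertices + edge midpoints, chain-ordered v1 m1 v2 m2 ...)
  if (has_contact && kc > 0.0 && range > 0.0) {
    int m = 2 * n;
    std::vector<double> px(m), py(m);
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      px[2 * i] = ax[i]; py[2 * i] = ay[i];
      px[2 * i + 1] = 0.5 * (ax[i] + ax[j]);
      py[2 * i + 1] = 0.5 * (ay[i] + ay[j]);
    }
    std::vector<double> gpx(m, 0.0), gpy(m, 0.0);
    double r2 = range * range;
    for (int i = 0; i < m; ++i) {
      for (int j = i + 1; j < m; ++j) {
        int dpos = j - i; if (m - dpos < dpos) dpos = m - dpos;
        if (dpos < 2) continue;  // a vertex and its own edge midpoint
        double dx = px[i] - px[j];
        if (dx > range || dx < -range) continue;
        double dy = py[i] - py[j];
        if (dy > range || dy < -range) continue;
        double d2 = dx * dx + dy * dy;
        if (d2 >= r2) continue;
        double d = std::sqrt(d2 > 1e-300 ? d2 : 1e-300);
        double gap = range - d;
        W += 0.5 * kc * gap * gap;
        if (want_grad) {
          double f = -kc * gap / d;
          gpx[i] += f * dx; gpy[i] += f * dy;
          gpx[j] -= f * dx; gpy[j] -= f * dy;
        }
      }
    }
    if (want_grad) {
      for (int i = 0; i < n; ++i) {
        int j = (i + 1) % n;
        gax[i] += gpx[2 * i] + 0.5 * gpx[2 * i + 1];
        gay[i] += gpy[2 * i] + 0.5 * gpy[2 * i + 1];
        gax[j] += 0.5 * gpx[2 * i + 1];
        gay[j] += 0.5 * gpy[2 * i + 1];
      }
    }
  }

  // one-sided corner-unfolding guard: signed area of the four corner
  // triangles of quad (a_i, a_j, b_j, b_i) must stay above the margin
  if (has_contact && hinge > 0.0) {
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double qx[4] = { bx[i], ax[i], ax[j], bx[j] };
      double qy[4] = { by[i], ay[i], ay[j], by[j] };
      // index map back to gradient arrays
      double *gx[4] = { &gbx[i], &gax[i], &gax[j], &gbx[j] };
      double *gy[4] = { &gby[i], &gay[i], &gay[j], &gby[j] };
      for (int c = 0; c < 4; ++c) {
        int c2 = (c + 1) % 4, c3 = (c + 2) % 4;
        double T = (qx[c2] - qx[c]) * (qy[c3] - qy[c2]) -
                   (qy[c2] - qy[c]) * (qx[c3] - qx[c2]);
        double h = T - hinge_margin;
        if (h < 0.0) {
          W += 0.5 * hinge * h * h;
          if (want_grad) {
            double kh = hinge * h;
            *gx[c]  += kh * (qy[c2] - qy[c3]);
            *gy[c]  += kh * (qx[c3] - qx[c2]);
            *gx[c2] += kh * (qy[c3] - qy[c]);
            *gy[c2] += kh * (qx[c] - qx[c3]);
            *gx[c3] += kh * (qy[c] - qy[c2]);
            *gy[c3] += kh * (qx[c2] - qx[c]);
          }
        }
      }
    }
  }

  if (!want_grad) return List::create(Named("W") = W, Named("grad") = R_NilValue);
  NumericVector grad(4 * n);
  for (int i = 0; i < n; ++i) {
    grad[i] = gax[i]; grad[n + i] = gay[i];
    grad[2 * n + i] = gbx[i]; grad[3 * n + i] = gby[i];
  }
  return List::create(Named("W") = W, Named("grad") = grad);
}

// [[Rcpp::export(name = ".area_residuals_cpp")]]
NumericVector area_residuals_cpp(NumericVector x, int n,
                                 double a_c, double a_y) {
  const double *ax = &x[0], *ay = &x[n], *bx = &x[2 * n], *by = &x[3 * n];
  NumericVector out(n + 1);
  double yolk = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double A = 0.5 * ((ax[i] * ay[j] - ax[j] * ay[i]) +
                      (ax[j] * by[j] - bx[j] * ay[j]) +
                      (bx[j] * by[i] - bx[i] * by[j]) +
                      (bx[i] * ay[i] - ax[i] * by[i]));
    out[i] = A - a_c;
    yolk += bx[i] * by[j] - bx[j] * by[i];
  }
  out[n] = 0.5 * yolk - a_y;
  return out;
}

// gradient of sum_i t[i] * A_cell_i + t_yolk * A_yolk
// [[Rcpp::export(name = ".area_weighted_grad_cpp")]]
NumericVector area_weighted_grad_cpp(NumericVector x, int n,
                                     NumericVector t_cells, double t_yolk) {
  const double *ax = &x[0], *ay = &x[n], *bx = &x[2 * n], *by = &x[3 * n];
  NumericVector g(4 * n);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n, p = (i + n - 1) % n;
    double ti = t_cells[i], tp = t_cells[p];
    g[i]         = 0.5 * (ti * (ay[j] - by[i]) + tp * (by[i] - ay[p]));
    g[n + i]     = 0.5 * (ti * (bx[i] - ax[j]) + tp * (ax[p] - bx[i]));
    g[2 * n + i] = 0.5 * (ti * (ay[i] - by[j]) + tp * (by[p] - ay[i])) +
                   0.5 * t_yolk * (by[j] - by[p]);
    g[3 * n + i] = 0.5 * (ti * (bx[j] - ax[i]) + tp * (ax[i] - bx[p])) +
                   0.5 * t_yolk * (bx[p] - bx[j]);
  }
  return g;
}
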