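// Clough-Tocher C1 piecewise-cubic interpolation on a triangulation.
//
// Each macro triangle is split at its centroid into three cubic
// Bernstein-Bezier mini patches.  Vertex values and estimated vertex
// gradients fix the outer control net; the cross-edge control points are
// condensed by forcing the transversal (edge-normal) derivative to vary
// linearly along each macro edge; the remaining interior ordinates follow
// from the C1 conditions across the internal edges of the split.
// The resulting interpolant is C1, reproduces quadratics when the vertex
// gradients are exact, and never extrapolates outside the triangulation.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
using namespace Rcpp;

// ---- small dense solver (normal equations, partial pivoting) -------------
static bool solve_sym(int n, double *A, double *b) {
  // A is n x n row-major, overwritten; b overwritten with solution
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double amax = std::fabs(A[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(A[r * n + col]);
      if (v > amax) { amax = v; piv = r; }
    }
    if (amax < 1e-12) return false;
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(A[col * n + c], A[piv * n + c]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < n; ++r) {
      double f = A[r * n + col] / A[col * n + col];
      for (int c = col; c < n; ++c) A[r * n + c] -= f * A[col * n + c];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < n; ++c) s -= A[r * n + c] * b[c];
    b[r] = s / A[r * n + r];
  }
  return true;
}

// Weighted least-squares gradient at one node from neighbour offsets.
// Fits z - z0 ~ gx*dx + gy*dy (+ quadratic terms when enough neighbours).
static void lsq_gradient(const std::vector<double> &dx,
                         const std::vector<double> &dy,
                         const std::vector<double> &dz,
                         double *gx, double *gy) {
  int m = (int)dx.size();
  *gx = 0.0; *gy = 0.0;
  if (m < 2) return;
  int p = (m >= 5) ? 5 : 2;  // quadratic fit when determined
  double A[25] = {0.0}, b[5] = {0.0};
  for (int i = 0; i < m; ++i) {
    double d2 = dx[i] * dx[i] + dy[i] * dy[i];
    if (d2 <= 0) continue;
    double w = 1.0 / d2;  // inverse squared-distance weights
    double phi[5] = {dx[i], dy[i], 0.5 * dx[i] * dx[i], dx[i] * dy[i],
                     0.5 * dy[i] * dy[i]};
    for (int r = 0; r < p; ++r) {
      for (int c = 0; c < p; ++c) A[r * p + c] += w * phi[r] * phi[c];
      b[r] += w * phi[r] * dz[i];
    }
  }
  if (!solve_sym(p, A, b)) {
    if (p == 5) {  // retry linear
      double A2[4] = {0.0}, b2[2] = {0.0};
      for (int i = 0; i < m; ++i) {
        double d2 = dx[i] * dx[i] + dy[i] * dy[i];
        if (d2 <= 0) continue;
        double w = 1.0 / d2;
        A2[0] += w * dx[i] * dx[i]; A2[1] += w * dx[i] * dy[i];
        A2[2] += w * dx[i] * dy[i]; A2[3] += w * dy[i] * dy[i];
        b2[0] += w * dx[i] * dz[i]; b2[1] += w * dy[i] * dz[i];
      }
      if (solve_sym(2, A2, b2)) { *gx = b2[0]; *gy = b2[1]; }
    }
    return;
  }
  *gx = b[0]; *gy = b[1];
}

// [[Rcpp::export]]
NumericMatrix ct_gradients(NumericVector px, NumericVector py,
                           NumericVector pz, IntegerMatrix tri) {
  int n = px.size(), nt = tri.nrow();
  // adjacency (1-ring) from triangle edges
  std::vector< std::set<int> > adj(n);
  for (int t = 0; t < nt; ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    adj[a].insert(b); adj[a].insert(c);
    adj[b].insert(a); adj[b].insert(c);
    adj[c].insert(a); adj[c].insert(b);
  }
  NumericMatrix g(n, 2);
  std::vector<double> dx, dy, dz;
  for (int i = 0; i < n; ++i) {
    dx.clear(); dy.clear(); dz.clear();
    std::set<int> nb = adj[i];
    if ((int)nb.size() < 5) {  // expand to 2-ring for boundary nodes
      std::set<int> ext = nb;
      for (std::set<int>::iterator it = nb.begin(); it != nb.end(); ++it)
        ext.insert(adj[*it].begin(), adj[*it].end());
      ext.erase(i);
      nb = ext;
    }
    for (std::set<int>::iterator it = nb.begin(); it != nb.end(); ++it) {
      dx.push_back(px[*it] - px[i]);
      dy.push_back(py[*it] - py[i]);
      dz.push_back(pz[*it] - pz[i]);
    }
    double gx, gy;
    lsq_gradient(dx, dy, dz, &gx, &gy);
    g(i, 0) = gx; g(i, 1) = gy;
  }
  return g;
}

// ---- point location: uniform bucket grid over triangle bboxes ------------
struct BucketGrid {
  double x0, y0, dx, dy;
  int nx, ny;
  std::vector< std::vector<int> > cells;
};

static void build_buckets(const NumericVector &px, const NumericVector &py,
                          const IntegerMatrix &tri, BucketGrid &bg) {
  int nt = tri.nrow();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < px.size(); ++i) {
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  int nside = (int)std::ceil(std::sqrt((double)std::max(nt, 1)));
  bg.nx = std::max(1, nside); bg.ny = std::max(1, nside);
  bg.x0 = xmin; bg.y0 = ymin;
  bg.dx = (xmax - xmin) / bg.nx; bg.dy = (ymax - ymin) / bg.ny;
  if (bg.dx <= 0) bg.dx = 1.0;
  if (bg.dy <= 0) bg.dy = 1.0;
  bg.cells.assign((size_t)bg.nx * bg.ny, std::vector<int>());
  for (int t = 0; t < nt; ++t) {
    double tx[3], ty[3];
    for (int k = 0; k < 3; ++k) {
      tx[k] = px[tri(t, k) - 1]; ty[k] = py[tri(t, k) - 1];
    }
    double bx0 = std::min(tx[0], std::min(tx[1], tx[2]));
    double bx1 = std::max(tx[0], std::max(tx[1], tx[2]));
    double by0 = std::min(ty[0], std::min(ty[1], ty[2]));
    double by1 = std::max(ty[0], std::max(ty[1], ty[2]));
    int ix0 = std::max(0, std::min(bg.nx - 1, (int)((bx0 - bg.x0) / bg.dx)));
    int ix1 = std::max(0, std::min(bg.nx - 1, (int)((bx1 - bg.x0) / bg.dx)));
    int iy0 = std::max(0, std::min(bg.ny - 1, (int)((by0 - bg.y0) / bg.dy)));
    int iy1 = std::max(0, std::min(bg.ny - 1, (int)((by1 - bg.y0) / bg.dy)));
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        bg.cells[(size_t)iy * bg.nx + ix].push_back(t);
  }
}

// Clough-Tocher evaluation inside one macro triangle.
// v: vertex coords (3x2), f: values, g: gradients (3x2), l: barycentric.
static double ct_tri_eval(const double vx[3], const double vy[3],
                          const double f[3], const double gx[3],
                          const double gy[3], const double lam[3]) {
  double cx = (vx[0] + vx[1] + vx[2]) / 3.0;
  double cy = (vy[0] + vy[1] + vy[2]) / 3.0;
  // macro edge control points e[i][j]: near vertex i along edge i->j
  double e[3][3], q[3];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      if (i == j) continue;
      e[i][j] = f[i] + (gx[i] * (vx[j] - vx[i]) + gy[i] * (vy[j] - vy[i])) / 3.0;
    }
    q[i] = f[i] + (gx[i] * (cx - vx[i]) + gy[i] * (cy - vy[i])) / 3.0;
  }
  // interior ordinate w[i] of mini patch on macro edge (i, i+1)
  double w[3];
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3;
    // mini triangle (Vi, Vj, C); barycentric gradients of that triangle
    double ax = vx[i], ay = vy[i], bx = vx[j], by = vy[j];
    double det = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    // grad lambda_1 (at Vi), lambda_2 (Vj), lambda_3 (C)
    double g1x = (by - cy) / det, g1y = (cx - bx) / det;
    double g2x = (cy - ay) / det, g2y = (ax - cx) / det;
    double g3x = (ay - by) / det, g3y = (bx - ax) / det;
    // transversal direction: normal to edge Vi-Vj
    double ex = bx - ax, ey = by - ay;
    double nxv = -ey, nyv = ex;
    double d1 = g1x * nxv + g1y * nyv;
    double d2 = g2x * nxv + g2y * nyv;
    double d3 = g3x * nxv + g3y * nyv;
    double E1 = d1 * f[i] + d2 * e[i][j] + d3 * q[i];
    double E2 = d1 * e[j][i] + d2 * f[j] + d3 * q[j];
    w[i] = (0.5 * (E1 + E2) - d1 * e[i][j] - d2 * e[j][i]) / d3;
  }
  double f0 = (2.0 * (w[0] + w[1] + w[2]) + q[0] + q[1] + q[2]) / 9.0;
  // locate mini triangle: the one opposite the smallest barycentric coord
  int k = 0;  // index with smallest lambda
  if (lam[1] < lam[k]) k = 1;
  if (lam[2] < lam[k]) k = 2;
  int i = (k + 1) % 3, j = (k + 2) % 3;  // mini (Vi, Vj, C) on edge (i, j)
  // Bezier ordinates of mini patch (Vi, Vj, C):
  double b300 = f[i], b030 = f[j], b003 = f0;
  double b210 = e[i][j], b120 = e[j][i];
  double b201 = q[i], b021 = q[j];
  double b111 = w[i];
  // second-ring ordinates via C1 conditions with adjacent mini patches
  double b102 = (w[i] + w[k] + q[i]) / 3.0;  // edge Vi-C, shared with mini (k, i)
  double b012 = (w[i] + w[j] + q[j]) / 3.0;  // edge Vj-C, shared with mini (j, k)
  // barycentric coords within the mini triangle
  double ax = vx[i], ay = vy[i], bx = vx[j], by = vy[j];
  double det = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
  // point from macro barycentric
  double qxp = lam[0] * vx[0] + lam[1] * vx[1] + lam[2] * vx[2];
  double qyp = lam[0] * vy[0] + lam[1] * vy[1] + lam[2] * vy[2];
  double u = ((bx - qxp) * (cy - qyp) - (cx - qxp) * (by - qyp)) / det;
  double v = ((cx - qxp) * (ay - qyp) - (ax - qxp) * (cy - qyp)) / det;
  double t = 1.0 - u - v;
  // cubic Bernstein expansion
  double u2 = u * u, v2 = v * v, t2 = t * t;
  return b300 * u2 * u + b030 * v2 * v + b003 * t2 * t +
         3.0 * (b210 * u2 * v + b120 * u * v2 +
                b201 * u2 * t + b021 * v2 * t +
                b102 * u * t2 + b012 * v * t2) +
         6.0 * b111 * u * v * t;
}

// [[Rcpp::export]]
NumericVector ct_evaluate(NumericVector px, NumericVector py,
                          NumericVector pz, IntegerMatrix tri,
                          NumericMatrix grad,
                          NumericVector qx, NumericVector qy) {
  int nq = qx.size();
  NumericVector out(nq, NA_REAL);
  if (tri.nrow() == 0) return out;
  BucketGrid bg;
  build_buckets(px, py, tri, bg);
  const double tol = -1e-9;
  for (int s = 0; s < nq; ++s) {
    double X = qx[s], Y = qy[s];
    if (!R_finite(X) || !R_finite(Y)) continue;
    int ix = (int)((X - bg.x0) / bg.dx), iy = (int)((Y - bg.y0) / bg.dy);
    if (ix < -1 || iy < -1 || ix > bg.nx || iy > bg.ny) continue;
    ix = std::max(0, std::min(bg.nx - 1, ix));
    iy = std::max(0, std::min(bg.ny - 1, iy));
    const std::vector<int> &cand = bg.cells[(size_t)iy * bg.nx + ix];
    for (size_t c = 0; c < cand.size(); ++c) {
      int t = cand[c];
      double vx[3], vy[3], f[3], gx[3], gy[3];
      for (int k = 0; k < 3; ++k) {
        int id = tri(t, k) - 1;
        vx[k] = px[id]; vy[k] = py[id]; f[k] = pz[id];
        gx[k] = grad(id, 0); gy[k] = grad(id, 1);
      }
      double det = (vx[1] - vx[0]) * (vy[2] - vy[0]) -
                   (vx[2] - vx[0]) * (vy[1] - vy[0]);
      if (det == 0.0) continue;
      double l1 = ((vx[1] - X) * (vy[2] - Y) - (vx[2] - X) * (vy[1] - Y)) / det;
      double l2 = ((vx[2] - X) * (vy[0] - Y) - (vx[0] - X) * (vy[2] - Y)) / det;
      double l3 = 1.0 - l1 - l2;
      if (l1 < tol || l2 < tol || l3 < tol) continue;
      double lam[3] = {l1, l2, l3};
      out[s] = ct_tri_eval(vx, vy, f, gx, gy, lam);
      break;
    }
  }
  return out;
}
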