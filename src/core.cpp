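// Numerical core: trilinear sampling, displacement-field algebra, Gaussian-
// mixture-field L2 energy with PPD reorientation, NNLS estimation, SPD(3)
// manifold operations, and the permutation Hotelling test.
//
// Conventions: 3D volumes are flattened column-major, voxel (i,j,k) at index
// i + nx*(j + ny*k); positions are 0-based voxel coordinates; displacement
// fields are V x 3 in voxel units; per-voxel 3x3 Jacobians are stored as
// V x 9 with J(r,c) in column 3*c + r.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INV_2PI_32 = 0.0634936359342409697857633; // (2*pi)^(-3/2)

// ---------------------------------------------------------------------------
// trilinear sampling
// ---------------------------------------------------------------------------

// Gather the 8 neighbour indices and weights for position (x,y,z).
// mode 0: zero outside the grid (images); mode 1: clamp to edge (fields).
static inline int trilinear_setup(double x, double y, double z,
                                  int nx, int ny, int nz, int mode,
                                  int *idx, double *wt) {
  if (mode == 1) {
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  } else {
    if (x < -1 || x > nx || y < -1 || y > ny || z < -1 || z > nz) return 0;
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int n = 0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk; if (k < 0 || k >= nz) continue;
    double wz = dk ? fz : 1.0 - fz; if (wz == 0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj; if (j < 0 || j >= ny) continue;
      double wy = dj ? fy : 1.0 - fy; if (wy == 0) continue;
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di; if (i < 0 || i >= nx) continue;
        double wx = di ? fx : 1.0 - fx; if (wx == 0) continue;
        idx[n] = i + nx * (j + ny * k);
        wt[n]  = wx * wy * wz;
        ++n;
      }
    }
  }
  return n;
}

// [[Rcpp::export]]
arma::mat cpp_sample_field(const arma::mat& field, IntegerVector dims,
                           const arma::mat& pts, int mode) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int M = pts.n_rows, C = field.n_cols;
  arma::mat out(M, C, arma::fill::zeros);
  int idx[8]; double wt[8];
  for (int m = 0; m < M; ++m) {
    int n = trilinear_setup(pts(m, 0), pts(m, 1), pts(m, 2), nx, ny, nz,
                            mode, idx, wt);
    for (int t = 0; t < n; ++t)
      for (int c = 0; c < C; ++c)
        out(m, c) += wt[t] * field(idx[t], c);
  }
  return out;
}

// out(x) = v(x) + d(x + v(x)); compositive update of displacement fields.
// [[Rcpp::export]]
arma::mat cpp_compose_disp(const arma::mat& v, const arma::mat& d,
                           IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz;
  arma::mat out(V, 3);
  int idx[8]; double wt[8];
  for (int k = 0, vox = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++vox) {
        double px = i + v(vox, 0), py = j + v(vox, 1), pz = k + v(vox, 2);
        int n = trilinear_setup(px, py, pz, nx, ny, nz, 1, idx, wt);
        double dx = 0, dy = 0, dz = 0;
        for (int t = 0; t < n; ++t) {
          dx += wt[t] * d(idx[t], 0);
          dy += wt[t] * d(idx[t], 1);
          dz += wt[t] * d(idx[t], 2);
        }
        out(vox, 0) = v(vox, 0) + dx;
        out(vox, 1) = v(vox, 1) + dy;
        out(vox, 2) = v(vox, 2) + dz;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Jacobians
// ---------------------------------------------------------------------------

// J = I + grad d; central differences in the interior, one-sided at faces.
// [[Rcpp::export]]
arma::mat cpp_jacobian(const arma::mat& d, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz;
  arma::mat J(V, 9);
  int strides[3] = {1, nx, nx * ny};
  int nmax[3] = {nx, ny, nz};
  for (int k = 0, vox = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++vox) {
        int pos[3] = {i, j, k};
        for (int ax = 0; ax < 3; ++ax) { // derivative direction (column)
          int lo = vox, hi = vox; double h = 0.0;
          if (pos[ax] > 0)            { lo -= strides[ax]; h += 1.0; }
          if (pos[ax] < nmax[ax] - 1) { hi += strides[ax]; h += 1.0; }
          for (int r = 0; r < 3; ++r) {
            double g = (h > 0) ? (d(hi, r) - d(lo, r)) / h : 0.0;
            J(vox, 3 * ax + r) = g + (r == ax ? 1.0 : 0.0);
          }
        }
      }
  return J;
}

// [[Rcpp::export]]
arma::vec cpp_det3(const arma::mat& J) {
  int V = J.n_rows;
  arma::vec out(V);
  for (int v = 0; v < V; ++v) {
    const double a = J(v,0), d0 = J(v,1), g = J(v,2);
    const double b = J(v,3), e = J(v,4), h = J(v,5);
    const double c = J(v,6), f = J(v,7), i = J(v,8);
    out(v) = a*(e*i - f*h) - b*(d0*i - f*g) + c*(d0*h - e*g);
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing (truncated kernel, renormalised at edges)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_smooth3(const arma::mat& field, IntegerVector dims, double sigma) {
  if (sigma <= 0) return field;
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int C = field.n_cols;
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t)
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
  arma::mat cur = field, nxt(field.n_rows, C);
  int n3[3] = {nx, ny, nz};
  int strides[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    for (int k = 0, vox = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++vox) {
          int pos[3] = {i, j, k};
          double wsum = 0;
          for (int c = 0; c < C; ++c) nxt(vox, c) = 0;
          for (int t = -rad; t <= rad; ++t) {
            int p = pos[ax] + t;
            if (p < 0 || p >= n3[ax]) continue;
            double w = ker[t + rad];
            wsum += w;
            int src = vox + t * strides[ax];
            for (int c = 0; c < C; ++c) nxt(vox, c) += w * cur(src, c);
          }
          for (int c = 0; c < C; ++c) nxt(vox, c) /= wsum;
        }
    cur = nxt;
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Gaussian mixture field energy
// ---------------------------------------------------------------------------
// Every mixture component has covariance C_k = p_k I + q_k u_k u_k', the
// 2*tau-scaled dictionary tensor (axially symmetric), so the Gaussian product
// kernel c(C_i, C_j) = (2pi)^{-3/2} det(C_i + C_j)^{-1/2} has the closed form
//   det = g (g^2 + (qi+qj) g + qi qj (1 - (ui.uj)^2)),  g = pi + pj.
// PPD reorientation of an axially symmetric component by Jacobian F maps its
// axis u to F u / |F u| and preserves the eigenvalues.

static inline double gm_kernel(double pi_, double qi, const double *ui,
                               double pj, double qj, const double *uj) {
  double g = pi_ + pj;
  double c = ui[0] * uj[0] + ui[1] * uj[1] + ui[2] * uj[2];
  double det = g * (g * g + (qi + qj) * g + qi * qj * (1.0 - c * c));
  return INV_2PI_32 / std::sqrt(det);
}

struct GmCtx {
  const arma::mat *axesF, *axesM;   // 3 x K unit axes
  const arma::vec *p, *q;           // covariance eigenvalue parameters
  int K;
};

// self term sum_{ij} w_i w_j c(C_i, C_j) over support, axes given per atom
static double self_term(const double *w, const int *sup, int ns,
                        const double *ax, const GmCtx& ctx) {
  double s = 0;
  const arma::vec& p = *ctx.p; const arma::vec& q = *ctx.q;
  for (int a = 0; a < ns; ++a) {
    int i = sup[a];
    const double *ui = ax + 3 * i;
    s += w[i] * w[i] * gm_kernel(p(i), q(i), ui, p(i), q(i), ui);
    for (int b = a + 1; b < ns; ++b) {
      int j = sup[b];
      s += 2.0 * w[i] * w[j] * gm_kernel(p(i), q(i), ui, p(j), q(j), ax + 3 * j);
    }
  }
  return s;
}

static double cross_term(const double *wa, const int *supa, int na,
                         const double *axa,
                         const double *wb, const int *supb, int nb,
                         const double *axb, const GmCtx& ctx) {
  double s = 0;
  const arma::vec& p = *ctx.p; const arma::vec& q = *ctx.q;
  for (int a = 0; a < na; ++a) {
    int i = supa[a];
    for (int b = 0; b < nb; ++b) {
      int j = supb[b];
      s += wa[i] * wb[j] *
           gm_kernel(p(i), q(i), axa + 3 * i, p(j), q(j), axb + 3 * j);
    }
  }
  return s;
}

// Squared L2 distance field between a fixed GMF and a moving GMF warped by
// displacement disp and PPD-reoriented by the per-voxel Jacobian Jv; with
// optional central finite-difference gradient w.r.t. the displacement.
// [[Rcpp::export]]
List cpp_gmf_energy(const arma::mat& Wf, const arma::mat& Wm,
                    IntegerVector dims,
                    const arma::mat& axesF, const arma::mat& axesM,
                    const arma::vec& p, const arma::vec& q,
                    const arma::mat& disp, const arma::mat& Jv,
                    double h, bool want_grad, bool snap = true) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz, K = Wf.n_cols;
  GmCtx ctx; ctx.axesF = &axesF; ctx.axesM = &axesM;
  ctx.p = &p; ctx.q = &q; ctx.K = K;
  arma::vec d2(V, arma::fill::zeros);
  arma::mat grad;
  if (want_grad) grad.zeros(V, 3);

  std::vector<double> wf(K), wb(K), axr(3 * K);
  std::vector<int> supF(K), supB(K);
  std::vector<char> axdone(K);
  int idx[8]; double wt[8];
  const double eps = 1e-12;

  for (int k = 0, vox = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++vox) {
        // fixed support (same 1% relative trim as the moving side)
        int nF = 0;
        double fsum = 0.0;
        for (int a = 0; a < K; ++a) { wf[a] = Wf(vox, a); fsum += wf[a]; }
        double fthr = std::max(eps, 0.01 * fsum);
        for (int a = 0; a < K; ++a)
          if (wf[a] > fthr) supF[nF++] = a;
        // reoriented moving axes (depend only on J at this voxel)
        std::fill(axdone.begin(), axdone.end(), 0);
        const double J00 = Jv(vox,0), J10 = Jv(vox,1), J20 = Jv(vox,2);
        const double J01 = Jv(vox,3), J11 = Jv(vox,4), J21 = Jv(vox,5);
        const double J02 = Jv(vox,6), J12 = Jv(vox,7), J22 = Jv(vox,8);
        auto reorient = [&](int a) {
          if (axdone[a]) return;
          double ux = axesM(0, a), uy = axesM(1, a), uz = axesM(2, a);
          double vx = J00 * ux + J01 * uy + J02 * uz;
          double vy = J10 * ux + J11 * uy + J12 * uz;
          double vz = J20 * ux + J21 * uy + J22 * uz;
          double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
          if (nrm < 1e-12) { vx = ux; vy = uy; vz = uz; nrm = 1.0; }
          vx /= nrm; vy /= nrm; vz /= nrm;
          if (snap && q(a) != 0.0) {
            // discretized PPD: reassign to the nearest dictionary axis so
            // moving and fixed components share one orientation set
            int best = -1; double bdot = -1.0;
            for (int b = 0; b < K; ++b) {
              if (q(b) == 0.0) continue;
              double dt = std::fabs(vx * axesF(0, b) + vy * axesF(1, b) +
                                    vz * axesF(2, b));
              if (dt > bdot) { bdot = dt; best = b; }
            }
            if (best >= 0) {
              double sgn = (vx * axesF(0, best) + vy * axesF(1, best) +
                            vz * axesF(2, best)) >= 0 ? 1.0 : -1.0;
              vx = sgn * axesF(0, best); vy = sgn * axesF(1, best);
              vz = sgn * axesF(2, best);
            }
          }
          axr[3 * a] = vx; axr[3 * a + 1] = vy; axr[3 * a + 2] = vz;
          axdone[a] = 1;
        };
        double selfF = (nF > 0)
          ? self_term(wf.data(), supF.data(), nF, axesF.memptr(), ctx) : 0.0;

        double px = i + disp(vox, 0), py = j + disp(vox, 1),
               pz = k + disp(vox, 2);

        auto eval_at = [&](double x, double y, double z) -> double {
          int n = trilinear_setup(x, y, z, nx, ny, nz, 0, idx, wt);
          int nB = 0;
          std::fill(wb.begin(), wb.end(), 0.0);
          double wsum = 0.0;
          for (int t = 0; t < n; ++t)
            for (int a = 0; a < K; ++a) {
              wb[a] += wt[t] * Wm(idx[t], a);
              wsum  += wt[t] * Wm(idx[t], a);
            }
          // components below 1% of the voxel mass are negligible for the
          // distance but dominate the pair count; drop them
          double thr = std::max(eps, 0.01 * wsum);
          for (int a = 0; a < K; ++a)
            if (wb[a] > thr) { supB[nB++] = a; reorient(a); }
          double selfM = (nB > 0)
            ? self_term(wb.data(), supB.data(), nB, axr.data(), ctx) : 0.0;
          double crss = (nF > 0 && nB > 0)
            ? cross_term(wf.data(), supF.data(), nF, axesF.memptr(),
                         wb.data(), supB.data(), nB, axr.data(), ctx) : 0.0;
          return selfF + selfM - 2.0 * crss;
        };

        d2(vox) = eval_at(px, py, pz);
        if (want_grad) {
          grad(vox, 0) = (eval_at(px + h, py, pz) - eval_at(px - h, py, pz)) / (2 * h);
          grad(vox, 1) = (eval_at(px, py + h, pz) - eval_at(px, py - h, pz)) / (2 * h);
          grad(vox, 2) = (eval_at(px, py, pz + h) - eval_at(px, py, pz - h)) / (2 * h);
        }
      }
  List out = List::create(Named("d2") = d2);
  if (want_grad) out["grad"] = grad;
  return out;
}

// Warp a weight field by disp and PPD-reorient by the per-voxel Jacobian.
// snap = true reassigns each reoriented component to the nearest dictionary
// orientation (result lives on the shared dictionary); snap = false returns
// the exact per-voxel reoriented axes alongside the sampled weights.
// [[Rcpp::export]]
List cpp_warp_reorient(const arma::mat& Wm, IntegerVector dims,
                       const arma::mat& disp, const arma::mat& Jv,
                       const arma::mat& axes, const arma::vec& q,
                       bool snap) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = nx * ny * nz, K = Wm.n_cols;
  arma::mat Wout(V, K, arma::fill::zeros);
  arma::mat axout;
  if (!snap) axout.set_size(V, 3 * K);
  int idx[8]; double wt[8];
  const double eps = 1e-12;
  for (int k = 0, vox = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++vox) {
        double px = i + disp(vox, 0), py = j + disp(vox, 1),
               pz = k + disp(vox, 2);
        int n = trilinear_setup(px, py, pz, nx, ny, nz, 0, idx, wt);
        std::vector<double> wb(K, 0.0);
        for (int t = 0; t < n; ++t)
          for (int a = 0; a < K; ++a) wb[a] += wt[t] * Wm(idx[t], a);
        const double J00 = Jv(vox,0), J10 = Jv(vox,1), J20 = Jv(vox,2);
        const double J01 = Jv(vox,3), J11 = Jv(vox,4), J21 = Jv(vox,5);
        const double J02 = Jv(vox,6), J12 = Jv(vox,7), J22 = Jv(vox,8);
        if (!snap)
          for (int a = 0; a < K; ++a) {
            axout(vox, 3 * a)     = axes(0, a);
            axout(vox, 3 * a + 1) = axes(1, a);
            axout(vox, 3 * a + 2) = axes(2, a);
          }
        for (int a = 0; a < K; ++a) {
          if (wb[a] <= eps) continue;
          if (q(a) == 0.0) { Wout(vox, a) += wb[a]; continue; } // isotropic
          double ux = axes(0, a), uy = axes(1, a), uz = axes(2, a);
          double vx = J00 * ux + J01 * uy + J02 * uz;
          double vy = J10 * ux + J11 * uy + J12 * uz;
          double vz = J20 * ux + J21 * uy + J22 * uz;
          double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
          if (nrm < 1e-12) { Wout(vox, a) += wb[a]; continue; }
          vx /= nrm; vy /= nrm; vz /= nrm;
          if (snap) {
            int best = a; double bdot = -1.0;
            for (int b = 0; b < K; ++b) {
              if (q(b) == 0.0) continue;
              double dt = std::fabs(vx * axes(0, b) + vy * axes(1, b) +
                                    vz * axes(2, b));
              if (dt > bdot) { bdot = dt; best = b; }
            }
            Wout(vox, best) += wb[a];
          } else {
            Wout(vox, a) = wb[a];
            axout(vox, 3 * a) = vx; axout(vox, 3 * a + 1) = vy;
            axout(vox, 3 * a + 2) = vz;
          }
        }
      }
  List out = List::create(Named("W") = Wout);
  if (!snap) out["axes"] = axout;
  return out;
}

// ---------------------------------------------------------------------------
// nonnegative least squares (Lawson-Hanson), ridge handled by augmentation
// ---------------------------------------------------------------------------

static arma::vec nnls_lh(const arma::mat& A, const arma::vec& b) {
  int n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> P(n, false);
  arma::vec w = A.t() * b;
  double tol = 1e-10 * (1.0 + arma::norm(b));
  int outer = 0, maxouter = 5 * n;
  while (outer++ < maxouter) {
    int t = -1; double wmax = tol;
    for (int i = 0; i < n; ++i)
      if (!P[i] && w(i) > wmax) { wmax = w(i); t = i; }
    if (t < 0) break;
    P[t] = true;
    int inner = 0;
    while (inner++ < maxouter) {
      std::vector<int> idx;
      for (int i = 0; i < n; ++i) if (P[i]) idx.push_back(i);
      arma::uvec ui(idx.size());
      for (size_t a = 0; a < idx.size(); ++a) ui(a) = idx[a];
      arma::mat Ap = A.cols(ui);
      arma::vec z;
      if (!arma::solve(z, Ap, b)) z = arma::pinv(Ap) * b;
      bool allpos = true; double alpha = 1.0;
      for (size_t a = 0; a < idx.size(); ++a)
        if (z(a) <= 0) {
          allpos = false;
          double xi = x(idx[a]);
          double aa = xi / (xi - z(a));
          if (aa < alpha) alpha = aa;
        }
      if (allpos) {
        x.zeros();
        for (size_t a = 0; a < idx.size(); ++a) x(idx[a]) = z(a);
        break;
      }
      for (size_t a = 0; a < idx.size(); ++a)
        x(idx[a]) += alpha * (z(a) - x(idx[a]));
      for (int i = 0; i < n; ++i)
        if (P[i] && x(i) <= 1e-14) { P[i] = false; x(i) = 0; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export]]
arma::vec cpp_nnls(const arma::mat& A, const arma::vec& b, double ridge) {
  if (ridge > 0) {
    int m = A.n_rows, n = A.n_cols;
    arma::mat Aa(m + n, n, arma::fill::zeros);
    Aa.rows(0, m - 1) = A;
    Aa.rows(m, m + n - 1) = std::sqrt(ridge) * arma::eye(n, n);
    arma::vec ba(m + n, arma::fill::zeros);
    ba.subvec(0, m - 1) = b;
    return nnls_lh(Aa, ba);
  }
  return nnls_lh(A, b);
}

// Columns of E are per-voxel attenuation vectors; returns K x V weights.
// [[Rcpp::export]]
arma::mat cpp_nnls_batch(const arma::mat& A, const arma::mat& E, double ridge) {
  int m = A.n_rows, n = A.n_cols, V = E.n_cols;
  arma::mat Aa;
  if (ridge > 0) {
    Aa.zeros(m + n, n);
    Aa.rows(0, m - 1) = A;
    Aa.rows(m, m + n - 1) = std::sqrt(ridge) * arma::eye(n, n);
  } else Aa = A;
  arma::mat W(n, V);
  arma::vec ba(ridge > 0 ? m + n : m, arma::fill::zeros);
  for (int v = 0; v < V; ++v) {
    ba.subvec(0, m - 1) = E.col(v);
    W.col(v) = nnls_lh(Aa, ba);
  }
  return W;
}

// ---------------------------------------------------------------------------
// SPD(3) machinery; tensors stored V x 6 in order dxx,dxy,dyy,dxz,dyz,dzz
// ---------------------------------------------------------------------------

static inline arma::mat33 unpack6(const double *t) {
  arma::mat33 M;
  M(0,0) = t[0]; M(0,1) = M(1,0) = t[1]; M(1,1) = t[2];
  M(0,2) = M(2,0) = t[3]; M(1,2) = M(2,1) = t[4]; M(2,2) = t[5];
  return M;
}

static inline void pack6(const arma::mat33& M, double *t) {
  t[0] = M(0,0); t[1] = 0.5 * (M(0,1) + M(1,0)); t[2] = M(1,1);
  t[3] = 0.5 * (M(0,2) + M(2,0)); t[4] = 0.5 * (M(1,2) + M(2,1)); t[5] = M(2,2);
}

static inline arma::mat33 spd_fun(const arma::mat33& M, double (*f)(double)) {
  arma::vec3 ev; arma::mat33 Q;
  arma::eig_sym(ev, Q, arma::symmatu(M));
  arma::vec3 fe;
  for (int i = 0; i < 3; ++i) fe(i) = f(ev(i));
  return Q * arma::diagmat(fe) * Q.t();
}

static double f_log(double x)   { return std::log(x); }
static double f_exp(double x)   { return std::exp(x); }
static double f_sqrt(double x)  { return std::sqrt(x); }
static double f_isqrt(double x) { return 1.0 / std::sqrt(x); }

// [[Rcpp::export]]
arma::mat cpp_spd_logm(const arma::mat& M) { return spd_fun(M, f_log); }
// [[Rcpp::export]]
arma::mat cpp_spd_expm(const arma::mat& M) { return spd_fun(M, f_exp); }
// [[Rcpp::export]]
arma::mat cpp_spd_sqrtm(const arma::mat& M) { return spd_fun(M, f_sqrt); }

// CDT = sqrt(J J') per voxel; returns V x 6 plus min det(J).
// [[Rcpp::export]]
List cpp_cdt_batch(const arma::mat& Jv) {
  int V = Jv.n_rows;
  arma::mat out(V, 6);
  double mindet = arma::datum::inf;
  for (int v = 0; v < V; ++v) {
    arma::mat33 J;
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) J(r, c) = Jv(v, 3 * c + r);
    double dt = arma::det(J);
    if (dt < mindet) mindet = dt;
    arma::mat33 S = spd_fun(J * J.t(), f_sqrt);
    double t[6]; pack6(S, t);
    for (int c = 0; c < 6; ++c) out(v, c) = t[c];
  }
  return List::create(Named("cdt") = out, Named("min_det") = mindet);
}

// Frechet mean per voxel of N tensors (cube V x 6 x N).
// metric 0 = affine-invariant fixed point, 1 = log-Euclidean closed form.
// [[Rcpp::export]]
List cpp_frechet_field(const arma::cube& X, double tol, int max_iter,
                       int metric) {
  int V = X.n_rows, N = X.n_slices;
  arma::mat mean(V, 6);
  arma::vec gnorm(V, arma::fill::zeros);
  arma::ivec iters(V, arma::fill::zeros);
  bool ok = true;
  for (int v = 0; v < V; ++v) {
    // log-Euclidean mean as closed form / initialisation
    arma::mat33 L(arma::fill::zeros);
    for (int s = 0; s < N; ++s) {
      double t[6]; for (int c = 0; c < 6; ++c) t[c] = X(v, c, s);
      L += spd_fun(unpack6(t), f_log);
    }
    arma::mat33 M = spd_fun(L / N, f_exp);
    if (metric == 0) {
      int it = 0;
      for (; it < max_iter; ++it) {
        arma::mat33 Mh = spd_fun(M, f_sqrt), Mih = spd_fun(M, f_isqrt);
        arma::mat33 T(arma::fill::zeros);
        for (int s = 0; s < N; ++s) {
          double t[6]; for (int c = 0; c < 6; ++c) t[c] = X(v, c, s);
          T += spd_fun(Mih * unpack6(t) * Mih, f_log);
        }
        T /= N;
        double g = arma::norm(T, "fro");
        gnorm(v) = g;
        if (g < tol) break;
        M = Mh * spd_fun(T, f_exp) * Mh;
      }
      iters(v) = it;
      if (it >= max_iter && gnorm(v) >= tol) ok = false;
    }
    double t[6]; pack6(M, t);
    for (int c = 0; c < 6; ++c) mean(v, c) = t[c];
  }
  return List::create(Named("mean") = mean, Named("gnorm") = gnorm,
                      Named("iters") = iters, Named("converged") = ok);
}

// Whitened tangent coordinates of N tensor fields at a base field.
// Affine-invariant: S = logm(M^-1/2 X M^-1/2); log-Euclidean: logm X - logm M.
// Coordinates per voxel: (s11, s22, s33, sqrt2*s12, sqrt2*s13, sqrt2*s23),
// so the Euclidean norm equals the Riemannian distance. Returns N x 6V.
// [[Rcpp::export]]
arma::mat cpp_tangent_coords(const arma::cube& X, const arma::mat& mean,
                             int metric) {
  int V = X.n_rows, N = X.n_slices;
  arma::mat out(N, 6 * V);
  const double s2 = std::sqrt(2.0);
  for (int v = 0; v < V; ++v) {
    double tm[6]; for (int c = 0; c < 6; ++c) tm[c] = mean(v, c);
    arma::mat33 M = unpack6(tm);
    arma::mat33 Mih, logM;
    if (metric == 0) Mih = spd_fun(M, f_isqrt); else logM = spd_fun(M, f_log);
    for (int s = 0; s < N; ++s) {
      double t[6]; for (int c = 0; c < 6; ++c) t[c] = X(v, c, s);
      arma::mat33 S;
      if (metric == 0) S = spd_fun(Mih * unpack6(t) * Mih, f_log);
      else S = spd_fun(unpack6(t), f_log) - logM;
      int o = 6 * v;
      out(s, o)     = S(0,0);
      out(s, o + 1) = S(1,1);
      out(s, o + 2) = S(2,2);
      out(s, o + 3) = s2 * S(0,1);
      out(s, o + 4) = s2 * S(0,2);
      out(s, o + 5) = s2 * S(1,2);
    }
  }
  return out;
}

// Tangent vector field -> SPD field at base M (inverse of the whitening map).
// [[Rcpp::export]]
arma::mat cpp_tangent_to_spd(const arma::vec& coords, const arma::mat& mean,
                             int metric) {
  int V = mean.n_rows;
  arma::mat out(V, 6);
  const double is2 = 1.0 / std::sqrt(2.0);
  for (int v = 0; v < V; ++v) {
    int o = 6 * v;
    arma::mat33 S;
    S(0,0) = coords(o); S(1,1) = coords(o+1); S(2,2) = coords(o+2);
    S(0,1) = S(1,0) = is2 * coords(o+3);
    S(0,2) = S(2,0) = is2 * coords(o+4);
    S(1,2) = S(2,1) = is2 * coords(o+5);
    double tm[6]; for (int c = 0; c < 6; ++c) tm[c] = mean(v, c);
    arma::mat33 M = unpack6(tm), R;
    if (metric == 0) {
      arma::mat33 Mh = spd_fun(M, f_sqrt);
      R = Mh * spd_fun(S, f_exp) * Mh;
    } else {
      R = spd_fun(spd_fun(M, f_log) + S, f_exp);
    }
    double t[6]; pack6(R, t);
    for (int c = 0; c < 6; ++c) out(v, c) = t[c];
  }
  return out;
}

// ---------------------------------------------------------------------------
// voxel-wise two-sample Hotelling T^2 with label permutations
// ---------------------------------------------------------------------------
// tang: cube V x 6 x N of tangent vectors at the pooled mean; labels: 0/1;
// perms: n_perm x N matrix of permuted 0/1 labelings (generated in R so the
// RNG stays under R's seed control). Returns observed T^2 and permutation
// p-values p = (1 + #{T*_b >= T_obs}) / (n_perm + 1).

static double hotelling_t2(const arma::mat& Xv, const int *lab, int N,
                           double ridge) {
  int nA = 0;
  for (int s = 0; s < N; ++s) nA += (lab[s] == 0);
  int nB = N - nA;
  if (nA < 2 || nB < 2) return 0.0;
  arma::vec6 mA(arma::fill::zeros), mB(arma::fill::zeros);
  for (int s = 0; s < N; ++s)
    if (lab[s] == 0) mA += Xv.col(s); else mB += Xv.col(s);
  mA /= nA; mB /= nB;
  arma::mat66 S(arma::fill::zeros);
  for (int s = 0; s < N; ++s) {
    arma::vec6 d = Xv.col(s) - (lab[s] == 0 ? mA : mB);
    S += d * d.t();
  }
  S /= (N - 2);
  S.diag() += ridge;
  arma::vec6 d = mA - mB;
  arma::vec6 x;
  if (!arma::solve(x, S, d, arma::solve_opts::likely_sympd))
    x = arma::pinv(S) * d;
  double t2 = (double)nA * nB / N * arma::dot(d, x);
  return t2 > 0 ? t2 : 0.0;
}

// [[Rcpp::export]]
List cpp_hotelling_perm(const arma::cube& tang, IntegerVector labels,
                        const arma::imat& perms, double ridge) {
  int V = tang.n_rows, N = tang.n_slices;
  int B = perms.n_rows;
  arma::vec stat(V), p(V);
  std::vector<int> lab(N), plab(N);
  for (int s = 0; s < N; ++s) lab[s] = labels[s];
  for (int v = 0; v < V; ++v) {
    arma::mat Xv(6, N);
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < 6; ++c) Xv(c, s) = tang(v, c, s);
    double obs = hotelling_t2(Xv, lab.data(), N, ridge);
    stat(v) = obs;
    int cnt = 0;
    for (int b = 0; b < B; ++b) {
      for (int s = 0; s < N; ++s) plab[s] = perms(b, s);
      if (hotelling_t2(Xv, plab.data(), N, ridge) >= obs) ++cnt;
    }
    p(v) = (1.0 + cnt) / (B + 1.0);
  }
  return List::create(Named("stat") = stat, Named("p") = p);
}
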