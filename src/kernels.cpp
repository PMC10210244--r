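// Particle-mesh and bonded-force kernels.
//
// Hot paths of the simulator: cloud-in-cell (CIC) assignment and force
// readout, intramolecular (bonded) forces, and the inner velocity-Verlet
// loop of the rRESPA integrator.  Everything here is plain double-precision
// arithmetic on flat arrays; all physics conventions (units, filter, energy
// functional) live on the R side.
//
// Grids are stored in R array order: index = ix + nx*(iy + ny*iz), 0-based
// here, with periodic wrap-around.  Positions are assumed wrapped into
// [0, L) per dimension; the kernels re-wrap defensively.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  // the subtraction can round to L for tiny negative inputs
  if (x >= L) x -= L;
  if (x < 0) x = 0;
  return x;
}

static inline void cic_stencil(double x, double h, int n,
                               int& i0, int& i1, double& w0, double& w1) {
  double u = x / h;
  double fl = std::floor(u);
  double f = u - fl;
  i0 = (int)fl % n; if (i0 < 0) i0 += n;
  i1 = i0 + 1; if (i1 == n) i1 = 0;
  w0 = 1.0 - f;
  w1 = f;
}

// [[Rcpp::export(name = ".cic_paint_cpp")]]
NumericVector cic_paint_cpp(const NumericMatrix& pos,
                            const IntegerVector& channel,
                            int nchan,
                            const IntegerVector& dims,
                            const NumericVector& box,
                            const NumericVector& weight) {
  const int N = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = box[0] / nx, hy = box[1] / ny, hz = box[2] / nz;
  const double invh3 = 1.0 / (hx * hy * hz);
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  NumericVector out(ncell * nchan);
  double* o = REAL(out);
  for (int p = 0; p < N; ++p) {
    int c = channel[p] - 1;
    if (c < 0 || c >= nchan) stop("channel index out of range");
    double w = weight[p] * invh3;
    int ix0, ix1, iy0, iy1, iz0, iz1;
    double wx0, wx1, wy0, wy1, wz0, wz1;
    cic_stencil(wrap1(pos(p, 0), box[0]), hx, nx, ix0, ix1, wx0, wx1);
    cic_stencil(wrap1(pos(p, 1), box[1]), hy, ny, iy0, iy1, wy0, wy1);
    cic_stencil(wrap1(pos(p, 2), box[2]), hz, nz, iz0, iz1, wz0, wz1);
    double* g = o + (R_xlen_t)c * ncell;
    g[ix0 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz0)] += w * wx0 * wy0 * wz0;
    g[ix1 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz0)] += w * wx1 * wy0 * wz0;
    g[ix0 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz0)] += w * wx0 * wy1 * wz0;
    g[ix1 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz0)] += w * wx1 * wy1 * wz0;
    g[ix0 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz1)] += w * wx0 * wy0 * wz1;
    g[ix1 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz1)] += w * wx1 * wy0 * wz1;
    g[ix0 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz1)] += w * wx0 * wy1 * wz1;
    g[ix1 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz1)] += w * wx1 * wy1 * wz1;
  }
  return out;
}

// Gather a per-channel 3-vector grid field onto particles with the same CIC
// stencil used for painting.  field is laid out as [cell, axis, channel].
// [[Rcpp::export(name = ".cic_gather_cpp")]]
NumericMatrix cic_gather_cpp(const NumericMatrix& pos,
                             const IntegerVector& channel,
                             int nchan,
                             const NumericVector& field,
                             const IntegerVector& dims,
                             const NumericVector& box) {
  const int N = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = box[0] / nx, hy = box[1] / ny, hz = box[2] / nz;
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  if ((R_xlen_t)field.size() != ncell * 3 * nchan)
    stop("field length does not match dims/channels");
  NumericMatrix out(N, 3);
  const double* f = REAL(field);
  for (int p = 0; p < N; ++p) {
    int c = channel[p] - 1;
    if (c < 0 || c >= nchan) stop("channel index out of range");
    int ix0, ix1, iy0, iy1, iz0, iz1;
    double wx0, wx1, wy0, wy1, wz0, wz1;
    cic_stencil(wrap1(pos(p, 0), box[0]), hx, nx, ix0, ix1, wx0, wx1);
    cic_stencil(wrap1(pos(p, 1), box[1]), hy, ny, iy0, iy1, wy0, wy1);
    cic_stencil(wrap1(pos(p, 2), box[2]), hz, nz, iz0, iz1, wz0, wz1);
    R_xlen_t id[8];
    double w[8];
    id[0] = ix0 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz0); w[0] = wx0 * wy0 * wz0;
    id[1] = ix1 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz0); w[1] = wx1 * wy0 * wz0;
    id[2] = ix0 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz0); w[2] = wx0 * wy1 * wz0;
    id[3] = ix1 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz0); w[3] = wx1 * wy1 * wz0;
    id[4] = ix0 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz1); w[4] = wx0 * wy0 * wz1;
    id[5] = ix1 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz1); w[5] = wx1 * wy0 * wz1;
    id[6] = ix0 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz1); w[6] = wx0 * wy1 * wz1;
    id[7] = ix1 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz1); w[7] = wx1 * wy1 * wz1;
    const double* fc = f + (R_xlen_t)c * ncell * 3;
    for (int ax = 0; ax < 3; ++ax) {
      const double* fa = fc + (R_xlen_t)ax * ncell;
      double acc = 0.0;
      for (int v = 0; v < 8; ++v) acc += w[v] * fa[id[v]];
      out(p, ax) = acc;
    }
  }
  return out;
}

// Gradient of the CIC-interpolated scalar field at the particle positions:
// returns d/dr of sum_g V(g) P(g - r), the exact derivative of the
// trilinear interpolant (dP/dr is +-1/h times the transverse weights).
// Because painting and readout share the kernel P, -this is the exact
// gradient of any grid energy that depends on the particles through P.
// field is laid out as [cell, channel].
// [[Rcpp::export(name = ".cic_gather_grad_cpp")]]
NumericMatrix cic_gather_grad_cpp(const NumericMatrix& pos,
                                  const IntegerVector& channel,
                                  int nchan,
                                  const NumericVector& field,
                                  const IntegerVector& dims,
                                  const NumericVector& box) {
  const int N = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = box[0] / nx, hy = box[1] / ny, hz = box[2] / nz;
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  if ((R_xlen_t)field.size() != ncell * nchan)
    stop("field length does not match dims/channels");
  NumericMatrix out(N, 3);
  const double* f = REAL(field);
  for (int p = 0; p < N; ++p) {
    int c = channel[p] - 1;
    if (c < 0 || c >= nchan) stop("channel index out of range");
    int ix0, ix1, iy0, iy1, iz0, iz1;
    double wx0, wx1, wy0, wy1, wz0, wz1;
    cic_stencil(wrap1(pos(p, 0), box[0]), hx, nx, ix0, ix1, wx0, wx1);
    cic_stencil(wrap1(pos(p, 1), box[1]), hy, ny, iy0, iy1, wy0, wy1);
    cic_stencil(wrap1(pos(p, 2), box[2]), hz, nz, iz0, iz1, wz0, wz1);
    const double* fc = f + (R_xlen_t)c * ncell;
    double v[8];
    v[0] = fc[ix0 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz0)];
    v[1] = fc[ix1 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz0)];
    v[2] = fc[ix0 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz0)];
    v[3] = fc[ix1 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz0)];
    v[4] = fc[ix0 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz1)];
    v[5] = fc[ix1 + (R_xlen_t)nx * (iy0 + (R_xlen_t)ny * iz1)];
    v[6] = fc[ix0 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz1)];
    v[7] = fc[ix1 + (R_xlen_t)nx * (iy1 + (R_xlen_t)ny * iz1)];
    // d w0 / dr = -1/h, d w1 / dr = +1/h per axis
    out(p, 0) = ((v[1] - v[0]) * wy0 * wz0 + (v[3] - v[2]) * wy1 * wz0 +
                 (v[5] - v[4]) * wy0 * wz1 + (v[7] - v[6]) * wy1 * wz1) / hx;
    out(p, 1) = ((v[2] - v[0]) * wx0 * wz0 + (v[3] - v[1]) * wx1 * wz0 +
                 (v[6] - v[4]) * wx0 * wz1 + (v[7] - v[5]) * wx1 * wz1) / hy;
    out(p, 2) = ((v[4] - v[0]) * wx0 * wy0 + (v[5] - v[1]) * wx1 * wy0 +
                 (v[6] - v[2]) * wx0 * wy1 + (v[7] - v[3]) * wx1 * wy1) / hz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bonded forces
// ---------------------------------------------------------------------------

struct BondedTopo {
  const double* bonds;   int nb;   // i j r0 k        (column-major, nb rows)
  const double* angles;  int na;   // i j k theta0 k
  const double* diheds;  int nd;   // i j k l n c phase
  const double* cbt_idx; int nc;   // i j k l
  const double* cbt_k;   int mk;   // nc x mk cosine coefficients of k(phi)
  const double* cbt_vp;  int mvp;
  const double* cbt_g0;  int mg0;
};

static inline void mindist(const double* p, int i, int j, const double* L,
                           int N, double* d) {
  for (int ax = 0; ax < 3; ++ax) {
    double v = p[i + N * ax] - p[j + N * ax];
    v -= L[ax] * std::nearbyint(v / L[ax]);
    d[ax] = v;
  }
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// cosine series f(phi) = sum_{m=0}^{M-1} a_m cos(m phi); also derivative
static inline double cosine_series(const double* a, int M, int row, int nrow,
                                   double phi, double* dfdphi) {
  double f = 0.0, df = 0.0;
  for (int m = 0; m < M; ++m) {
    double am = a[row + nrow * m];
    f += am * std::cos(m * phi);
    df -= am * m * std::sin(m * phi);
  }
  *dfdphi = df;
  return f;
}

// angle gradient helper: given u = ri - rj, v = rk - rj (min image already),
// accumulates forces for dU/dtheta into fi, fj, fk.  Returns sin(theta) used.
static inline double angle_forces(const double* u, const double* v,
                                  double dUdtheta,
                                  double* fi, double* fj, double* fk,
                                  int* warn) {
  double lu = std::sqrt(dot3(u, u)), lv = std::sqrt(dot3(v, v));
  double ct = dot3(u, v) / (lu * lv);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double st = std::sqrt(1.0 - ct * ct);
  if (st < 1e-8) { st = 1e-8; (*warn)++; }  // capped safe derivative
  // dtheta/dri = -(1/ st) * d cos/dri ; dcos/dri = (v/lv - ct*u/lu)/lu
  for (int ax = 0; ax < 3; ++ax) {
    double dci = (v[ax] / lv - ct * u[ax] / lu) / lu;
    double dck = (u[ax] / lu - ct * v[ax] / lv) / lv;
    double gi = dUdtheta * (-1.0 / st) * dci;  // dU/dri
    double gk = dUdtheta * (-1.0 / st) * dck;
    fi[ax] -= gi;
    fk[ax] -= gk;
    fj[ax] += gi + gk;
  }
  return st;
}

// dihedral angle phi and gradients; IUPAC convention (cis = 0, right-handed
// positive).  Returns false for a degenerate (collinear) inner geometry.
static inline bool dihedral_angle(const double* b1, const double* b2,
                                  const double* b3, double* phi,
                                  double* dphidri, double* dphidrj,
                                  double* dphidrk, double* dphidrl) {
  double n1[3], n2[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
  double lb2 = std::sqrt(dot3(b2, b2));
  if (n1sq < 1e-16 || n2sq < 1e-16 || lb2 < 1e-12) return false;
  double cr[3];
  cross3(n1, n2, cr);
  double x = dot3(n1, n2);
  double y = dot3(cr, b2) / lb2;
  // IUPAC convention: phi = 0 at cis, right-handed positive
  *phi = std::atan2(y, x);
  // standard analytic gradients
  for (int ax = 0; ax < 3; ++ax) {
    dphidri[ax] = -lb2 / n1sq * n1[ax];
    dphidrl[ax] =  lb2 / n2sq * n2[ax];
  }
  double s12 = dot3(b1, b2) / (lb2 * lb2);
  double s32 = dot3(b3, b2) / (lb2 * lb2);
  for (int ax = 0; ax < 3; ++ax) {
    dphidrj[ax] = -(1.0 + s12) * dphidri[ax] + s32 * dphidrl[ax];
    dphidrk[ax] = s12 * dphidri[ax] - (1.0 + s32) * dphidrl[ax];
  }
  return true;
}

static double bonded_eval(const double* p, int N, const double* L,
                          const BondedTopo& T, double* F, int* warn) {
  double U = 0.0;
  // bonds: 0.5 kb (r - r0)^2
  for (int t = 0; t < T.nb; ++t) {
    int i = (int)T.bonds[t + T.nb * 0] - 1;
    int j = (int)T.bonds[t + T.nb * 1] - 1;
    double r0 = T.bonds[t + T.nb * 2];
    double kb = T.bonds[t + T.nb * 3];
    double d[3];
    mindist(p, i, j, L, N, d);
    double r = std::sqrt(dot3(d, d));
    double dr = r - r0;
    U += 0.5 * kb * dr * dr;
    if (r > 1e-12) {
      double c = -kb * dr / r;  // force on i along +d
      for (int ax = 0; ax < 3; ++ax) {
        F[i + N * ax] += c * d[ax];
        F[j + N * ax] -= c * d[ax];
      }
    }
  }
  // angles: 0.5 ka (theta - theta0)^2
  for (int t = 0; t < T.na; ++t) {
    int i = (int)T.angles[t + T.na * 0] - 1;
    int j = (int)T.angles[t + T.na * 1] - 1;
    int k = (int)T.angles[t + T.na * 2] - 1;
    double th0 = T.angles[t + T.na * 3];
    double ka  = T.angles[t + T.na * 4];
    double u[3], v[3];
    mindist(p, i, j, L, N, u);
    mindist(p, k, j, L, N, v);
    double lu = std::sqrt(dot3(u, u)), lv = std::sqrt(dot3(v, v));
    double ct = dot3(u, v) / (lu * lv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    U += 0.5 * ka * (th - th0) * (th - th0);
    double fi[3] = {0, 0, 0}, fj[3] = {0, 0, 0}, fk[3] = {0, 0, 0};
    angle_forces(u, v, ka * (th - th0), fi, fj, fk, warn);
    for (int ax = 0; ax < 3; ++ax) {
      F[i + N * ax] += fi[ax];
      F[j + N * ax] += fj[ax];
      F[k + N * ax] += fk[ax];
    }
  }
  // proper dihedrals: c (1 + cos(n phi - phase))
  for (int t = 0; t < T.nd; ++t) {
    int i = (int)T.diheds[t + T.nd * 0] - 1;
    int j = (int)T.diheds[t + T.nd * 1] - 1;
    int k = (int)T.diheds[t + T.nd * 2] - 1;
    int l = (int)T.diheds[t + T.nd * 3] - 1;
    double n  = T.diheds[t + T.nd * 4];
    double c  = T.diheds[t + T.nd * 5];
    double ph = T.diheds[t + T.nd * 6];
    double b1[3], b2[3], b3[3];
    mindist(p, j, i, L, N, b1);
    mindist(p, k, j, L, N, b2);
    mindist(p, l, k, L, N, b3);
    double phi, gi[3], gj[3], gk[3], gl[3];
    if (!dihedral_angle(b1, b2, b3, &phi, gi, gj, gk, gl)) { (*warn)++; continue; }
    U += c * (1.0 + std::cos(n * phi - ph));
    double dU = -c * n * std::sin(n * phi - ph);
    for (int ax = 0; ax < 3; ++ax) {
      F[i + N * ax] -= dU * gi[ax];
      F[j + N * ax] -= dU * gj[ax];
      F[k + N * ax] -= dU * gk[ax];
      F[l + N * ax] -= dU * gl[ax];
    }
  }
  // combined bending-torsional backbone terms:
  //   U = 0.5 k(phi) (gamma - gamma0(phi))^2 + Vp(phi)
  // gamma is the bending angle of (i, j, k); phi the dihedral of (i, j, k, l).
  for (int t = 0; t < T.nc; ++t) {
    int i = (int)T.cbt_idx[t + T.nc * 0] - 1;
    int j = (int)T.cbt_idx[t + T.nc * 1] - 1;
    int k = (int)T.cbt_idx[t + T.nc * 2] - 1;
    int l = (int)T.cbt_idx[t + T.nc * 3] - 1;
    double b1[3], b2[3], b3[3];
    mindist(p, j, i, L, N, b1);
    mindist(p, k, j, L, N, b2);
    mindist(p, l, k, L, N, b3);
    double phi, gi[3], gj[3], gk[3], gl[3];
    if (!dihedral_angle(b1, b2, b3, &phi, gi, gj, gk, gl)) { (*warn)++; continue; }
    double dk, dvp, dg0;
    double kk  = cosine_series(T.cbt_k,  T.mk,  t, T.nc, phi, &dk);
    double vp  = cosine_series(T.cbt_vp, T.mvp, t, T.nc, phi, &dvp);
    double g0  = cosine_series(T.cbt_g0, T.mg0, t, T.nc, phi, &dg0);
    // bending angle gamma of triplet (i, j, k): u = ri - rj, v = rk - rj
    double u[3], v[3];
    mindist(p, i, j, L, N, u);
    mindist(p, k, j, L, N, v);
    double lu = std::sqrt(dot3(u, u)), lv = std::sqrt(dot3(v, v));
    double ct = dot3(u, v) / (lu * lv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double gamma = std::acos(ct);
    double dev = gamma - g0;
    U += 0.5 * kk * dev * dev + vp;
    // dU/dphi at fixed gamma
    double dUdphi = 0.5 * dk * dev * dev - kk * dev * dg0 + dvp;
    for (int ax = 0; ax < 3; ++ax) {
      F[i + N * ax] -= dUdphi * gi[ax];
      F[j + N * ax] -= dUdphi * gj[ax];
      F[k + N * ax] -= dUdphi * gk[ax];
      F[l + N * ax] -= dUdphi * gl[ax];
    }
    // dU/dgamma
    double fi[3] = {0, 0, 0}, fj[3] = {0, 0, 0}, fk[3] = {0, 0, 0};
    angle_forces(u, v, kk * dev, fi, fj, fk, warn);
    for (int ax = 0; ax < 3; ++ax) {
      F[i + N * ax] += fi[ax];
      F[j + N * ax] += fj[ax];
      F[k + N * ax] += fk[ax];
    }
  }
  return U;
}

// [[Rcpp::export(name = ".bonded_forces_cpp")]]
List bonded_forces_cpp(const NumericMatrix& pos, const NumericVector& box,
                       const List& topo) {
  const int N = pos.nrow();
  // keep matrices alive for the duration of the call
  NumericMatrix b = topo["bonds"], a = topo["angles"], d = topo["dihedrals"];
  NumericMatrix ci = topo["cbt_idx"], ck = topo["cbt_k"], cv = topo["cbt_vp"],
                cg = topo["cbt_g0"];
  BondedTopo T;
  T.bonds = REAL(b); T.nb = b.nrow();
  T.angles = REAL(a); T.na = a.nrow();
  T.diheds = REAL(d); T.nd = d.nrow();
  T.cbt_idx = REAL(ci); T.nc = ci.nrow();
  T.cbt_k = REAL(ck); T.mk = ck.ncol();
  T.cbt_vp = REAL(cv); T.mvp = cv.ncol();
  T.cbt_g0 = REAL(cg); T.mg0 = cg.ncol();
  NumericMatrix F(N, 3);
  int warn = 0;
  double U = bonded_eval(REAL(pos), N, REAL(box), T, REAL(F), &warn);
  return List::create(_["forces"] = F, _["energy"] = U,
                      _["n_degenerate"] = warn);
}

// Inner rRESPA loop: nsteps velocity-Verlet steps under bonded forces only.
// pos and vel are modified copies; the field-force impulse is applied outside.
// forces0 must hold the bonded forces at the entry positions.
// [[Rcpp::export(name = ".inner_verlet_cpp")]]
List inner_verlet_cpp(const NumericMatrix& pos0, const NumericMatrix& vel0,
                      const NumericVector& invmass, const NumericVector& box,
                      double dt, int nsteps, const List& topo,
                      const NumericMatrix& forces0) {
  const int N = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0), F = clone(forces0);
  NumericMatrix b = topo["bonds"], a = topo["angles"], d = topo["dihedrals"];
  NumericMatrix ci = topo["cbt_idx"], ck = topo["cbt_k"], cv = topo["cbt_vp"],
                cg = topo["cbt_g0"];
  BondedTopo T;
  T.bonds = REAL(b); T.nb = b.nrow();
  T.angles = REAL(a); T.na = a.nrow();
  T.diheds = REAL(d); T.nd = d.nrow();
  T.cbt_idx = REAL(ci); T.nc = ci.nrow();
  T.cbt_k = REAL(ck); T.mk = ck.ncol();
  T.cbt_vp = REAL(cv); T.mvp = cv.ncol();
  T.cbt_g0 = REAL(cg); T.mg0 = cg.ncol();
  double* P = REAL(pos);
  double* V = REAL(vel);
  double* Fp = REAL(F);
  const double* im = REAL(invmass);
  const double* L = REAL(box);
  int warn = 0;
  double U = NA_REAL;
  const double half = 0.5 * dt;
  for (int s = 0; s < nsteps; ++s) {
    for (int ax = 0; ax < 3; ++ax)
      for (int i = 0; i < N; ++i)
        V[i + N * ax] += half * im[i] * Fp[i + N * ax];
    for (int ax = 0; ax < 3; ++ax)
      for (int i = 0; i < N; ++i) {
        double x = P[i + N * ax] + dt * V[i + N * ax];
        P[i + N * ax] = wrap1(x, L[ax]);
      }
    std::fill(Fp, Fp + (R_xlen_t)3 * N, 0.0);
    U = bonded_eval(P, N, L, T, Fp, &warn);
    if (!std::isfinite(U)) stop("non-finite bonded energy during integration");
    for (int ax = 0; ax < 3; ++ax)
      for (int i = 0; i < N; ++i)
        V[i + N * ax] += half * im[i] * Fp[i + N * ax];
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["forces"] = F,
                      _["energy"] = U, _["n_degenerate"] = warn);
}
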