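// Streamline propagation and rasterization kernels.
//
// Conventions shared with the R side:
//  * tensor fields are numeric arrays of dim (nx, ny, nz, 6) holding the
//    unique coefficients (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) per voxel;
//  * `origin` is the world-mm position of the *corner* of voxel (1,1,1),
//    so the center of 1-based voxel (i,j,k) is origin + (i-0.5)*voxel_size;
//  * all streamline points are world mm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Field {
  const double *coef;
  int nx, ny, nz;
  double vox;
  double ox, oy, oz;

  long idx(int i, int j, int k, int c) const {
    return (long)i + (long)nx * ((long)j + (long)ny * ((long)k + (long)nz * c));
  }

  bool in_bounds(const double *p) const {
    return p[0] >= ox && p[0] <= ox + nx * vox &&
           p[1] >= oy && p[1] <= oy + ny * vox &&
           p[2] >= oz && p[2] <= oz + nz * vox;
  }

  // Trilinear interpolation of the 6 coefficients at world point p.
  // Returns false when p lies outside the field bounding box.
  bool interp(const double *p, double *out) const {
    if (!in_bounds(p)) return false;
    // continuous 0-based voxel-center coordinates
    double u = (p[0] - ox) / vox - 0.5;
    double v = (p[1] - oy) / vox - 0.5;
    double w = (p[2] - oz) / vox - 0.5;
    // clamp into the center lattice (constant extrapolation in the half-voxel rim)
    u = std::min(std::max(u, 0.0), (double)(nx - 1));
    v = std::min(std::max(v, 0.0), (double)(ny - 1));
    w = std::min(std::max(w, 0.0), (double)(nz - 1));
    int i0 = std::min((int)std::floor(u), nx - 2 >= 0 ? nx - 2 : 0);
    int j0 = std::min((int)std::floor(v), ny - 2 >= 0 ? ny - 2 : 0);
    int k0 = std::min((int)std::floor(w), nz - 2 >= 0 ? nz - 2 : 0);
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fu = u - i0, fv = v - j0, fw = w - k0;
    int i1 = std::min(i0 + 1, nx - 1);
    int j1 = std::min(j0 + 1, ny - 1);
    int k1 = std::min(k0 + 1, nz - 1);
    for (int c = 0; c < 6; ++c) {
      double c000 = coef[idx(i0, j0, k0, c)], c100 = coef[idx(i1, j0, k0, c)];
      double c010 = coef[idx(i0, j1, k0, c)], c110 = coef[idx(i1, j1, k0, c)];
      double c001 = coef[idx(i0, j0, k1, c)], c101 = coef[idx(i1, j0, k1, c)];
      double c011 = coef[idx(i0, j1, k1, c)], c111 = coef[idx(i1, j1, k1, c)];
      double c00 = c000 * (1 - fu) + c100 * fu;
      double c10 = c010 * (1 - fu) + c110 * fu;
      double c01 = c001 * (1 - fu) + c101 * fu;
      double c11 = c011 * (1 - fu) + c111 * fu;
      double c0 = c00 * (1 - fv) + c10 * fv;
      double c1 = c01 * (1 - fv) + c11 * fv;
      out[c] = c0 * (1 - fw) + c1 * fw;
    }
    return true;
  }
};

// FA from the 6 unique coefficients, via rotation-invariant Frobenius norms.
double fa6(const double *d) {
  double dxx = d[0], dxy = d[1], dxz = d[2], dyy = d[3], dyz = d[4], dzz = d[5];
  double off2 = 2.0 * (dxy * dxy + dxz * dxz + dyz * dyz);
  double tot2 = dxx * dxx + dyy * dyy + dzz * dzz + off2;
  if (tot2 <= 0.0) return 0.0;
  double m = (dxx + dyy + dzz) / 3.0;
  double dev2 = (dxx - m) * (dxx - m) + (dyy - m) * (dyy - m) +
                (dzz - m) * (dzz - m) + off2;
  double fa2 = 1.5 * dev2 / tot2;
  if (fa2 < 0.0) fa2 = 0.0;
  if (fa2 > 1.0) fa2 = 1.0;
  return std::sqrt(fa2);
}

arma::mat33 to_mat(const double *d) {
  arma::mat33 D;
  D(0, 0) = d[0]; D(0, 1) = d[1]; D(0, 2) = d[2];
  D(1, 0) = d[1]; D(1, 1) = d[3]; D(1, 2) = d[4];
  D(2, 0) = d[2]; D(2, 1) = d[4]; D(2, 2) = d[5];
  return D;
}

// principal eigenvector with the fixed sign convention (nonnegative x
// component; ties broken on y, then z), plus the largest eigenvalue
bool principal_axis(const double *d, arma::vec3 &e1, double &lam1) {
  arma::vec eigval;
  arma::mat eigvec;
  if (!arma::eig_sym(eigval, eigvec, to_mat(d))) return false;
  lam1 = eigval(2);
  e1 = eigvec.col(2);
  double s = e1(0);
  if (s == 0.0) s = e1(1);
  if (s == 0.0) s = e1(2);
  if (s < 0.0) e1 = -e1;
  return true;
}

// TEND deflection: v_out = normalize(f*e1 + (1-f)*((1-g)*v + g*Dhat*v)),
// Dhat = D/lambda1; sign-aligned with v (no backtracking).
bool deflect(const double *d, const arma::vec3 &v, double f, double g,
             arma::vec3 &out) {
  arma::mat33 D = to_mat(d);
  double tr = D(0, 0) + D(1, 1) + D(2, 2);
  if (tr <= 0.0 && arma::norm(D, "fro") == 0.0) {
    out = v;  // zero tensor: pass-through
    return true;
  }
  arma::vec3 e1;
  double lam1;
  if (!principal_axis(d, e1, lam1)) return false;
  if (lam1 <= 0.0) { out = v; return true; }
  if (arma::dot(e1, v) < 0) e1 = -e1;  // deflect toward the incoming heading
  arma::vec3 w = f * e1 + (1.0 - f) * ((1.0 - g) * v + g * (D * v) / lam1);
  double n = arma::norm(w);
  if (n == 0.0) { out = v; return true; }
  w /= n;
  if (arma::dot(w, v) < 0) w = -w;
  out = w;
  return true;
}

// One propagation direction. Appends points after `seed` into `pts`.
void track_one_dir(const Field &fld, const arma::vec3 &seed,
                   const arma::vec3 &v0, double step, double fa_thr,
                   double cos_max, int max_steps, double f, double g,
                   bool rk4, std::vector<arma::vec3> &pts) {
  arma::vec3 p = seed;
  arma::vec3 v = v0;
  double d[6];
  for (int s = 0; s < max_steps; ++s) {
    if (!fld.interp(p.memptr(), d)) break;
    arma::vec3 vn;
    if (!rk4) {
      if (!deflect(d, v, f, g, vn)) break;
    } else {
      // classical RK4 on dp/ds = deflect(D(p), v)
      arma::vec3 k1, k2, k3, k4;
      double dt[6];
      if (!deflect(d, v, f, g, k1)) break;
      arma::vec3 p2 = p + 0.5 * step * k1;
      if (!fld.interp(p2.memptr(), dt) || !deflect(dt, k1, f, g, k2)) break;
      arma::vec3 p3 = p + 0.5 * step * k2;
      if (!fld.interp(p3.memptr(), dt) || !deflect(dt, k2, f, g, k3)) break;
      arma::vec3 p4 = p + step * k3;
      if (!fld.interp(p4.memptr(), dt) || !deflect(dt, k3, f, g, k4)) break;
      vn = k1 + 2.0 * k2 + 2.0 * k3 + k4;
      double n = arma::norm(vn);
      if (n == 0.0) break;
      vn /= n;
      if (arma::dot(vn, v) < 0) vn = -vn;
    }
    if (arma::dot(vn, v) < cos_max) break;  // curvature stop
    arma::vec3 pn = p + step * vn;
    double dn[6];
    if (!fld.interp(pn.memptr(), dn)) break;   // left the volume
    if (fa6(dn) < fa_thr) break;               // anisotropy stop
    pts.push_back(pn);
    p = pn;
    v = vn;
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_interp_tensor")]]
NumericVector cpp_interp_tensor(NumericVector coef, IntegerVector dim,
                                double voxel_size, NumericVector origin,
                                NumericVector p) {
  Field fld{coef.begin(), dim[0], dim[1], dim[2], voxel_size,
            origin[0], origin[1], origin[2]};
  double out[6];
  if (!fld.interp(p.begin(), out)) {
    NumericVector res(6, NA_REAL);
    return res;
  }
  return NumericVector(out, out + 6);
}

// [[Rcpp::export(name = ".cpp_fa6")]]
NumericVector cpp_fa6(NumericMatrix d6) {
  NumericVector out(d6.nrow());
  for (int i = 0; i < d6.nrow(); ++i) {
    double d[6];
    for (int c = 0; c < 6; ++c) d[c] = d6(i, c);
    out[i] = fa6(d);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_principal_eigenvector")]]
NumericVector cpp_principal_eigenvector(NumericVector d6) {
  arma::vec3 e1;
  double lam1;
  if (!principal_axis(d6.begin(), e1, lam1)) stop("eigen decomposition failed");
  NumericVector out = NumericVector::create(e1(0), e1(1), e1(2));
  out.attr("lambda1") = lam1;
  return out;
}

// [[Rcpp::export(name = ".cpp_tend_deflect")]]
NumericVector cpp_tend_deflect(NumericVector d6, NumericVector v_in, double f,
                               double g) {
  arma::vec3 v{v_in[0], v_in[1], v_in[2]};
  arma::vec3 out;
  if (!deflect(d6.begin(), v, f, g, out)) stop("eigen decomposition failed");
  return NumericVector::create(out(0), out(1), out(2));
}

// Clamp negative eigenvalues to zero voxel-wise; returns modified coefficient
// array plus the number of clamped voxels.
// [[Rcpp::export(name = ".cpp_clamp_tensors")]]
List cpp_clamp_tensors(NumericVector coef, IntegerVector dim) {
  NumericVector out = clone(coef);
  long nvox = (long)dim[0] * dim[1] * dim[2];
  long n_clamped = 0;
  arma::vec eigval;
  arma::mat eigvec;
  for (long v = 0; v < nvox; ++v) {
    double d[6];
    for (int c = 0; c < 6; ++c) d[c] = coef[v + nvox * c];
    if (!arma::eig_sym(eigval, eigvec, to_mat(d))) continue;
    if (eigval(0) >= 0.0) continue;
    ++n_clamped;
    for (int i = 0; i < 3; ++i)
      if (eigval(i) < 0.0) eigval(i) = 0.0;
    arma::mat33 D = eigvec * arma::diagmat(eigval) * eigvec.t();
    out[v + nvox * 0] = D(0, 0);
    out[v + nvox * 1] = D(0, 1);
    out[v + nvox * 2] = D(0, 2);
    out[v + nvox * 3] = D(1, 1);
    out[v + nvox * 4] = D(1, 2);
    out[v + nvox * 5] = D(2, 2);
  }
  return List::create(_["coef"] = out, _["n_clamped"] = (double)n_clamped);
}

// Bidirectional TEND propagation from each seed. Returns a list of n x 3
// point matrices (world mm), each with the seed appearing exactly once.
// [[Rcpp::export(name = ".cpp_track_seeds")]]
List cpp_track_seeds(NumericVector coef, IntegerVector dim, double voxel_size,
                     NumericVector origin, NumericMatrix seeds, double step,
                     double fa_thr, double max_angle_deg, int max_steps,
                     double f, double g, bool rk4) {
  Field fld{coef.begin(), dim[0], dim[1], dim[2], voxel_size,
            origin[0], origin[1], origin[2]};
  double cos_max = std::cos(max_angle_deg * M_PI / 180.0);
  int n_seeds = seeds.nrow();
  List out(n_seeds);
  for (int s = 0; s < n_seeds; ++s) {
    arma::vec3 seed{seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    double d[6];
    bool ok = fld.interp(seed.memptr(), d);
    std::vector<arma::vec3> fwd, bwd;
    if (ok && fa6(d) >= fa_thr) {
      arma::vec3 e1;
      double lam1;
      if (principal_axis(d, e1, lam1) && lam1 > 0) {
        track_one_dir(fld, seed, e1, step, fa_thr, cos_max, max_steps, f, g,
                      rk4, fwd);
        track_one_dir(fld, seed, -e1, step, fa_thr, cos_max, max_steps, f, g,
                      rk4, bwd);
      }
    }
    int n = (int)bwd.size() + 1 + (int)fwd.size();
    NumericMatrix m(n, 3);
    int r = 0;
    for (int i = (int)bwd.size() - 1; i >= 0; --i, ++r)
      for (int c = 0; c < 3; ++c) m(r, c) = bwd[i](c);
    for (int c = 0; c < 3; ++c) m(r, c) = seed(c);
    ++r;
    for (size_t i = 0; i < fwd.size(); ++i, ++r)
      for (int c = 0; c < 3; ++c) m(r, c) = fwd[i](c);
    out[s] = m;
  }
  return out;
}

// Rasterize streamlines: supersample each segment at <= `sample_mm` spacing
// and mark every voxel containing a sample point.
// [[Rcpp::export(name = ".cpp_rasterize_streamlines")]]
IntegerVector cpp_rasterize_streamlines(List streamlines, IntegerVector dim,
                                        double voxel_size,
                                        NumericVector origin,
                                        double sample_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector grid((long)nx * ny * nz);
  grid.attr("dim") = dim;
  auto mark = [&](double x, double y, double z) {
    int i = (int)std::floor((x - origin[0]) / voxel_size);
    int j = (int)std::floor((y - origin[1]) / voxel_size);
    int k = (int)std::floor((z - origin[2]) / voxel_size);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return;
    grid[(long)i + (long)nx * ((long)j + (long)ny * k)] = 1;
  };
  for (int s = 0; s < streamlines.size(); ++s) {
    NumericMatrix m = streamlines[s];
    int np = m.nrow();
    if (np == 0) continue;
    mark(m(0, 0), m(0, 1), m(0, 2));
    for (int p = 1; p < np; ++p) {
      double ax = m(p - 1, 0), ay = m(p - 1, 1), az = m(p - 1, 2);
      double bx = m(p, 0), by = m(p, 1), bz = m(p, 2);
      double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay) +
                             (bz - az) * (bz - az));
      int nsub = std::max(1, (int)std::ceil(len / sample_mm));
      for (int q = 1; q <= nsub; ++q) {
        double t = (double)q / nsub;
        mark(ax + t * (bx - ax), ay + t * (by - ay), az + t * (bz - az));
      }
    }
  }
  return grid;
}
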