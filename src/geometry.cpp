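#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable 3-D Gaussian smoothing (zero padding outside the array).
// sigma is in voxel units; callers crop with a margin >= 3*sigma so the
// padding never touches foreground.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_gaussian_smooth3d")]]
NumericVector cpp_gaussian_smooth3d(NumericVector arr, NumericVector sigma) {
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3) stop("expected a 3-D array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];

  auto kernel = [](double s) {
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double tot = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = s > 0 ? std::exp(-0.5 * i * i / (s * s)) : (i == 0 ? 1.0 : 0.0);
      tot += k[i + r];
    }
    for (double &w : k) w /= tot;
    return k;
  };

  NumericVector a = clone(arr);
  NumericVector b(arr.size());
  b.attr("dim") = dim;

  std::vector<double> kx = kernel(sigma[0]), ky = kernel(sigma[1]),
                      kz = kernel(sigma[2]);
  int rx = ((int)kx.size() - 1) / 2, ry = ((int)ky.size() - 1) / 2,
      rz = ((int)kz.size() - 1) / 2;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int i = -rx; i <= rx; ++i) {
          int xi = x + i;
          if (xi < 0 || xi >= nx) continue;
          acc += kx[i + rx] * a[xi + nx * (y + (R_xlen_t)ny * z)];
        }
        b[x + nx * (y + (R_xlen_t)ny * z)] = acc;
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int i = -ry; i <= ry; ++i) {
          int yi = y + i;
          if (yi < 0 || yi >= ny) continue;
          acc += ky[i + ry] * b[x + nx * (yi + (R_xlen_t)ny * z)];
        }
        a[x + nx * (y + (R_xlen_t)ny * z)] = acc;
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int i = -rz; i <= rz; ++i) {
          int zi = z + i;
          if (zi < 0 || zi >= nz) continue;
          acc += kz[i + rz] * a[x + nx * (y + (R_xlen_t)ny * zi)];
        }
        b[x + nx * (y + (R_xlen_t)ny * z)] = acc;
      }
  return b;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar field sampled at voxel centers.
// Each grid cube is split into the six Kuhn tetrahedra sharing the main
// diagonal; the decomposition is translation-invariant, so shared cube faces
// are triangulated compatibly and the extracted surface is watertight when
// the foreground does not touch the array border. Iso-vertices live on grid
// edges and are deduplicated by edge id. World coordinate of grid point
// (i,j,k) (0-based) is (i*sx, j*sy, k*sz) plus the supplied origin.
// ---------------------------------------------------------------------------

static const int TET[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
static const int CUBE_OFF[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0},
  {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}
};

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector field, NumericVector spacing,
                       NumericVector origin, double iso) {
  IntegerVector dim = field.attr("dim");
  if (dim.size() != 3) stop("expected a 3-D array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::unordered_map<long long, int> edge_vert;
  std::vector<double> V;           // xyz triples
  std::vector<int> F;              // vertex ids, triangles

  auto gid = [&](int x, int y, int z) -> long long {
    return (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
  };
  auto fval = [&](int x, int y, int z) -> double {
    return field[x + nx * (y + (R_xlen_t)ny * z)];
  };
  auto edge_point = [&](long long ga, long long gb, double fa, double fb,
                        const double *pa, const double *pb) -> int {
    long long a = std::min(ga, gb), b = std::max(ga, gb);
    long long key = a * (long long)(nx * (long long)ny * nz) + b;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    int id = (int)(V.size() / 3);
    V.push_back(pa[0] + t * (pb[0] - pa[0]));
    V.push_back(pa[1] + t * (pb[1] - pa[1]));
    V.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vert[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c,
                  const double in_c[3], const double out_c[3]) {
    // orient so the normal points from inside (f > iso) to outside
    double u[3], w[3], n[3], d[3];
    for (int i = 0; i < 3; ++i) {
      u[i] = V[3 * b + i] - V[3 * a + i];
      w[i] = V[3 * c + i] - V[3 * a + i];
      d[i] = out_c[i] - in_c[i];
    }
    n[0] = u[1] * w[2] - u[2] * w[1];
    n[1] = u[2] * w[0] - u[0] * w[2];
    n[2] = u[0] * w[1] - u[1] * w[0];
    double dp = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
    if (dp < 0) std::swap(b, c);
    F.push_back(a); F.push_back(b); F.push_back(c);
  };

  double P[8][3]; double fv[8]; long long gv[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CUBE_OFF[c][0], cy = y + CUBE_OFF[c][1], cz = z + CUBE_OFF[c][2];
          fv[c] = fval(cx, cy, cz);
          gv[c] = gid(cx, cy, cz);
          P[c][0] = origin[0] + cx * sx;
          P[c][1] = origin[1] + cy * sy;
          P[c][2] = origin[2] + cz * sz;
          if (fv[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TET[t][0], TET[t][1], TET[t][2], TET[t][3]};
          int ins[4], outs[4]; int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (fv[vi[c]] > iso) ins[ni++] = vi[c]; else outs[no++] = vi[c];
          }
          if (ni == 0 || ni == 4) continue;
          double ic[3] = {0, 0, 0}, oc[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int i = 0; i < 3; ++i) ic[i] += P[ins[c]][i] / ni;
          for (int c = 0; c < no; ++c)
            for (int i = 0; i < 3; ++i) oc[i] += P[outs[c]][i] / no;
          if (ni == 1) {
            int a = edge_point(gv[ins[0]], gv[outs[0]], fv[ins[0]], fv[outs[0]], P[ins[0]], P[outs[0]]);
            int b = edge_point(gv[ins[0]], gv[outs[1]], fv[ins[0]], fv[outs[1]], P[ins[0]], P[outs[1]]);
            int c = edge_point(gv[ins[0]], gv[outs[2]], fv[ins[0]], fv[outs[2]], P[ins[0]], P[outs[2]]);
            emit(a, b, c, ic, oc);
          } else if (ni == 3) {
            int a = edge_point(gv[outs[0]], gv[ins[0]], fv[outs[0]], fv[ins[0]], P[outs[0]], P[ins[0]]);
            int b = edge_point(gv[outs[0]], gv[ins[1]], fv[outs[0]], fv[ins[1]], P[outs[0]], P[ins[1]]);
            int c = edge_point(gv[outs[0]], gv[ins[2]], fv[outs[0]], fv[ins[2]], P[outs[0]], P[ins[2]]);
            emit(a, b, c, ic, oc);
          } else { // ni == 2
            int p1 = edge_point(gv[ins[0]], gv[outs[0]], fv[ins[0]], fv[outs[0]], P[ins[0]], P[outs[0]]);
            int p2 = edge_point(gv[ins[0]], gv[outs[1]], fv[ins[0]], fv[outs[1]], P[ins[0]], P[outs[1]]);
            int p3 = edge_point(gv[ins[1]], gv[outs[1]], fv[ins[1]], fv[outs[1]], P[ins[1]], P[outs[1]]);
            int p4 = edge_point(gv[ins[1]], gv[outs[0]], fv[ins[1]], fv[outs[0]], P[ins[1]], P[outs[0]]);
            emit(p1, p2, p3, ic, oc);
            emit(p1, p3, p4, ic, oc);
          }
        }
      }

  int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix vm(nv, 3);
  IntegerMatrix fm(nf, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) vm(i, j) = V[3 * i + j];
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) fm(i, j) = F[3 * i + j] + 1; // 1-based
  return List::create(_["vertices"] = vm, _["faces"] = fm);
}

// ---------------------------------------------------------------------------
// Voxelization of a closed triangle mesh by scan conversion: for every voxel
// column along axis 0, ray crossings with the mesh are collected and the
// voxel centers between successive crossing pairs (even-odd rule, interval
// closed on the left) are marked inside. The ray is offset by tiny
// irrational fractions of the spacing so that rays never pass exactly
// through mesh edges of rationally-placed geometry.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_voxelize_mesh")]]
LogicalVector cpp_voxelize_mesh(NumericMatrix verts, IntegerMatrix faces,
                                IntegerVector dims, NumericVector spacing,
                                NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ey = sy * 7.548776662466927e-05;
  const double ez = sz * 5.698402909980532e-05;

  std::vector<std::vector<double>> cross((size_t)ny * nz);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    double x0 = verts(i0, 0) - origin[0], y0 = verts(i0, 1) - origin[1], z0 = verts(i0, 2) - origin[2];
    double x1 = verts(i1, 0) - origin[0], y1 = verts(i1, 1) - origin[1], z1 = verts(i1, 2) - origin[2];
    double x2 = verts(i2, 0) - origin[0], y2 = verts(i2, 1) - origin[1], z2 = verts(i2, 2) - origin[2];
    double area2 = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
    if (std::fabs(area2) < 1e-12) continue; // projection degenerate: ray in plane
    double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    double zmin = std::min({z0, z1, z2}), zmax = std::max({z0, z1, z2});
    int jmin = std::max(0, (int)std::ceil((ymin - ey) / sy));
    int jmax = std::min(ny - 1, (int)std::floor((ymax - ey) / sy));
    int kmin = std::max(0, (int)std::ceil((zmin - ez) / sz));
    int kmax = std::min(nz - 1, (int)std::floor((zmax - ez) / sz));
    for (int k = kmin; k <= kmax; ++k) {
      double pz = k * sz + ez;
      for (int j = jmin; j <= jmax; ++j) {
        double py = j * sy + ey;
        double b0 = (y1 - py) * (z2 - pz) - (z1 - pz) * (y2 - py);
        double b1 = (y2 - py) * (z0 - pz) - (z2 - pz) * (y0 - py);
        double b2 = (y0 - py) * (z1 - pz) - (z0 - pz) * (y1 - py);
        bool pos = b0 > 0 && b1 > 0 && b2 > 0;
        bool neg = b0 < 0 && b1 < 0 && b2 < 0;
        if (!pos && !neg) continue;
        double w0 = b0 / area2, w1 = b1 / area2, w2 = b2 / area2;
        double xc = w0 * x0 + w1 * x1 + w2 * x2;
        cross[(size_t)j + (size_t)ny * k].push_back(xc);
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dims;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &cs = cross[(size_t)j + (size_t)ny * k];
      if (cs.size() < 2) continue;
      std::sort(cs.begin(), cs.end());
      size_t npair = cs.size() / 2;
      for (size_t p = 0; p < npair; ++p) {
        double xa = cs[2 * p], xb = cs[2 * p + 1];
        int ia = std::max(0, (int)std::ceil(xa / sx - 1e-9));
        int ib = std::min(nx - 1, (int)std::ceil(xb / sx - 1e-9) - 1);
        for (int i = ia; i <= ib; ++i)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return out;
}
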