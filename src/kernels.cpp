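#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Circular Hough accumulator.
//
// Each edge pixel votes for all candidate centres at distance r, for every
// radius in `radii`.  Coordinates are 0-based (x = column, y = row).  The
// accumulator is returned as an integer array of dim (ny, nx, n_radii).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".hough_vote_cpp")]]
IntegerVector hough_vote_cpp(IntegerVector edge_y, IntegerVector edge_x,
                             int ny, int nx, IntegerVector radii) {
  const int nr = radii.size();
  IntegerVector acc(ny * nx * nr);
  acc.attr("dim") = IntegerVector::create(ny, nx, nr);
  const int ne = edge_y.size();
  for (int ir = 0; ir < nr; ++ir) {
    const double r = radii[ir];
    // ~1 px arc spacing around the circumference
    const int nang = std::max(16, (int)std::ceil(2.0 * M_PI * r));
    std::vector<int> dys(nang), dxs(nang);
    for (int t = 0; t < nang; ++t) {
      const double th = 2.0 * M_PI * t / nang;
      dxs[t] = (int)std::lround(r * std::cos(th));
      dys[t] = (int)std::lround(r * std::sin(th));
    }
    for (int e = 0; e < ne; ++e) {
      const int ey = edge_y[e], ex = edge_x[e];
      for (int t = 0; t < nang; ++t) {
        const int cy = ey + dys[t], cx = ex + dxs[t];
        if (cy >= 0 && cy < ny && cx >= 0 && cx < nx)
          acc[cy + ny * (cx + nx * ir)] += 1;
      }
    }
  }
  return acc;
}

// ---------------------------------------------------------------------------
// Multi-pass raster-scan (chamfer) geodesic distance transform on the
// 8-connected pixel grid.
//
// weight_kind 0: unit weights -> per-step cost is the step length (1 or
// sqrt(2)); the result is the chamfer approximation of the distance to the
// seed set.  weight_kind 1: squared-gradient weights -> per-step cost is
// (dI)^2 / len, the discretisation of the squared-gradient path integral.
//
// Forward sweeps relax from {left, up-left, up, up-right}; backward sweeps
// from the mirrored set.  Sweeps alternate until a full forward+backward
// cycle changes no pixel by more than `tol`, or `max_passes` sweeps run.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".raster_scan_cpp")]]
List raster_scan_cpp(Nullable<NumericMatrix> image_, LogicalMatrix seeds,
                     int weight_kind, int max_passes, double tol) {
  const int ny = seeds.nrow(), nx = seeds.ncol();
  const double SQ2 = std::sqrt(2.0);
  const bool grad = (weight_kind == 1);
  NumericMatrix img;
  if (grad) {
    if (image_.isNull()) stop("image required for gradient weights");
    img = image_.get();
    if (img.nrow() != ny || img.ncol() != nx) stop("image/seed shape mismatch");
  }
  NumericMatrix dist(ny, nx);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  bool any_seed = false;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      if (seeds(i, j)) { dist(i, j) = 0.0; any_seed = true; }
  if (!any_seed) stop("empty seed set");

  // neighbour offsets (dy, dx, step length) for the forward causal set
  const int fdy[4] = { 0, -1, -1, -1 };
  const int fdx[4] = { -1, -1, 0, 1 };
  const double flen[4] = { 1.0, SQ2, 1.0, SQ2 };

  int passes = 0;
  bool converged = false;
  double cycle_change = 0.0;
  while (passes < max_passes) {
    const bool forward = (passes % 2 == 0);
    double max_change = 0.0;
    if (forward) {
      for (int i = 0; i < ny; ++i) {
        for (int j = 0; j < nx; ++j) {
          double best = dist(i, j);
          for (int k = 0; k < 4; ++k) {
            const int pi = i + fdy[k], pj = j + fdx[k];
            if (pi < 0 || pi >= ny || pj < 0 || pj >= nx) continue;
            const double dn = dist(pi, pj);
            if (!R_FINITE(dn)) continue;
            double w;
            if (grad) {
              const double d = img(i, j) - img(pi, pj);
              w = d * d / flen[k];
            } else w = flen[k];
            if (dn + w < best) best = dn + w;
          }
          if (best < dist(i, j)) {
            const double ch = dist(i, j) - best;
            if (R_FINITE(ch) && ch > max_change) max_change = ch;
            if (!R_FINITE(dist(i, j))) max_change = R_PosInf;
            dist(i, j) = best;
          }
        }
      }
    } else {
      for (int i = ny - 1; i >= 0; --i) {
        for (int j = nx - 1; j >= 0; --j) {
          double best = dist(i, j);
          for (int k = 0; k < 4; ++k) {
            const int pi = i - fdy[k], pj = j - fdx[k];
            if (pi < 0 || pi >= ny || pj < 0 || pj >= nx) continue;
            const double dn = dist(pi, pj);
            if (!R_FINITE(dn)) continue;
            double w;
            if (grad) {
              const double d = img(i, j) - img(pi, pj);
              w = d * d / flen[k];
            } else w = flen[k];
            if (dn + w < best) best = dn + w;
          }
          if (best < dist(i, j)) {
            const double ch = dist(i, j) - best;
            if (R_FINITE(ch) && ch > max_change) max_change = ch;
            if (!R_FINITE(dist(i, j))) max_change = R_PosInf;
            dist(i, j) = best;
          }
        }
      }
    }
    ++passes;
    if (forward) {
      cycle_change = max_change;
    } else {
      cycle_change = std::max(cycle_change, max_change);
      if (cycle_change <= tol) { converged = true; break; }
    }
  }
  return List::create(_["distance"] = dist, _["passes"] = passes,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Border pixels of a binary label image: pixels whose 8-neighbourhood
// contains the other label (either class qualifies).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".border_pixels_cpp")]]
LogicalMatrix border_pixels_cpp(IntegerMatrix labels) {
  const int ny = labels.nrow(), nx = labels.ncol();
  LogicalMatrix out(ny, nx);
  for (int i = 0; i < ny; ++i) {
    for (int j = 0; j < nx; ++j) {
      const int v = labels(i, j);
      bool border = false;
      for (int di = -1; di <= 1 && !border; ++di)
        for (int dj = -1; dj <= 1 && !border; ++dj) {
          if (di == 0 && dj == 0) continue;
          const int pi = i + di, pj = j + dj;
          if (pi < 0 || pi >= ny || pj < 0 || pj >= nx) continue;
          if (labels(pi, pj) != v) border = true;
        }
      out(i, j) = border;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching-tetrahedra isosurface of a 3D scalar field.
//
// The array is indexed (z, y, x) in R's column-major layout.  Each unit cell
// is split into 6 tetrahedra around the main diagonal; the decomposition
// uses the same face diagonals in adjacent cells, so the triangulated
// isosurface is watertight.  Triangles are wound so normals point from
// values > level toward values < level (outward for a bright object).
// Returns one row per triangle vertex: (x, y, z) in voxel index units.
// ---------------------------------------------------------------------------
static inline void interp_vert(const double *p1, const double *p2,
                               double v1, double v2, double level,
                               double *out) {
  double t = (level - v1) / (v2 - v1);
  if (t < 0) t = 0; if (t > 1) t = 1;
  for (int c = 0; c < 3; ++c) out[c] = p1[c] + t * (p2[c] - p1[c]);
}

// [[Rcpp::export(name = ".marching_tetra_cpp")]]
NumericMatrix marching_tetra_cpp(NumericVector vol, double level) {
  IntegerVector dm = vol.attr("dim");
  const int nz = dm[0], ny = dm[1], nx = dm[2];
  // 6-tetra decomposition; corner id bits: c = ix + 2*iy + 4*iz
  static const int tets[6][4] = {
    {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
    {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
  };
  std::vector<double> tri;  // flat (x,y,z) per vertex, 9 per triangle
  double cpos[8][3], cval[8];
  const double *vp = vol.begin();
  for (int z = 0; z + 1 < nz; ++z) {
    for (int y = 0; y + 1 < ny; ++y) {
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int ix = x + (c & 1), iy = y + ((c >> 1) & 1), iz = z + ((c >> 2) & 1);
          cpos[c][0] = ix; cpos[c][1] = iy; cpos[c][2] = iz;
          cval[c] = vp[iz + (size_t)nz * (iy + (size_t)ny * ix)];
          if (cval[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4];
          int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            const int ci = tets[t][c];
            if (cval[ci] > level) in_idx[nin++] = ci; else out_idx[nout++] = ci;
          }
          if (nin == 0 || nin == 4) continue;
          double v[4][3];  // up to 4 crossing vertices
          double ref[3];   // a point on the inside, for orientation
          int ntri = 0;
          double tris[2][3][3];
          if (nin == 1 || nin == 3) {
            const bool inv = (nin == 3);
            const int a = inv ? out_idx[0] : in_idx[0];
            const int *others = inv ? in_idx : out_idx;
            for (int k = 0; k < 3; ++k)
              interp_vert(cpos[a], cpos[others[k]], cval[a], cval[others[k]],
                          level, v[k]);
            for (int c = 0; c < 3; ++c) ref[c] = inv ?
              (cpos[others[0]][c] + cpos[others[1]][c] + cpos[others[2]][c]) / 3.0
              : cpos[a][c];
            ntri = 1;
            for (int k = 0; k < 3; ++k)
              for (int c = 0; c < 3; ++c) tris[0][k][c] = v[k][c];
          } else {  // 2 in, 2 out: quad AC, AD, BD, BC (A,B in; C,D out)
            const int A = in_idx[0], B = in_idx[1];
            const int C = out_idx[0], D = out_idx[1];
            interp_vert(cpos[A], cpos[C], cval[A], cval[C], level, v[0]);
            interp_vert(cpos[A], cpos[D], cval[A], cval[D], level, v[1]);
            interp_vert(cpos[B], cpos[D], cval[B], cval[D], level, v[2]);
            interp_vert(cpos[B], cpos[C], cval[B], cval[C], level, v[3]);
            for (int c = 0; c < 3; ++c) ref[c] = 0.5 * (cpos[A][c] + cpos[B][c]);
            ntri = 2;
            for (int c = 0; c < 3; ++c) {
              tris[0][0][c] = v[0][c]; tris[0][1][c] = v[1][c]; tris[0][2][c] = v[2][c];
              tris[1][0][c] = v[0][c]; tris[1][1][c] = v[2][c]; tris[1][2][c] = v[3][c];
            }
          }
          for (int k = 0; k < ntri; ++k) {
            // orient so the normal points away from the inside reference
            double e1[3], e2[3], n[3], cen[3], d[3];
            for (int c = 0; c < 3; ++c) {
              e1[c] = tris[k][1][c] - tris[k][0][c];
              e2[c] = tris[k][2][c] - tris[k][0][c];
              cen[c] = (tris[k][0][c] + tris[k][1][c] + tris[k][2][c]) / 3.0;
              d[c] = cen[c] - ref[c];
            }
            n[0] = e1[1] * e2[2] - e1[2] * e2[1];
            n[1] = e1[2] * e2[0] - e1[0] * e2[2];
            n[2] = e1[0] * e2[1] - e1[1] * e2[0];
            const double dot = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
            const bool flip = dot < 0;
            const int order[3] = { 0, flip ? 2 : 1, flip ? 1 : 2 };
            for (int kk = 0; kk < 3; ++kk)
              for (int c = 0; c < 3; ++c)
                tri.push_back(tris[k][order[kk]][c]);
          }
        }
      }
    }
  }
  const int nvert = (int)(tri.size() / 3);
  NumericMatrix out(nvert, 3);
  for (int i = 0; i < nvert; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = tri[3 * i + c];
  return out;
}
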