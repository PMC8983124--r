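// Low-level binary-image primitives shared by the QCT and morphometry
// stages: connected-component labelling, threshold region growing,
// dilation/erosion with arbitrary structuring-element offsets, and
// border-flood hole filling.  All functions accept 2-D or 3-D arrays
// (a 2-D array is treated as a single-slice volume, so 26-connectivity
// degenerates to 8-connectivity in the plane).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
};

Grid grid_from(SEXP x) {
  SEXP d = Rf_getAttrib(x, R_DimSymbol);
  if (Rf_isNull(d)) stop("input must be a 2-D or 3-D array");
  IntegerVector dim(d);
  Grid g;
  if (dim.size() == 2) {
    g.nx = dim[0]; g.ny = dim[1]; g.nz = 1;
  } else if (dim.size() == 3) {
    g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  } else {
    stop("input must be a 2-D or 3-D array");
  }
  return g;
}

// neighbourhood offsets; for flat grids (nz == 1) dz is fixed at 0
std::vector<std::array<int, 3>> neighbours(const Grid& g, int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 (faces) or 26 (full)");
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz) {
    if (g.nz == 1 && dz != 0) continue;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        off.push_back({dx, dy, dz});
      }
    }
  }
  return off;
}

inline void unravel(R_xlen_t idx, const Grid& g, int& x, int& y, int& z) {
  R_xlen_t plane = (R_xlen_t)g.nx * g.ny;
  z = (int)(idx / plane);
  R_xlen_t rem = idx % plane;
  y = (int)(rem / g.nx);
  x = (int)(rem % g.nx);
}

}  // namespace

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, int connectivity) {
  Grid g = grid_from(mask);
  if (g.n() != mask.size()) stop("dim attribute inconsistent with length");
  auto off = neighbours(g, connectivity);
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = mask.attr("dim");
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x, y, z;
      unravel(v, g, x, y, z);
      for (const auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny ||
            zz < 0 || zz >= g.nz) continue;
        R_xlen_t j = (R_xlen_t)zz * g.nx * g.ny + (R_xlen_t)yy * g.nx + xx;
        if (mask[j] == TRUE && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector vol, R_xlen_t seed0,
                              double threshold) {
  Grid g = grid_from(vol);
  if (seed0 < 0 || seed0 >= vol.size()) stop("seed voxel outside the volume");
  auto off = neighbours(g, 26);
  LogicalVector out(vol.size(), FALSE);
  out.attr("dim") = vol.attr("dim");
  if (!(vol[seed0] <= threshold))
    stop("seed voxel HU exceeds the growth threshold");
  std::vector<R_xlen_t> stack;
  out[seed0] = TRUE;
  stack.push_back(seed0);
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int x, y, z;
    unravel(v, g, x, y, z);
    for (const auto& o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny ||
          zz < 0 || zz >= g.nz) continue;
      R_xlen_t j = (R_xlen_t)zz * g.nx * g.ny + (R_xlen_t)yy * g.nx + xx;
      if (!out[j] && vol[j] <= threshold) {
        out[j] = TRUE;
        stack.push_back(j);
      }
    }
  }
  return out;
}

// Dilation by an explicit offset list (rows of `offsets` are dx,dy,dz in
// voxels; include the origin row for a reflexive element).  Voxels pushed
// outside the grid are dropped.
// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerMatrix offsets) {
  Grid g = grid_from(mask);
  LogicalVector out(mask.size(), FALSE);
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (mask[i] != TRUE) continue;
    int x, y, z;
    unravel(i, g, x, y, z);
    for (int k = 0; k < offsets.nrow(); ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1),
          zz = z + offsets(k, 2);
      if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny ||
          zz < 0 || zz >= g.nz) continue;
      out[(R_xlen_t)zz * g.nx * g.ny + (R_xlen_t)yy * g.nx + xx] = TRUE;
    }
  }
  return out;
}

// Erosion: voxel survives iff every offset lands inside the grid on a
// foreground voxel (outside counts as background).
// [[Rcpp::export(name = ".erode_cpp")]]
LogicalVector erode_cpp(LogicalVector mask, IntegerMatrix offsets) {
  Grid g = grid_from(mask);
  LogicalVector out(mask.size(), FALSE);
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (mask[i] != TRUE) continue;
    int x, y, z;
    unravel(i, g, x, y, z);
    bool keep = true;
    for (int k = 0; k < offsets.nrow() && keep; ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1),
          zz = z + offsets(k, 2);
      if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny ||
          zz < 0 || zz >= g.nz || mask[(R_xlen_t)zz * g.nx * g.ny +
                                       (R_xlen_t)yy * g.nx + xx] != TRUE)
        keep = false;
    }
    if (keep) out[i] = TRUE;
  }
  return out;
}

// Hole filling: flood the background from every border voxel
// (face-connected); background voxels never reached are enclosed cavities
// and are added to the mask.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalVector fill_holes_cpp(LogicalVector mask) {
  Grid g = grid_from(mask);
  auto off = neighbours(g, 6);
  std::vector<char> reached(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    int x, y, z;
    unravel(i, g, x, y, z);
    bool border = x == 0 || x == g.nx - 1 || y == 0 || y == g.ny - 1;
    if (g.nz > 1) border = border || z == 0 || z == g.nz - 1;
    if (border && mask[i] != TRUE && !reached[i]) {
      reached[i] = 1;
      stack.push_back(i);
      while (!stack.empty()) {
        R_xlen_t v = stack.back();
        stack.pop_back();
        int vx, vy, vz;
        unravel(v, g, vx, vy, vz);
        for (const auto& o : off) {
          int xx = vx + o[0], yy = vy + o[1], zz = vz + o[2];
          if (xx < 0 || xx >= g.nx || yy < 0 || yy >= g.ny ||
              zz < 0 || zz >= g.nz) continue;
          R_xlen_t j = (R_xlen_t)zz * g.nx * g.ny + (R_xlen_t)yy * g.nx + xx;
          if (mask[j] != TRUE && !reached[j]) {
            reached[j] = 1;
            stack.push_back(j);
          }
        }
      }
    }
  }
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = (mask[i] == TRUE || !reached[i]) ? TRUE : FALSE;
  return out;
}
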