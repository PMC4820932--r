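#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Single-axis tomography operators.
//
// Volume layout follows R's array(dim = c(n, n, n)): index = x + n*(y + n*z),
// x the fastest-varying dimension. The tilt axis is y (vertical in the
// image); the beam travels along z at zero tilt. The volume centre sits at
// voxel coordinate c = n/2 (0-based), matching the convention used for
// shifts and masks throughout the package.
//
// project_vol_cpp integrates the volume along rotated rays with bilinear
// interpolation in the x-z plane; back_project_cpp scatters image values
// into the volume with the *same* bilinear weights, so the two routines are
// exact matrix adjoints of one another (up to floating-point roundoff).

// [[Rcpp::export]]
NumericMatrix project_vol_cpp(NumericVector vol, int n, double angle_deg) {
  NumericMatrix img(n, n);
  const double a = angle_deg * M_PI / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  const double c = n / 2.0;
  const double* v = REAL(vol);
  const int nn = n * n;

  for (int ix = 0; ix < n; ++ix) {
    const double dx = ix - c;
    for (int t = 0; t < n; ++t) {
      const double dt = t - c;
      const double xs = c + ca * dx + sa * dt;
      const double zs = c - sa * dx + ca * dt;
      const int x0 = (int)std::floor(xs);
      const int z0 = (int)std::floor(zs);
      if (x0 < -1 || x0 > n - 1 || z0 < -1 || z0 > n - 1) continue;
      const double fx = xs - x0, fz = zs - z0;
      const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
      const double w01 = (1 - fx) * fz,       w11 = fx * fz;
      const bool okx0 = x0 >= 0 && x0 < n, okx1 = x0 + 1 >= 0 && x0 + 1 < n;
      const bool okz0 = z0 >= 0 && z0 < n, okz1 = z0 + 1 >= 0 && z0 + 1 < n;
      double* col = &img(0, 0) + ix;  // img(ix, iy) stride n in iy
      for (int iy = 0; iy < n; ++iy) {
        double s = 0.0;
        const int by = n * iy;
        if (okx0 && okz0) s += w00 * v[x0     + by + nn * z0];
        if (okx1 && okz0) s += w10 * v[x0 + 1 + by + nn * z0];
        if (okx0 && okz1) s += w01 * v[x0     + by + nn * (z0 + 1)];
        if (okx1 && okz1) s += w11 * v[x0 + 1 + by + nn * (z0 + 1)];
        col[(size_t)n * iy] += s;
      }
    }
  }
  return img;
}

// Accumulates the adjoint of project_vol_cpp into `vol` (modified in place).
// [[Rcpp::export]]
void back_project_cpp(NumericVector vol, NumericMatrix img, int n,
                      double angle_deg, double weight) {
  const double a = angle_deg * M_PI / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  const double c = n / 2.0;
  double* v = REAL(vol);
  const int nn = n * n;

  for (int ix = 0; ix < n; ++ix) {
    const double dx = ix - c;
    for (int t = 0; t < n; ++t) {
      const double dt = t - c;
      const double xs = c + ca * dx + sa * dt;
      const double zs = c - sa * dx + ca * dt;
      const int x0 = (int)std::floor(xs);
      const int z0 = (int)std::floor(zs);
      if (x0 < -1 || x0 > n - 1 || z0 < -1 || z0 > n - 1) continue;
      const double fx = xs - x0, fz = zs - z0;
      const double w00 = weight * (1 - fx) * (1 - fz);
      const double w10 = weight * fx * (1 - fz);
      const double w01 = weight * (1 - fx) * fz;
      const double w11 = weight * fx * fz;
      const bool okx0 = x0 >= 0 && x0 < n, okx1 = x0 + 1 >= 0 && x0 + 1 < n;
      const bool okz0 = z0 >= 0 && z0 < n, okz1 = z0 + 1 >= 0 && z0 + 1 < n;
      const double* col = &img(0, 0) + ix;
      for (int iy = 0; iy < n; ++iy) {
        const double p = col[(size_t)n * iy];
        if (p == 0.0) continue;
        const int by = n * iy;
        if (okx0 && okz0) v[x0     + by + nn * z0]       += w00 * p;
        if (okx1 && okz0) v[x0 + 1 + by + nn * z0]       += w10 * p;
        if (okx0 && okz1) v[x0     + by + nn * (z0 + 1)] += w01 * p;
        if (okx1 && okz1) v[x0 + 1 + by + nn * (z0 + 1)] += w11 * p;
      }
    }
  }
}

// Connected-component labelling of a binary mask laid out as an R array of
// dim `dims` (length 2 or 3). 8-connectivity in 2D, 26-connectivity in 3D.
// Returns integer labels (0 = background), numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nd = dims.size();
  const int nx = dims[0];
  const int ny = dims[1];
  const int nz = (nd == 3) ? dims[2] : 1;
  const size_t ntot = (size_t)nx * ny * nz;
  IntegerVector labels(ntot, 0);
  const int* m = LOGICAL(mask);
  int* lab = INTEGER(labels);
  int next_label = 0;
  std::vector<size_t> stack;

  for (size_t start = 0; start < ntot; ++start) {
    if (m[start] != TRUE || lab[start] != 0) continue;
    ++next_label;
    stack.clear();
    stack.push_back(start);
    lab[start] = next_label;
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int cx = cur % nx;
      const int cy = (cur / nx) % ny;
      const int cz = cur / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int z = cz + dz;
        if (z < 0 || z >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y = cy + dy;
          if (y < 0 || y >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int x = cx + dx;
            if (x < 0 || x >= nx) continue;
            const size_t idx = x + (size_t)nx * (y + (size_t)ny * z);
            if (m[idx] == TRUE && lab[idx] == 0) {
              lab[idx] = next_label;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// --- stack operators in a y-fastest scratch layout -----------------------
//
// The per-ray inner loop runs over the tilt-axis coordinate y; transposing
// the volume to volT[y + n*(x + n*z)] (and images to imgT[y + n*x]) makes
// those accesses contiguous. The transpose costs one pass per stack call
// and the loops run several-fold faster than in the R array layout.

static void transpose_to_yfirst(const double* v, double* vt, int n) {
  for (int z = 0; z < n; ++z)
    for (int y = 0; y < n; ++y) {
      const double* src = v + (size_t)n * y + (size_t)n * n * z;
      double* dst = vt + (size_t)n * n * z + y;
      for (int x = 0; x < n; ++x) dst[(size_t)n * x] = src[x];
    }
}

static void transpose_from_yfirst(const double* vt, double* v, int n) {
  for (int z = 0; z < n; ++z)
    for (int y = 0; y < n; ++y) {
      double* dst = v + (size_t)n * y + (size_t)n * n * z;
      const double* src = vt + (size_t)n * n * z + y;
      for (int x = 0; x < n; ++x) dst[x] = src[(size_t)n * x];
    }
}

// Project a volume at every angle of a tilt series in one call.
// Returns an n x n x n_angles stack (R array layout).
// [[Rcpp::export]]
NumericVector project_stack_cpp(NumericVector vol, int n,
                                NumericVector angles) {
  const int nimg = angles.size();
  NumericVector out((size_t)n * n * nimg);
  std::vector<double> vt((size_t)n * n * n);
  transpose_to_yfirst(REAL(vol), vt.data(), n);
  std::vector<double> imgT((size_t)n * n);
  const double c = n / 2.0;

  for (int a = 0; a < nimg; ++a) {
    const double ang = angles[a] * M_PI / 180.0;
    const double ca = std::cos(ang), sa = std::sin(ang);
    std::fill(imgT.begin(), imgT.end(), 0.0);
    for (int ix = 0; ix < n; ++ix) {
      const double dx = ix - c;
      double* icol = imgT.data() + (size_t)n * ix;
      for (int t = 0; t < n; ++t) {
        const double dt = t - c;
        const double xs = c + ca * dx + sa * dt;
        const double zs = c - sa * dx + ca * dt;
        const int x0 = (int)std::floor(xs);
        const int z0 = (int)std::floor(zs);
        if (x0 >= 0 && x0 < n - 1 && z0 >= 0 && z0 < n - 1) {
          const double fx = xs - x0, fz = zs - z0;
          const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
          const double w01 = (1 - fx) * fz, w11 = fx * fz;
          const double* p00 = vt.data() + (size_t)n * x0 + (size_t)n * n * z0;
          const double* p10 = p00 + n;
          const double* p01 = p00 + (size_t)n * n;
          const double* p11 = p01 + n;
          for (int iy = 0; iy < n; ++iy)
            icol[iy] += w00 * p00[iy] + w10 * p10[iy] +
                        w01 * p01[iy] + w11 * p11[iy];
        } else if (x0 >= -1 && x0 <= n - 1 && z0 >= -1 && z0 <= n - 1) {
          // boundary-straddling rays: slow path with zero padding
          const double fx = xs - x0, fz = zs - z0;
          const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
          const double w01 = (1 - fx) * fz, w11 = fx * fz;
          const bool okx0 = x0 >= 0 && x0 < n, okx1 = x0 + 1 >= 0 && x0 + 1 < n;
          const bool okz0 = z0 >= 0 && z0 < n, okz1 = z0 + 1 >= 0 && z0 + 1 < n;
          for (int iy = 0; iy < n; ++iy) {
            double s = 0.0;
            if (okx0 && okz0) s += w00 * vt[iy + (size_t)n * x0 + (size_t)n * n * z0];
            if (okx1 && okz0) s += w10 * vt[iy + (size_t)n * (x0 + 1) + (size_t)n * n * z0];
            if (okx0 && okz1) s += w01 * vt[iy + (size_t)n * x0 + (size_t)n * n * (z0 + 1)];
            if (okx1 && okz1) s += w11 * vt[iy + (size_t)n * (x0 + 1) + (size_t)n * n * (z0 + 1)];
            icol[iy] += s;
          }
        }
      }
    }
    // imgT[y + n*x] -> out[x + n*y] for this image
    double* o = REAL(out) + (size_t)n * n * a;
    for (int ix = 0; ix < n; ++ix) {
      const double* icol2 = imgT.data() + (size_t)n * ix;
      for (int iy = 0; iy < n; ++iy) o[ix + (size_t)n * iy] = icol2[iy];
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, nimg);
  return out;
}

// Back-project an image stack (exact adjoint of project_stack_cpp, summed
// over images, each multiplied by `weight`).
// [[Rcpp::export]]
NumericVector back_project_stack_cpp(NumericVector images, int n,
                                     NumericVector angles, double weight) {
  const int nimg = angles.size();
  NumericVector out((size_t)n * n * n);
  std::vector<double> vt((size_t)n * n * n, 0.0);
  std::vector<double> imgT((size_t)n * n);
  const double c = n / 2.0;

  for (int a = 0; a < nimg; ++a) {
    const double* im = REAL(images) + (size_t)n * n * a;
    for (int ix = 0; ix < n; ++ix) {
      double* icol = imgT.data() + (size_t)n * ix;
      for (int iy = 0; iy < n; ++iy) icol[iy] = im[ix + (size_t)n * iy];
    }
    const double ang = angles[a] * M_PI / 180.0;
    const double ca = std::cos(ang), sa = std::sin(ang);
    for (int ix = 0; ix < n; ++ix) {
      const double dx = ix - c;
      const double* icol = imgT.data() + (size_t)n * ix;
      for (int t = 0; t < n; ++t) {
        const double dt = t - c;
        const double xs = c + ca * dx + sa * dt;
        const double zs = c - sa * dx + ca * dt;
        const int x0 = (int)std::floor(xs);
        const int z0 = (int)std::floor(zs);
        if (x0 < -1 || x0 > n - 1 || z0 < -1 || z0 > n - 1) continue;
        const double fx = xs - x0, fz = zs - z0;
        const double w00 = weight * (1 - fx) * (1 - fz);
        const double w10 = weight * fx * (1 - fz);
        const double w01 = weight * (1 - fx) * fz;
        const double w11 = weight * fx * fz;
        if (x0 >= 0 && x0 < n - 1 && z0 >= 0 && z0 < n - 1) {
          double* p00 = vt.data() + (size_t)n * x0 + (size_t)n * n * z0;
          double* p10 = p00 + n;
          double* p01 = p00 + (size_t)n * n;
          double* p11 = p01 + n;
          for (int iy = 0; iy < n; ++iy) {
            const double p = icol[iy];
            p00[iy] += w00 * p; p10[iy] += w10 * p;
            p01[iy] += w01 * p; p11[iy] += w11 * p;
          }
        } else {
          const bool okx0 = x0 >= 0 && x0 < n, okx1 = x0 + 1 >= 0 && x0 + 1 < n;
          const bool okz0 = z0 >= 0 && z0 < n, okz1 = z0 + 1 >= 0 && z0 + 1 < n;
          for (int iy = 0; iy < n; ++iy) {
            const double p = icol[iy];
            if (p == 0.0) continue;
            if (okx0 && okz0) vt[iy + (size_t)n * x0 + (size_t)n * n * z0] += w00 * p;
            if (okx1 && okz0) vt[iy + (size_t)n * (x0 + 1) + (size_t)n * n * z0] += w10 * p;
            if (okx0 && okz1) vt[iy + (size_t)n * x0 + (size_t)n * n * (z0 + 1)] += w01 * p;
            if (okx1 && okz1) vt[iy + (size_t)n * (x0 + 1) + (size_t)n * n * (z0 + 1)] += w11 * p;
          }
        }
      }
    }
  }
  transpose_from_yfirst(vt.data(), REAL(out), n);
  out.attr("dim") = IntegerVector::create(n, n, n);
  return out;
}

// Separable Gaussian blur of an n^3 volume, zero padding outside the grid.
// [[Rcpp::export]]
NumericVector gaussian_blur3_cpp(NumericVector vol, int n, double sigma_px) {
  const int r = std::max(1, (int)std::ceil(4.0 * sigma_px));
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma_px * sigma_px));
    ksum += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= ksum;

  NumericVector out(clone(vol));
  std::vector<double> line(n), tmp(n);
  double* o = REAL(out);
  const size_t nn = (size_t)n * n;
  for (int axis = 0; axis < 3; ++axis) {
    const size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)n : nn;
    for (int b = 0; b < n; ++b)
      for (int cdx = 0; cdx < n; ++cdx) {
        size_t base;
        if (axis == 0) base = (size_t)n * b + nn * cdx;
        else if (axis == 1) base = b + nn * cdx;
        else base = b + (size_t)n * cdx;
        for (int i = 0; i < n; ++i) line[i] = o[base + stride * i];
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
          for (int j = lo; j <= hi; ++j) s += k[j - i + r] * line[j];
          tmp[i] = s;
        }
        for (int i = 0; i < n; ++i) o[base + stride * i] = tmp[i];
      }
  }
  out.attr("dim") = IntegerVector::create(n, n, n);
  return out;
}
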