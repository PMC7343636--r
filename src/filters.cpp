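#include <Rcpp.h>
using namespace Rcpp;

// Volumes are stored as R arrays with dim = c(nz, ny, nx), column-major,
// so the z index varies fastest. linear index = z + nz*(y + ny*x), 0-based.

static inline int reflect_index(int i, int n) {
  // reflect-101-free variant: simple mirror at the border (…, 1, 0 | 0, 1, …)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Correlate a 1D symmetric kernel along one axis of a 3D volume with
// mirror padding. axis: 0 = z, 1 = y, 2 = x.
// [[Rcpp::export]]
NumericVector conv3d_axis(NumericVector vol, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int klen = kernel.size();
  const int r = klen / 2;  // klen is odd
  NumericVector out(vol.size());

  const int nax = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  if (klen > nax)
    stop("smoothing kernel (%d taps) is larger than the volume axis (%d voxels)",
         klen, nax);

  const R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nz : (R_xlen_t)nz * ny;
  // reflected neighbor offsets (in elements) per position along the axis
  std::vector<R_xlen_t> offs((size_t)nax * klen);
  for (int p = 0; p < nax; ++p)
    for (int k = -r; k <= r; ++k)
      offs[(size_t)p * klen + (k + r)] =
        ((R_xlen_t)reflect_index(p + k, nax) - p) * stride;

  const double* kv = REAL(kernel);
  const double* in = REAL(vol);
  double* op = REAL(out);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) {
        const int p = (axis == 0) ? z : (axis == 1) ? y : x;
        const R_xlen_t* o = &offs[(size_t)p * klen];
        const double* c = in + base + z;
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) acc += kv[k] * c[o[k]];
        op[base + z] = acc;
      }
    }
  }
  return out;
}

// Connected-component labeling of a binary volume under 6/18/26
// connectivity. Components are numbered 1, 2, ... in the scan order
// (column-major linear order) of each component's first voxel, which makes
// the labeling deterministic.
// [[Rcpp::export]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int ax = -1; ax <= 1; ++ax)
    for (int ay = -1; ay <= 1; ++ay)
      for (int az = -1; az <= 1; ++az) {
        int manh = std::abs(ax) + std::abs(ay) + std::abs(az);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nn = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur % nz);
      int rest = (int)(cur / nz);
      int y = rest % ny;
      int x = rest / ny;
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Per-label voxel count, centroid sums and intensity sums in one pass.
// Returns a matrix with one row per label: count, sum_z, sum_y, sum_x,
// sum_intensity (centroids divided out on the R side).
// [[Rcpp::export]]
NumericMatrix label_stats(IntegerVector labels, IntegerVector dim,
                          NumericVector intensity, int n_labels) {
  const int nz = dim[0], ny = dim[1];
  NumericMatrix out(n_labels, 5);
  const R_xlen_t n = labels.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int lab = labels[i];
    if (lab == 0) continue;
    int z = (int)(i % nz);
    int rest = (int)(i / nz);
    int y = rest % ny;
    int x = rest / ny;
    out(lab - 1, 0) += 1.0;
    out(lab - 1, 1) += z + 1;  // 1-based voxel coordinates
    out(lab - 1, 2) += y + 1;
    out(lab - 1, 3) += x + 1;
    out(lab - 1, 4) += intensity[i];
  }
  return out;
}

// Slice-wise rigid resampling of a (z,y,x) volume: each z-slice is
// inverse-warped under a rotation (about the slice center) plus
// translation, with bilinear interpolation and zero fill outside.
// [[Rcpp::export]]
NumericVector warp_stack(NumericVector vol, IntegerVector dim,
                         double rotation_deg, double dy, double dx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  const double th = rotation_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (ny + 1) / 2.0, cx = (nx + 1) / 2.0;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      // inverse map: p = R^T (p' - c - t) + c  (1-based coordinates)
      double yy = (y + 1) - cy - dy;
      double xx = (x + 1) - cx - dx;
      double sy = ct * yy + st * xx + cy;
      double sx = -st * yy + ct * xx + cx;
      int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      double fy = sy - y0, fx = sx - x0;
      double w00 = (1 - fy) * (1 - fx), w01 = (1 - fy) * fx;
      double w10 = fy * (1 - fx), w11 = fy * fx;
      bool i00 = y0 >= 1 && y0 <= ny && x0 >= 1 && x0 <= nx;
      bool i01 = y0 >= 1 && y0 <= ny && x0 + 1 >= 1 && x0 + 1 <= nx;
      bool i10 = y0 + 1 >= 1 && y0 + 1 <= ny && x0 >= 1 && x0 <= nx;
      bool i11 = y0 + 1 >= 1 && y0 + 1 <= ny && x0 + 1 >= 1 && x0 + 1 <= nx;
      for (int z = 0; z < nz; ++z) {
        double v = 0.0;
        if (i00) v += w00 * vol[z + (R_xlen_t)nz * ((y0 - 1) + (R_xlen_t)ny * (x0 - 1))];
        if (i01) v += w01 * vol[z + (R_xlen_t)nz * ((y0 - 1) + (R_xlen_t)ny * x0)];
        if (i10) v += w10 * vol[z + (R_xlen_t)nz * (y0 + (R_xlen_t)ny * (x0 - 1))];
        if (i11) v += w11 * vol[z + (R_xlen_t)nz * (y0 + (R_xlen_t)ny * x0)];
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = v;
      }
    }
  }
  return out;
}

// Poisson shot noise (photon_scale photons per intensity unit; non-finite
// scale disables it) followed by Gaussian read noise, rounded and clamped
// to the 16-bit range. Uses R's RNG stream.
// [[Rcpp::export]]
NumericVector sensor_noise(NumericVector vol, double photon_scale,
                           double read_noise_sd) {
  const R_xlen_t n = vol.size();
  NumericVector out(n);
  const bool shot = R_FINITE(photon_scale) && photon_scale > 0;
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = vol[i];
    if (shot) v = ::Rf_rpois(v * photon_scale) / photon_scale;
    if (read_noise_sd > 0) v += ::Rf_rnorm(0.0, read_noise_sd);
    v = std::nearbyint(v);
    if (v < 0) v = 0;
    if (v > 65535) v = 65535;
    out[i] = v;
  }
  PutRNGstate();
  return out;
}
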