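#include <Rcpp.h>
using namespace Rcpp;

// symmetric (half-sample reflection) boundary: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Correlate a 3D array with a 1D kernel along one axis (0-based axis index).
// out[p] = sum_t kernel[t] * x[p + t - origin], symmetric padding.
// [[Rcpp::export]]
NumericVector cpp_conv1d_axis(NumericVector arr, IntegerVector dim,
                              NumericVector kernel, int axis, int origin) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2], K = kernel.size();
  const int nAx = (axis == 0) ? n1 : ((axis == 1) ? n2 : n3);
  NumericVector out(arr.size());
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int pos = (axis == 0) ? i : ((axis == 1) ? j : k);
        double acc = 0.0;
        for (int t = 0; t < K; ++t) {
          const int q = reflect_index(pos + t - origin, nAx);
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii = q; else if (axis == 1) jj = q; else kk = q;
          acc += kernel[t] * arr[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)];
        }
        out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// Resample a 3D volume onto a new isotropic grid.
// Voxel centre of output voxel i sits at (i + 0.5) * newSpacing (per axis, mm);
// mapped to continuous input index (pos / spacing) - 0.5.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, NumericVector newSpacing,
                           bool nearest) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int m1 = (int)std::round(n1 * spacing[0] / newSpacing[0]);
  int m2 = (int)std::round(n2 * spacing[1] / newSpacing[1]);
  int m3 = (int)std::round(n3 * spacing[2] / newSpacing[2]);
  if (m1 < 1) m1 = 1; if (m2 < 1) m2 = 1; if (m3 < 1) m3 = 1;
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  for (int k = 0; k < m3; ++k)
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i) {
        double x = ((i + 0.5) * newSpacing[0]) / spacing[0] - 0.5;
        double y = ((j + 0.5) * newSpacing[1]) / spacing[1] - 0.5;
        double z = ((k + 0.5) * newSpacing[2]) / spacing[2] - 0.5;
        double val;
        if (nearest) {
          int xi = (int)std::round(x), yi = (int)std::round(y), zi = (int)std::round(z);
          xi = std::min(std::max(xi, 0), n1 - 1);
          yi = std::min(std::max(yi, 0), n2 - 1);
          zi = std::min(std::max(zi, 0), n3 - 1);
          val = vol[xi + (R_xlen_t)n1 * (yi + (R_xlen_t)n2 * zi)];
        } else {
          x = std::min(std::max(x, 0.0), (double)(n1 - 1));
          y = std::min(std::max(y, 0.0), (double)(n2 - 1));
          z = std::min(std::max(z, 0.0), (double)(n3 - 1));
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
          int x1 = std::min(x0 + 1, n1 - 1), y1 = std::min(y0 + 1, n2 - 1), z1 = std::min(z0 + 1, n3 - 1);
          double fx = x - x0, fy = y - y0, fz = z - z0;
          auto at = [&](int a, int b, int c) {
            return vol[a + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c)];
          };
          val =
            at(x0,y0,z0) * (1-fx)*(1-fy)*(1-fz) + at(x1,y0,z0) * fx*(1-fy)*(1-fz) +
            at(x0,y1,z0) * (1-fx)*fy*(1-fz)     + at(x1,y1,z0) * fx*fy*(1-fz) +
            at(x0,y0,z1) * (1-fx)*(1-fy)*fz     + at(x1,y0,z1) * fx*(1-fy)*fz +
            at(x0,y1,z1) * (1-fx)*fy*fz         + at(x1,y1,z1) * fx*fy*fz;
        }
        out[i + (R_xlen_t)m1 * (j + (R_xlen_t)m2 * k)] = val;
      }
  out.attr("dim") = IntegerVector::create(m1, m2, m3);
  return out;
}
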