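#include <Rcpp.h>
using namespace Rcpp;

// The 13 unique 3D offsets at Chebyshev distance 1 (26-connectivity, up to sign).
static const int DIRS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{-1,1,1}
};

// Symmetric per-direction co-occurrence counts at distance 1.
// levels: integer grid, 0 outside the ROI, 1..ng inside.
// Returns ng x ng x 13 counts; each in-mask pair contributes to (a,b) and (b,a).
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector out((R_xlen_t)ng * ng * 13);
  auto lev = [&](int i, int j, int k) {
    return levels[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
  };
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          const int a = lev(i, j, k);
          if (a <= 0) continue;
          const int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
          const int b = lev(ii, jj, kk);
          if (b <= 0) continue;
          out[(a - 1) + (R_xlen_t)ng * ((b - 1) + (R_xlen_t)ng * d)] += 1.0;
          out[(b - 1) + (R_xlen_t)ng * ((a - 1) + (R_xlen_t)ng * d)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length matrices over the 13 directions.
// Returns ng x maxlen x 13; runs are maximal same-level segments of in-mask
// voxels along each direction (out-of-mask voxels break runs).
// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int maxlen = std::max(n1, std::max(n2, n3));
  NumericVector out((R_xlen_t)ng * maxlen * 13);
  auto lev = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) return 0;
    return levels[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
  };
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          const int a = lev(i, j, k);
          if (a <= 0) continue;
          // only start runs where the previous voxel does not continue them
          if (lev(i - dx, j - dy, k - dz) == a) continue;
          int len = 1;
          while (lev(i + len * dx, j + len * dy, k + len * dz) == a) ++len;
          out[(a - 1) + (R_xlen_t)ng * ((len - 1) + (R_xlen_t)maxlen * d)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// Rotation-invariant uniform LBP (8 neighbours, radius 1), slice by slice
// along the third axis. Neighbour intensities are taken from the image
// regardless of mask membership; the centre pixel must be in-mask and have a
// complete 3x3 in-slice neighbourhood. Returns 10 pooled code counts
// (codes 0..8 uniform, 9 non-uniform) and the number of coded pixels.
// [[Rcpp::export]]
List cpp_lbp_hist(NumericVector vol, IntegerVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  // circular neighbour order
  static const int OFF[8][2] = {
    {-1,-1},{0,-1},{1,-1},{1,0},{1,1},{0,1},{-1,1},{-1,0}
  };
  NumericVector hist(10);
  double nvalid = 0.0;
  auto at = [&](int i, int j, int k) {
    return vol[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
  };
  auto inmask = [&](int i, int j, int k) {
    return mask[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] != 0;
  };
  for (int k = 0; k < n3; ++k)
    for (int j = 1; j < n2 - 1; ++j)
      for (int i = 1; i < n1 - 1; ++i) {
        if (!inmask(i, j, k)) continue;
        const double c = at(i, j, k);
        int bits[8];
        for (int t = 0; t < 8; ++t)
          bits[t] = at(i + OFF[t][0], j + OFF[t][1], k) >= c ? 1 : 0;
        int trans = 0, ones = 0;
        for (int t = 0; t < 8; ++t) {
          ones += bits[t];
          if (bits[t] != bits[(t + 1) % 8]) ++trans;
        }
        const int code = (trans <= 2) ? ones : 9;
        hist[code] += 1.0;
        nvalid += 1.0;
      }
  return List::create(_["counts"] = hist, _["n"] = nvalid);
}
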