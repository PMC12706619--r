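#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour label resampling under an inverse rigid map, restricted
// to the output block [lo, hi] (0-based voxel indices). For each output
// voxel center p the source point is q = Ri (p - pivot) + off, rounded
// half-up to a voxel index; out-of-grid sources stay background.
// [[Rcpp::export(name = ".nn_resample_cpp")]]
IntegerVector nn_resample_cpp(IntegerVector grid, IntegerVector dim,
                              IntegerVector lo, IntegerVector hi,
                              NumericVector origin, NumericVector spacing,
                              NumericMatrix Ri, NumericVector pivot,
                              NumericVector off) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const double r11 = Ri(0,0), r12 = Ri(0,1), r13 = Ri(0,2);
  const double r21 = Ri(1,0), r22 = Ri(1,1), r23 = Ri(1,2);
  const double r31 = Ri(2,0), r32 = Ri(2,1), r33 = Ri(2,2);
  for (int k = lo[2]; k <= hi[2]; ++k) {
    double pz = k * spacing[2] + origin[2] - pivot[2];
    for (int j = lo[1]; j <= hi[1]; ++j) {
      double py = j * spacing[1] + origin[1] - pivot[1];
      for (int i = lo[0]; i <= hi[0]; ++i) {
        double px = i * spacing[0] + origin[0] - pivot[0];
        double qx = r11 * px + r12 * py + r13 * pz + off[0];
        double qy = r21 * px + r22 * py + r23 * pz + off[1];
        double qz = r31 * px + r32 * py + r33 * pz + off[2];
        int si = (int)std::floor((qx - origin[0]) / spacing[0] + 0.5);
        int sj = (int)std::floor((qy - origin[1]) / spacing[1] + 0.5);
        int sk = (int)std::floor((qz - origin[2]) / spacing[2] + 0.5);
        if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
          continue;
        int v = grid[si + (R_xlen_t)nx * (sj + (R_xlen_t)ny * sk)];
        if (v != 0)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = v;
      }
    }
  }
  return out;
}

// Voxel-center inclusion test for an (optionally rotated) ellipsoid over
// the block [lo, hi]: a center p is inside when the back-mapped point
// q = R^T (p - pivot) + pivot satisfies sum(((q - c)/s)^2) < 1 (strict).
// Spheres are ellipsoids with equal semiaxes. Sets matching voxels of
// `grid` to 1 in place (grid is modified and also returned).
// [[Rcpp::export(name = ".fill_ellipsoid_cpp")]]
IntegerVector fill_ellipsoid_cpp(IntegerVector grid, IntegerVector dim,
                                 IntegerVector lo, IntegerVector hi,
                                 NumericVector origin, NumericVector spacing,
                                 NumericMatrix R, NumericVector pivot,
                                 NumericVector center, NumericVector semi) {
  const int nx = dim[0], ny = dim[1];
  // back-map uses R^T
  const double r11 = R(0,0), r12 = R(1,0), r13 = R(2,0);
  const double r21 = R(0,1), r22 = R(1,1), r23 = R(2,1);
  const double r31 = R(0,2), r32 = R(1,2), r33 = R(2,2);
  const double ax = semi[0], ay = semi[1], az = semi[2];
  for (int k = lo[2]; k <= hi[2]; ++k) {
    double pz = k * spacing[2] + origin[2] - pivot[2];
    for (int j = lo[1]; j <= hi[1]; ++j) {
      double py = j * spacing[1] + origin[1] - pivot[1];
      for (int i = lo[0]; i <= hi[0]; ++i) {
        double px = i * spacing[0] + origin[0] - pivot[0];
        double qx = (r11 * px + r12 * py + r13 * pz + pivot[0] - center[0]) / ax;
        double qy = (r21 * px + r22 * py + r23 * pz + pivot[1] - center[1]) / ay;
        double qz = (r31 * px + r32 * py + r33 * pz + pivot[2] - center[2]) / az;
        if (qx * qx + qy * qy + qz * qz < 1.0)
          grid[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
      }
    }
  }
  return grid;
}
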