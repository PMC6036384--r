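#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Noise-free rasterization of a continuous scene (marker cylinders over an
// ellipsoidal body containing ellipsoidal blobs, air elsewhere) onto a voxel
// grid given by a 0-based voxel->world affine. Each voxel averages sup^3
// point samples over its sensitive volume: the full in-plane footprint and,
// through-plane, the fraction z_frac of the voxel (slice thickness divided by
// the reconstructed inter-slice spacing; the slice-gap region contributes
// nothing). Composition priority at a sample point: marker cylinder, then
// first containing blob (only inside the body), then body, then air (0).
//
// cylinders: m x 9  (cx,cy,cz, ax,ay,az, radius, half_length, value)
// body:      length 7 (cx,cy,cz, sx,sy,sz, value) or length 0 for no body
// blobs:     m x 7  (cx,cy,cz, sx,sy,sz, value)
// [[Rcpp::export(name = ".rasterize_scene")]]
NumericVector rasterize_scene(IntegerVector dims, NumericMatrix affine,
                              int sup, double z_frac,
                              NumericMatrix cylinders,
                              NumericVector body,
                              NumericMatrix blobs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, 0.0);

  const int ncyl = cylinders.nrow();
  const int nblob = blobs.nrow();
  const bool has_body = body.size() >= 7;

  // affine columns
  double m[3][3], t[3];
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) m[r][c] = affine(r, c);
    t[r] = affine(r, 3);
  }
  // voxel world diagonal, used as margin for the coarse center test
  double diag = 0.0;
  for (int c = 0; c < 3; ++c) {
    double cl = std::sqrt(m[0][c] * m[0][c] + m[1][c] * m[1][c] + m[2][c] * m[2][c]);
    diag += cl * cl;
  }
  diag = std::sqrt(diag);

  // conservative world-space bounding boxes per primitive
  const int nprim = ncyl + (has_body ? 1 : 0) + nblob;
  std::vector<double> blo(3 * nprim), bhi(3 * nprim);
  int p = 0;
  for (int c = 0; c < ncyl; ++c, ++p) {
    double r = cylinders(c, 6) + cylinders(c, 7);
    for (int a = 0; a < 3; ++a) {
      blo[3 * p + a] = cylinders(c, a) - r;
      bhi[3 * p + a] = cylinders(c, a) + r;
    }
  }
  if (has_body) {
    for (int a = 0; a < 3; ++a) {
      blo[3 * p + a] = body[a] - body[3 + a];
      bhi[3 * p + a] = body[a] + body[3 + a];
    }
    ++p;
  }
  for (int b = 0; b < nblob; ++b, ++p) {
    for (int a = 0; a < 3; ++a) {
      blo[3 * p + a] = blobs(b, a) - blobs(b, 3 + a);
      bhi[3 * p + a] = blobs(b, a) + blobs(b, 3 + a);
    }
  }

  // supersampling offsets in voxel units
  std::vector<double> off(sup);
  for (int s = 0; s < sup; ++s) off[s] = (s + 0.5) / sup - 0.5;
  const double inv_ns = 1.0 / ((double)sup * sup * sup);

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        // coarse test on the voxel center
        double cx = m[0][0] * i + m[0][1] * j + m[0][2] * k + t[0];
        double cy = m[1][0] * i + m[1][1] * j + m[1][2] * k + t[1];
        double cz = m[2][0] * i + m[2][1] * j + m[2][2] * k + t[2];
        bool near = false;
        for (int q = 0; q < nprim && !near; ++q) {
          if (cx >= blo[3 * q] - diag && cx <= bhi[3 * q] + diag &&
              cy >= blo[3 * q + 1] - diag && cy <= bhi[3 * q + 1] + diag &&
              cz >= blo[3 * q + 2] - diag && cz <= bhi[3 * q + 2] + diag)
            near = true;
        }
        if (!near) continue;

        double acc = 0.0;
        for (int sk = 0; sk < sup; ++sk) {
          double w = k + off[sk] * z_frac;
          for (int sj = 0; sj < sup; ++sj) {
            double v = j + off[sj];
            for (int si = 0; si < sup; ++si) {
              double u = i + off[si];
              double px = m[0][0] * u + m[0][1] * v + m[0][2] * w + t[0];
              double py = m[1][0] * u + m[1][1] * v + m[1][2] * w + t[1];
              double pz = m[2][0] * u + m[2][1] * v + m[2][2] * w + t[2];
              double val = 0.0;
              bool done = false;
              for (int c = 0; c < ncyl && !done; ++c) {
                double dx = px - cylinders(c, 0);
                double dy = py - cylinders(c, 1);
                double dz = pz - cylinders(c, 2);
                double ax = dx * cylinders(c, 3) + dy * cylinders(c, 4) +
                            dz * cylinders(c, 5);
                if (std::fabs(ax) > cylinders(c, 7)) continue;
                double rad2 = dx * dx + dy * dy + dz * dz - ax * ax;
                if (rad2 <= cylinders(c, 6) * cylinders(c, 6)) {
                  val = cylinders(c, 8);
                  done = true;
                }
              }
              if (!done && has_body) {
                double ex = (px - body[0]) / body[3];
                double ey = (py - body[1]) / body[4];
                double ez = (pz - body[2]) / body[5];
                if (ex * ex + ey * ey + ez * ez <= 1.0) {
                  val = body[6];
                  for (int b = 0; b < nblob; ++b) {
                    double bx = (px - blobs(b, 0)) / blobs(b, 3);
                    double by = (py - blobs(b, 1)) / blobs(b, 4);
                    double bz = (pz - blobs(b, 2)) / blobs(b, 5);
                    if (bx * bx + by * by + bz * bz <= 1.0) {
                      val = blobs(b, 6);
                      break;
                    }
                  }
                }
              }
              acc += val;
            }
          }
        }
        out[idx] = acc * inv_ns;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
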