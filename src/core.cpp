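#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// half-sample symmetric reflection: ... c b a | a b c ... | c b a
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Separable 2D convolution with reflective boundary. Implemented over
// reflect-padded buffers so the inner loops run on contiguous memory.
// [[Rcpp::export]]
NumericMatrix cpp_sep_conv(const NumericMatrix& img,
                           const NumericVector& ky,
                           const NumericVector& kx) {
  int nr = img.nrow(), nc = img.ncol();
  int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  // pass 1: convolve along rows (y), rows padded by reflection
  std::vector<double> colbuf(nr + 2 * ry);
  NumericMatrix tmp(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double* in = &img(0, c);
    for (int t = -ry; t < nr + ry; ++t)
      colbuf[t + ry] = in[reflect_idx(t, nr)];
    double* o = &tmp(0, c);
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      const double* src = colbuf.data() + r;
      for (int k = 0; k <= 2 * ry; ++k) acc += ky[k] * src[k];
      o[r] = acc;
    }
  }
  // pass 2: convolve along columns (x); accumulate column-contiguous slices
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double* o = &out(0, c);
    for (int k = -rx; k <= rx; ++k) {
      const double* src = &tmp(0, reflect_idx(c + k, nc));
      double w = kx[k + rx];
      for (int r = 0; r < nr; ++r) o[r] += w * src[r];
    }
  }
  return out;
}

// Subpixel centerline refinement: move each path point transverse to its
// local direction onto the response-weighted centroid of the ridge profile.
// px: n x 2 (row, col) positions (1-based, fractional allowed).
// [[Rcpp::export]]
NumericMatrix cpp_refine_centerline(const NumericMatrix& px0,
                                    const NumericMatrix& resp,
                                    int iters, double halfWidth) {
  int n = px0.nrow();
  NumericMatrix px = clone(px0);
  if (n < 5) return px;
  int nr = resp.nrow(), nc = resp.ncol();
  auto bilin = [&](double y, double x) -> double {
    if (y < 1) y = 1; if (y > nr - 1e-6) y = nr - 1e-6;
    if (x < 1) x = 1; if (x > nc - 1e-6) x = nc - 1e-6;
    int y0 = (int)y, x0 = (int)x;
    double fy = y - y0, fx = x - x0;
    return resp(y0 - 1, x0 - 1) * (1 - fy) * (1 - fx) +
           resp(y0, x0 - 1) * fy * (1 - fx) +
           resp(y0 - 1, x0) * (1 - fy) * fx +
           resp(y0, x0) * fy * fx;
  };
  for (int it = 0; it < iters; ++it) {
    NumericMatrix snap = clone(px);
    for (int i = 0; i < n; ++i) {
      int k = i; if (k < 2) k = 2; if (k > n - 3) k = n - 3;
      double dy = snap(k + 2, 0) - snap(k - 2, 0);
      double dx = snap(k + 2, 1) - snap(k - 2, 1);
      double len = std::sqrt(dy * dy + dx * dx);
      if (len == 0) len = 1;
      double ty = -dx / len, tx = dy / len;
      double num = 0, den = 0;
      for (double o = -halfWidth; o <= halfWidth + 1e-9; o += 0.5) {
        double w = bilin(snap(i, 0) + o * ty, snap(i, 1) + o * tx);
        num += o * w; den += w;
      }
      double delta = den > 0 ? num / den : 0.0;
      if (delta > 2) delta = 2; if (delta < -2) delta = -2;
      px(i, 0) = snap(i, 0) + delta * ty;
      px(i, 1) = snap(i, 1) + delta * tx;
    }
  }
  // moving-average smoothing removes the residual staircase wiggle
  if (n >= 7) {
    NumericMatrix sm = clone(px);
    for (int j = 0; j < 2; ++j) {
      for (int i = 0; i < n; ++i) {
        int lo = std::max(0, i - 2), hi = std::min(n - 1, i + 2);
        double acc = 0;
        for (int t = lo; t <= hi; ++t) acc += px(t, j);
        sm(i, j) = acc / (hi - lo + 1);
      }
    }
    px = sm;
  }
  return px;
}

// Grayscale erosion/dilation with a non-flat structuring function.
// se is a (2r+1)x(2r+1) matrix of heights (<= 0), NA outside the support.
// Window pixels falling outside the image are ignored (border handling).
// Implementation: one vectorizable shifted pass per SE entry.
static NumericMatrix gray_morph(const NumericMatrix& img,
                                const NumericMatrix& se, bool erode) {
  int nr = img.nrow(), nc = img.ncol();
  int sr = se.nrow(), sc = se.ncol();
  int ry = (sr - 1) / 2, rx = (sc - 1) / 2;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), erode ? R_PosInf : R_NegInf);
  const double* in = img.begin();
  double* o = out.begin();
  for (int a = 0; a < sr; ++a) {
    for (int b = 0; b < sc; ++b) {
      if (NumericMatrix::is_na(se(a, b))) continue;
      int dy = a - ry, dx = b - rx;
      if (!erode) { dy = -dy; dx = -dx; }
      double h = se(a, b);
      int c0 = std::max(0, -dx), c1 = std::min(nc, nc - dx);
      int r0 = std::max(0, -dy), r1 = std::min(nr, nr - dy);
      for (int c = c0; c < c1; ++c) {
        const double* src = in + (R_xlen_t)(c + dx) * nr + dy;
        double* dst = o + (R_xlen_t)c * nr;
        if (erode) {
          for (int r = r0; r < r1; ++r) {
            double v = src[r] - h;
            if (v < dst[r]) dst[r] = v;
          }
        } else {
          for (int r = r0; r < r1; ++r) {
            double v = src[r] + h;
            if (v > dst[r]) dst[r] = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img, const NumericMatrix& se) {
  return gray_morph(img, se, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img, const NumericMatrix& se) {
  return gray_morph(img, se, false);
}

// Zhang-Suen thinning of a binary image (0/1 integer matrix) to a 1-px skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int,int>> kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          int p2 = P(r-1,c), p3 = P(r-1,c+1), p4 = P(r,c+1), p5 = P(r+1,c+1),
              p6 = P(r+1,c), p7 = P(r+1,c-1), p8 = P(r,c-1), p9 = P(r-1,c-1);
          int B = p2+p3+p4+p5+p6+p7+p8+p9;
          if (B < 2 || B > 6) continue;
          int A = (p2==0&&p3==1)+(p3==0&&p4==1)+(p4==0&&p5==1)+(p5==0&&p6==1)+
                  (p6==0&&p7==1)+(p7==0&&p8==1)+(p8==0&&p9==1)+(p9==0&&p2==1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2*p4*p6 != 0 || p4*p6*p8 != 0) continue;
          } else {
            if (p2*p4*p8 != 0 || p2*p6*p8 != 0) continue;
          }
          kill.push_back({r, c});
        }
      }
      if (!kill.empty()) changed = true;
      for (auto& rc : kill) img(rc.first, rc.second) = 0;
    }
  }
  return img;
}

// 8-connected labeling of a binary image (0/1 integer matrix).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + nr * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dy && !dx) continue;
            int rr = pr + dy, cc = pc + dx;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Trace the branches of a junction-free skeleton (0/1 matrix): label the
// 8-connected components and order each one's pixels by walking from an
// endpoint. Returns a list of n x 2 matrices of 1-based (row, col).
// [[Rcpp::export]]
List cpp_trace_branches(const IntegerMatrix& seg) {
  int nr = seg.nrow(), nc = seg.ncol();
  std::vector<signed char> visited((size_t)nr * nc, 0);
  auto at = [&](int r, int c) -> bool {
    return r >= 0 && r < nr && c >= 0 && c < nc && seg(r, c);
  };
  auto degree = [&](int r, int c) {
    int d = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dy && !dx) continue;
        if (at(r + dy, c + dx)) ++d;
      }
    return d;
  };
  List out;
  std::vector<int> rows, cols;
  // two passes: start at endpoints first, then mop up cycles
  for (int pass = 0; pass < 2; ++pass) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!seg(r, c) || visited[(size_t)r + (size_t)nr * c]) continue;
        if (pass == 0 && degree(r, c) > 1) continue;
        rows.clear(); cols.clear();
        int cr = r, cc = c;
        while (true) {
          visited[(size_t)cr + (size_t)nr * cc] = 1;
          rows.push_back(cr + 1); cols.push_back(cc + 1);
          int nrr = -1, ncc = -1;
          for (int dy = -1; dy <= 1 && nrr < 0; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dy && !dx) continue;
              int rr = cr + dy, c2 = cc + dx;
              if (at(rr, c2) && !visited[(size_t)rr + (size_t)nr * c2]) {
                nrr = rr; ncc = c2; break;
              }
            }
          if (nrr < 0) break;
          cr = nrr; cc = ncc;
        }
        IntegerMatrix m((int)rows.size(), 2);
        for (int k = 0; k < (int)rows.size(); ++k) {
          m(k, 0) = rows[k]; m(k, 1) = cols[k];
        }
        out.push_back(m);
      }
    }
  }
  return out;
}

// Render fiber tubes into a 3D binary mask.
// segs: rows of (y1, x1, z1, y2, x2, z2, radius), all in micrometres.
// dims: (ny, nx, nz); voxel: (vy, vx, vz) um per pixel. Voxel centres sit at
// ((i-1)*vy, (j-1)*vx, (k-1)*vz) for 1-based indices, i.e. 0-based * voxel.
// [[Rcpp::export]]
IntegerVector cpp_render_tubes(const NumericMatrix& segs,
                               const IntegerVector& dims,
                               const NumericVector& voxel) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  double vy = voxel[0], vx = voxel[1], vz = voxel[2];
  IntegerVector out(ny * (R_xlen_t)nx * nz, 0);
  out.attr("dim") = dims;
  for (int s = 0; s < segs.nrow(); ++s) {
    double y1 = segs(s,0), x1 = segs(s,1), z1 = segs(s,2);
    double y2 = segs(s,3), x2 = segs(s,4), z2 = segs(s,5);
    double rad = segs(s,6), rad2 = rad * rad;
    double dy = y2-y1, dx = x2-x1, dz = z2-z1;
    double len2 = dy*dy + dx*dx + dz*dz;
    // bounding box in voxel indices
    int i0 = std::max(0, (int) std::floor((std::min(y1,y2) - rad) / vy));
    int i1 = std::min(ny-1, (int) std::ceil((std::max(y1,y2) + rad) / vy));
    int j0 = std::max(0, (int) std::floor((std::min(x1,x2) - rad) / vx));
    int j1 = std::min(nx-1, (int) std::ceil((std::max(x1,x2) + rad) / vx));
    int k0 = std::max(0, (int) std::floor((std::min(z1,z2) - rad) / vz));
    int k1 = std::min(nz-1, (int) std::ceil((std::max(z1,z2) + rad) / vz));
    for (int k = k0; k <= k1; ++k) {
      double pz = k * vz;
      for (int j = j0; j <= j1; ++j) {
        double px = j * vx;
        for (int i = i0; i <= i1; ++i) {
          double py = i * vy;
          double wy = py-y1, wx = px-x1, wz = pz-z1;
          double t = len2 > 0 ? (wy*dy + wx*dx + wz*dz) / len2 : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double qy = wy - t*dy, qx = wx - t*dx, qz = wz - t*dz;
          if (qy*qy + qx*qx + qz*qz <= rad2)
            out[i + (R_xlen_t)ny * (j + (R_xlen_t)nx * k)] = 1;
        }
      }
    }
  }
  return out;
}

static inline double clamp01(double t) { return t < 0 ? 0 : (t > 1 ? 1 : t); }

// Closest-approach events between two polylines (n x 3 matrices of y,x,z um).
// Returns a matrix with one row per segment pair whose minimum distance is
// <= dmax: (ia, ib, dist, y, x, z, angA_deg, angB_deg); angles are in-plane
// (y-x) tangent orientations in [0, 180), measured from the +y axis.
// [[Rcpp::export]]
NumericMatrix cpp_polyline_contacts(const NumericMatrix& A,
                                    const NumericMatrix& B,
                                    double dmax) {
  int na = A.nrow() - 1, nb = B.nrow() - 1;
  std::vector<double> rows;
  for (int i = 0; i < na; ++i) {
    double p1y=A(i,0), p1x=A(i,1), p1z=A(i,2);
    double d1y=A(i+1,0)-p1y, d1x=A(i+1,1)-p1x, d1z=A(i+1,2)-p1z;
    for (int j = 0; j < nb; ++j) {
      double p2y=B(j,0), p2x=B(j,1), p2z=B(j,2);
      double d2y=B(j+1,0)-p2y, d2x=B(j+1,1)-p2x, d2z=B(j+1,2)-p2z;
      // closest approach of two segments (standard clamped solution)
      double ry=p1y-p2y, rx=p1x-p2x, rz=p1z-p2z;
      double a = d1y*d1y+d1x*d1x+d1z*d1z;
      double e = d2y*d2y+d2x*d2x+d2z*d2z;
      double f = d2y*ry+d2x*rx+d2z*rz;
      double s, t;
      if (a <= 1e-12 && e <= 1e-12) { s = 0; t = 0; }
      else if (a <= 1e-12) { s = 0; t = clamp01(f / e); }
      else {
        double c = d1y*ry+d1x*rx+d1z*rz;
        if (e <= 1e-12) { t = 0; s = clamp01(-c / a); }
        else {
          double b = d1y*d2y+d1x*d2x+d1z*d2z;
          double denom = a*e - b*b;
          s = denom > 1e-12 ? clamp01((b*f - c*e) / denom) : 0.0;
          t = clamp01((b*s + f) / e);
          s = clamp01((b*t - c) / a);
        }
      }
      double q1y=p1y+s*d1y, q1x=p1x+s*d1x, q1z=p1z+s*d1z;
      double q2y=p2y+t*d2y, q2x=p2x+t*d2x, q2z=p2z+t*d2z;
      double ddy=q1y-q2y, ddx=q1x-q2x, ddz=q1z-q2z;
      double dist = std::sqrt(ddy*ddy + ddx*ddx + ddz*ddz);
      if (dist <= dmax) {
        // map atan2 range (-180, 180] onto the undirected range [0, 180)
        double angA = std::atan2(d1x, d1y) * 180.0 / M_PI;
        double angB = std::atan2(d2x, d2y) * 180.0 / M_PI;
        if (angA < 0) angA += 180.0;
        if (angB < 0) angB += 180.0;
        if (angA >= 180.0) angA -= 180.0;
        if (angB >= 180.0) angB -= 180.0;
        rows.insert(rows.end(), { (double)(i+1), (double)(j+1), dist,
          0.5*(q1y+q2y), 0.5*(q1x+q2x), 0.5*(q1z+q2z), angA, angB });
      }
    }
  }
  int n = (int)(rows.size() / 8);
  NumericMatrix out(n, 8);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < 8; ++c) out(r, c) = rows[r*8 + c];
  colnames(out) = CharacterVector::create("seg_a","seg_b","dist","y","x","z",
                                          "ang_a","ang_b");
  return out;
}
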