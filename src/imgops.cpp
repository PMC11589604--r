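#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Images are numeric matrices in [0,1]; pixel (x, y) (0-based, x = column,
// y = row) lives at mat(y, x). Bilinear sampling everywhere.

static inline double sample_bilinear(const NumericMatrix& img, double x, double y,
                                     bool& ok) {
  int h = img.nrow(), w = img.ncol();
  if (x < 0 || y < 0 || x > w - 1.0 || y > h - 1.0) { ok = false; return 0.0; }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
  double fx = x - x0, fy = y - y0;
  ok = true;
  return img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy) +
         img(y1, x0) * (1 - fx) * fy + img(y1, x1) * fx * fy;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& v : k) v /= s;
  NumericMatrix tmp(h, w), out(h, w);
  // horizontal pass, reflected borders
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xi = x + i;
        if (xi < 0) xi = -xi;
        if (xi > w - 1) xi = 2 * (w - 1) - xi;
        acc += img(y, xi) * k[i + r];
      }
      tmp(y, x) = acc;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int yi = y + i;
        if (yi < 0) yi = -yi;
        if (yi > h - 1) yi = 2 * (h - 1) - yi;
        acc += tmp(yi, x) * k[i + r];
      }
      out(y, x) = acc;
    }
  return out;
}

// Generic inverse-map resampling: out(i) = src(xmap(i), ymap(i)).
// [[Rcpp::export]]
List cpp_remap(const NumericMatrix& src, const NumericMatrix& xmap,
               const NumericMatrix& ymap, double fill) {
  int h = xmap.nrow(), w = xmap.ncol();
  NumericMatrix out(h, w);
  LogicalMatrix valid(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      bool ok;
      double v = sample_bilinear(src, xmap(y, x), ymap(y, x), ok);
      out(y, x) = ok ? v : fill;
      valid(y, x) = ok;
    }
  return List::create(_["pixels"] = out, _["valid"] = valid);
}

// 3D local extrema of a difference-of-Gaussian stack (list of matrices,
// same size). Returns candidates as rows (x, y, layer, value), 0-based
// x/y, 1-based layer index into `dogs` for interior layers only.
// [[Rcpp::export]]
NumericMatrix cpp_dog_extrema(const List& dogs, double thresh, int border) {
  int n = dogs.size();
  std::vector<NumericMatrix> d(n);
  for (int i = 0; i < n; ++i) d[i] = as<NumericMatrix>(dogs[i]);
  int h = d[0].nrow(), w = d[0].ncol();
  std::vector<double> rows;
  for (int l = 1; l < n - 1; ++l) {
    for (int y = border; y < h - border; ++y)
      for (int x = border; x < w - border; ++x) {
        double v = d[l](y, x);
        if (std::fabs(v) < thresh) continue;
        bool mx = true, mn = true;
        for (int dl = -1; dl <= 1 && (mx || mn); ++dl)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dl == 0 && dy == 0 && dx == 0) continue;
              double u = d[l + dl](y + dy, x + dx);
              if (u >= v) mx = false;
              if (u <= v) mn = false;
            }
        if (mx || mn) {
          rows.push_back(x); rows.push_back(y);
          rows.push_back(l + 1); rows.push_back(v);
        }
      }
  }
  int m = rows.size() / 4;
  NumericMatrix out(m, 4);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = rows[4 * i + j];
  return out;
}

// Dominant gradient orientation per keypoint (36-bin Gaussian-weighted
// histogram with parabolic peak refinement). kps columns: x, y, sigma.
// [[Rcpp::export]]
NumericVector cpp_orientations(const NumericMatrix& img, const NumericMatrix& kps) {
  int h = img.nrow(), w = img.ncol(), n = kps.nrow();
  NumericVector th(n);
  for (int i = 0; i < n; ++i) {
    double cx = kps(i, 0), cy = kps(i, 1), sg = kps(i, 2);
    double wsig = 1.5 * sg;
    int r = std::max(2, (int)std::ceil(3.0 * wsig));
    double hist[36] = {0};
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx) {
        int x = (int)std::round(cx) + dx, y = (int)std::round(cy) + dy;
        if (x < 1 || y < 1 || x > w - 2 || y > h - 2) continue;
        double gx = 0.5 * (img(y, x + 1) - img(y, x - 1));
        double gy = 0.5 * (img(y + 1, x) - img(y - 1, x));
        double mag = std::sqrt(gx * gx + gy * gy);
        double wgt = std::exp(-0.5 * (dx * dx + dy * dy) / (wsig * wsig));
        double ang = std::atan2(gy, gx); // (-pi, pi]
        int bin = (int)std::floor((ang + M_PI) / (2 * M_PI) * 36.0);
        if (bin < 0) bin = 0;
        if (bin > 35) bin = 35;
        hist[bin] += mag * wgt;
      }
    // smooth the histogram once (circular box of 3)
    double sm[36];
    for (int b = 0; b < 36; ++b)
      sm[b] = (hist[(b + 35) % 36] + hist[b] + hist[(b + 1) % 36]) / 3.0;
    int bmax = 0;
    for (int b = 1; b < 36; ++b) if (sm[b] > sm[bmax]) bmax = b;
    double l = sm[(bmax + 35) % 36], c = sm[bmax], rr = sm[(bmax + 1) % 36];
    double denom = l - 2 * c + rr;
    double off = (std::fabs(denom) > 1e-12) ? 0.5 * (l - rr) / denom : 0.0;
    if (off < -0.5) off = -0.5;
    if (off > 0.5) off = 0.5;
    th[i] = -M_PI + (bmax + 0.5 + off) * (2 * M_PI / 36.0);
  }
  return th;
}

// Rotation/scale-normalized patch descriptors: an n x n grid of bilinear
// samples with spacing spacing_mult * sigma, rotated by theta, mean-removed
// and L2-normalized. kps columns: x, y, sigma, theta.
// [[Rcpp::export]]
NumericMatrix cpp_patch_descriptors(const NumericMatrix& img, const NumericMatrix& kps,
                                    int n, double spacing_mult) {
  int nk = kps.nrow();
  NumericMatrix out(nk, n * n);
  double c0 = (n - 1) / 2.0;
  for (int i = 0; i < nk; ++i) {
    double cx = kps(i, 0), cy = kps(i, 1), sg = kps(i, 2), th = kps(i, 3);
    double sp = spacing_mult * sg;
    double ct = std::cos(th), st = std::sin(th);
    double sum = 0.0;
    std::vector<double> v(n * n);
    for (int r = 0; r < n; ++r)
      for (int c = 0; c < n; ++c) {
        double u = (c - c0) * sp, w2 = (r - c0) * sp;
        double x = cx + ct * u - st * w2;
        double y = cy + st * u + ct * w2;
        bool ok;
        double s = sample_bilinear(img, x, y, ok);
        v[r * n + c] = ok ? s : 0.0;
        sum += v[r * n + c];
      }
    double mean = sum / (n * n), nrm = 0.0;
    for (int j = 0; j < n * n; ++j) { v[j] -= mean; nrm += v[j] * v[j]; }
    nrm = std::sqrt(nrm);
    if (nrm < 1e-9) nrm = 1.0;
    for (int j = 0; j < n * n; ++j) out(i, j) = v[j] / nrm;
  }
  return out;
}

// Warp `frame` (with logical mask) into `canvas` through the 2x3 inverse
// pose (canvas -> frame), writing only inside the bounding box
// [x0,x1] x [y0,y1] (0-based, inclusive). Last-writer-wins. Returns the
// updated canvas and coverage mask.
// [[Rcpp::export]]
List cpp_warp_into(const NumericMatrix& canvas, const LogicalMatrix& cmask,
                   const NumericMatrix& frame, const LogicalMatrix& fmask,
                   const NumericMatrix& inv_pose,
                   int x0, int y0, int x1, int y1) {
  NumericMatrix out = clone(canvas);
  LogicalMatrix msk = clone(cmask);
  int h = canvas.nrow(), w = canvas.ncol();
  int fh = frame.nrow(), fw = frame.ncol();
  double a = inv_pose(0, 0), b = inv_pose(0, 1), tx = inv_pose(0, 2);
  double c = inv_pose(1, 0), d = inv_pose(1, 1), ty = inv_pose(1, 2);
  x0 = std::max(x0, 0); y0 = std::max(y0, 0);
  x1 = std::min(x1, w - 1); y1 = std::min(y1, h - 1);
  for (int y = y0; y <= y1; ++y)
    for (int x = x0; x <= x1; ++x) {
      double fx = a * x + b * y + tx;
      double fy = c * x + d * y + ty;
      if (fx < 0 || fy < 0 || fx > fw - 1.0 || fy > fh - 1.0) continue;
      int nx = (int)std::lround(fx), ny = (int)std::lround(fy);
      if (nx < 0) nx = 0; if (nx > fw - 1) nx = fw - 1;
      if (ny < 0) ny = 0; if (ny > fh - 1) ny = fh - 1;
      if (!fmask(ny, nx)) continue;
      bool ok;
      double v = sample_bilinear(frame, fx, fy, ok);
      if (!ok) continue;
      out(y, x) = v;
      msk(y, x) = true;
    }
  return List::create(_["canvas"] = out, _["mask"] = msk);
}

// Gradient-orientation-histogram descriptors (4x4 spatial cells x 8
// orientation bins = 128-d) computed on an n x n rotated/scale-normalized
// sample grid with trilinear soft binning, Gaussian spatial weighting,
// clamped at 0.2 and renormalized. kps columns: x, y, sigma, theta.
// [[Rcpp::export]]
NumericMatrix cpp_grad_descriptors(const NumericMatrix& img, const NumericMatrix& kps,
                                   int n, double spacing_mult) {
  int nk = kps.nrow();
  const int nc = 4, nb = 8, nd = nc * nc * nb;
  NumericMatrix out(nk, nd);
  double c0 = (n - 1) / 2.0;
  for (int i = 0; i < nk; ++i) {
    double cx = kps(i, 0), cy = kps(i, 1), sg = kps(i, 2), th = kps(i, 3);
    double sp = spacing_mult * sg;
    double ct = std::cos(th), st = std::sin(th);
    std::vector<double> d(nd, 0.0);
    for (int r = 0; r < n; ++r)
      for (int c = 0; c < n; ++c) {
        double u = (c - c0) * sp, v = (r - c0) * sp;
        double x = cx + ct * u - st * v;
        double y = cy + st * u + ct * v;
        bool s1, s2, s3, s4;
        double gx = 0.5 * (sample_bilinear(img, x + 1, y, s1) -
                           sample_bilinear(img, x - 1, y, s2));
        double gy = 0.5 * (sample_bilinear(img, x, y + 1, s3) -
                           sample_bilinear(img, x, y - 1, s4));
        if (!(s1 && s2 && s3 && s4)) continue;
        // rotate the gradient into the keypoint frame
        double rx = ct * gx + st * gy;
        double ry = -st * gx + ct * gy;
        double mag = std::sqrt(rx * rx + ry * ry);
        double wgt = std::exp(-0.5 * ((c - c0) * (c - c0) + (r - c0) * (r - c0)) /
                              (0.5 * n * 0.5 * n));
        double ang = std::atan2(ry, rx);
        double ob = (ang + M_PI) / (2 * M_PI) * nb - 0.5;
        double cb = (double)c / n * nc - 0.5;
        double rb = (double)r / n * nc - 0.5;
        int ob0 = (int)std::floor(ob), cb0 = (int)std::floor(cb), rb0 = (int)std::floor(rb);
        double of = ob - ob0, cf = cb - cb0, rf = rb - rb0;
        for (int dr = 0; dr <= 1; ++dr)
          for (int dc = 0; dc <= 1; ++dc)
            for (int dob = 0; dob <= 1; ++dob) {
              int rr = rb0 + dr, cc2 = cb0 + dc;
              if (rr < 0 || rr >= nc || cc2 < 0 || cc2 >= nc) continue;
              int oo = ((ob0 + dob) % nb + nb) % nb;
              double w3 = (dr ? rf : 1 - rf) * (dc ? cf : 1 - cf) *
                          (dob ? of : 1 - of);
              d[(rr * nc + cc2) * nb + oo] += mag * wgt * w3;
            }
      }
    double nrm = 0.0;
    for (int j = 0; j < nd; ++j) nrm += d[j] * d[j];
    nrm = std::sqrt(nrm);
    if (nrm < 1e-9) nrm = 1.0;
    double nrm2 = 0.0;
    for (int j = 0; j < nd; ++j) {
      d[j] = std::min(d[j] / nrm, 0.2);
      nrm2 += d[j] * d[j];
    }
    nrm2 = std::sqrt(nrm2);
    if (nrm2 < 1e-9) nrm2 = 1.0;
    for (int j = 0; j < nd; ++j) out(i, j) = d[j] / nrm2;
  }
  return out;
}

// Subpixel refinement of correspondences by warp-compensated, translation-
// only Lucas-Kanade: for each source point pA, the template is imgA around
// pA; imgB is sampled at tf(pA + u) + delta over the window and delta is
// iterated. Returns refined B-coordinates (tf(pA) + delta) and the final
// RMS intensity residual per point (negative = failed/out of bounds).
// [[Rcpp::export]]
List cpp_lk_refine(const NumericMatrix& imgA, const NumericMatrix& imgB,
                   const NumericMatrix& ptsA, const NumericMatrix& tf,
                   int half_win, int iters) {
  int n = ptsA.nrow();
  NumericMatrix out(n, 2);
  NumericVector rms(n);
  double a = tf(0, 0), b = tf(0, 1), tx = tf(0, 2);
  double c = tf(1, 0), d = tf(1, 1), ty = tf(1, 2);
  int wlen = 2 * half_win + 1;
  std::vector<double> tmpl(wlen * wlen);
  for (int i = 0; i < n; ++i) {
    double px = ptsA(i, 0), py = ptsA(i, 1);
    bool ok = true;
    int k = 0;
    for (int uy = -half_win; uy <= half_win && ok; ++uy)
      for (int ux = -half_win; ux <= half_win; ++ux, ++k) {
        bool s;
        tmpl[k] = sample_bilinear(imgA, px + ux, py + uy, s);
        if (!s) { ok = false; break; }
      }
    if (!ok) { out(i, 0) = a * px + b * py + tx; out(i, 1) = c * px + d * py + ty; rms[i] = -1; continue; }
    double dx = 0, dy = 0, res2 = 0;
    for (int it = 0; it < iters && ok; ++it) {
      double h11 = 0, h12 = 0, h22 = 0, g1 = 0, g2 = 0;
      res2 = 0;
      k = 0;
      for (int uy = -half_win; uy <= half_win && ok; ++uy)
        for (int ux = -half_win; ux <= half_win; ++ux, ++k) {
          double qx = a * (px + ux) + b * (py + uy) + tx + dx;
          double qy = c * (px + ux) + d * (py + uy) + ty + dy;
          bool s1, s2, s3, s4, s5;
          double v = sample_bilinear(imgB, qx, qy, s1);
          double gx = 0.5 * (sample_bilinear(imgB, qx + 1, qy, s2) -
                             sample_bilinear(imgB, qx - 1, qy, s3));
          double gy = 0.5 * (sample_bilinear(imgB, qx, qy + 1, s4) -
                             sample_bilinear(imgB, qx, qy - 1, s5));
          if (!(s1 && s2 && s3 && s4 && s5)) { ok = false; break; }
          double e = v - tmpl[k];
          res2 += e * e;
          h11 += gx * gx; h12 += gx * gy; h22 += gy * gy;
          g1 += gx * e; g2 += gy * e;
        }
      if (!ok) break;
      double det = h11 * h22 - h12 * h12;
      if (det < 1e-12) { ok = false; break; }
      double sx = -(h22 * g1 - h12 * g2) / det;
      double sy = -(h11 * g2 - h12 * g1) / det;
      dx += sx; dy += sy;
      if (sx * sx + sy * sy < 1e-6) break;
      if (dx * dx + dy * dy > 25) { ok = false; break; }
    }
    out(i, 0) = a * px + b * py + tx + dx;
    out(i, 1) = c * px + d * py + ty + dy;
    rms[i] = ok ? std::sqrt(res2 / (wlen * wlen)) : -1.0;
  }
  return List::create(_["pts"] = out, _["rms"] = rms);
}

// Stamp soft-edged curves (vessels) into a texture: darkens pixels within
// `radius` of any path point toward `value` with a 1px soft edge.
// xs/ys are 0-based path coordinates.
// [[Rcpp::export]]
void cpp_draw_curve(NumericMatrix tex, const NumericVector& xs, const NumericVector& ys,
                    double radius, double value) {
  int h = tex.nrow(), w = tex.ncol(), n = xs.size();
  double edge = 1.0;
  for (int i = 0; i < n; ++i) {
    double cx = xs[i], cy = ys[i];
    int r = (int)std::ceil(radius + edge);
    int xlo = std::max(0, (int)std::floor(cx) - r), xhi = std::min(w - 1, (int)std::ceil(cx) + r);
    int ylo = std::max(0, (int)std::floor(cy) - r), yhi = std::min(h - 1, (int)std::ceil(cy) + r);
    for (int y = ylo; y <= yhi; ++y)
      for (int x = xlo; x <= xhi; ++x) {
        double dd = std::sqrt((x - cx) * (x - cx) + (y - cy) * (y - cy));
        double wgt = (radius + edge - dd) / edge;
        if (wgt <= 0) continue;
        if (wgt > 1) wgt = 1;
        double v = tex(y, x) * (1 - wgt) + value * wgt;
        if (v < tex(y, x)) tex(y, x) = v;
      }
  }
}
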