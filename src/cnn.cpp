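// Low-level numerical kernels: 3x3 same-padding convolution with backward
// pass, 2x2 max-pooling, nearest-neighbour upsampling, Voronoi distance
// fields for the synthetic pericellular lattice, 8-connected component
// labelling, and even-odd polygon rasterization.
//
// All arrays use R's column-major layout; image tensors are dim(H, W, C),
// i.e. element (y, x, c) lives at y + H*x + H*W*c (0-based). Everything is
// single-threaded and allocation-free in the inner loops so results are
// bit-reproducible.
#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static inline int dim3(const NumericVector& a, int k) {
  IntegerVector d = a.attr("dim");
  return d[k];
}

// y[h,w,co] = b[co] + sum_{dy,dx,ci} x[h+dy-1, w+dx-1, ci] * w[dy,dx,ci,co]
// (zero padding outside the image). Kernel is fixed 3x3.
// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  const int H = dim3(x, 0), W = dim3(x, 1), Ci = dim3(x, 2);
  IntegerVector wd = w.attr("dim");
  const int Co = wd[3];
  NumericVector out(H * W * Co);
  out.attr("dim") = IntegerVector::create(H, W, Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* po = out.begin();
  for (int co = 0; co < Co; ++co) {
    for (int xx = 0; xx < W; ++xx) {
      for (int yy = 0; yy < H; ++yy) {
        double acc = b[co];
        for (int ci = 0; ci < Ci; ++ci) {
          for (int dx = -1; dx <= 1; ++dx) {
            int sx = xx + dx;
            if (sx < 0 || sx >= W) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int sy = yy + dy;
              if (sy < 0 || sy >= H) continue;
              // w index: (dy+1, dx+1, ci, co), dims (3,3,Ci,Co)
              acc += px[sy + H * sx + H * W * ci] *
                     pw[(dy + 1) + 3 * (dx + 1) + 9 * ci + 9 * Ci * co];
            }
          }
        }
        po[yy + H * xx + H * W * co] = acc;
      }
    }
  }
  return out;
}

// Gradients of the same convolution. Returns gx (like x), gw (like w),
// gb (length Co) given upstream gradient gout (like the forward output).
// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gout) {
  const int H = dim3(x, 0), W = dim3(x, 1), Ci = dim3(x, 2);
  IntegerVector wd = w.attr("dim");
  const int Co = wd[3];
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  NumericVector gb(Co);
  const double* px = x.begin();
  const double* pw = w.begin();
  const double* pg = gout.begin();
  double* pgx = gx.begin();
  double* pgw = gw.begin();
  for (int co = 0; co < Co; ++co) {
    for (int xx = 0; xx < W; ++xx) {
      for (int yy = 0; yy < H; ++yy) {
        const double g = pg[yy + H * xx + H * W * co];
        gb[co] += g;
        for (int ci = 0; ci < Ci; ++ci) {
          for (int dx = -1; dx <= 1; ++dx) {
            int sx = xx + dx;
            if (sx < 0 || sx >= W) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int sy = yy + dy;
              if (sy < 0 || sy >= H) continue;
              const int xi = sy + H * sx + H * W * ci;
              const int wi = (dy + 1) + 3 * (dx + 1) + 9 * ci + 9 * Ci * co;
              pgw[wi] += px[xi] * g;
              pgx[xi] += pw[wi] * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2; H and W must be even. Returns the pooled
// tensor and the flat (0-based) argmax index into x for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  const int H = dim3(x, 0), W = dim3(x, 1), C = dim3(x, 2);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector amax(Ho * Wo * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int xx = 0; xx < Wo; ++xx) {
      for (int yy = 0; yy < Ho; ++yy) {
        int best = 2 * yy + H * (2 * xx) + H * W * c;
        double bv = px[best];
        const int cand[3] = {2 * yy + 1 + H * (2 * xx) + H * W * c,
                             2 * yy + H * (2 * xx + 1) + H * W * c,
                             2 * yy + 1 + H * (2 * xx + 1) + H * W * c};
        for (int k = 0; k < 3; ++k)
          if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
        const int oi = yy + Ho * xx + Ho * Wo * c;
        po[oi] = bv;
        amax[oi] = best;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector gout, IntegerVector argmax,
                          IntegerVector dimx) {
  NumericVector gx(dimx[0] * dimx[1] * dimx[2]);
  gx.attr("dim") = dimx;
  for (int i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  return gx;
}

// Nearest-neighbour x2 upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x) {
  const int H = dim3(x, 0), W = dim3(x, 1), C = dim3(x, 2);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int xx = 0; xx < Wo; ++xx)
      for (int yy = 0; yy < Ho; ++yy)
        po[yy + Ho * xx + Ho * Wo * c] =
            px[(yy / 2) + H * (xx / 2) + H * W * c];
  return out;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector gout) {
  const int Ho = dim3(gout, 0), Wo = dim3(gout, 1), C = dim3(gout, 2);
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx(H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  const double* pg = gout.begin();
  double* px = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int xx = 0; xx < Wo; ++xx)
      for (int yy = 0; yy < Ho; ++yy)
        px[(yy / 2) + H * (xx / 2) + H * W * c] +=
            pg[yy + Ho * xx + Ho * Wo * c];
  return gx;
}

// For every pixel of an H x W grid, the distances to the nearest and
// second-nearest seed point and their (1-based) indices. Seeds are given as
// (y, x) in 0-based pixel coordinates. Brute force over seeds; adequate for
// the few hundred simulated myocyte centres used per slide.
// [[Rcpp::export(name = ".voronoi_field")]]
List voronoi_field(NumericVector sy, NumericVector sx, int H, int W) {
  const int n = sy.size();
  NumericMatrix d1(H, W), d2(H, W);
  IntegerMatrix i1(H, W), i2(H, W);
  for (int xx = 0; xx < W; ++xx) {
    for (int yy = 0; yy < H; ++yy) {
      double b1 = R_PosInf, b2 = R_PosInf;
      int j1 = 0, j2 = 0;
      for (int k = 0; k < n; ++k) {
        const double dy = yy - sy[k], dx = xx - sx[k];
        const double d = dy * dy + dx * dx;
        if (d < b1) { b2 = b1; j2 = j1; b1 = d; j1 = k + 1; }
        else if (d < b2) { b2 = d; j2 = k + 1; }
      }
      d1(yy, xx) = std::sqrt(b1);
      d2(yy, xx) = std::sqrt(b2);
      i1(yy, xx) = j1;
      i2(yy, xx) = j2;
    }
  }
  return List::create(_["d1"] = d1, _["d2"] = d2, _["i1"] = i1, _["i2"] = i2);
}

// 8-connected component labelling of a binary mask (BFS flood fill).
// Returns an integer matrix of labels 1..n, 0 for background.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      if (mask(y0, x0) == 0 || lab(y0, x0) != 0) continue;
      ++next;
      lab(y0, x0) = next;
      q.push(y0 + H * x0);
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int y = p % H, x = p / H;
        for (int dx = -1; dx <= 1; ++dx) {
          const int nx = x + dx;
          if (nx < 0 || nx >= W) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int ny = y + dy;
            if (ny < 0 || ny >= H || (dy == 0 && dx == 0)) continue;
            if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
              lab(ny, nx) = next;
              q.push(ny + H * nx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Even-odd scanline rasterization of closed polygon rings given in 0-based
// pixel-centre coordinates. `rings` is a list of 2-column (x, y) matrices.
// A pixel (row r, col c) is foreground when the point (c, r) is inside an
// odd number of ring crossings; all rings share one parity so holes carve
// out correctly.
// [[Rcpp::export(name = ".rasterize_rings")]]
IntegerMatrix rasterize_rings(List rings, int H, int W) {
  IntegerMatrix out(H, W);
  std::vector<double> xs;
  for (int r = 0; r < H; ++r) {
    const double yr = (double)r;
    xs.clear();
    for (int k = 0; k < rings.size(); ++k) {
      NumericMatrix ring = rings[k];
      const int n = ring.nrow();
      for (int i = 0; i < n; ++i) {
        const int j = (i + 1) % n;
        double x1 = ring(i, 0), y1 = ring(i, 1);
        double x2 = ring(j, 0), y2 = ring(j, 1);
        if ((y1 <= yr && y2 > yr) || (y2 <= yr && y1 > yr)) {
          xs.push_back(x1 + (yr - y1) / (y2 - y1) * (x2 - x1));
        }
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    // fill between successive crossing pairs
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k]);
      int c1 = (int)std::floor(xs[k + 1]);
      // a crossing exactly on a pixel centre: treat centre as inside the
      // left span only (ceil/floor above already do this)
      if (c0 < 0) c0 = 0;
      if (c1 >= W) c1 = W - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = 1;
    }
  }
  return out;
}
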