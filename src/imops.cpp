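// Low-level raster operations: Zhang-Suen thinning, affine resampling,
// and binary dilation with a square structuring element.

#include <RcppArmadillo.h>
using namespace Rcpp;

// Zhang-Suen morphological thinning to a 1-px-wide skeleton.
// Neighbours p2..p9 run clockwise from north, matching the classic
// formulation; two sub-iterations alternate until no pixel changes.
// [[Rcpp::export]]
IntegerMatrix thin_zhang_suen_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix M = clone(mask);
  auto at = [&](int r, int c) -> int {
    return (r < 0 || r >= H || c < 0 || c >= W) ? 0 : M(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (M(r, c) != 1) continue;
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c),     p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int p[8] = {p2, p3, p4, p5, p6, p7, p8, p9};
          int A = 0;
          for (int i = 0; i < 8; ++i)
            if (p[i] == 0 && p[(i + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({r, c});
        }
      }
      for (auto& rc : kill) M(rc.first, rc.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return M;
}

// Inverse-map affine resampler. For output pixel (r, c) (0-based) the
// source location is  src = A %*% c(r, c) + t.  Bilinear interpolation
// for photographs, nearest-neighbour for masks. Samples falling outside
// the source raster either raise an error or take `fill`.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, int out_h, int out_w,
                                  NumericMatrix A, NumericVector t,
                                  bool bilinear, double fill,
                                  bool error_outside) {
  IntegerVector dim = src.attr("dim");
  const int H = dim[0], W = dim[1], C = (dim.size() == 3) ? dim[2] : 1;
  NumericVector out(out_h * out_w * C);
  const double a00 = A(0, 0), a01 = A(0, 1), a10 = A(1, 0), a11 = A(1, 1);
  const double eps = 1e-9;
  for (int c = 0; c < out_w; ++c) {
    for (int r = 0; r < out_h; ++r) {
      double sr = a00 * r + a01 * c + t[0];
      double sc = a10 * r + a11 * c + t[1];
      bool outside = sr < -eps || sr > H - 1 + eps || sc < -eps || sc > W - 1 + eps;
      if (outside) {
        if (error_outside)
          stop("sample location (%.2f, %.2f) falls outside the source raster", sr, sc);
        for (int ch = 0; ch < C; ++ch)
          out[r + c * out_h + ch * out_h * out_w] = fill;
        continue;
      }
      sr = std::min(std::max(sr, 0.0), (double)(H - 1));
      sc = std::min(std::max(sc, 0.0), (double)(W - 1));
      if (bilinear) {
        int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        double fr = sr - r0, fc = sc - c0;
        for (int ch = 0; ch < C; ++ch) {
          const double* s = &src[ch * H * W];
          double v = (1 - fr) * (1 - fc) * s[r0 + c0 * H] +
                     fr * (1 - fc) * s[r1 + c0 * H] +
                     (1 - fr) * fc * s[r0 + c1 * H] +
                     fr * fc * s[r1 + c1 * H];
          out[r + c * out_h + ch * out_h * out_w] = v;
        }
      } else {
        int rn = (int)std::floor(sr + 0.5), cn = (int)std::floor(sc + 0.5);
        rn = std::min(std::max(rn, 0), H - 1);
        cn = std::min(std::max(cn, 0), W - 1);
        for (int ch = 0; ch < C; ++ch)
          out[r + c * out_h + ch * out_h * out_w] = src[rn + cn * H + ch * H * W];
      }
    }
  }
  if (C > 1) out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  else out.attr("dim") = IntegerVector::create(out_h, out_w);
  return out;
}

// Binary dilation with a k x k square structuring element. For even k
// the element extends one pixel further down/right than up/left, which
// reproduces the footprint of a k-pixel-wide pencil stroke.
// [[Rcpp::export]]
IntegerMatrix dilate_square_cpp(IntegerMatrix mask, int k) {
  const int H = mask.nrow(), W = mask.ncol();
  const int lo = -(k - 1) / 2, hi = k / 2;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) != 1) continue;
      for (int dc = lo; dc <= hi; ++dc)
        for (int dr = lo; dr <= hi; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W) out(rr, cc) = 1;
        }
    }
  return out;
}
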