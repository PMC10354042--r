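// Low-level numerical kernels: im2col convolutions (forward/backward),
// transposed convolutions, pixelwise softmax cross-entropy, and raster
// utilities (connected components, modal filter, affine warp, NCC offset
// search, local maxima).
//
// Tensor layout matches R arrays: feature maps are (H, W, C) or (H, W, C, N),
// column-major, so an arma::cube(H, W, C) aliases one sample directly.
// Conv weights are (k, k, Cin, Cout); im2col row index = kr + kc*k + cin*k*k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out_size(int H, int k, int s, int p, int d) {
  return (H + 2 * p - d * (k - 1) - 1) / s + 1;
}

static void im2col(const arma::cube& x, int k, int s, int p, int d,
                   arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = conv_out_size(H, k, s, p, d);
  const int Wo = conv_out_size(W, k, s, p, d);
  cols.zeros(k * k * C, Ho * Wo);
  for (int cin = 0; cin < C; ++cin) {
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int row = kr + kc * k + cin * k * k;
        for (int j = 0; j < Wo; ++j) {
          const int c_in = j * s - p + kc * d;
          if (c_in < 0 || c_in >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int r_in = i * s - p + kr * d;
            if (r_in < 0 || r_in >= H) continue;
            cols(row, i + j * Ho) = x(r_in, c_in, cin);
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int s, int p, int d, arma::cube& x) {
  const int Ho = conv_out_size(H, k, s, p, d);
  const int Wo = conv_out_size(W, k, s, p, d);
  x.zeros(H, W, C);
  for (int cin = 0; cin < C; ++cin) {
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int row = kr + kc * k + cin * k * k;
        for (int j = 0; j < Wo; ++j) {
          const int c_in = j * s - p + kc * d;
          if (c_in < 0 || c_in >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int r_in = i * s - p + kr * d;
            if (r_in < 0 || r_in >= H) continue;
            x(r_in, c_in, cin) += cols(row, i + j * Ho);
          }
        }
      }
    }
  }
}

static arma::cube sample_cube(const NumericVector& a, int H, int W, int C,
                              int n) {
  // zero-copy view of sample n of an (H, W, C, N) array
  return arma::cube(const_cast<double*>(a.begin()) + (size_t)n * H * W * C,
                    H, W, C, false, true);
}

static IntegerVector tensor_dims(const NumericVector& a, int expect_min) {
  if (!a.hasAttribute("dim")) stop("input must be a dim-ed array");
  IntegerVector d = a.attr("dim");
  if (d.size() < expect_min) stop("array has too few dimensions");
  return d;
}

// ---- convolution -----------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad, int dil) {
  IntegerVector xd = tensor_dims(x, 3);
  IntegerVector wd = tensor_dims(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("conv kernel must be square");
  if (Cin != C) stop("channel mismatch: input has %d, weights expect %d", C, Cin);
  const int Ho = conv_out_size(H, k, stride, pad, dil);
  const int Wo = conv_out_size(W, k, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube(x, H, W, C, n);
    im2col(xs, k, stride, pad, dil, cols);
    arma::mat Y(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                false, true);
    Y = cols.t() * Wm;
    Y.each_row() += bv.t();
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad, int dil) {
  IntegerVector xd = tensor_dims(x, 3);
  IntegerVector wd = tensor_dims(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = conv_out_size(H, k, stride, pad, dil);
  const int Wo = conv_out_size(W, k, stride, pad, dil);

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dWm(k * k * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  arma::mat cols, dcols;
  arma::cube dxs;
  for (int n = 0; n < N; ++n) {
    arma::cube xs = sample_cube(x, H, W, C, n);
    arma::mat DY(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                 Ho * Wo, Cout, false, true);
    im2col(xs, k, stride, pad, dil, cols);
    dWm += cols * DY;
    db += arma::sum(DY, 0).t();
    dcols = Wm * DY.t();
    col2im(dcols, H, W, C, k, stride, pad, dil, dxs);
    std::copy(dxs.memptr(), dxs.memptr() + (size_t)H * W * C,
              dx.begin() + (size_t)n * H * W * C);
  }
  dx.attr("dim") = xd;
  NumericVector dw(dWm.memptr(), dWm.memptr() + dWm.n_elem);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution. Weights are stored in the shape of the underlying
// conv that maps output -> input: (k, k, Cout, Cin). Output size is
// (H-1)*stride - 2*pad + k.

// [[Rcpp::export]]
NumericVector cpp_convt_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = tensor_dims(x, 3);
  IntegerVector wd = tensor_dims(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  const int k = wd[0], Cout = wd[2], Cin = wd[3];
  if (Cin != C) stop("channel mismatch in transposed conv");
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;
  if (conv_out_size(Ho, k, stride, pad, 1) != H ||
      conv_out_size(Wo, k, stride, pad, 1) != W)
    stop("inconsistent transposed-conv geometry");

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cout, Cin, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::mat dcols;
  arma::cube ys;
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                H * W, C, false, true);
    dcols = Wm * X.t();
    col2im(dcols, Ho, Wo, Cout, k, stride, pad, 1, ys);
    for (int co = 0; co < Cout; ++co) ys.slice(co) += bv(co);
    std::copy(ys.memptr(), ys.memptr() + (size_t)Ho * Wo * Cout,
              y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convt_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  IntegerVector xd = tensor_dims(x, 3);
  IntegerVector wd = tensor_dims(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2];
  const int N = xd.size() == 4 ? xd[3] : 1;
  const int k = wd[0], Cout = wd[2], Cin = wd[3];
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cout, Cin, false, true);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dWm(k * k * Cout, Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    arma::cube dys = sample_cube(dy, Ho, Wo, Cout, n);
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                H * W, C, false, true);
    im2col(dys, k, stride, pad, 1, cols);       // (k2*Cout, H*W)
    arma::mat DX(dx.begin() + (size_t)n * H * W * C, H * W, C, false, true);
    DX = cols.t() * Wm;
    dWm += cols * X;
    for (int co = 0; co < Cout; ++co) db(co) += arma::accu(dys.slice(co));
  }
  dx.attr("dim") = xd;
  NumericVector dw(dWm.memptr(), dWm.memptr() + dWm.n_elem);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---- softmax cross-entropy --------------------------------------------------

// logits: (H, W, K, N); labels: (H, W, N) integer in 0..K, 0 = ignored pixel.
// Loss is the mean over non-ignored pixels; grad is d(loss)/d(logits).

// [[Rcpp::export]]
List cpp_softmax_ce(NumericVector logits, IntegerVector labels) {
  IntegerVector ld = tensor_dims(logits, 4);
  const int H = ld[0], W = ld[1], K = ld[2], N = ld[3];
  NumericVector grad((size_t)H * W * K * N);
  grad.attr("dim") = ld;

  double loss = 0.0;
  long n_valid = 0, n_correct = 0;
  std::vector<double> z(K);
  const double* lp = logits.begin();
  double* gp = grad.begin();
  const int* yp = labels.begin();

  // first pass: count valid pixels (grad needs 1/M scaling)
  const size_t npix = (size_t)H * W * N;
  for (size_t t = 0; t < npix; ++t) if (yp[t] > 0) ++n_valid;
  const double invM = n_valid > 0 ? 1.0 / (double)n_valid : 0.0;

  for (int n = 0; n < N; ++n) {
    const size_t off_l = (size_t)n * H * W * K;
    const size_t off_y = (size_t)n * H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const size_t pix = i + (size_t)j * H;
        const int y = yp[off_y + pix];
        double zmax = -1e300;
        for (int c = 0; c < K; ++c) {
          z[c] = lp[off_l + pix + (size_t)c * H * W];
          if (z[c] > zmax) zmax = z[c];
        }
        double se = 0.0;
        int amax = 0;
        for (int c = 0; c < K; ++c) {
          z[c] = std::exp(z[c] - zmax);
          se += z[c];
          if (z[c] > z[amax]) amax = c;
        }
        if (y < 1) continue;  // ignored: grad stays zero
        const double py = z[y - 1] / se;
        loss -= std::log(std::max(py, 1e-300));
        if (amax == y - 1) ++n_correct;
        for (int c = 0; c < K; ++c) {
          double p = z[c] / se;
          gp[off_l + pix + (size_t)c * H * W] =
              (p - (c == y - 1 ? 1.0 : 0.0)) * invM;
        }
      }
    }
  }
  return List::create(_["loss"] = n_valid ? loss / n_valid : NA_REAL,
                      _["grad"] = grad,
                      _["n_valid"] = (double)n_valid,
                      _["n_correct"] = (double)n_correct);
}

// [[Rcpp::export]]
NumericVector cpp_softmax(NumericVector logits) {
  // (H, W, K[, N]) -> per-pixel softmax over dimension 3
  IntegerVector ld = tensor_dims(logits, 3);
  const int H = ld[0], W = ld[1], K = ld[2];
  const int N = ld.size() == 4 ? ld[3] : 1;
  NumericVector out(clone(logits));
  double* op = out.begin();
  std::vector<double> z(K);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * H * W * K;
    for (size_t pix = 0; pix < (size_t)H * W; ++pix) {
      double zmax = -1e300;
      for (int c = 0; c < K; ++c) {
        z[c] = op[off + pix + (size_t)c * H * W];
        if (z[c] > zmax) zmax = z[c];
      }
      double se = 0.0;
      for (int c = 0; c < K; ++c) { z[c] = std::exp(z[c] - zmax); se += z[c]; }
      for (int c = 0; c < K; ++c) op[off + pix + (size_t)c * H * W] = z[c] / se;
    }
  }
  return out;
}

// ---- raster utilities -------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity == 4 ? 4 : 8;
  // row-major scan so component ids are ordered by (top row, left col)
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int q = 0; q < nn; ++q) {
          const int rr = r + dr8[q], cc = c + dc8[q];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix cpp_modal_filter(IntegerMatrix x, int win) {
  // mode over a win x win window; ties keep the centre value when it is
  // among the modes, otherwise the smallest tied value
  const int H = x.nrow(), W = x.ncol();
  if (win % 2 == 0 || win < 1) stop("window must be odd and positive");
  if (win == 1) return clone(x);
  const int r = win / 2;
  int vmax = 0;
  for (int i = 0; i < H * W; ++i) if (x[i] > vmax) vmax = x[i];
  IntegerMatrix out(H, W);
  std::vector<int> cnt(vmax + 1);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int di = -r; di <= r; ++di) {
        const int ii = i + di;
        if (ii < 0 || ii >= H) continue;
        for (int dj = -r; dj <= r; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          ++cnt[x(ii, jj)];
        }
      }
      int best = 0;
      for (int v = 1; v <= vmax; ++v) if (cnt[v] > cnt[best]) best = v;
      if (cnt[x(i, j)] == cnt[best]) best = x(i, j);
      out(i, j) = best;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector img, NumericMatrix A,
                              int out_h, int out_w, bool bilinear,
                              double fill) {
  // pull warp: output (r, c) sampled at input coords A %*% c(r, c, 1)
  IntegerVector d = tensor_dims(img, 3);
  const int H = d[0], W = d[1], C = d[2];
  if (A.nrow() != 2 || A.ncol() != 3) stop("affine matrix must be 2x3");
  NumericVector out((size_t)out_h * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  const double* ip = img.begin();
  double* op = out.begin();
  for (int j = 0; j < out_w; ++j) {
    for (int i = 0; i < out_h; ++i) {
      const double sr = A(0, 0) * i + A(0, 1) * j + A(0, 2);
      const double sc = A(1, 0) * i + A(1, 1) * j + A(1, 2);
      for (int c = 0; c < C; ++c) {
        double v = fill;
        if (bilinear) {
          const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
          if (r0 >= 0 && r0 + 1 < H && c0 >= 0 && c0 + 1 < W) {
            const double fr = sr - r0, fc = sc - c0;
            const size_t base = (size_t)c * H * W;
            const double v00 = ip[base + r0 + (size_t)c0 * H];
            const double v10 = ip[base + r0 + 1 + (size_t)c0 * H];
            const double v01 = ip[base + r0 + (size_t)(c0 + 1) * H];
            const double v11 = ip[base + r0 + 1 + (size_t)(c0 + 1) * H];
            v = v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
                v01 * (1 - fr) * fc + v11 * fr * fc;
          }
        } else {
          const int r0 = (int)std::lround(sr), c0 = (int)std::lround(sc);
          if (r0 >= 0 && r0 < H && c0 >= 0 && c0 < W)
            v = ip[(size_t)c * H * W + r0 + (size_t)c0 * H];
        }
        op[(size_t)c * out_h * out_w + i + (size_t)j * out_h] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ncc_offset(NumericMatrix tpl, NumericMatrix img) {
  // best integer shift of tpl inside img (img larger by 2*radius each way)
  const int h = tpl.nrow(), w = tpl.ncol();
  const int rr = (img.nrow() - h) / 2, rc = (img.ncol() - w) / 2;
  if (img.nrow() < h || img.ncol() < w) stop("search image smaller than template");
  arma::mat T(const_cast<double*>(tpl.begin()), h, w, false, true);
  arma::mat I(const_cast<double*>(img.begin()), img.nrow(), img.ncol(), false, true);
  const double tmean = arma::mean(arma::vectorise(T));
  arma::mat T0 = T - tmean;
  const double tnorm = std::sqrt(arma::accu(T0 % T0));
  double best = -2.0;
  int bdr = 0, bdc = 0;
  for (int dr = 0; dr <= 2 * rr; ++dr) {
    for (int dc = 0; dc <= 2 * rc; ++dc) {
      arma::mat S = I.submat(dr, dc, dr + h - 1, dc + w - 1);
      const double smean = arma::mean(arma::vectorise(S));
      arma::mat S0 = S - smean;
      const double snorm = std::sqrt(arma::accu(S0 % S0));
      if (tnorm < 1e-12 || snorm < 1e-12) continue;
      const double ncc = arma::accu(T0 % S0) / (tnorm * snorm);
      if (ncc > best) { best = ncc; bdr = dr - rr; bdc = dc - rc; }
    }
  }
  return List::create(_["dr"] = bdr, _["dc"] = bdc, _["ncc"] = best);
}

// [[Rcpp::export]]
List cpp_local_maxima(NumericMatrix img, double threshold, int min_dist) {
  // peaks above threshold, greedily enforcing a minimum Euclidean separation
  const int H = img.nrow(), W = img.ncol();
  std::vector<std::tuple<double, int, int>> cand;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const double v = img(i, j);
      if (v <= threshold) continue;
      bool ismax = true;
      for (int di = -1; di <= 1 && ismax; ++di) {
        for (int dj = -1; dj <= 1; ++dj) {
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (di == 0 && dj == 0) continue;
          // strict on earlier neighbours breaks plateau ties deterministically
          if (img(ii, jj) > v ||
              (img(ii, jj) == v && (ii < i || (ii == i && jj < j)))) {
            ismax = false;
            break;
          }
        }
      }
      if (ismax) cand.push_back({v, i, j});
    }
  }
  std::stable_sort(cand.begin(), cand.end(),
                   [](const auto& a, const auto& b) {
                     return std::get<0>(a) > std::get<0>(b);
                   });
  std::vector<int> rs, cs;
  const double d2min = (double)min_dist * min_dist;
  for (const auto& [v, i, j] : cand) {
    bool ok = true;
    for (size_t q = 0; q < rs.size(); ++q) {
      const double dr = rs[q] - i, dc = cs[q] - j;
      if (dr * dr + dc * dc < d2min) { ok = false; break; }
    }
    if (ok) { rs.push_back(i); cs.push_back(j); }
  }
  return List::create(_["row"] = IntegerVector(rs.begin(), rs.end()),
                      _["col"] = IntegerVector(cs.begin(), cs.end()));
}

// [[Rcpp::export]]
NumericVector cpp_disk_mean(NumericMatrix img, IntegerVector row,
                            IntegerVector col, double radius) {
  // mean of img over a disk of given radius around each 0-based centre
  const int H = img.nrow(), W = img.ncol();
  const int n = row.size();
  const int r = (int)std::ceil(radius);
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double s = 0.0;
    int m = 0;
    for (int di = -r; di <= r; ++di) {
      for (int dj = -r; dj <= r; ++dj) {
        if (di * di + dj * dj > radius * radius) continue;
        const int i = row[q] + di, j = col[q] + dj;
        if (i < 0 || i >= H || j < 0 || j >= W) continue;
        s += img(i, j);
        ++m;
      }
    }
    out[q] = m > 0 ? s / m : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_blur_sep(NumericMatrix img, NumericVector kernel) {
  // separable convolution with reflect padding (odd-length kernel)
  const int H = img.nrow(), W = img.ncol();
  const int k = kernel.size(), r = k / 2;
  if (k % 2 == 0) stop("kernel length must be odd");
  NumericMatrix tmp(H, W), out(H, W);
  auto refl = [](int i, int n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
    return std::max(0, std::min(n - 1, i));
  };
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int q = -r; q <= r; ++q) s += kernel[q + r] * img(refl(i + q, H), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int q = -r; q <= r; ++q) s += kernel[q + r] * tmp(i, refl(j + q, W));
      out(i, j) = s;
    }
  return out;
}
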