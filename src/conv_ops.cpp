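// Convolution and resampling kernels for the segmentation network.
// Tensors are R arrays H x W x C (column-major, row index fastest), mapped
// onto arma::cube(n_rows = H, n_cols = W, n_slices = C) without copy semantics
// changing the layout. Weights are R arrays kh x kw x inC_per_group x outC.
//
// "Same" padding with stride s: out = ceil(in / s); total pad
// max((out-1)*s + k_eff - in, 0) split floor(top)/rest(bottom), where
// k_eff = (k-1)*dilation + 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct ConvGeom {
  int H, W, Cin, kh, kw, Cout, G, Cin_g, Cout_g;
  int stride, dil, oh, ow, pad_top, pad_left;
};

static ConvGeom conv_geom(const arma::cube& x, const IntegerVector& wdim,
                          int stride, int dil, int groups) {
  ConvGeom g;
  g.H = x.n_rows; g.W = x.n_cols; g.Cin = x.n_slices;
  g.kh = wdim[0]; g.kw = wdim[1]; g.Cin_g = wdim[2]; g.Cout = wdim[3];
  g.G = groups;
  if (g.Cin != g.Cin_g * g.G) stop("input channels (%d) != weight channels (%d) * groups (%d)",
                                   g.Cin, g.Cin_g, g.G);
  if (g.Cout % g.G != 0) stop("output channels not divisible by groups");
  g.Cout_g = g.Cout / g.G;
  g.stride = stride; g.dil = dil;
  g.oh = (g.H + stride - 1) / stride;
  g.ow = (g.W + stride - 1) / stride;
  int keh = (g.kh - 1) * dil + 1, kew = (g.kw - 1) * dil + 1;
  int pad_h = std::max((g.oh - 1) * stride + keh - g.H, 0);
  int pad_w = std::max((g.ow - 1) * stride + kew - g.W, 0);
  g.pad_top = pad_h / 2; g.pad_left = pad_w / 2;
  return g;
}

// im2col for one group: rows = kh*kw*Cin_g (kh fastest, then kw, then channel),
// cols = oh*ow (row index fastest, matching R matrix layout).
static void im2col_group(const arma::cube& x, const ConvGeom& g, int grp,
                         arma::mat& cols) {
  const int P = g.oh * g.ow;
  cols.set_size(g.kh * g.kw * g.Cin_g, P);
  for (int c = 0; c < g.Cin_g; ++c) {
    const arma::mat& xs = x.slice(grp * g.Cin_g + c);
    for (int kj = 0; kj < g.kw; ++kj) {
      for (int ki = 0; ki < g.kh; ++ki) {
        const int rr = ki + g.kh * kj + g.kh * g.kw * c;
        for (int ox = 0; ox < g.ow; ++ox) {
          const int sx = ox * g.stride - g.pad_left + kj * g.dil;
          double* colp = cols.colptr(0) + rr; // stride over columns manually
          if (sx < 0 || sx >= g.W) {
            for (int oy = 0; oy < g.oh; ++oy)
              cols(rr, oy + g.oh * ox) = 0.0;
            continue;
          }
          for (int oy = 0; oy < g.oh; ++oy) {
            const int sy = oy * g.stride - g.pad_top + ki * g.dil;
            cols(rr, oy + g.oh * ox) =
              (sy < 0 || sy >= g.H) ? 0.0 : xs(sy, sx);
          }
          (void)colp;
        }
      }
    }
  }
}

static arma::mat weight_mat(const NumericVector& w, const ConvGeom& g, int grp) {
  // rows = Cout_g, cols = kh*kw*Cin_g matching im2col row order
  arma::mat W(g.Cout_g, g.kh * g.kw * g.Cin_g);
  const int khw = g.kh * g.kw;
  for (int oc = 0; oc < g.Cout_g; ++oc) {
    const int ocg = grp * g.Cout_g + oc;
    for (int c = 0; c < g.Cin_g; ++c)
      for (int kj = 0; kj < g.kw; ++kj)
        for (int ki = 0; ki < g.kh; ++ki)
          W(oc, ki + g.kh * kj + khw * c) =
            w[ki + g.kh * (kj + g.kw * (c + g.Cin_g * ocg))];
  }
  return W;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x_, NumericVector w_, NumericVector b_,
                         int stride, int dilation, int groups) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  arma::cube x(x_.begin(), xd[0], xd[1], xd[2], false);
  ConvGeom g = conv_geom(x, wd, stride, dilation, groups);
  NumericVector out_(g.oh * g.ow * g.Cout);
  out_.attr("dim") = IntegerVector::create(g.oh, g.ow, g.Cout);
  arma::cube out(out_.begin(), g.oh, g.ow, g.Cout, false);
  arma::mat cols;
  for (int grp = 0; grp < g.G; ++grp) {
    im2col_group(x, g, grp, cols);
    arma::mat W = weight_mat(w_, g, grp);
    arma::mat Y = W * cols; // Cout_g x P
    for (int oc = 0; oc < g.Cout_g; ++oc) {
      const int ocg = grp * g.Cout_g + oc;
      arma::mat ys(Y.row(oc).t());
      ys.reshape(g.oh, g.ow);
      out.slice(ocg) = ys + b_[ocg];
    }
  }
  return out_;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x_, NumericVector w_, NumericVector dy_,
                int stride, int dilation, int groups) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim"), yd = dy_.attr("dim");
  arma::cube x(x_.begin(), xd[0], xd[1], xd[2], false);
  ConvGeom g = conv_geom(x, wd, stride, dilation, groups);
  if (yd[0] != g.oh || yd[1] != g.ow || yd[2] != g.Cout)
    stop("gradient shape mismatch in conv backward");
  arma::cube dy(dy_.begin(), g.oh, g.ow, g.Cout, false);

  NumericVector dx_(g.H * g.W * g.Cin);
  dx_.attr("dim") = IntegerVector::create(g.H, g.W, g.Cin);
  arma::cube dx(dx_.begin(), g.H, g.W, g.Cin, false);
  NumericVector dw_(w_.size());
  dw_.attr("dim") = wd;
  NumericVector db_(g.Cout);

  const int P = g.oh * g.ow;
  const int khw = g.kh * g.kw;
  arma::mat cols;
  for (int grp = 0; grp < g.G; ++grp) {
    im2col_group(x, g, grp, cols);
    arma::mat W = weight_mat(w_, g, grp);
    arma::mat dY(g.Cout_g, P);
    for (int oc = 0; oc < g.Cout_g; ++oc) {
      const int ocg = grp * g.Cout_g + oc;
      const arma::mat& s = dy.slice(ocg);
      double acc = 0.0;
      for (int ox = 0; ox < g.ow; ++ox)
        for (int oy = 0; oy < g.oh; ++oy) {
          dY(oc, oy + g.oh * ox) = s(oy, ox);
          acc += s(oy, ox);
        }
      db_[ocg] = acc;
    }
    arma::mat dW = dY * cols.t(); // Cout_g x (kh*kw*Cin_g)
    for (int oc = 0; oc < g.Cout_g; ++oc) {
      const int ocg = grp * g.Cout_g + oc;
      for (int c = 0; c < g.Cin_g; ++c)
        for (int kj = 0; kj < g.kw; ++kj)
          for (int ki = 0; ki < g.kh; ++ki)
            dw_[ki + g.kh * (kj + g.kw * (c + g.Cin_g * ocg))] =
              dW(oc, ki + g.kh * kj + khw * c);
    }
    arma::mat dcols = W.t() * dY; // (kh*kw*Cin_g) x P
    // col2im scatter
    for (int c = 0; c < g.Cin_g; ++c) {
      arma::mat& dxs = dx.slice(grp * g.Cin_g + c);
      for (int kj = 0; kj < g.kw; ++kj)
        for (int ki = 0; ki < g.kh; ++ki) {
          const int rr = ki + g.kh * kj + khw * c;
          for (int ox = 0; ox < g.ow; ++ox) {
            const int sx = ox * g.stride - g.pad_left + kj * g.dil;
            if (sx < 0 || sx >= g.W) continue;
            for (int oy = 0; oy < g.oh; ++oy) {
              const int sy = oy * g.stride - g.pad_top + ki * g.dil;
              if (sy < 0 || sy >= g.H) continue;
              dxs(sy, sx) += dcols(rr, oy + g.oh * ox);
            }
          }
        }
    }
  }
  return List::create(_["dx"] = dx_, _["dw"] = dw_, _["db"] = db_);
}

// Corner-aligned bilinear resize: output corner samples coincide with input
// corner samples; src coordinate of output index i is i * (n_in-1)/(n_out-1)
// (0 when n_out == 1 or n_in == 1).
// [[Rcpp::export(name = ".bilinear_resize_fwd")]]
NumericVector bilinear_resize_fwd(NumericVector x_, int oh, int ow) {
  IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  arma::cube x(x_.begin(), H, W, C, false);
  NumericVector out_(oh * ow * C);
  out_.attr("dim") = IntegerVector::create(oh, ow, C);
  arma::cube out(out_.begin(), oh, ow, C, false);
  const double sy = (oh > 1 && H > 1) ? double(H - 1) / double(oh - 1) : 0.0;
  const double sx = (ow > 1 && W > 1) ? double(W - 1) / double(ow - 1) : 0.0;
  for (int ox = 0; ox < ow; ++ox) {
    const double fx = ox * sx;
    const int x0 = std::min(int(fx), W - 1), x1 = std::min(x0 + 1, W - 1);
    const double wx = fx - x0;
    for (int oy = 0; oy < oh; ++oy) {
      const double fy = oy * sy;
      const int y0 = std::min(int(fy), H - 1), y1 = std::min(y0 + 1, H - 1);
      const double wy = fy - y0;
      for (int c = 0; c < C; ++c) {
        const arma::mat& xs = x.slice(c);
        out(oy, ox, c) =
          (1 - wy) * ((1 - wx) * xs(y0, x0) + wx * xs(y0, x1)) +
          wy       * ((1 - wx) * xs(y1, x0) + wx * xs(y1, x1));
      }
    }
  }
  return out_;
}

// [[Rcpp::export(name = ".bilinear_resize_bwd")]]
NumericVector bilinear_resize_bwd(NumericVector dy_, int H, int W) {
  IntegerVector yd = dy_.attr("dim");
  const int oh = yd[0], ow = yd[1], C = yd[2];
  arma::cube dy(dy_.begin(), oh, ow, C, false);
  NumericVector dx_(H * W * C);
  dx_.attr("dim") = IntegerVector::create(H, W, C);
  arma::cube dx(dx_.begin(), H, W, C, false);
  const double sy = (oh > 1 && H > 1) ? double(H - 1) / double(oh - 1) : 0.0;
  const double sx = (ow > 1 && W > 1) ? double(W - 1) / double(ow - 1) : 0.0;
  for (int ox = 0; ox < ow; ++ox) {
    const double fx = ox * sx;
    const int x0 = std::min(int(fx), W - 1), x1 = std::min(x0 + 1, W - 1);
    const double wx = fx - x0;
    for (int oy = 0; oy < oh; ++oy) {
      const double fy = oy * sy;
      const int y0 = std::min(int(fy), H - 1), y1 = std::min(y0 + 1, H - 1);
      const double wy = fy - y0;
      for (int c = 0; c < C; ++c) {
        const double g = dy(oy, ox, c);
        dx(y0, x0, c) += (1 - wy) * (1 - wx) * g;
        dx(y0, x1, c) += (1 - wy) * wx * g;
        dx(y1, x0, c) += wy * (1 - wx) * g;
        dx(y1, x1, c) += wy * wx * g;
      }
    }
  }
  return dx_;
}
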