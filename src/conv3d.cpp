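#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Valid 3x3x3 convolution and its backward pass.
//
// Strategy: hold the volume channel-major (C x XYZ, zero-padded at the tail
// so shifted views stay in bounds). For each of the 27 kernel offsets, the
// input voxels feeding output voxel j form the contiguous column range
// [j + off, ...] when the output grid keeps the full X and Y extents and
// restricts only Z. The convolution is then 27 accumulating DGEMMs on
// zero-copy column views (~15% redundant columns, discarded afterwards),
// which avoids any im2col gather and runs at near-DGEMM speed.

// 0-based linear indices of the valid output voxels within the full-X/Y grid.
static arma::uvec valid_indices(int X, int Y, int OX, int OY, int OZ) {
  arma::uvec idx(static_cast<arma::uword>(OX) * OY * OZ);
  arma::uword t = 0;
  for (int z = 0; z < OZ; ++z)
    for (int y = 0; y < OY; ++y)
      for (int x = 0; x < OX; ++x)
        idx[t++] = x + static_cast<arma::uword>(X) * (y + static_cast<arma::uword>(Y) * z);
  return idx;
}

static void kernel_offsets(int X, int Y, arma::uword *offs) {
  int o = 0;
  for (int oz = 0; oz < 3; ++oz)
    for (int oy = 0; oy < 3; ++oy)
      for (int ox = 0; ox < 3; ++ox)
        offs[o++] = ox + static_cast<arma::uword>(X) * (oy + static_cast<arma::uword>(Y) * oz);
}

// x: [X,Y,Z,Cin] array; w: (27*Cin) x F matrix, rows offset-major
// (row = o*Cin + c, o = ox + 3*oy + 9*oz); b: F. Returns [X-2,Y-2,Z-2,F].
// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("input must be a 4D array");
  int X = d[0], Y = d[1], Z = d[2], C = d[3];
  if (X < 3 || Y < 3 || Z < 3) stop("spatial dimensions must be >= 3 for a valid 3x3x3 convolution");
  if (w.nrow() != 27 * C) stop("weight rows must equal 27 * input channels");
  int OX = X - 2, OY = Y - 2, OZ = Z - 2;
  int F = w.ncol();
  arma::uword XYZ = static_cast<arma::uword>(X) * Y * Z;
  arma::uword M = static_cast<arma::uword>(X) * Y * OZ;
  arma::uword N = static_cast<arma::uword>(OX) * OY * OZ;
  arma::uword maxoff = 2 + 2 * static_cast<arma::uword>(X) +
    2 * static_cast<arma::uword>(X) * Y;

  arma::mat Xm(x.begin(), XYZ, C, false, true);
  arma::mat Xpad(C, XYZ + maxoff, arma::fill::zeros);
  Xpad.head_cols(XYZ) = Xm.t();
  arma::mat Wm(w.begin(), 27 * C, F, false, true);

  arma::uword offs[27];
  kernel_offsets(X, Y, offs);

  arma::mat OutT(F, M, arma::fill::zeros);
  for (int o = 0; o < 27; ++o) {
    arma::mat view(const_cast<double*>(Xpad.colptr(offs[o])), C, M, false, true);
    OutT += Wm.rows(o * C, o * C + C - 1).t() * view;
  }

  arma::uvec vi = valid_indices(X, Y, OX, OY, OZ);
  NumericVector out(N * F);
  arma::mat Out(out.begin(), N, F, false, true);
  Out = OutT.cols(vi).t();
  arma::rowvec bv(b.begin(), F);
  Out.each_row() += bv;
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, F);
  return out;
}

// Backward pass. x: forward input [X,Y,Z,Cin]; w: (27*Cin) x F;
// gout: [OX,OY,OZ,F]. Returns list(gx, gw, gb).
// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericMatrix w, NumericVector gout) {
  IntegerVector d = x.attr("dim");
  int X = d[0], Y = d[1], Z = d[2], C = d[3];
  int OX = X - 2, OY = Y - 2, OZ = Z - 2;
  int F = w.ncol();
  arma::uword XYZ = static_cast<arma::uword>(X) * Y * Z;
  arma::uword M = static_cast<arma::uword>(X) * Y * OZ;
  arma::uword N = static_cast<arma::uword>(OX) * OY * OZ;
  arma::uword maxoff = 2 + 2 * static_cast<arma::uword>(X) +
    2 * static_cast<arma::uword>(X) * Y;
  IntegerVector dg = gout.attr("dim");
  if (dg[0] != OX || dg[1] != OY || dg[2] != OZ || dg[3] != F)
    stop("gradient shape does not match convolution output");

  arma::mat Xm(x.begin(), XYZ, C, false, true);
  arma::mat Xpad(C, XYZ + maxoff, arma::fill::zeros);
  Xpad.head_cols(XYZ) = Xm.t();
  arma::mat Wm(w.begin(), 27 * C, F, false, true);
  arma::mat Gm(gout.begin(), N, F, false, true);

  arma::uword offs[27];
  kernel_offsets(X, Y, offs);
  arma::uvec vi = valid_indices(X, Y, OX, OY, OZ);

  // scatter the output gradient onto the full-X/Y grid (invalid cols = 0)
  arma::mat GfullT(F, M, arma::fill::zeros);
  GfullT.cols(vi) = Gm.t();

  arma::mat GW(27 * C, F);
  arma::mat GXpad(C, XYZ + maxoff, arma::fill::zeros);
  for (int o = 0; o < 27; ++o) {
    arma::mat xview(const_cast<double*>(Xpad.colptr(offs[o])), C, M, false, true);
    GW.rows(o * C, o * C + C - 1) = xview * GfullT.t();
    arma::mat gview(GXpad.colptr(offs[o]), C, M, false, true);
    gview += Wm.rows(o * C, o * C + C - 1) * GfullT;
  }

  NumericMatrix gw(27 * C, F);
  std::copy(GW.begin(), GW.end(), gw.begin());
  NumericVector gb(F);
  arma::rowvec sb = arma::sum(Gm, 0);
  std::copy(sb.begin(), sb.end(), gb.begin());
  NumericVector gx(static_cast<R_xlen_t>(XYZ) * C);
  arma::mat GXout(gx.begin(), XYZ, C, false, true);
  GXout = GXpad.head_cols(XYZ).t();
  gx.attr("dim") = d;
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}
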