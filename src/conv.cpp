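// Direct same-padded 2D cross-correlation (CNN convention) and its
// gradients.  Arrays are column-major: x (ny, nx, cin), W (k, k, cin, cout),
// y (ny, nx, cout).  Kernel index (a, b) taps input pixel
// (i + a - 1 - p, j + b - 1 - p) with zero padding, p = (k - 1) / 2.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector W, NumericVector b,
                         int ny, int nx, int cin, int k, int cout) {
  const int p = (k - 1) / 2;
  NumericVector y(ny * (R_xlen_t)nx * cout);
  const double *px = x.begin(), *pw = W.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int co = 0; co < cout; ++co) {
    const double bias = pb[co];
    double *yc = py + (R_xlen_t)co * ny * nx;
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) yc[i + (R_xlen_t)j * ny] = bias;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + (R_xlen_t)ci * ny * nx;
      const double *wc = pw + ((R_xlen_t)co * cin + ci) * k * k;
      for (int bb = 0; bb < k; ++bb) {
        const int dj = bb - p;
        for (int aa = 0; aa < k; ++aa) {
          const int di = aa - p;
          const double w = wc[aa + bb * k];
          if (w == 0.0) continue;
          const int j0 = std::max(0, -dj), j1 = std::min(nx, nx - dj);
          const int i0 = std::max(0, -di), i1 = std::min(ny, ny - di);
          for (int j = j0; j < j1; ++j) {
            const double *xs = xc + (R_xlen_t)(j + dj) * ny + di;
            double *ys = yc + (R_xlen_t)j * ny;
            for (int i = i0; i < i1; ++i) ys[i] += w * xs[i];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(ny, nx, cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_grad(NumericVector dY, NumericVector x, NumericVector W,
                     int ny, int nx, int cin, int k, int cout) {
  const int p = (k - 1) / 2;
  NumericVector dX(ny * (R_xlen_t)nx * cin);
  NumericVector dW(k * (R_xlen_t)k * cin * cout);
  NumericVector db(cout);
  const double *pdy = dY.begin(), *px = x.begin(), *pw = W.begin();
  double *pdx = dX.begin(), *pdw = dW.begin(), *pdb = db.begin();
  for (int co = 0; co < cout; ++co) {
    const double *dyc = pdy + (R_xlen_t)co * ny * nx;
    double s = 0.0;
    for (R_xlen_t t = 0; t < (R_xlen_t)ny * nx; ++t) s += dyc[t];
    pdb[co] = s;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + (R_xlen_t)ci * ny * nx;
      const double *wc = pw + ((R_xlen_t)co * cin + ci) * k * k;
      double *dxc = pdx + (R_xlen_t)ci * ny * nx;
      double *dwc = pdw + ((R_xlen_t)co * cin + ci) * k * k;
      for (int bb = 0; bb < k; ++bb) {
        const int dj = bb - p;
        for (int aa = 0; aa < k; ++aa) {
          const int di = aa - p;
          const double w = wc[aa + bb * k];
          const int j0 = std::max(0, -dj), j1 = std::min(nx, nx - dj);
          const int i0 = std::max(0, -di), i1 = std::min(ny, ny - di);
          double acc = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double *xs = xc + (R_xlen_t)(j + dj) * ny + di;
            const double *dys = dyc + (R_xlen_t)j * ny;
            double *dxs = dxc + (R_xlen_t)(j + dj) * ny + di;
            for (int i = i0; i < i1; ++i) {
              acc += dys[i] * xs[i];
              dxs[i] += w * dys[i];
            }
          }
          dwc[aa + bb * k] += acc;
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(ny, nx, cin);
  dW.attr("dim") = IntegerVector::create(k, k, cin, cout);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
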