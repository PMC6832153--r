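// Convolution and max-pooling kernels for the CNN, operating on the
// package's channel-fastest layout: each sample is one column enumerating
// (channel, row, col) with channel varying fastest. Valid padding only.
//
// Loop order iterates kernel elements outermost so the inner loops stream
// contiguously over output positions and filters.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// X: (c*h*w) x n; W: (c*kh*kw) x f (column-major over (c, ki, kj));
// returns (f*oh*ow) x n with filter index fastest.
// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericMatrix conv_fwd_cpp(const NumericMatrix& X, IntegerVector in_shape,
                           const NumericMatrix& W, NumericVector b,
                           IntegerVector kernel, IntegerVector stride,
                           bool relu) {
  const int h = in_shape[0], c = in_shape[2], w = in_shape[1];
  const int kh = kernel[0], kw = kernel[1], sh = stride[0], sw = stride[1];
  const int oh = (h - kh) / sh + 1, ow = (w - kw) / sw + 1;
  const int f = W.ncol(), n = X.ncol(), ckk = W.nrow();
  // transpose weights so filters are contiguous per kernel element
  std::vector<double> wt((size_t)ckk * f);
  for (int p = 0; p < ckk; ++p)
    for (int fi = 0; fi < f; ++fi) wt[(size_t)p * f + fi] = W(p, fi);
  NumericMatrix out(f * oh * ow, n);
  for (int s = 0; s < n; ++s) {
    const double* xs = &X(0, s);
    double* os = &out(0, s);
    for (int pos = 0; pos < oh * ow; ++pos) {
      double* o = os + (size_t)pos * f;
      for (int fi = 0; fi < f; ++fi) o[fi] = b[fi];
    }
    int p = 0;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        for (int ch = 0; ch < c; ++ch) {
          const double* wp = &wt[(size_t)p * f];
          for (int oj = 0; oj < ow; ++oj) {
            const double* xcol = xs + ch + ki * c + kj * c * h + (size_t)(oj * sw) * c * h;
            double* ocol = os + (size_t)f * oh * oj;
            for (int oi = 0; oi < oh; ++oi) {
              const double xv = xcol[(size_t)oi * sh * c];
              double* o = ocol + (size_t)f * oi;
              for (int fi = 0; fi < f; ++fi) o[fi] += wp[fi] * xv;
            }
          }
          ++p;
        }
      }
    }
    if (relu) {
      for (int q = 0; q < f * oh * ow; ++q) if (os[q] < 0.0) os[q] = 0.0;
    }
  }
  return out;
}

// Gradients of the convolution. dOut: (f*oh*ow) x n.
// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(const NumericMatrix& X, IntegerVector in_shape,
                  const NumericMatrix& W, IntegerVector kernel,
                  IntegerVector stride, const NumericMatrix& dOut,
                  const NumericMatrix& Aout, bool relu) {
  const int h = in_shape[0], c = in_shape[2], w = in_shape[1];
  const int kh = kernel[0], kw = kernel[1], sh = stride[0], sw = stride[1];
  const int oh = (h - kh) / sh + 1, ow = (w - kw) / sw + 1;
  const int f = W.ncol(), n = X.ncol(), ckk = W.nrow();
  std::vector<double> wt((size_t)ckk * f), dwt((size_t)ckk * f, 0.0);
  for (int p = 0; p < ckk; ++p)
    for (int fi = 0; fi < f; ++fi) wt[(size_t)p * f + fi] = W(p, fi);
  NumericMatrix dX(X.nrow(), n);
  NumericVector db(f);
  std::vector<double> dgate((size_t)f * oh * ow);
  for (int s = 0; s < n; ++s) {
    const double* xs = &X(0, s);
    double* dxs = &dX(0, s);
    const double* d0 = &dOut(0, s);
    if (relu) {
      const double* as = &Aout(0, s);
      for (int q = 0; q < f * oh * ow; ++q)
        dgate[q] = (as[q] > 0.0) ? d0[q] : 0.0;
    } else {
      for (int q = 0; q < f * oh * ow; ++q) dgate[q] = d0[q];
    }
    const double* ds = dgate.data();
    for (int pos = 0; pos < oh * ow; ++pos) {
      const double* d = ds + (size_t)pos * f;
      for (int fi = 0; fi < f; ++fi) db[fi] += d[fi];
    }
    int p = 0;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        for (int ch = 0; ch < c; ++ch) {
          const double* wp = &wt[(size_t)p * f];
          double* dwp = &dwt[(size_t)p * f];
          for (int oj = 0; oj < ow; ++oj) {
            const double* xcol = xs + ch + ki * c + kj * c * h + (size_t)(oj * sw) * c * h;
            double* dxcol = dxs + ch + ki * c + kj * c * h + (size_t)(oj * sw) * c * h;
            const double* dcol = ds + (size_t)f * oh * oj;
            for (int oi = 0; oi < oh; ++oi) {
              const double xv = xcol[(size_t)oi * sh * c];
              const double* d = dcol + (size_t)f * oi;
              double dot = 0.0;
              for (int fi = 0; fi < f; ++fi) {
                dwp[fi] += d[fi] * xv;
                dot += wp[fi] * d[fi];
              }
              dxcol[(size_t)oi * sh * c] += dot;
            }
          }
          ++p;
        }
      }
    }
  }
  NumericMatrix dW(ckk, f);
  for (int p = 0; p < ckk; ++p)
    for (int fi = 0; fi < f; ++fi) dW(p, fi) = dwt[(size_t)p * f + fi];
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Max pooling with floor division (trailing rows/cols dropped).
// Returns the pooled values and 1-based within-sample argmax indices.
// [[Rcpp::export(name = ".pool_fwd_cpp")]]
List pool_fwd_cpp(const NumericMatrix& X, IntegerVector in_shape,
                  IntegerVector pool) {
  const int h = in_shape[0], c = in_shape[2], w = in_shape[1];
  const int ph = pool[0], pw = pool[1];
  const int fh = h / ph, fw = w / pw;
  const int n = X.ncol();
  NumericMatrix out(c * fh * fw, n);
  IntegerMatrix amax(c * fh * fw, n);
  for (int s = 0; s < n; ++s) {
    const double* xs = &X(0, s);
    double* os = &out(0, s);
    int* as = &amax(0, s);
    for (int fj = 0; fj < fw; ++fj) {
      for (int fi = 0; fi < fh; ++fi) {
        for (int ch = 0; ch < c; ++ch) {
          double best = R_NegInf; int besti = -1;
          for (int pj = 0; pj < pw; ++pj) {
            for (int pi = 0; pi < ph; ++pi) {
              const int idx = ch + (fi * ph + pi) * c + (fj * pw + pj) * c * h;
              if (xs[idx] > best) { best = xs[idx]; besti = idx; }
            }
          }
          const int o = ch + fi * c + fj * c * fh;
          os[o] = best;
          as[o] = besti + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export(name = ".pool_bwd_cpp")]]
NumericMatrix pool_bwd_cpp(const NumericMatrix& dOut, const IntegerMatrix& amax,
                           int in_len) {
  const int n = dOut.ncol(), m = dOut.nrow();
  NumericMatrix dX(in_len, n);
  for (int s = 0; s < n; ++s) {
    const double* d = &dOut(0, s);
    const int* a = &amax(0, s);
    double* dx = &dX(0, s);
    for (int i = 0; i < m; ++i) dx[a[i] - 1] += d[i];
  }
  return dX;
}
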