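// Dense optical flow by polynomial expansion (Farneback).
// Each frame is locally approximated by a quadratic polynomial
// f(o) ~ o'Ao + b'o + c over a Gaussian-weighted neighborhood; equating the
// expansions of consecutive frames yields, per pixel, A d = -(b2 - b1)/2 for
// the displacement d, solved in a least-squares sense over an averaging
// window and refined iteratively over an image pyramid.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> Img; // row-major nr x nc

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// correlation with a centered 1D kernel along columns (x) then rows (y),
// replicate border
static void corr_sep(const Img& in, Img& out, int nr, int nc,
                     const std::vector<double>& kx,
                     const std::vector<double>& ky, Img& tmp) {
  int hx = ((int)kx.size() - 1) / 2, hy = ((int)ky.size() - 1) / 2;
  tmp.assign((size_t)nr * nc, 0.0);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double s = 0;
      for (int o = -hx; o <= hx; ++o)
        s += kx[o + hx] * in[(size_t)r * nc + clampi(c + o, nc)];
      tmp[(size_t)r * nc + c] = s;
    }
  out.assign((size_t)nr * nc, 0.0);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double s = 0;
      for (int o = -hy; o <= hy; ++o)
        s += ky[o + hy] * tmp[(size_t)clampi(r + o, nr) * nc + c];
      out[(size_t)r * nc + c] = s;
    }
}

struct PolyExp { Img a11, a12, a22, b1, b2; };

// quadratic polynomial expansion with Gaussian applicability (half-width n)
static void poly_expand(const Img& f, int nr, int nc, int n, double sigma,
                        PolyExp& P) {
  int w = 2 * n + 1;
  std::vector<double> g(w), xg(w), x2g(w);
  double sum = 0;
  for (int i = -n; i <= n; ++i) {
    g[i + n] = std::exp(-0.5 * i * i / (sigma * sigma));
    sum += g[i + n];
  }
  for (int i = -n; i <= n; ++i) {
    g[i + n] /= sum;
    xg[i + n] = i * g[i + n];
    x2g[i + n] = (double)i * i * g[i + n];
  }
  double mu2 = 0, mu4 = 0;
  for (int i = -n; i <= n; ++i) {
    mu2 += g[i + n] * i * i;
    mu4 += g[i + n] * (double)i * i * i * i;
  }
  // inverse of the 3x3 Gram matrix for the (1, x^2, y^2) block
  // [1 mu2 mu2; mu2 mu4 mu2^2; mu2 mu2^2 mu4]
  double m22 = mu2 * mu2;
  double a = 1, b = mu2, d = mu4, e = m22;
  // Gram matrix [[a,b,b],[b,d,e],[b,e,d]]
  double det = a * (d * d - e * e) - b * (b * d - e * b) + b * (b * e - d * b);
  double i11 = (d * d - e * e) / det;
  double i12 = -(b * d - b * e) / det;
  double i22 = (a * d - b * b) / det;
  double i23 = (b * b - a * e) / det;
  // r4 = i12*m00 + i22*m20 + i23*m02 ; r5 symmetric; r1 unused

  Img m00, m10, m01, m20, m02, m11, tmp;
  corr_sep(f, m00, nr, nc, g, g, tmp);
  corr_sep(f, m10, nr, nc, xg, g, tmp);
  corr_sep(f, m01, nr, nc, g, xg, tmp);
  corr_sep(f, m20, nr, nc, x2g, g, tmp);
  corr_sep(f, m02, nr, nc, g, x2g, tmp);
  corr_sep(f, m11, nr, nc, xg, xg, tmp);

  size_t N = (size_t)nr * nc;
  P.a11.resize(N); P.a12.resize(N); P.a22.resize(N);
  P.b1.resize(N); P.b2.resize(N);
  for (size_t k = 0; k < N; ++k) {
    double r2 = m10[k] / mu2;           // b_x
    double r3 = m01[k] / mu2;           // b_y
    double r4 = i12 * m00[k] + i22 * m20[k] + i23 * m02[k]; // A_xx
    double r5 = i12 * m00[k] + i23 * m20[k] + i22 * m02[k]; // A_yy
    double r6 = m11[k] / m22;           // 2*A_xy
    P.a11[k] = r4;
    P.a22[k] = r5;
    P.a12[k] = 0.5 * r6;
    P.b1[k] = r2;
    P.b2[k] = r3;
  }
}

// bilinear sample of a row-major image at fractional (row, col), clamped
static inline double bilin(const Img& im, int nr, int nc, double fr,
                           double fc) {
  if (fr < 0) fr = 0; if (fr > nr - 1) fr = nr - 1;
  if (fc < 0) fc = 0; if (fc > nc - 1) fc = nc - 1;
  int r0 = (int)fr, c0 = (int)fc;
  int r1 = r0 + 1 < nr ? r0 + 1 : r0, c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double wr = fr - r0, wc = fc - c0;
  return (1 - wr) * ((1 - wc) * im[(size_t)r0 * nc + c0] +
                     wc * im[(size_t)r0 * nc + c1]) +
         wr * ((1 - wc) * im[(size_t)r1 * nc + c0] +
               wc * im[(size_t)r1 * nc + c1]);
}

// one-level flow update; u = x (column) displacement, v = y (row) displacement
static void flow_iterate(const PolyExp& P1, const PolyExp& P2, int nr, int nc,
                         Img& u, Img& v, int winsize, int iters) {
  size_t N = (size_t)nr * nc;
  Img g11(N), g12(N), g22(N), h1(N), h2(N), tmp;
  std::vector<double> box(winsize, 1.0 / winsize);
  for (int it = 0; it < iters; ++it) {
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        size_t k = (size_t)r * nc + c;
        double d0x = u[k], d0y = v[k];
        double fr = r + d0y, fc = c + d0x;
        double a11 = 0.5 * (P1.a11[k] + bilin(P2.a11, nr, nc, fr, fc));
        double a12 = 0.5 * (P1.a12[k] + bilin(P2.a12, nr, nc, fr, fc));
        double a22 = 0.5 * (P1.a22[k] + bilin(P2.a22, nr, nc, fr, fc));
        double dbx = -0.5 * (bilin(P2.b1, nr, nc, fr, fc) - P1.b1[k]) +
                     a11 * d0x + a12 * d0y;
        double dby = -0.5 * (bilin(P2.b2, nr, nc, fr, fc) - P1.b2[k]) +
                     a12 * d0x + a22 * d0y;
        g11[k] = a11 * a11 + a12 * a12;
        g12[k] = a12 * (a11 + a22);
        g22[k] = a22 * a22 + a12 * a12;
        h1[k] = a11 * dbx + a12 * dby;
        h2[k] = a12 * dbx + a22 * dby;
      }
    // average the normal equations over the window (box filter)
    Img G11, G12, G22, H1, H2;
    corr_sep(g11, G11, nr, nc, box, box, tmp); g11 = G11;
    corr_sep(g12, G12, nr, nc, box, box, tmp); g12 = G12;
    corr_sep(g22, G22, nr, nc, box, box, tmp); g22 = G22;
    corr_sep(h1, H1, nr, nc, box, box, tmp); h1 = H1;
    corr_sep(h2, H2, nr, nc, box, box, tmp); h2 = H2;
    for (size_t k = 0; k < N; ++k) {
      double det = g11[k] * g22[k] - g12[k] * g12[k];
      if (std::fabs(det) > 1e-12) {
        u[k] = (g22[k] * h1[k] - g12[k] * h2[k]) / det;
        v[k] = (g11[k] * h2[k] - g12[k] * h1[k]) / det;
      } // else keep previous estimate
    }
  }
}

static void downsample2(const Img& in, int nr, int nc, Img& out, int& nr2,
                        int& nc2) {
  nr2 = (nr + 1) / 2;
  nc2 = (nc + 1) / 2;
  out.assign((size_t)nr2 * nc2, 0.0);
  for (int r = 0; r < nr2; ++r)
    for (int c = 0; c < nc2; ++c) {
      double s = 0;
      int cnt = 0;
      for (int dr = 0; dr < 2; ++dr)
        for (int dc = 0; dc < 2; ++dc) {
          int rr = 2 * r + dr, cc = 2 * c + dc;
          if (rr < nr && cc < nc) { s += in[(size_t)rr * nc + cc]; ++cnt; }
        }
      out[(size_t)r * nc2 + c] = s / cnt;
    }
}

static void upsample_flow(const Img& in, int nr, int nc, Img& out, int nr2,
                          int nc2) {
  out.assign((size_t)nr2 * nc2, 0.0);
  for (int r = 0; r < nr2; ++r)
    for (int c = 0; c < nc2; ++c) {
      double fr = std::min((double)(nr - 1), r / 2.0);
      double fc = std::min((double)(nc - 1), c / 2.0);
      int r0 = (int)fr, c0 = (int)fc;
      int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
      double wr = fr - r0, wc = fc - c0;
      double val = (1 - wr) * ((1 - wc) * in[(size_t)r0 * nc + c0] +
                               wc * in[(size_t)r0 * nc + c1]) +
                   wr * ((1 - wc) * in[(size_t)r1 * nc + c0] +
                         wc * in[(size_t)r1 * nc + c1]);
      out[(size_t)r * nc2 + c] = 2.0 * val;
    }
}

// [[Rcpp::export(name = ".farneback_cpp")]]
List farneback_cpp(NumericMatrix frame1, NumericMatrix frame2, int levels,
                   int winsize, int iters, int poly_n, double poly_sigma) {
  int nr = frame1.nrow(), nc = frame1.ncol();
  if (frame2.nrow() != nr || frame2.ncol() != nc)
    stop("frames must share dimensions");
  // build pyramids (level 0 = full resolution)
  std::vector<Img> p1(levels), p2(levels);
  std::vector<int> NR(levels), NC(levels);
  // NumericMatrix is column-major; transpose into row-major buffers
  Img f1((size_t)nr * nc), f2((size_t)nr * nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      f1[(size_t)r * nc + c] = frame1(r, c);
      f2[(size_t)r * nc + c] = frame2(r, c);
    }
  p1[0] = f1; p2[0] = f2;
  NR[0] = nr; NC[0] = nc;
  for (int l = 1; l < levels; ++l) {
    downsample2(p1[l - 1], NR[l - 1], NC[l - 1], p1[l], NR[l], NC[l]);
    downsample2(p2[l - 1], NR[l - 1], NC[l - 1], p2[l], NR[l], NC[l]);
  }
  Img u, v;
  for (int l = levels - 1; l >= 0; --l) {
    int lr = NR[l], lc = NC[l];
    if (lr < poly_n * 2 + 1 || lc < poly_n * 2 + 1) continue;
    if (u.empty()) {
      u.assign((size_t)lr * lc, 0.0);
      v.assign((size_t)lr * lc, 0.0);
    } else {
      Img u2, v2;
      upsample_flow(u, NR[l + 1], NC[l + 1], u2, lr, lc);
      upsample_flow(v, NR[l + 1], NC[l + 1], v2, lr, lc);
      u = u2; v = v2;
    }
    PolyExp P1, P2;
    poly_expand(p1[l], lr, lc, poly_n, poly_sigma, P1);
    poly_expand(p2[l], lr, lc, poly_n, poly_sigma, P2);
    flow_iterate(P1, P2, lr, lc, u, v, winsize, iters);
  }
  if (u.empty()) stop("image too small for the polynomial window");
  NumericMatrix U(nr, nc), V(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      U(r, c) = u[(size_t)r * nc + c];
      V(r, c) = v[(size_t)r * nc + c];
    }
  return List::create(_["dx"] = U, _["dy"] = V);
}
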