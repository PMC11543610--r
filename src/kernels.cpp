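// Numerical kernels: 3x3x3 convolution (im2col + GEMM) with gradients,
// trilinear / nearest-neighbour warping with gradients, and an exact
// anisotropic Euclidean distance transform (separable lower-envelope scan).
//
// Volume layout everywhere: column-major R arrays dim (nx, ny, nz, C);
// displacement fields dim (nx, ny, nz, 3) with offsets in voxels along
// axes 1..3. All computations in double precision, single-threaded.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BIG = 1e20;

// ---------------------------------------------------------------- conv3 ----

// persistent GEMM workspaces, grown on demand (single-threaded R session).
// The convolution path defaults to single precision (weights, activations
// and their gradients tolerate float32, and both GEMM throughput and
// im2col bandwidth double); a double path is kept for exact gradient
// checking, selected per call.
static std::vector<float> f_bufA, f_bufB, f_bufX, f_bufW, f_bufO;
static std::vector<double> d_bufA, d_bufB;

static void to_float(const double* src, float* dst, size_t n) {
  for (size_t i = 0; i < n; i++) dst[i] = (float)src[i];
}

// im2col for a 3x3x3 neighbourhood, zero padding 1. Column j = k + 27*c with
// k = (kx+1) + 3*(ky+1) + 9*(kz+1) matches the flattening order of an R
// weight array dim (3,3,3,Cin,Cout). Every element of A is overwritten
// (data or explicit zero), so A needs no prior initialization.
template <typename T, typename S>
static void im2col3(const S* x, int nx, int ny, int nz, int C, T* Abuf) {
  const size_t N = (size_t)nx * ny * nz;
  for (int c = 0; c < C; c++) {
    const S* xc = x + (size_t)c * N;
    for (int kz = -1; kz <= 1; kz++)
      for (int ky = -1; ky <= 1; ky++)
        for (int kx = -1; kx <= 1; kx++) {
          int k = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          T* col = Abuf + ((size_t)k + 27 * (size_t)c) * N;
          int x0 = std::max(0, -kx), x1 = std::min(nx, nx - kx);
          for (int z = 0; z < nz; z++) {
            int zz = z + kz;
            T* plane = col + (size_t)z * ny * nx;
            if (zz < 0 || zz >= nz) {
              std::memset(plane, 0, sizeof(T) * (size_t)ny * nx);
              continue;
            }
            for (int y = 0; y < ny; y++) {
              int yy = y + ky;
              T* dst = plane + (size_t)y * nx;
              if (yy < 0 || yy >= ny) {
                std::memset(dst, 0, sizeof(T) * nx);
                continue;
              }
              const S* src = xc + ((size_t)zz * ny + yy) * nx + (x0 + kx);
              if (x0 > 0) dst[0] = (T)0;
              if (x1 < nx) dst[nx - 1] = (T)0;
              for (int i = 0; i < x1 - x0; i++) dst[x0 + i] = (T)src[i];
            }
          }
        }
  }
}

// adjoint of im2col3: scatter-add columns back into a volume
template <typename T>
static void col2im3(const T* A, int nx, int ny, int nz, int C, double* dx) {
  const size_t N = (size_t)nx * ny * nz;
  std::memset(dx, 0, sizeof(double) * N * (size_t)C);
  for (int c = 0; c < C; c++) {
    double* xc = dx + (size_t)c * N;
    for (int kz = -1; kz <= 1; kz++)
      for (int ky = -1; ky <= 1; ky++)
        for (int kx = -1; kx <= 1; kx++) {
          int k = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          const T* col = A + ((size_t)k + 27 * (size_t)c) * N;
          int x0 = std::max(0, -kx), x1 = std::min(nx, nx - kx);
          if (x1 <= x0) continue;
          for (int z = 0; z < nz; z++) {
            int zz = z + kz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; y++) {
              int yy = y + ky;
              if (yy < 0 || yy >= ny) continue;
              double* dst = xc + ((size_t)zz * ny + yy) * nx + (x0 + kx);
              const T* src = col + ((size_t)z * ny + y) * nx + x0;
              for (int i = 0; i < x1 - x0; i++) dst[i] += src[i];
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
NumericVector conv3_fwd(NumericVector x, NumericVector w, NumericVector b,
                        IntegerVector dim, bool single) {
  int nx = dim[0], ny = dim[1], nz = dim[2], Ci = dim[3];
  int Co = b.size();
  const size_t N = (size_t)nx * ny * nz;
  const size_t K = 27 * (size_t)Ci;
  NumericVector out(N * (size_t)Co);
  double* op = REAL(out);
  if (single) {
    if (f_bufA.size() < N * K) f_bufA.resize(N * K);
    if (f_bufW.size() < K * (size_t)Co) f_bufW.resize(K * (size_t)Co);
    if (f_bufO.size() < N * (size_t)Co) f_bufO.resize(N * (size_t)Co);
    to_float(REAL(w), f_bufW.data(), K * (size_t)Co);
    im2col3<float>(REAL(x), nx, ny, nz, Ci, f_bufA.data());
    arma::fmat A(f_bufA.data(), N, K, false, true);
    arma::fmat Wm(f_bufW.data(), K, Co, false, true);
    arma::fmat Om(f_bufO.data(), N, Co, false, true);
    Om = A * Wm;
    for (int c = 0; c < Co; c++) {
      const float* oc = f_bufO.data() + (size_t)c * N;
      double bc = b[c];
      for (size_t i = 0; i < N; i++) op[(size_t)c * N + i] = oc[i] + bc;
    }
  } else {
    if (d_bufA.size() < N * K) d_bufA.resize(N * K);
    im2col3<double>(REAL(x), nx, ny, nz, Ci, d_bufA.data());
    arma::mat A(d_bufA.data(), N, K, false, true);
    arma::mat Wm(REAL(w), K, Co, false, true);
    arma::mat Om(op, N, Co, false, true);
    Om = A * Wm;
    for (int c = 0; c < Co; c++) Om.col(c) += b[c];
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, Co);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(NumericVector x, NumericVector w, NumericVector dout,
               IntegerVector dim, int Co, bool want_dx, bool single) {
  int nx = dim[0], ny = dim[1], nz = dim[2], Ci = dim[3];
  const size_t N = (size_t)nx * ny * nz;
  const size_t K = 27 * (size_t)Ci;
  NumericVector dwv(K * (size_t)Co), db(Co);
  SEXP dxs = R_NilValue;
  NumericVector dx;
  if (want_dx) {
    dx = NumericVector(N * (size_t)Ci);
    dx.attr("dim") = IntegerVector::create(nx, ny, nz, Ci);
    dxs = dx;
  }
  if (single) {
    if (f_bufA.size() < N * K) f_bufA.resize(N * K);
    if (f_bufO.size() < N * (size_t)Co) f_bufO.resize(N * (size_t)Co);
    to_float(REAL(dout), f_bufO.data(), N * (size_t)Co);
    im2col3<float>(REAL(x), nx, ny, nz, Ci, f_bufA.data());
    arma::fmat A(f_bufA.data(), N, K, false, true);
    arma::fmat dOut(f_bufO.data(), N, Co, false, true);
    arma::fmat dW = A.t() * dOut;
    for (size_t i = 0; i < dW.n_elem; i++) dwv[i] = dW.memptr()[i];
    for (int c = 0; c < Co; c++) db[c] = arma::accu(dOut.col(c));
    if (want_dx) {
      if (f_bufB.size() < N * K) f_bufB.resize(N * K);
      if (f_bufW.size() < K * (size_t)Co) f_bufW.resize(K * (size_t)Co);
      to_float(REAL(w), f_bufW.data(), K * (size_t)Co);
      arma::fmat Wm(f_bufW.data(), K, Co, false, true);
      arma::fmat dA(f_bufB.data(), N, K, false, true);
      dA = dOut * Wm.t();
      col2im3<float>(f_bufB.data(), nx, ny, nz, Ci, REAL(dx));
    }
  } else {
    if (d_bufA.size() < N * K) d_bufA.resize(N * K);
    im2col3<double>(REAL(x), nx, ny, nz, Ci, d_bufA.data());
    arma::mat A(d_bufA.data(), N, K, false, true);
    arma::mat dOut(REAL(dout), N, Co, false, true);
    arma::mat dW = A.t() * dOut;
    for (size_t i = 0; i < dW.n_elem; i++) dwv[i] = dW.memptr()[i];
    for (int c = 0; c < Co; c++) db[c] = arma::accu(dOut.col(c));
    if (want_dx) {
      if (d_bufB.size() < N * K) d_bufB.resize(N * K);
      arma::mat Wm(REAL(w), K, Co, false, true);
      arma::mat dA(d_bufB.data(), N, K, false, true);
      dA = dOut * Wm.t();
      col2im3<double>(d_bufB.data(), nx, ny, nz, Ci, REAL(dx));
    }
  }
  dwv.attr("dim") = IntegerVector::create(3, 3, 3, Ci, Co);
  return List::create(_["dx"] = dxs, _["dw"] = dwv, _["db"] = db);
}

// ----------------------------------------------------------------- warp ----

// trilinear sampling of src at p + phi[p], border-clamped
// [[Rcpp::export(name = ".warp_linear")]]
NumericVector warp_linear_cpp(NumericVector src, NumericVector field,
                              IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  const size_t N = (size_t)nx * ny * nz;
  const double *s = REAL(src), *f = REAL(field);
  NumericVector out(N * (size_t)C);
  double* o = REAL(out);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t p = ((size_t)z * ny + y) * nx + x;
        double ux = x + f[p], uy = y + f[p + N], uz = z + f[p + 2 * N];
        ux = std::min(std::max(ux, 0.0), (double)(nx - 1));
        uy = std::min(std::max(uy, 0.0), (double)(ny - 1));
        uz = std::min(std::max(uz, 0.0), (double)(nz - 1));
        int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
            z0 = (int)std::floor(uz);
        double fx = ux - x0, fy = uy - y0, fz = uz - z0;
        int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
            z1 = std::min(z0 + 1, nz - 1);
        for (int c = 0; c < C; c++) {
          const double* sc = s + (size_t)c * N;
          double c000 = sc[((size_t)z0 * ny + y0) * nx + x0];
          double c100 = sc[((size_t)z0 * ny + y0) * nx + x1];
          double c010 = sc[((size_t)z0 * ny + y1) * nx + x0];
          double c110 = sc[((size_t)z0 * ny + y1) * nx + x1];
          double c001 = sc[((size_t)z1 * ny + y0) * nx + x0];
          double c101 = sc[((size_t)z1 * ny + y0) * nx + x1];
          double c011 = sc[((size_t)z1 * ny + y1) * nx + x0];
          double c111 = sc[((size_t)z1 * ny + y1) * nx + x1];
          double cx00 = c000 + fx * (c100 - c000);
          double cx10 = c010 + fx * (c110 - c010);
          double cx01 = c001 + fx * (c101 - c001);
          double cx11 = c011 + fx * (c111 - c011);
          double cxy0 = cx00 + fy * (cx10 - cx00);
          double cxy1 = cx01 + fy * (cx11 - cx01);
          o[p + (size_t)c * N] = cxy0 + fz * (cxy1 - cxy0);
        }
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  return out;
}

// gradients of warp_linear w.r.t. source and field. Clamped samples carry
// zero gradient w.r.t. the field (derivative of the clamp).
// [[Rcpp::export(name = ".warp_linear_bwd")]]
List warp_linear_bwd_cpp(NumericVector src, NumericVector field,
                         NumericVector dout, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  const size_t N = (size_t)nx * ny * nz;
  const double *s = REAL(src), *f = REAL(field), *dO = REAL(dout);
  NumericVector dsrc(N * (size_t)C), dfield(N * 3);
  double *dS = REAL(dsrc), *dF = REAL(dfield);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t p = ((size_t)z * ny + y) * nx + x;
        double rx = x + f[p], ry = y + f[p + N], rz = z + f[p + 2 * N];
        double ux = std::min(std::max(rx, 0.0), (double)(nx - 1));
        double uy = std::min(std::max(ry, 0.0), (double)(ny - 1));
        double uz = std::min(std::max(rz, 0.0), (double)(nz - 1));
        double gx = (rx > 0.0 && rx < nx - 1) ? 1.0 : 0.0;
        double gy = (ry > 0.0 && ry < ny - 1) ? 1.0 : 0.0;
        double gz = (rz > 0.0 && rz < nz - 1) ? 1.0 : 0.0;
        int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
            z0 = (int)std::floor(uz);
        double fx = ux - x0, fy = uy - y0, fz = uz - z0;
        int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
            z1 = std::min(z0 + 1, nz - 1);
        double w000 = (1 - fx) * (1 - fy) * (1 - fz);
        double w100 = fx * (1 - fy) * (1 - fz);
        double w010 = (1 - fx) * fy * (1 - fz);
        double w110 = fx * fy * (1 - fz);
        double w001 = (1 - fx) * (1 - fy) * fz;
        double w101 = fx * (1 - fy) * fz;
        double w011 = (1 - fx) * fy * fz;
        double w111 = fx * fy * fz;
        size_t i000 = ((size_t)z0 * ny + y0) * nx + x0;
        size_t i100 = ((size_t)z0 * ny + y0) * nx + x1;
        size_t i010 = ((size_t)z0 * ny + y1) * nx + x0;
        size_t i110 = ((size_t)z0 * ny + y1) * nx + x1;
        size_t i001 = ((size_t)z1 * ny + y0) * nx + x0;
        size_t i101 = ((size_t)z1 * ny + y0) * nx + x1;
        size_t i011 = ((size_t)z1 * ny + y1) * nx + x0;
        size_t i111 = ((size_t)z1 * ny + y1) * nx + x1;
        double ax = 0, ay = 0, az = 0;
        for (int c = 0; c < C; c++) {
          const double* sc = s + (size_t)c * N;
          double g = dO[p + (size_t)c * N];
          dS[i000 + c * N] += g * w000;
          dS[i100 + c * N] += g * w100;
          dS[i010 + c * N] += g * w010;
          dS[i110 + c * N] += g * w110;
          dS[i001 + c * N] += g * w001;
          dS[i101 + c * N] += g * w101;
          dS[i011 + c * N] += g * w011;
          dS[i111 + c * N] += g * w111;
          double c000 = sc[i000], c100 = sc[i100], c010 = sc[i010],
                 c110 = sc[i110], c001 = sc[i001], c101 = sc[i101],
                 c011 = sc[i011], c111 = sc[i111];
          // d value / d fx etc.
          double dvx = (1 - fy) * (1 - fz) * (c100 - c000) +
                       fy * (1 - fz) * (c110 - c010) +
                       (1 - fy) * fz * (c101 - c001) + fy * fz * (c111 - c011);
          double dvy = (1 - fx) * (1 - fz) * (c010 - c000) +
                       fx * (1 - fz) * (c110 - c100) +
                       (1 - fx) * fz * (c011 - c001) + fx * fz * (c111 - c101);
          double dvz = (1 - fx) * (1 - fy) * (c001 - c000) +
                       fx * (1 - fy) * (c101 - c100) +
                       (1 - fx) * fy * (c011 - c010) + fx * fy * (c111 - c110);
          ax += g * dvx;
          ay += g * dvy;
          az += g * dvz;
        }
        dF[p] = gx * ax;
        dF[p + N] = gy * ay;
        dF[p + 2 * N] = gz * az;
      }
  dsrc.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  dfield.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["dsrc"] = dsrc, _["dfield"] = dfield);
}

// nearest-neighbour sampling; ties round half away from the grid origin
// (floor(u + 0.5) on the clamped non-negative coordinate)
// [[Rcpp::export(name = ".warp_nearest")]]
NumericVector warp_nearest_cpp(NumericVector src, NumericVector field,
                               IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  const size_t N = (size_t)nx * ny * nz;
  const double *s = REAL(src), *f = REAL(field);
  NumericVector out(N * (size_t)C);
  double* o = REAL(out);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t p = ((size_t)z * ny + y) * nx + x;
        double ux = x + f[p], uy = y + f[p + N], uz = z + f[p + 2 * N];
        ux = std::min(std::max(ux, 0.0), (double)(nx - 1));
        uy = std::min(std::max(uy, 0.0), (double)(ny - 1));
        uz = std::min(std::max(uz, 0.0), (double)(nz - 1));
        int xi = std::min((int)std::floor(ux + 0.5), nx - 1);
        int yi = std::min((int)std::floor(uy + 0.5), ny - 1);
        int zi = std::min((int)std::floor(uz + 0.5), nz - 1);
        size_t q = ((size_t)zi * ny + yi) * nx + xi;
        for (int c = 0; c < C; c++) o[p + (size_t)c * N] = s[q + (size_t)c * N];
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------- norm / act / pool ----

// group normalization over a batch-of-one tensor (nx,ny,nz,C), groups of
// consecutive channels; returns out plus per-group mean and inverse std
// [[Rcpp::export(name = ".gn_fwd")]]
List gn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                IntegerVector dim, int g, double eps) {
  const size_t N = (size_t)dim[0] * dim[1] * dim[2];
  int C = dim[3];
  int cg = C / g;
  const double* xp = REAL(x);
  NumericVector out(N * (size_t)C), mu(g), istd(g);
  double* op = REAL(out);
  for (int gi = 0; gi < g; gi++) {
    const double* xg = xp + (size_t)gi * cg * N;
    size_t m = (size_t)cg * N;
    double s = 0, ss = 0;
    for (size_t i = 0; i < m; i++) {
      s += xg[i];
      ss += xg[i] * xg[i];
    }
    double mean = s / m;
    double var = ss / m - mean * mean;
    double is = 1.0 / std::sqrt(var + eps);
    mu[gi] = mean;
    istd[gi] = is;
    for (int c = 0; c < cg; c++) {
      int ch = gi * cg + c;
      double ga = gamma[ch], be = beta[ch];
      const double* xi = xg + (size_t)c * N;
      double* oi = op + (size_t)ch * N;
      for (size_t i = 0; i < N; i++) oi[i] = ga * (xi[i] - mean) * is + be;
    }
  }
  out.attr("dim") = dim;
  return List::create(_["out"] = out, _["mu"] = mu, _["istd"] = istd,
                      _["g"] = g, _["dims"] = dim);
}

// [[Rcpp::export(name = ".gn_bwd")]]
List gn_bwd_cpp(NumericVector x, NumericVector gamma, NumericVector dout,
                NumericVector mu, NumericVector istd, IntegerVector dim,
                int g) {
  const size_t N = (size_t)dim[0] * dim[1] * dim[2];
  int C = dim[3];
  int cg = C / g;
  const double *xp = REAL(x), *dp = REAL(dout);
  NumericVector dx(N * (size_t)C), dgamma(C), dbeta(C);
  double* dxp = REAL(dx);
  for (int gi = 0; gi < g; gi++) {
    size_t m = (size_t)cg * N;
    double mean = mu[gi], is = istd[gi];
    double t1 = 0, t2 = 0;
    for (int c = 0; c < cg; c++) {
      int ch = gi * cg + c;
      const double* xi = xp + (size_t)ch * N;
      const double* di = dp + (size_t)ch * N;
      double ga = gamma[ch], sg = 0, sb = 0;
      for (size_t i = 0; i < N; i++) {
        double xh = (xi[i] - mean) * is;
        double dh = di[i] * ga;
        t1 += dh;
        t2 += dh * xh;
        sg += di[i] * xh;
        sb += di[i];
      }
      dgamma[ch] = sg;
      dbeta[ch] = sb;
    }
    t1 /= m;
    t2 /= m;
    for (int c = 0; c < cg; c++) {
      int ch = gi * cg + c;
      const double* xi = xp + (size_t)ch * N;
      const double* di = dp + (size_t)ch * N;
      double ga = gamma[ch];
      double* dxi = dxp + (size_t)ch * N;
      for (size_t i = 0; i < N; i++) {
        double xh = (xi[i] - mean) * is;
        dxi[i] = (di[i] * ga - t1 - xh * t2) * is;
      }
    }
  }
  dx.attr("dim") = dim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// activations: 0 = relu, 1 = leaky relu, 2 = sigmoid
// [[Rcpp::export(name = ".act_fwd")]]
NumericVector act_fwd_cpp(NumericVector x, int type, double slope) {
  size_t n = x.size();
  NumericVector out(n);
  const double* xp = REAL(x);
  double* op = REAL(out);
  if (type == 0) {
    for (size_t i = 0; i < n; i++) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  } else if (type == 1) {
    for (size_t i = 0; i < n; i++) op[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  } else {
    for (size_t i = 0; i < n; i++) op[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// backward from the pre-activation input (relu / lrelu) or output (sigmoid)
// [[Rcpp::export(name = ".act_bwd")]]
NumericVector act_bwd_cpp(NumericVector ref, NumericVector dout, int type,
                          double slope) {
  size_t n = ref.size();
  NumericVector dx(n);
  const double *rp = REAL(ref), *dp = REAL(dout);
  double* xp = REAL(dx);
  if (type == 0) {
    for (size_t i = 0; i < n; i++) xp[i] = rp[i] > 0 ? dp[i] : 0.0;
  } else if (type == 1) {
    for (size_t i = 0; i < n; i++) xp[i] = rp[i] > 0 ? dp[i] : slope * dp[i];
  } else {
    for (size_t i = 0; i < n; i++) xp[i] = dp[i] * rp[i] * (1.0 - rp[i]);
  }
  dx.attr("dim") = dout.attr("dim");
  return dx;
}

// 2x2x2 max pooling with argmax bookkeeping (offset index 0..7)
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  int hx = nx / 2, hy = ny / 2, hz = nz / 2;
  const size_t N = (size_t)nx * ny * nz;
  const size_t M = (size_t)hx * hy * hz;
  const double* xp = REAL(x);
  NumericVector out(M * (size_t)C);
  IntegerVector idx(M * (size_t)C);
  double* op = REAL(out);
  int* ip = INTEGER(idx);
  for (int c = 0; c < C; c++) {
    const double* xc = xp + (size_t)c * N;
    double* oc = op + (size_t)c * M;
    int* ic = ip + (size_t)c * M;
    for (int z = 0; z < hz; z++)
      for (int y = 0; y < hy; y++)
        for (int xo = 0; xo < hx; xo++) {
          double best = -1e300;
          int bk = 0;
          for (int dz = 0; dz < 2; dz++)
            for (int dy = 0; dy < 2; dy++)
              for (int dx = 0; dx < 2; dx++) {
                double v = xc[((size_t)(2 * z + dz) * ny + (2 * y + dy)) * nx +
                              (2 * xo + dx)];
                int k = dx + 2 * dy + 4 * dz;
                if (v > best) {
                  best = v;
                  bk = k;
                }
              }
          oc[((size_t)z * hy + y) * hx + xo] = best;
          ic[((size_t)z * hy + y) * hx + xo] = bk;
        }
  }
  out.attr("dim") = IntegerVector::create(hx, hy, hz, C);
  return List::create(_["out"] = out, _["idx"] = idx, _["dims"] = dim);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd_cpp(IntegerVector idx, NumericVector dout,
                               IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = dim[3];
  int hx = nx / 2, hy = ny / 2, hz = nz / 2;
  const size_t N = (size_t)nx * ny * nz;
  const size_t M = (size_t)hx * hy * hz;
  NumericVector dx(N * (size_t)C);
  double* xp = REAL(dx);
  const double* dp = REAL(dout);
  const int* ip = INTEGER(idx);
  for (int c = 0; c < C; c++) {
    const double* dc = dp + (size_t)c * M;
    const int* ic = ip + (size_t)c * M;
    double* xc = xp + (size_t)c * N;
    for (int z = 0; z < hz; z++)
      for (int y = 0; y < hy; y++)
        for (int xo = 0; xo < hx; xo++) {
          size_t o = ((size_t)z * hy + y) * hx + xo;
          int k = ic[o];
          int dxk = k & 1, dyk = (k >> 1) & 1, dzk = (k >> 2) & 1;
          xc[((size_t)(2 * z + dzk) * ny + (2 * y + dyk)) * nx +
             (2 * xo + dxk)] += dc[o];
        }
  }
  dx.attr("dim") = dim;
  return dx;
}

// ------------------------------------------------------------------ EDT ----

// 1D squared-distance transform over samples at positions i*s
// (Felzenszwalb-Huttenlocher lower envelope of parabolas)
static void dt1d(const double* fin, double* d, int* v, double* z, int n,
                 double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * s, fs = 0;
    while (true) {
      double xv = v[k] * s;
      fs = ((fin[q] + xq * xq) - (fin[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (fs <= z[k] && k > 0) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = fs;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + fin[v[k]];
  }
}

// Euclidean distance (in spacing units) from every voxel to the nearest
// site voxel. Exact for anisotropic spacing.
// [[Rcpp::export(name = ".edt_from_sites")]]
NumericVector edt_from_sites(LogicalVector sites, IntegerVector dim,
                             NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<double> g(N);
  for (size_t i = 0; i < N; i++) g[i] = sites[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> fbuf(nmax), dbuf(nmax), zbuf(nmax + 1);
  std::vector<int> vbuf(nmax);
  // x pass
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      double* row = &g[((size_t)z * ny + y) * nx];
      dt1d(row, dbuf.data(), vbuf.data(), zbuf.data(), nx, spacing[0]);
      std::memcpy(row, dbuf.data(), sizeof(double) * nx);
    }
  // y pass
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++) fbuf[y] = g[((size_t)z * ny + y) * nx + x];
      dt1d(fbuf.data(), dbuf.data(), vbuf.data(), zbuf.data(), ny, spacing[1]);
      for (int y = 0; y < ny; y++) g[((size_t)z * ny + y) * nx + x] = dbuf[y];
    }
  // z pass
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      for (int z = 0; z < nz; z++) fbuf[z] = g[((size_t)z * ny + y) * nx + x];
      dt1d(fbuf.data(), dbuf.data(), vbuf.data(), zbuf.data(), nz, spacing[2]);
      for (int z = 0; z < nz; z++) g[((size_t)z * ny + y) * nx + x] = dbuf[z];
    }
  NumericVector out(N);
  for (size_t i = 0; i < N; i++) out[i] = std::sqrt(g[i]);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
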