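#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather sliding 5x5 (or k x k) patches of a zero-padded (Hp x Wp x C) cube
// into a (p1 - p0) x (k*k*C) matrix, one row per output pixel.  Output pixels
// are indexed column-major over the (ho x wo) output grid: p = i + j * ho,
// 0-based.  Column layout: channel-major, then kernel column, then kernel row
// (dh fastest); the weight matrices use the same layout.
// [[Rcpp::export]]
arma::mat im2col_range(const arma::cube& xpad, int k, int stride,
                       int ho, int wo, int p0, int p1) {
  const int nc = xpad.n_slices;
  const int K = k * k * nc;
  const int P = ho * wo;
  arma::mat out(p1 - p0, K);
  if (p0 == 0 && p1 == P) {
    // full frame: each (c, dw, dh) column is a strided copy down the rows
    int col = 0;
    for (int c = 0; c < nc; ++c)
      for (int dw = 0; dw < k; ++dw)
        for (int dh = 0; dh < k; ++dh, ++col) {
          double* dst = out.colptr(col);
          for (int j = 0; j < wo; ++j) {
            const double* src = &xpad(dh, j * stride + dw, c);
            double* d = dst + (size_t)j * ho;
            for (int i = 0; i < ho; ++i) d[i] = src[(size_t)i * stride];
          }
        }
  } else {
    for (int p = p0; p < p1; ++p) {
      const int i = p % ho, j = p / ho;
      const int hi = i * stride, wj = j * stride;
      int col = 0;
      for (int c = 0; c < nc; ++c)
        for (int dw = 0; dw < k; ++dw)
          for (int dh = 0; dh < k; ++dh)
            out(p - p0, col++) = xpad(hi + dh, wj + dw, c);
    }
  }
  return out;
}

// Scatter-add the adjoint of im2col_range back onto the padded input grid.
// [[Rcpp::export]]
arma::cube col2im_acc(const arma::mat& dxcol, int hp, int wp, int nc,
                      int k, int stride, int ho, int wo) {
  arma::cube out(hp, wp, nc, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < nc; ++c)
    for (int dw = 0; dw < k; ++dw)
      for (int dh = 0; dh < k; ++dh, ++col) {
        const double* src = dxcol.colptr(col);
        for (int j = 0; j < wo; ++j) {
          double* dst = &out(dh, j * stride + dw, c);
          const double* s = src + (size_t)j * ho;
          for (int i = 0; i < ho; ++i) dst[(size_t)i * stride] += s[i];
        }
      }
  return out;
}

// Label 3D connected components of a logical volume stored column-major with
// dims = c(z, y, x).  connectivity is 6 (face) or 26 (face+edge+vertex).
// Returns an integer volume of the same length; background stays 0 and
// components are numbered 1..n in scan order.
// [[Rcpp::export]]
IntegerVector label_components_3d(const LogicalVector& mask,
                                  const IntegerVector& dims,
                                  int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> off_z, off_y, off_x;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (connectivity == 6 && (std::abs(dz) + std::abs(dy) + std::abs(dx)) != 1)
          continue;
        off_z.push_back(dz); off_y.push_back(dy); off_x.push_back(dx);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> todo;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    todo.clear();
    todo.push_back(s);
    while (!todo.empty()) {
      const R_xlen_t cur = todo.back();
      todo.pop_back();
      const int z = (int)(cur % nz);
      const int y = (int)((cur / nz) % ny);
      const int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (size_t q = 0; q < off_z.size(); ++q) {
        const int zz = z + off_z[q], yy = y + off_y[q], xx = x + off_x[q];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        const R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          todo.push_back(idx);
        }
      }
    }
  }
  return lab;
}

// CRC-32 (IEEE 802.3) of a raw vector, returned as a double so the full
// unsigned 32-bit range survives the trip into R.  Used by the ZIP writer.
// [[Rcpp::export]]
double crc32_raw(const RawVector& data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
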