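#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Oriented-Gaussian slice projector (forward A_k and exact adjoint A_k^T).
//
// The slice pixel (i,j) (0-based) sits at world point  srot * (i*ssp, j*ssp, 0)' + str.
// The PSF covariance `cov` is given in WORLD coordinates (already rotated into the
// volume frame by the slice transform).  Kernel weights are evaluated at volume
// voxel centers, truncated at Mahalanobis radius `trunc_sd`, and renormalized to
// sum to one over the in-extent support, so constants are mapped to constants.
// The adjoint reuses the identical weights, so <Ax, y> == <x, A'y> to rounding.
// [[Rcpp::export]]
SEXP cpp_project(NumericVector vol, IntegerVector vdim,
                 arma::mat vdir, arma::vec vsp, arma::vec vorg,
                 arma::mat srot, arma::vec str, double ssp,
                 int nx, int ny,
                 arma::mat cov, double trunc_sd,
                 int mode, NumericMatrix y) {
  const int n0 = vdim[0], n1 = vdim[1], n2 = vdim[2];
  arma::mat icov = arma::inv_sympd(cov);
  arma::mat W2I = arma::diagmat(1.0 / vsp) * vdir.t();  // world offset -> index offset
  arma::mat Sidx = W2I * cov * W2I.t();
  const double hw0 = trunc_sd * std::sqrt(Sidx(0, 0));
  const double hw1 = trunc_sd * std::sqrt(Sidx(1, 1));
  const double hw2 = trunc_sd * std::sqrt(Sidx(2, 2));
  const double t2 = trunc_sd * trunc_sd;
  const double *xv = vol.begin();

  NumericMatrix out_f(nx, ny);
  NumericVector out_a;
  if (mode == 1) {
    out_a = NumericVector((R_xlen_t)n0 * n1 * n2);
    out_a.attr("dim") = vdim;
  }
  int nsupp = 0;
  std::vector<int> idxbuf;
  std::vector<double> wbuf;
  idxbuf.reserve(512); wbuf.reserve(512);

  // voxel-index step vectors in world coordinates and their icov images,
  // hoisted so the inner loop is an incremental quadratic-form update
  arma::vec u0 = vdir.col(0) * vsp(0), u1 = vdir.col(1) * vsp(1),
            u2 = vdir.col(2) * vsp(2);
  arma::vec e0 = icov * u0, e1 = icov * u1, e2 = icov * u2;
  const double q00 = arma::dot(u0, e0);
  arma::vec c(3), ic(3), base(3), eb(3), row(3);
  for (int j = 0; j < ny; j++) {
    for (int i = 0; i < nx; i++) {
      c = srot.col(0) * (i * ssp) + srot.col(1) * (j * ssp) + str;
      ic = W2I * (c - vorg);
      int a0 = (int)std::ceil(ic(0) - hw0), b0 = (int)std::floor(ic(0) + hw0);
      int a1 = (int)std::ceil(ic(1) - hw1), b1 = (int)std::floor(ic(1) + hw1);
      int a2 = (int)std::ceil(ic(2) - hw2), b2 = (int)std::floor(ic(2) + hw2);
      if (a0 < 0) a0 = 0; if (b0 > n0 - 1) b0 = n0 - 1;
      if (a1 < 0) a1 = 0; if (b1 > n1 - 1) b1 = n1 - 1;
      if (a2 < 0) a2 = 0; if (b2 > n2 - 1) b2 = n2 - 1;
      if (a0 > b0 || a1 > b1 || a2 > b2) continue;
      idxbuf.clear(); wbuf.clear();
      double Wsum = 0.0;
      for (int q2 = a2; q2 <= b2; q2++) {
        for (int q1 = a1; q1 <= b1; q1++) {
          base = vorg - c + u1 * q1 + u2 * q2;
          eb = icov * base;
          const double m_base = arma::dot(base, eb);
          const double m_lin = 2.0 * arma::dot(u0, eb);
          const R_xlen_t rowpos = (R_xlen_t)n0 * (q1 + (R_xlen_t)n1 * q2);
          for (int q0 = a0; q0 <= b0; q0++) {
            double m = m_base + q0 * (m_lin + q0 * q00);
            if (m <= t2) {
              double w = std::exp(-0.5 * m);
              Wsum += w;
              idxbuf.push_back(q0 + rowpos);
              wbuf.push_back(w);
            }
          }
        }
      }
      if (Wsum <= 0.0) continue;
      nsupp++;
      if (mode == 0) {
        double acc = 0.0;
        for (size_t t = 0; t < wbuf.size(); ++t) acc += wbuf[t] * xv[idxbuf[t]];
        out_f(i, j) = acc / Wsum;
      } else {
        double coef = y(i, j) / Wsum;
        if (coef != 0.0)
          for (size_t t = 0; t < wbuf.size(); ++t) out_a[idxbuf[t]] += coef * wbuf[t];
      }
    }
  }
  if (mode == 0) { out_f.attr("n_support") = nsupp; return out_f; }
  out_a.attr("n_support") = nsupp;
  return out_a;
}

static inline double catmull_rom(double t, int k) {
  // weight of tap k in {-1,0,1,2} for fractional offset t in [0,1)
  double a = -0.5;
  double x = std::fabs(t - (k - 1));
  if (x < 1.0) return (a + 2.0) * x * x * x - (a + 3.0) * x * x + 1.0;
  if (x < 2.0) return a * x * x * x - 5.0 * a * x * x + 8.0 * a * x - 4.0 * a;
  return 0.0;
}

// Resample `vol` onto a target grid.  `trot`/`ttr` map TARGET world points into
// SOURCE world points (ITK sampling convention).  Out-of-extent -> 0.
// method: 0 nearest (ties toward the lower index), 1 trilinear, 2 cubic spline.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector vdim,
                           arma::mat sdir, arma::vec ssp, arma::vec sorg,
                           IntegerVector tdim,
                           arma::mat tdir, arma::vec tsp, arma::vec torg,
                           arma::mat trot, arma::vec ttr,
                           int method) {
  const int n0 = vdim[0], n1 = vdim[1], n2 = vdim[2];
  const int m0 = tdim[0], m1 = tdim[1], m2 = tdim[2];
  arma::mat W2I = arma::diagmat(1.0 / ssp) * sdir.t();
  const double *xv = vol.begin();
  NumericVector out((R_xlen_t)m0 * m1 * m2);
  out.attr("dim") = tdim;
  arma::vec w(3), p(3), s(3);
  R_xlen_t pos = 0;
  for (int q2 = 0; q2 < m2; q2++) {
    for (int q1 = 0; q1 < m1; q1++) {
      for (int q0 = 0; q0 < m0; q0++, pos++) {
        w = tdir.col(0) * (tsp(0) * q0) + tdir.col(1) * (tsp(1) * q1) +
            tdir.col(2) * (tsp(2) * q2) + torg;
        p = trot * w + ttr;
        s = W2I * (p - sorg);
        if (method == 0) {
          int i0 = (int)std::ceil(s(0) - 0.5);
          int i1 = (int)std::ceil(s(1) - 0.5);
          int i2 = (int)std::ceil(s(2) - 0.5);
          if (i0 < 0 || i0 >= n0 || i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2) continue;
          out[pos] = xv[i0 + n0 * (i1 + n1 * i2)];
        } else if (method == 1) {
          int f0 = (int)std::floor(s(0)), f1 = (int)std::floor(s(1)), f2 = (int)std::floor(s(2));
          double t0 = s(0) - f0, t1 = s(1) - f1, t2 = s(2) - f2;
          double acc = 0.0;
          for (int c2 = 0; c2 <= 1; c2++) {
            int i2 = f2 + c2; if (i2 < 0 || i2 >= n2) continue;
            double w2 = c2 ? t2 : 1.0 - t2;
            for (int c1 = 0; c1 <= 1; c1++) {
              int i1 = f1 + c1; if (i1 < 0 || i1 >= n1) continue;
              double w1 = c1 ? t1 : 1.0 - t1;
              for (int c0 = 0; c0 <= 1; c0++) {
                int i0 = f0 + c0; if (i0 < 0 || i0 >= n0) continue;
                double w0 = c0 ? t0 : 1.0 - t0;
                acc += w0 * w1 * w2 * xv[i0 + n0 * (i1 + n1 * i2)];
              }
            }
          }
          out[pos] = acc;
        } else {
          int f0 = (int)std::floor(s(0)), f1 = (int)std::floor(s(1)), f2 = (int)std::floor(s(2));
          double t0 = s(0) - f0, t1 = s(1) - f1, t2 = s(2) - f2;
          double acc = 0.0;
          for (int c2 = 0; c2 <= 3; c2++) {
            int i2 = f2 + c2 - 1; if (i2 < 0 || i2 >= n2) continue;
            double w2 = catmull_rom(t2, c2);
            for (int c1 = 0; c1 <= 3; c1++) {
              int i1 = f1 + c1 - 1; if (i1 < 0 || i1 >= n1) continue;
              double w1 = catmull_rom(t1, c1);
              for (int c0 = 0; c0 <= 3; c0++) {
                int i0 = f0 + c0 - 1; if (i0 < 0 || i0 >= n0) continue;
                acc += catmull_rom(t0, c0) * w1 * w2 * xv[i0 + n0 * (i1 + n1 * i2)];
              }
            }
          }
          out[pos] = acc;
        }
      }
    }
  }
  return out;
}

// Nearest-voxel splat of scattered samples onto a regular grid; ties toward the
// lower index.  Returns the weighted-value and weight accumulation arrays.
// pts: 3 x n continuous 0-based voxel indices in the target grid.
// [[Rcpp::export]]
List cpp_splat(arma::mat pts, NumericVector vals, NumericVector wts, IntegerVector tdim) {
  const int n0 = tdim[0], n1 = tdim[1], n2 = tdim[2];
  NumericVector num((R_xlen_t)n0 * n1 * n2), den((R_xlen_t)n0 * n1 * n2);
  num.attr("dim") = tdim; den.attr("dim") = tdim;
  const arma::uword n = pts.n_cols;
  for (arma::uword k = 0; k < n; k++) {
    int i0 = (int)std::ceil(pts(0, k) - 0.5);
    int i1 = (int)std::ceil(pts(1, k) - 0.5);
    int i2 = (int)std::ceil(pts(2, k) - 0.5);
    if (i0 < 0 || i0 >= n0 || i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2) continue;
    R_xlen_t pos = i0 + (R_xlen_t)n0 * (i1 + (R_xlen_t)n1 * i2);
    num[pos] += wts[k] * vals[k];
    den[pos] += wts[k];
  }
  return List::create(_["num"] = num, _["den"] = den);
}

// 26-connected component labelling of a binary 3D array (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back(); queue.pop_back();
      int i0 = cur % n0, i1 = (cur / n0) % n1, i2 = cur / ((R_xlen_t)n0 * n1);
      for (int d2 = -1; d2 <= 1; d2++) {
        int j2 = i2 + d2; if (j2 < 0 || j2 >= n2) continue;
        for (int d1 = -1; d1 <= 1; d1++) {
          int j1 = i1 + d1; if (j1 < 0 || j1 >= n1) continue;
          for (int d0 = -1; d0 <= 1; d0++) {
            int j0 = i0 + d0; if (j0 < 0 || j0 >= n0) continue;
            R_xlen_t q = j0 + (R_xlen_t)n0 * (j1 + (R_xlen_t)n1 * j2);
            if (mask[q] && !lab[q]) { lab[q] = next; queue.push_back(q); }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// max over columns of A of the min Euclidean distance to any column of B.
// [[Rcpp::export]]
double cpp_maxmin_dist(arma::mat A, arma::mat B) {
  double worst = 0.0;
  for (arma::uword i = 0; i < A.n_cols; i++) {
    double best = arma::datum::inf;
    for (arma::uword j = 0; j < B.n_cols; j++) {
      double d = arma::norm(A.col(i) - B.col(j));
      if (d < best) best = d;
    }
    if (best > worst) worst = best;
  }
  return worst;
}

// Batched projector over many slices sharing one volume grid: one call per
// solver iteration instead of one per slice.  Slice s has rotation columns
// srots.cols(3s..3s+2), translation strs.col(s), pixel spacing ssps[s], shape
// nxs[s] x nys[s] and world-frame PSF covariance covs.cols(3s..3s+2).
// mode 0: returns the concatenated forward projections (pixel-major per
// slice); mode 1: consumes the concatenated y and returns the accumulated
// adjoint volume.
// [[Rcpp::export]]
NumericVector cpp_project_batch(NumericVector vol, IntegerVector vdim,
                                arma::mat vdir, arma::vec vsp, arma::vec vorg,
                                arma::mat srots, arma::mat strs,
                                arma::vec ssps, IntegerVector nxs,
                                IntegerVector nys, arma::mat covs,
                                double trunc_sd, int mode, NumericVector yflat) {
  const int n0 = vdim[0], n1 = vdim[1], n2 = vdim[2];
  const int nsl = strs.n_cols;
  const double t2 = trunc_sd * trunc_sd;
  const double *xv = vol.begin();
  arma::mat W2I = arma::diagmat(1.0 / vsp) * vdir.t();
  arma::vec u0 = vdir.col(0) * vsp(0), u1 = vdir.col(1) * vsp(1),
            u2 = vdir.col(2) * vsp(2);

  R_xlen_t total_px = 0;
  for (int s = 0; s < nsl; s++) total_px += (R_xlen_t)nxs[s] * nys[s];
  NumericVector out(mode == 0 ? total_px : (R_xlen_t)n0 * n1 * n2);
  if (mode == 1) out.attr("dim") = vdim;

  std::vector<int> idxbuf; std::vector<double> wbuf;
  idxbuf.reserve(1024); wbuf.reserve(1024);
  arma::vec c(3), ic(3), base(3), eb(3);
  R_xlen_t off = 0;
  for (int s = 0; s < nsl; s++) {
    arma::mat srot = srots.cols(3 * s, 3 * s + 2);
    arma::vec str = strs.col(s);
    const double ssp = ssps(s);
    const int nx = nxs[s], ny = nys[s];
    arma::mat icov = arma::inv_sympd(covs.cols(3 * s, 3 * s + 2));
    arma::mat Sidx = W2I * covs.cols(3 * s, 3 * s + 2) * W2I.t();
    const double hw0 = trunc_sd * std::sqrt(Sidx(0, 0));
    const double hw1 = trunc_sd * std::sqrt(Sidx(1, 1));
    const double hw2 = trunc_sd * std::sqrt(Sidx(2, 2));
    arma::vec e0 = icov * u0;
    const double q00 = arma::dot(u0, e0);
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        const R_xlen_t pix = off + i + (R_xlen_t)nx * j;
        c = srot.col(0) * (i * ssp) + srot.col(1) * (j * ssp) + str;
        ic = W2I * (c - vorg);
        int a0 = (int)std::ceil(ic(0) - hw0), b0 = (int)std::floor(ic(0) + hw0);
        int a1 = (int)std::ceil(ic(1) - hw1), b1 = (int)std::floor(ic(1) + hw1);
        int a2 = (int)std::ceil(ic(2) - hw2), b2 = (int)std::floor(ic(2) + hw2);
        if (a0 < 0) a0 = 0; if (b0 > n0 - 1) b0 = n0 - 1;
        if (a1 < 0) a1 = 0; if (b1 > n1 - 1) b1 = n1 - 1;
        if (a2 < 0) a2 = 0; if (b2 > n2 - 1) b2 = n2 - 1;
        if (a0 > b0 || a1 > b1 || a2 > b2) continue;
        idxbuf.clear(); wbuf.clear();
        double Wsum = 0.0;
        for (int q2 = a2; q2 <= b2; q2++) {
          for (int q1 = a1; q1 <= b1; q1++) {
            base = vorg - c + u1 * q1 + u2 * q2;
            eb = icov * base;
            const double m_base = arma::dot(base, eb);
            const double m_lin = 2.0 * arma::dot(u0, eb);
            const R_xlen_t rowpos = (R_xlen_t)n0 * (q1 + (R_xlen_t)n1 * q2);
            for (int q0 = a0; q0 <= b0; q0++) {
              double m = m_base + q0 * (m_lin + q0 * q00);
              if (m <= t2) {
                double w = std::exp(-0.5 * m);
                Wsum += w;
                idxbuf.push_back(q0 + rowpos);
                wbuf.push_back(w);
              }
            }
          }
        }
        if (Wsum <= 0.0) continue;
        if (mode == 0) {
          double acc = 0.0;
          for (size_t t = 0; t < wbuf.size(); ++t) acc += wbuf[t] * xv[idxbuf[t]];
          out[pix] = acc / Wsum;
        } else {
          double coef = yflat[pix] / Wsum;
          if (coef != 0.0)
            for (size_t t = 0; t < wbuf.size(); ++t) out[idxbuf[t]] += coef * wbuf[t];
        }
      }
    }
    off += (R_xlen_t)nx * ny;
  }
  return out;
}

// Interpolate `vol` at transformed world points: value i is taken at
// rot * pts.col(i) + tr in the volume's world frame.  Points falling outside
// the extent yield NA.  method: 0 nearest, 1 trilinear.
// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector vol, IntegerVector vdim,
                                arma::mat sdir, arma::vec ssp, arma::vec sorg,
                                arma::mat pts, arma::mat rot, arma::vec tr,
                                int method) {
  const int n0 = vdim[0], n1 = vdim[1], n2 = vdim[2];
  arma::mat W2I = arma::diagmat(1.0 / ssp) * sdir.t();
  const double *xv = vol.begin();
  const arma::uword n = pts.n_cols;
  NumericVector out(n);
  arma::vec p(3), s(3);
  for (arma::uword k = 0; k < n; k++) {
    p = rot * pts.col(k) + tr;
    s = W2I * (p - sorg);
    if (method == 0) {
      int i0 = (int)std::ceil(s(0) - 0.5);
      int i1 = (int)std::ceil(s(1) - 0.5);
      int i2 = (int)std::ceil(s(2) - 0.5);
      if (i0 < 0 || i0 >= n0 || i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2) {
        out[k] = NA_REAL;
      } else {
        out[k] = xv[i0 + n0 * (i1 + n1 * i2)];
      }
    } else {
      int f0 = (int)std::floor(s(0)), f1 = (int)std::floor(s(1)), f2 = (int)std::floor(s(2));
      if (f0 < 0 || f0 + 1 >= n0 || f1 < 0 || f1 + 1 >= n1 || f2 < 0 || f2 + 1 >= n2) {
        out[k] = NA_REAL;
        continue;
      }
      double t0 = s(0) - f0, t1 = s(1) - f1, t2 = s(2) - f2;
      double acc = 0.0;
      for (int c2 = 0; c2 <= 1; c2++)
        for (int c1 = 0; c1 <= 1; c1++)
          for (int c0 = 0; c0 <= 1; c0++)
            acc += (c0 ? t0 : 1 - t0) * (c1 ? t1 : 1 - t1) * (c2 ? t2 : 1 - t2) *
                   xv[(f0 + c0) + n0 * ((f1 + c1) + n1 * (f2 + c2))];
      out[k] = acc;
    }
  }
  return out;
}
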