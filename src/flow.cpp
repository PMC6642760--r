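#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Horn-Schunck optical flow between two grayscale frames.
//
// u is the flow component along columns (image x, rightward), v along rows
// (image y, downward).  Spatial/temporal derivatives use the classical
// forward-difference averages over the 2x2x2 cube; the smoothness term uses
// the 6/12-weighted neighbour average; the solver is the Jacobi fixed-point
// iteration from zero initial flow.  Border pixels replicate their nearest
// interior neighbour.
// [[Rcpp::export(name = ".hornSchunckCpp")]]
List hornSchunckCpp(NumericMatrix a, NumericMatrix b, double alpha,
                    int nIter, bool trace = false) {
  const int nr = a.nrow(), nc = a.ncol();
  NumericMatrix Ex(nr, nc), Ey(nr, nc), Et(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j1 = std::min(j + 1, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int i1 = std::min(i + 1, nr - 1);
      Ex(i, j) = 0.25 * ((a(i, j1) - a(i, j)) + (a(i1, j1) - a(i1, j)) +
                         (b(i, j1) - b(i, j)) + (b(i1, j1) - b(i1, j)));
      Ey(i, j) = 0.25 * ((a(i1, j) - a(i, j)) + (a(i1, j1) - a(i, j1)) +
                         (b(i1, j) - b(i, j)) + (b(i1, j1) - b(i, j1)));
      Et(i, j) = 0.25 * ((b(i, j) - a(i, j)) + (b(i1, j) - a(i1, j)) +
                         (b(i, j1) - a(i, j1)) + (b(i1, j1) - a(i1, j1)));
    }
  }

  NumericMatrix u(nr, nc), v(nr, nc), un(nr, nc), vn(nr, nc);
  NumericVector resid(trace ? nIter : 0);
  const double a2 = alpha * alpha;
  const size_t n = (size_t)nr * nc;

  // Precompute the per-pixel update coefficients once.
  std::vector<double> cEx(n), cEy(n), cEt(n), den(n);
  {
    const double *ex = REAL(Ex), *ey = REAL(Ey), *et = REAL(Et);
    for (size_t q = 0; q < n; ++q) {
      cEx[q] = ex[q];
      cEy[q] = ey[q];
      cEt[q] = et[q];
      den[q] = a2 + ex[q] * ex[q] + ey[q] * ey[q];
    }
  }

  double *up = REAL(u), *vp = REAL(v), *unp = REAL(un), *vnp = REAL(vn);
  for (int it = 0; it < nIter; ++it) {
    for (int j = 0; j < nc; ++j) {
      const int jm = std::max(j - 1, 0), jp = std::min(j + 1, nc - 1);
      const double *ucm = up + (size_t)jm * nr, *ucc = up + (size_t)j * nr,
                   *ucp = up + (size_t)jp * nr;
      const double *vcm = vp + (size_t)jm * nr, *vcc = vp + (size_t)j * nr,
                   *vcp = vp + (size_t)jp * nr;
      double *uo = unp + (size_t)j * nr, *vo = vnp + (size_t)j * nr;
      const size_t col = (size_t)j * nr;
      for (int i = 0; i < nr; ++i) {
        const int im = std::max(i - 1, 0), ip = std::min(i + 1, nr - 1);
        const double ubar =
            (ucm[i] + ucp[i] + ucc[im] + ucc[ip]) / 6.0 +
            (ucm[im] + ucm[ip] + ucp[im] + ucp[ip]) / 12.0;
        const double vbar =
            (vcm[i] + vcp[i] + vcc[im] + vcc[ip]) / 6.0 +
            (vcm[im] + vcm[ip] + vcp[im] + vcp[ip]) / 12.0;
        const size_t q = col + i;
        const double num = (cEx[q] * ubar + cEy[q] * vbar + cEt[q]) / den[q];
        uo[i] = ubar - cEx[q] * num;
        vo[i] = vbar - cEy[q] * num;
      }
    }
    std::swap(up, unp);
    std::swap(vp, vnp);
    if (trace) {
      double s = 0.0;
      for (size_t q = 0; q < n; ++q) {
        double r = cEx[q] * up[q] + cEy[q] * vp[q] + cEt[q];
        s += r * r;
      }
      resid[it] = s;
    }
  }

  // After an odd number of swaps the freshest values live in un/vn.
  NumericMatrix uOut = (up == REAL(u)) ? u : un;
  NumericMatrix vOut = (vp == REAL(v)) ? v : vn;
  List out = List::create(Named("u") = uOut, Named("v") = vOut);
  if (trace) out["residuals"] = resid;
  return out;
}

// 2-D median filter with shrinking windows at the borders: the neighbourhood
// is clipped to the image, never padded.  The median of an even-sized window
// is the mean of the two central order statistics (matching stats::median).
// [[Rcpp::export(name = ".medianFilter2dCpp")]]
NumericMatrix medianFilter2dCpp(NumericMatrix x, int size) {
  const int nr = x.nrow(), nc = x.ncol(), h = size / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)size * size);
  for (int j = 0; j < nc; ++j) {
    int j0 = std::max(j - h, 0), j1 = std::min(j + h, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(i - h, 0), i1 = std::min(i + h, nr - 1);
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) buf.push_back(x(ii, jj));
      size_t n = buf.size(), m = n / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}
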