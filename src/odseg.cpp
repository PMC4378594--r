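#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Harmonic (Laplace) inpainting of the pixels flagged in `mask`, holding all
// other pixels fixed as Dirichlet data. Red-black (checkerboard) Gauss-Seidel,
// optionally over-relaxed (omega > 1, SOR); stops when the largest per-pixel
// update falls below `tol` or after `maxit` sweeps. Border pixels average
// over their in-bounds neighbours only. Results are clamped to the range of
// the Dirichlet data, so the discrete maximum principle holds exactly even
// for unconverged or over-relaxed sweeps.
// [[Rcpp::export(name = ".inpaint_gs")]]
NumericMatrix inpaint_gs(NumericMatrix img, LogicalMatrix mask,
                         double tol, int maxit, double omega = 1.0) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out = clone(img);

  // collect masked pixel coordinates, split by checkerboard colour
  std::vector<int> ri[2], ci[2];
  double init = 0.0; long nfree = 0;
  double lo = R_PosInf, hi = R_NegInf;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (!mask(i, j)) {
        double v = out(i, j);
        init += v; ++nfree;
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
  init = nfree > 0 ? init / nfree : 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) {
        int col = (i + j) & 1;
        ri[col].push_back(i); ci[col].push_back(j);
        out(i, j) = init;  // deterministic start: mean of the fixed data
      }
  if (ri[0].empty() && ri[1].empty()) return out;

  int it = 0;
  for (; it < maxit; ++it) {
    double delta = 0.0;
    for (int col = 0; col < 2; ++col) {
      const std::vector<int> &rr = ri[col], &cc = ci[col];
      for (size_t k = 0; k < rr.size(); ++k) {
        int i = rr[k], j = cc[k];
        double s = 0.0; int n = 0;
        if (i > 0)      { s += out(i - 1, j); ++n; }
        if (i < nr - 1) { s += out(i + 1, j); ++n; }
        if (j > 0)      { s += out(i, j - 1); ++n; }
        if (j < nc - 1) { s += out(i, j + 1); ++n; }
        double v = out(i, j) + omega * (s / n - out(i, j));
        if (v < lo) v = lo;
        if (v > hi) v = hi;
        double d = std::fabs(v - out(i, j));
        if (d > delta) delta = d;
        out(i, j) = v;
      }
    }
    if (delta < tol) { ++it; break; }
  }
  out.attr("iterations") = it;
  return out;
}

// Circle-Hough accumulator for one radius: every edge pixel votes for all
// candidate centres displaced by the supplied circle offsets.
// [[Rcpp::export(name = ".hough_accumulate")]]
IntegerMatrix hough_accumulate(IntegerVector er, IntegerVector ec,
                               int nr, int nc,
                               IntegerVector dy, IntegerVector dx) {
  IntegerMatrix acc(nr, nc);
  int ne = er.size(), no = dy.size();
  for (int k = 0; k < ne; ++k) {
    int r0 = er[k], c0 = ec[k];
    for (int o = 0; o < no; ++o) {
      int r = r0 + dy[o], c = c0 + dx[o];
      if (r >= 0 && r < nr && c >= 0 && c < nc) acc(r, c) += 1;
    }
  }
  return acc;
}

// 8-connected component labelling of a binary mask (stack-based flood fill).
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
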