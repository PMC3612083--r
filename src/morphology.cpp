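#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale erosion by a non-flat structuring element.
// se is a (2r+1)x(2r+1) matrix of heights, NA outside the support.
// Border handling: offsets falling outside the image are ignored
// (equivalent to padding with +Inf), which keeps the envelope below
// the observed surface near edges.
// [[Rcpp::export]]
NumericMatrix cpp_ball_erode(NumericMatrix img, NumericMatrix se) {
  int nr = img.nrow(), nc = img.ncol();
  int sr = se.nrow(), sc = se.ncol();
  int rr = sr / 2, rc = sc / 2;
  NumericMatrix out(nr, nc);

  // Precompute support offsets and heights
  std::vector<int> di, dj;
  std::vector<double> h;
  for (int i = 0; i < sr; ++i)
    for (int j = 0; j < sc; ++j)
      if (!NumericMatrix::is_na(se(i, j))) {
        di.push_back(i - rr);
        dj.push_back(j - rc);
        h.push_back(se(i, j));
      }
  int m = (int)di.size();

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = img(ii, jj) - h[k];
        if (v < best) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Grayscale dilation by a non-flat structuring element (reflected kernel).
// [[Rcpp::export]]
NumericMatrix cpp_ball_dilate(NumericMatrix img, NumericMatrix se) {
  int nr = img.nrow(), nc = img.ncol();
  int sr = se.nrow(), sc = se.ncol();
  int rr = sr / 2, rc = sc / 2;
  NumericMatrix out(nr, nc);

  std::vector<int> di, dj;
  std::vector<double> h;
  for (int i = 0; i < sr; ++i)
    for (int j = 0; j < sc; ++j)
      if (!NumericMatrix::is_na(se(i, j))) {
        di.push_back(i - rr);
        dj.push_back(j - rc);
        h.push_back(se(i, j));
      }
  int m = (int)di.size();

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = R_NegInf;
      for (int k = 0; k < m; ++k) {
        int ii = i - di[k], jj = j - dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = img(ii, jj) + h[k];
        if (v > best) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// 8-connected component labeling of a logical/0-1 matrix.
// Labels are assigned in column-major scan order of the first pixel of
// each component, so the result is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::queue<std::pair<int, int> > q;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < 8; ++k) {
          int ii = p.first + di[k], jj = p.second + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
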