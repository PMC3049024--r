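// Dynamic programming cores for profile searches and progressive alignment.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// Local (Smith-Waterman style) alignment of a position-specific score model
// against one integer-coded target sequence, affine gaps with per-column
// open/extend penalties. Returns the best local score and its target span.

static void pssm_local_one(const mat &S, const vec &gapo, const vec &gape,
                           const int *target, int n, double &best,
                           int &t_from, int &t_to,
                           std::vector<double> &Mrow, std::vector<double> &Xrow,
                           std::vector<double> &Yrow, std::vector<int> &st0,
                           std::vector<int> &st1) {
  const int L = S.n_rows;
  const double NEG = -1e30;
  Mrow.assign(n + 1, 0.0);
  Xrow.assign(n + 1, NEG);
  Yrow.assign(n + 1, NEG);
  st0.assign(n + 1, 0);
  st1.assign(n + 1, 0);
  for (int j = 0; j <= n; ++j) st0[j] = j;
  best = 0.0; t_from = 0; t_to = 0;
  const double *Sp = S.memptr();        // column-major, L rows
  for (int i = 1; i <= L; ++i) {
    const double go = gapo[i - 1], ge = gape[i - 1];
    double diagM = Mrow[0], diagX = Xrow[0], diagY = Yrow[0];
    int diagS = st0[0];
    Mrow[0] = 0.0; Xrow[0] = NEG; Yrow[0] = NEG;
    st1[0] = 0;
    double yprev = NEG;
    for (int j = 1; j <= n; ++j) {
      double upM = Mrow[j], upX = Xrow[j], upY = Yrow[j];
      int upS = st0[j];
      double sub = Sp[(size_t)target[j - 1] * L + (i - 1)];
      double m0 = diagM;
      int s0 = diagS;
      if (diagX > m0) { m0 = diagX; }
      if (diagY > m0) { m0 = diagY; }
      if (0.0 >= m0) { m0 = 0.0; s0 = j - 1; }
      double mc = sub + m0;
      double xc = std::max(upM - go, upX - ge);
      double yc = std::max(Mrow[j - 1] - go, yprev - ge);
      Mrow[j] = mc; Xrow[j] = xc; Yrow[j] = yc; yprev = yc;
      st1[j] = s0;
      if (mc > best) { best = mc; t_from = s0 + 1; t_to = j; }
      diagM = upM; diagX = upX; diagY = upY; diagS = upS;
    }
    std::swap(st0, st1);
  }
}

// [[Rcpp::export]]
List cpp_pssm_search(const arma::mat &S, const arma::vec &gapo,
                     const arma::vec &gape, const Rcpp::List &targets) {
  int nt = targets.size();
  Rcpp::NumericVector score(nt);
  Rcpp::IntegerVector from(nt), to(nt);
  std::vector<double> Mrow, Xrow, Yrow;
  std::vector<int> st0, st1;
  for (int t = 0; t < nt; ++t) {
    Rcpp::IntegerVector tg = targets[t];
    double b; int f, e;
    pssm_local_one(S, gapo, gape, tg.begin(), tg.size(), b, f, e,
                   Mrow, Xrow, Yrow, st0, st1);
    score[t] = b; from[t] = f; to[t] = e;
  }
  return List::create(Named("score") = score, Named("from") = from,
                      Named("to") = to);
}

// Global affine alignment of two profiles given a precomputed column-pair
// score matrix S (La x Lb). Returns two index vectors (0 = gap).

// [[Rcpp::export]]
List cpp_profile_align(const arma::mat &S, double gapo, double gape) {
  const int La = S.n_rows, Lb = S.n_cols;
  const double NEG = -1e30;
  mat M(La + 1, Lb + 1, fill::value(NEG));
  mat X(La + 1, Lb + 1, fill::value(NEG)); // gap in B (A column alone)
  mat Y(La + 1, Lb + 1, fill::value(NEG)); // gap in A
  M(0, 0) = 0.0;
  for (int i = 1; i <= La; ++i) X(i, 0) = -gapo - gape * (i - 1);
  for (int j = 1; j <= Lb; ++j) Y(0, j) = -gapo - gape * (j - 1);
  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      double d = std::max(std::max(M(i - 1, j - 1), X(i - 1, j - 1)),
                          Y(i - 1, j - 1));
      M(i, j) = d + S(i - 1, j - 1);
      X(i, j) = std::max(std::max(M(i - 1, j) - gapo, X(i - 1, j) - gape),
                         Y(i - 1, j) - gapo);
      Y(i, j) = std::max(std::max(M(i, j - 1) - gapo, Y(i, j - 1) - gape),
                         X(i, j - 1) - gapo);
    }
  }
  // traceback
  std::vector<int> ai, bi;
  int i = La, j = Lb;
  int state; // 0=M,1=X,2=Y
  double fin = std::max(std::max(M(i, j), X(i, j)), Y(i, j));
  state = (fin == M(i, j)) ? 0 : (fin == X(i, j)) ? 1 : 2;
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      ai.push_back(i); bi.push_back(j);
      double d = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      state = (std::fabs(d - M(i, j)) < 1e-9) ? 0
              : (std::fabs(d - X(i, j)) < 1e-9) ? 1 : 2;
    } else if ((state == 1 && i > 0) || (j == 0 && i > 0)) {
      ai.push_back(i); bi.push_back(0);
      double v = X(i, j);
      --i;
      if (std::fabs(v - (M(i, j) - gapo)) < 1e-9) state = 0;
      else if (std::fabs(v - (X(i, j) - gape)) < 1e-9) state = 1;
      else state = 2;
    } else {
      ai.push_back(0); bi.push_back(j);
      double v = Y(i, j);
      --j;
      if (std::fabs(v - (M(i, j) - gapo)) < 1e-9) state = 0;
      else if (std::fabs(v - (Y(i, j) - gape)) < 1e-9) state = 1;
      else state = 2;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(Named("a") = ai, Named("b") = bi,
                      Named("score") = fin);
}
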