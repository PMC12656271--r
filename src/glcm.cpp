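#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// A 4x4 window with a single (dx, dy) offset yields at most 9 ordered pixel
// pairs (18 symmetric entries), so pair counts are kept in tiny linear-scan
// vectors rather than a dense levels x levels matrix.
struct PairCounts {
  std::vector<int> i, j;
  std::vector<double> n;
  double total = 0.0;
  void add(int a, int b) {
    for (size_t k = 0; k < i.size(); ++k) {
      if (i[k] == a && j[k] == b) { n[k] += 1.0; total += 1.0; return; }
    }
    i.push_back(a); j.push_back(b); n.push_back(1.0); total += 1.0;
  }
};

// metric order: mean, var, hom, con, dis, et, sem, cor
static void pair_metrics(const PairCounts &pc, double *out) {
  const size_t m = pc.i.size();
  double mu_i = 0.0, mu_j = 0.0;
  for (size_t k = 0; k < m; ++k) {
    double p = pc.n[k] / pc.total;
    mu_i += pc.i[k] * p;
    mu_j += pc.j[k] * p;
  }
  double var_i = 0.0, var_j = 0.0, cov = 0.0;
  double hom = 0.0, con = 0.0, dis = 0.0, et = 0.0, sem = 0.0;
  for (size_t k = 0; k < m; ++k) {
    double p = pc.n[k] / pc.total;
    double di = pc.i[k] - mu_i, dj = pc.j[k] - mu_j;
    double d = pc.i[k] - pc.j[k];
    var_i += di * di * p;
    var_j += dj * dj * p;
    cov   += di * dj * p;
    hom   += p / (1.0 + d * d);
    con   += d * d * p;
    dis   += std::fabs(d) * p;
    if (p > 0.0) et -= p * std::log(p);
    sem   += p * p;
  }
  double sd = std::sqrt(var_i) * std::sqrt(var_j);
  out[0] = mu_i;
  out[1] = var_i;
  out[2] = hom;
  out[3] = con;
  out[4] = dis;
  out[5] = et;
  out[6] = sem;
  out[7] = (sd > 0.0) ? cov / sd : 0.0;
}

//' @title Sliding-window GLCM metric means (compiled backend)
//' @description For each window position (given stride) compute the eight
//'   co-occurrence metrics of the window GLCM at a single (dx, dy) offset
//'   and return their means over all positions. Offset convention:
//'   a pixel at (row, col) pairs with (row + dy, col + dx).
//' @keywords internal
// [[Rcpp::export(name = ".glcmWindowMeansCpp")]]
NumericVector glcm_window_means(IntegerMatrix lv, int window, int dx, int dy,
                                bool symmetric, int stride) {
  const int nr = lv.nrow(), nc = lv.ncol();
  if (window > nr || window > nc)
    stop("window larger than image");
  if (std::abs(dx) >= window || std::abs(dy) >= window)
    stop("offset leaves no valid pixel pair inside the window");
  if (stride < 1) stop("stride must be >= 1");

  NumericVector acc(8);
  double wm[8];
  long nwin = 0;
  for (int r0 = 0; r0 + window <= nr; r0 += stride) {
    for (int c0 = 0; c0 + window <= nc; c0 += stride) {
      PairCounts pc;
      for (int r = r0; r < r0 + window; ++r) {
        int r2 = r + dy;
        if (r2 < r0 || r2 >= r0 + window) continue;
        for (int c = c0; c < c0 + window; ++c) {
          int c2 = c + dx;
          if (c2 < c0 || c2 >= c0 + window) continue;
          int a = lv(r, c), b = lv(r2, c2);
          pc.add(a, b);
          if (symmetric) pc.add(b, a);
        }
      }
      if (pc.total == 0.0) continue;
      pair_metrics(pc, wm);
      for (int k = 0; k < 8; ++k) acc[k] += wm[k];
      ++nwin;
    }
  }
  if (nwin == 0) stop("no window position produced a valid pixel pair");
  for (int k = 0; k < 8; ++k) acc[k] /= (double)nwin;
  acc.names() = CharacterVector::create("mean", "var", "hom", "con",
                                        "dis", "et", "sem", "cor");
  return acc;
}
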