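#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grid-bucketed hard-core dart throwing. The bucket side equals the hard-core
// distance, so any conflicting point lives in the 3x3 bucket neighbourhood.
class HardCoreGrid {
public:
  HardCoreGrid(double xmin, double ymin, double xmax, double ymax, double s)
    : s_(s), s2_(s * s), xmin_(xmin), ymin_(ymin) {
    nx_ = std::max(1, (int)std::ceil((xmax - xmin) / std::max(s, 1e-9)));
    ny_ = std::max(1, (int)std::ceil((ymax - ymin) / std::max(s, 1e-9)));
    // cap bucket count for tiny spacings over large windows
    if ((double)nx_ * (double)ny_ > 4e6) {
      double scale = std::sqrt(((double)nx_ * (double)ny_) / 4e6);
      nx_ = std::max(1, (int)(nx_ / scale));
      ny_ = std::max(1, (int)(ny_ / scale));
    }
    wx_ = (xmax - xmin) / nx_;
    wy_ = (ymax - ymin) / ny_;
    cells_.resize((size_t)nx_ * ny_);
  }

  bool conflicts(double x, double y) const {
    if (s_ <= 0) return false;
    int ix = bucket_x(x), iy = bucket_y(y);
    int rx = (int)std::ceil(s_ / wx_), ry = (int)std::ceil(s_ / wy_);
    for (int jx = std::max(0, ix - rx); jx <= std::min(nx_ - 1, ix + rx); ++jx)
      for (int jy = std::max(0, iy - ry); jy <= std::min(ny_ - 1, iy + ry); ++jy)
        for (int id : cells_[(size_t)jy * nx_ + jx]) {
          double dx = px_[id] - x, dy = py_[id] - y;
          if (dx * dx + dy * dy < s2_) return true;
        }
    return false;
  }

  void insert(double x, double y) {
    px_.push_back(x);
    py_.push_back(y);
    cells_[(size_t)bucket_y(y) * nx_ + bucket_x(x)].push_back((int)px_.size() - 1);
  }

private:
  int bucket_x(double x) const {
    int i = (int)((x - xmin_) / wx_);
    return std::min(std::max(i, 0), nx_ - 1);
  }
  int bucket_y(double y) const {
    int i = (int)((y - ymin_) / wy_);
    return std::min(std::max(i, 0), ny_ - 1);
  }
  double s_, s2_, xmin_, ymin_, wx_, wy_;
  int nx_, ny_;
  std::vector<double> px_, py_;
  std::vector<std::vector<int>> cells_;
};

// Place n points in the window [xmin,xmax]x[ymin,ymax] with pairwise distance
// >= min_spacing (also against `existing` points). mode 0: uniform proposals.
// mode 1: annulus proposals -- a hole is drawn with probability prob_w, then a
// uniform angle and a uniform radius in [r_lo[h], r_hi[h]] around its centre.
// Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List place_hardcore_cpp(int n, NumericVector window, double min_spacing,
                        int max_rejections, NumericMatrix existing, int mode,
                        NumericVector hole_x, NumericVector hole_y,
                        NumericVector r_lo, NumericVector r_hi,
                        NumericVector prob_w) {
  double xmin = window[0], ymin = window[1], xmax = window[2], ymax = window[3];
  HardCoreGrid grid(xmin, ymin, xmax, ymax, std::max(min_spacing, 1e-9));
  for (int i = 0; i < existing.nrow(); ++i) grid.insert(existing(i, 0), existing(i, 1));

  int nh = hole_x.size();
  std::vector<double> cumw(nh);
  double tot = 0;
  for (int h = 0; h < nh; ++h) { tot += prob_w[h]; cumw[h] = tot; }

  NumericVector ox(n), oy(n);
  IntegerVector ohole(n);
  int placed = 0;
  long long rejections = 0;
  while (placed < n) {
    double x, y;
    int hole = NA_INTEGER;
    if (mode == 1) {
      double u = R::runif(0.0, tot);
      int h = 0;
      while (h < nh - 1 && cumw[h] < u) ++h;
      double ang = R::runif(0.0, 2.0 * M_PI);
      double rad = R::runif(r_lo[h], r_hi[h]);
      x = hole_x[h] + rad * std::cos(ang);
      y = hole_y[h] + rad * std::sin(ang);
      hole = h + 1;
      if (x < xmin || x > xmax || y < ymin || y > ymax) {
        if (++rejections > max_rejections)
          stop("packing failure: rim proposals keep falling outside the window (placed %d of %d)",
               placed, n);
        continue;
      }
    } else {
      x = R::runif(xmin, xmax);
      y = R::runif(ymin, ymax);
    }
    if (min_spacing > 0 && grid.conflicts(x, y)) {
      if (++rejections > max_rejections)
        stop("packing failure: min_spacing = %g is the binding constraint (placed %d of %d points)",
             min_spacing, placed, n);
      continue;
    }
    grid.insert(x, y);
    ox[placed] = x;
    oy[placed] = y;
    ohole[placed] = hole;
    ++placed;
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["hole"] = ohole,
                      _["rejections"] = (double)rejections);
}
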