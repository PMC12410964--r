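#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state (rest/move) random walker in a rectangular chamber with
// reflecting walls. Sequential per-frame state makes this the one hot
// loop in the package; everything around it stays in R.
//
// entryRate: per-frame probability of rest -> move (already modulated by
// phase, startle and siesta). moveExitRate: move -> rest. While moving,
// step length ~ |N(0, stepScale)| and heading diffuses by N(0, turnSd);
// with probability foodBias the heading is redrawn to point at
// (targetX, targetY) plus the same angular noise. Uses R's RNG, so a
// set.seed() in the caller makes the walk reproducible bit for bit.
// [[Rcpp::export(name = ".walkCpp")]]
List walkCpp(NumericVector entryRate, double moveExitRate,
             double stepScale, double turnSd, double foodBias,
             double xMin, double xMax, double yMin, double yMax,
             double targetX, double targetY) {
  const int n = entryRate.size();
  NumericVector x(n), y(n);
  IntegerVector state(n);
  double cx = (xMin + xMax) / 2.0, cy = (yMin + yMax) / 2.0;
  double heading = R::runif(0.0, 2.0 * M_PI);
  // keep positions strictly below the max edge: chamber is [min, max)
  const double ex = (xMax - xMin) * 1e-9, ey = (yMax - yMin) * 1e-9;
  int st = 0;
  for (int i = 0; i < n; ++i) {
    if (st == 0) {
      if (R::unif_rand() < entryRate[i]) st = 1;
    } else {
      if (R::unif_rand() < moveExitRate) st = 0;
    }
    if (st == 1) {
      if (foodBias > 0.0 && R::unif_rand() < foodBias) {
        heading = std::atan2(targetY - cy, targetX - cx) +
                  R::norm_rand() * turnSd;
      } else {
        heading += R::norm_rand() * turnSd;
      }
      const double step = std::fabs(R::norm_rand()) * stepScale;
      cx += step * std::cos(heading);
      cy += step * std::sin(heading);
      while (cx < xMin || cx >= xMax) {
        if (cx < xMin) cx = 2.0 * xMin - cx;
        if (cx >= xMax) cx = 2.0 * xMax - cx - ex;
      }
      while (cy < yMin || cy >= yMax) {
        if (cy < yMin) cy = 2.0 * yMin - cy;
        if (cy >= yMax) cy = 2.0 * yMax - cy - ey;
      }
    }
    x[i] = cx;
    y[i] = cy;
    state[i] = st;
  }
  return List::create(_["x"] = x, _["y"] = y, _["state"] = state);
}
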