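// Overdamped Langevin dynamics (unit friction, Euler-Maruyama) on the 2D
// double well U(x, y) = h (x^2 - 1)^2 + y^2 / 2, with history-dependent
// Gaussian bias deposited along the rotated CV s = x cos(theta) + y
// sin(theta). Uses R's RNG so that set.seed() in R controls each run.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sum of deposited hills and its derivative at CV value s.
static inline double biasAt(double s, const std::vector<double> &hc,
                            const std::vector<double> &hh, double w2,
                            double &dVds) {
  double v = 0.0;
  dVds = 0.0;
  for (size_t k = 0; k < hc.size(); ++k) {
    double d = s - hc[k];
    double e = hh[k] * std::exp(-d * d / (2.0 * w2));
    v += e;
    dVds -= d / w2 * e;
  }
  return v;
}

// [[Rcpp::export(name = ".langevinRunCpp")]]
List langevinRunCpp(double barrier, double thetaDeg, double hillHeight,
                    double hillWidth, double biasFactor, int pace, double dt,
                    double temperature, double commitThreshold, double tMax,
                    int stride, double x0, double y0) {
  const double theta = thetaDeg * M_PI / 180.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  const double beta = 1.0 / temperature;
  const double noise = std::sqrt(2.0 * dt / beta);
  const double w2 = hillWidth * hillWidth;
  const bool wellTempered = R_finite(biasFactor);
  const long nSteps = (long)std::ceil(tMax / dt);

  std::vector<double> hc, hh, ht;          // hill centers/heights/times
  std::vector<double> recT, recS, recV;
  double x = x0, y = y0;
  double transition = NA_REAL;
  double dVds = 0.0, dummy = 0.0;

  recT.push_back(0.0);
  recS.push_back(x * ct + y * st);
  recV.push_back(biasAt(recS[0], hc, hh, w2, dummy));

  for (long step = 1; step <= nSteps; ++step) {
    double s = x * ct + y * st;
    double V = biasAt(s, hc, hh, w2, dVds);
    double fx = -4.0 * barrier * x * (x * x - 1.0) - dVds * ct;
    double fy = -y - dVds * st;
    double xPrev = x;
    x += fx * dt + noise * norm_rand();
    y += fy * dt + noise * norm_rand();
    if (std::fabs(x) > 1e3 || std::fabs(y) > 1e3)
      stop("step-size error: integrator blow-up (|coordinate| > 1e3); "
           "reduce dt");
    double t = step * dt;
    if (x >= commitThreshold) {
      // first-passage time interpolated within the step
      double frac = (commitThreshold - xPrev) / (x - xPrev);
      transition = (step - 1 + frac) * dt;
      double sT = x * ct + y * st;
      double vT = biasAt(sT, hc, hh, w2, dummy);
      if (recT.back() < transition) {
        recT.push_back(transition);
        recS.push_back(sT);
        recV.push_back(vT);
      }
      break;  // bias deposition stops at transition
    }
    if (hillHeight > 0.0 && step % pace == 0) {
      double sDep = x * ct + y * st;
      double h = hillHeight;
      if (wellTempered) {
        double vHere = biasAt(sDep, hc, hh, w2, dummy);
        h *= std::exp(-vHere / ((biasFactor - 1.0) * temperature));
      }
      hc.push_back(sDep);
      hh.push_back(h);
      ht.push_back(t);
    }
    if (step % stride == 0 || step == nSteps) {
      double sRec = x * ct + y * st;
      double vRec = biasAt(sRec, hc, hh, w2, dummy);
      recT.push_back(t);
      recS.push_back(sRec);
      recV.push_back(vRec);
    }
  }

  return List::create(
      _["time"] = wrap(recT), _["cv"] = wrap(recS), _["bias"] = wrap(recV),
      _["transition"] = transition, _["hillCenters"] = wrap(hc),
      _["hillHeights"] = wrap(hh), _["hillTimes"] = wrap(ht));
}

// Repeated unbiased first-passage times x0 -> commitThreshold, restarting
// after each transition; used for the brute-force reference rate.
// [[Rcpp::export(name = ".firstPassageTimesCpp")]]
NumericVector firstPassageTimesCpp(double barrier, double dt,
                                   double temperature,
                                   double commitThreshold, int nTransitions,
                                   double tBudget, double x0, double y0) {
  const double beta = 1.0 / temperature;
  const double noise = std::sqrt(2.0 * dt / beta);
  std::vector<double> fpt;
  double x = x0, y = y0;
  long step = 0;
  long startStep = 0;
  const long maxSteps = (long)std::ceil(tBudget / dt);
  while ((int)fpt.size() < nTransitions && step < maxSteps) {
    ++step;
    double fx = -4.0 * barrier * x * (x * x - 1.0);
    double fy = -y;
    double xPrev = x;
    x += fx * dt + noise * norm_rand();
    y += fy * dt + noise * norm_rand();
    if (x >= commitThreshold) {
      double frac = (commitThreshold - xPrev) / (x - xPrev);
      fpt.push_back((step - 1 + frac - startStep) * dt);
      x = x0;
      y = y0;
      startStep = step;
    }
  }
  return wrap(fpt);
}
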