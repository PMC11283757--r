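#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Concentration field of a continuously releasing point source at the
// capillary mouth. Outside the capillary: half-space continuous point
// source, C = C0 + 1e6 * Q/(2 pi D r) * erfc(r / sqrt(4 D t)) in uM with
// Q in fmol/s, D in um^2/s, r in um (1 fmol/um^3 == 1 mol/l). Radii below
// the mouth radius are capped at the mouth concentration. Inside the
// capillary: a 1D erf profile interpolating from the mouth concentration
// at the entrance to the reservoir concentration deep inside, continuous
// at the mouth.
static double conc_at(double x, double y, double t,
                      double Q, double D, double C0,
                      double srcx, double srcy,
                      double reservoir, double mouthR,
                      bool decaying, double sourceTau,
                      double capW, double capL) {
  if (t <= 0.0) return C0;
  double amp = decaying ? std::exp(-t / sourceTau) : 1.0;
  double mouth = C0 + amp * 1e6 * Q / (2.0 * M_PI * D * mouthR) *
                 std::erfc(mouthR / std::sqrt(4.0 * D * t));
  bool insideCap = (x >= 0.0 && x <= capL && std::fabs(y) <= capW / 2.0);
  if (insideCap) {
    double res = C0 + amp * (reservoir - C0);
    return mouth + (res - mouth) * std::erf(x / std::sqrt(4.0 * D * t));
  }
  double dx = x - srcx, dy = y - srcy;
  double r = std::sqrt(dx * dx + dy * dy);
  if (r < mouthR) return mouth;
  return C0 + amp * 1e6 * Q / (2.0 * M_PI * D * r) *
         std::erfc(r / std::sqrt(4.0 * D * t));
}

// [[Rcpp::export(name = ".concField")]]
NumericVector concField(NumericVector x, NumericVector y, double t,
                        List model, double capW, double capL) {
  double Q = model["Q"], D = model["D"], C0 = model["C0"];
  NumericVector src = model["source"];
  double reservoir = model["reservoirConc"], mouthR = model["mouthRadius"];
  bool decaying = model["decayingSource"];
  double sourceTau = model["sourceTau"];
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = conc_at(x[i], y[i], t, Q, D, C0, src[0], src[1],
                     reservoir, mouthR, decaying, sourceTau, capW, capL);
  return out;
}

// Valid positions: capillary interior (open at the mouth, closed at the
// far end), or the dish within the arena radius; the glass wall is
// excluded.
static bool valid_pos(double x, double y, double capW, double capL,
                      double wall, double arenaR) {
  double w2 = capW / 2.0;
  if (x >= 0.0 && x <= capL) {
    if (std::fabs(y) <= w2) return true;        // channel interior
    if (std::fabs(y) <= w2 + wall) return false; // glass
  }
  return x * x + y * y <= arenaR * arenaR;
}

// [[Rcpp::export(name = ".simulateSwimmers")]]
List simulateSwimmers(int nCells, double v0, double rotDiff, double chi,
                      double kappa, double turnGain, double giveUpTime,
                      double kHalf, double dt, double duration,
                      double arenaR, List model, double capW, double capL,
                      double wall, int outEvery) {
  double Q = model["Q"], D = model["D"], C0 = model["C0"];
  NumericVector src = model["source"];
  double reservoir = model["reservoirConc"], mouthR = model["mouthRadius"];
  bool decaying = model["decayingSource"];
  double sourceTau = model["sourceTau"];

  int nsteps = (int)std::round(duration / dt);
  int nout = nsteps / outEvery + 1;
  NumericMatrix X(nCells, nout), Y(nCells, nout);

  std::vector<double> x(nCells), y(nCells), th(nCells);
  // Two-state behaviour: "searching" cells steer up-gradient and turn more
  // inside the patch (area-restricted search); with rate 1/giveUpTime a
  // searcher inside the patch gives up and "leaves" ballistically (no
  // steering, baseline turning) until the concentration falls back to
  // background patch levels.
  std::vector<int> leaving(nCells, 0);
  double cPatch = 0.25 * reservoir + C0;   // patch threshold
  double cLow = 0.1 * reservoir + C0;      // leave-state exit threshold
  // initial positions: uniform over the dish (outside the capillary)
  for (int i = 0; i < nCells; ++i) {
    for (int tries = 0; tries < 10000; ++tries) {
      double px = (2.0 * R::runif(0, 1) - 1.0) * arenaR;
      double py = (2.0 * R::runif(0, 1) - 1.0) * arenaR;
      bool inCap = (px >= 0.0 && px <= capL &&
                    std::fabs(py) <= capW / 2.0 + wall);
      if (!inCap && px * px + py * py <= arenaR * arenaR) {
        x[i] = px; y[i] = py; break;
      }
    }
    th[i] = R::runif(0, 2.0 * M_PI);
    X(i, 0) = x[i]; Y(i, 0) = y[i];
  }

  double sig0 = std::sqrt(2.0 * rotDiff * dt);
  double h = 0.5;          // finite-difference step for the gradient, um
  double eps = 1e-6;       // concentration floor in the log-sensing term
  int col = 1;
  for (int s = 1; s <= nsteps; ++s) {
    double t = s * dt;
    for (int i = 0; i < nCells; ++i) {
      double v = v0;
      double sig = sig0;
      if (chi > 0.0 || kappa > 0.0 || turnGain > 0.0) {
        double C = conc_at(x[i], y[i], t, Q, D, C0, src[0], src[1],
                           reservoir, mouthR, decaying, sourceTau,
                           capW, capL);
        if (kappa > 0.0) v = v0 * (1.0 + kappa * C / (C + kHalf));
        if (chi > 0.0 || turnGain > 0.0) {
          double gx = (conc_at(x[i] + h, y[i], t, Q, D, C0, src[0], src[1],
                               reservoir, mouthR, decaying, sourceTau,
                               capW, capL) -
                       conc_at(x[i] - h, y[i], t, Q, D, C0, src[0], src[1],
                               reservoir, mouthR, decaying, sourceTau,
                               capW, capL)) / (2.0 * h);
          double gy = (conc_at(x[i], y[i] + h, t, Q, D, C0, src[0], src[1],
                               reservoir, mouthR, decaying, sourceTau,
                               capW, capL) -
                       conc_at(x[i], y[i] - h, t, Q, D, C0, src[0], src[1],
                               reservoir, mouthR, decaying, sourceTau,
                               capW, capL)) / (2.0 * h);
          double gnorm = std::sqrt(gx * gx + gy * gy);
          if (gnorm > 0.0) {
            double target = std::atan2(gy, gx);
            if (!leaving[i]) {
              if (chi > 0.0)
                th[i] += chi * v * (gnorm / (C + eps)) *
                         std::sin(target - th[i]) * dt;
              if (turnGain > 0.0)
                sig = sig0 * std::sqrt(1.0 + turnGain * C / (C + kHalf));
              if (giveUpTime > 0.0 && C > cPatch &&
                  R::runif(0, 1) < dt / giveUpTime)
                leaving[i] = 1;
            } else if (C < cLow) {
              leaving[i] = 0;
            }
          }
        }
      }
      th[i] += sig * R::norm_rand();
      double xn = x[i] + v * std::cos(th[i]) * dt;
      double yn = y[i] + v * std::sin(th[i]) * dt;
      if (valid_pos(xn, yn, capW, capL, wall, arenaR)) {
        x[i] = xn; y[i] = yn;
      } else {
        th[i] += M_PI;   // bounce back; rotational noise decorrelates
      }
    }
    if (s % outEvery == 0) {
      for (int i = 0; i < nCells; ++i) { X(i, col) = x[i]; Y(i, col) = y[i]; }
      ++col;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}
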