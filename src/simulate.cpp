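#include <Rcpp.h>
using namespace Rcpp;

// modulo via floor division (keeps the symbol footprint to old libm)
static inline double mod_2pi(double a) {
  return a - 2.0 * M_PI * std::floor(a / (2.0 * M_PI));
}

static inline double wrap_pi(double a) {
  return mod_2pi(a + M_PI) - M_PI;
}

static inline int quadrant_of(double x, double y, double phase) {
  double ang = mod_2pi(std::atan2(y, x) - phase);
  int k = (int)std::floor(ang / (M_PI / 2.0));
  if (k > 3) k = 3;
  return k;
}

// Correlated random walk in a circular arena with specular boundary
// reflection, LED-coupled speed/turning/upwind modulation and a
// crossing-probability quadrant bias. Uses R's RNG so set.seed() governs
// the draw sequence. State vectors are indexed by the departing frame:
// the step from frame i to i+1 uses led_on[i]/onset_win[i]/offset_win[i].
// [[Rcpp::export]]
List crw_simulate(int n_frames, double dt,
                  double x0, double y0, double theta0,
                  double radius,
                  double base_speed, double speed_sd, double noise_sd,
                  LogicalVector led_on, LogicalVector onset_win,
                  LogicalVector offset_win,
                  double speed_mult, double onset_boost,
                  double upwind_bias,
                  double q_bias, double q_phase, LogicalVector favored) {
  NumericVector x(n_frames), y(n_frames), theta(n_frames);
  double px = x0, py = y0, th = theta0;
  x[0] = px; y[0] = py; theta[0] = th;
  for (int i = 0; i + 1 < n_frames; ++i) {
    double th_new = th;
    if (offset_win[i] && upwind_bias > 0) {
      double r = std::sqrt(px * px + py * py);
      if (r > 1e-9) {
        double phi_out = std::atan2(py, px);
        th_new += upwind_bias * wrap_pi(phi_out - th_new);
      }
    }
    double sd_i = onset_win[i] ? noise_sd * (1.0 + onset_boost) : noise_sd;
    if (sd_i > 0) th_new += R::rnorm(0.0, sd_i);
    th_new = wrap_pi(th_new);

    double sp = R::rnorm(base_speed, speed_sd);
    if (sp < 0) sp = 0;
    if (led_on[i]) sp *= speed_mult;
    double step = sp * dt;

    double nx = px + step * std::cos(th_new);
    double ny = py + step * std::sin(th_new);
    double r2 = std::sqrt(nx * nx + ny * ny);
    if (r2 > radius) {
      // specular reflection: fold the overshoot back across the wall and
      // mirror the heading about the local tangent
      double ux = nx / r2, uy = ny / r2;
      double excess = r2 - radius;
      nx -= 2.0 * excess * ux;
      ny -= 2.0 * excess * uy;
      double dn = std::cos(th_new) * ux + std::sin(th_new) * uy;
      double vx = std::cos(th_new) - 2.0 * dn * ux;
      double vy = std::sin(th_new) - 2.0 * dn * uy;
      th_new = std::atan2(vy, vx);
      double r3 = std::sqrt(nx * nx + ny * ny);
      if (r3 > radius) {  // pathological overshoot; clamp inside
        nx *= 0.99 * radius / r3;
        ny *= 0.99 * radius / r3;
      }
    }

    if (q_bias > 0) {
      int q_old = quadrant_of(px, py, q_phase);
      int q_new = quadrant_of(nx, ny, q_phase);
      if (favored[q_old] && !favored[q_new] && unif_rand() < q_bias) {
        // semi-permeable quadrant boundary: the crossing is rejected and
        // the fly reflects specularly off the boundary line, which yields
        // a multiplicative dwell bias (stationary density ratio
        // ~ 1/(1 - q_bias)) toward the favored label
        double mid = std::atan2(py + ny, px + nx);
        double phi_b = q_phase +
          (M_PI / 2.0) * std::round((mid - q_phase) / (M_PI / 2.0));
        double c2 = std::cos(2.0 * phi_b), s2 = std::sin(2.0 * phi_b);
        double rx = c2 * nx + s2 * ny;   // mirror across the boundary ray
        double ry = s2 * nx - c2 * ny;
        nx = rx; ny = ry;
        th_new = wrap_pi(2.0 * phi_b - th_new);
      }
    }
    px = nx; py = ny;
    th = th_new;
    x[i + 1] = px; y[i + 1] = py; theta[i + 1] = th;
  }
  return List::create(_["x"] = x, _["y"] = y, _["theta"] = theta);
}
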