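#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of a dynamic round. Mirrors the R-level ops (read_sensors,
// combine_behaviors, step_kinematics) expression-for-expression so that a
// reference loop written with those ops and the same RNG seed reproduces
// the trajectory exactly; a test holds the two paths together.

// R's `%%` for doubles (Arith.c myfmod, positive modulus).
static inline double rmod(double x1, double x2) {
  double tmp = x1 - std::floor(x1 / x2) * x2;
  return tmp - std::floor(tmp / x2) * x2;
}

// wrap to (-pi, pi], identical to wrap_angle() in R/arena.R
static inline double wrap_angle(double x) {
  double w = rmod(x - M_PI, 2.0 * M_PI) - M_PI;
  if (w <= -M_PI) w = M_PI;
  return w;
}

// One left/right activation pair (linear falloff x rectified cosine).
static inline void sensor_pair(double px, double py, double heading,
                               double tx, double ty, double range,
                               double half, double *out) {
  double dx = tx - px, dy = ty - py;
  double d = std::sqrt(dx * dx + dy * dy);
  double prox = 1.0 - d / range;
  if (prox <= 0.0) { out[0] = 0.0; out[1] = 0.0; return; }
  double beta = (d < 1e-12) ? 0.0 : wrap_angle(std::atan2(dy, dx) - heading);
  double cl = std::cos(beta - half), cr = std::cos(beta + half);
  out[0] = prox * (cl > 0.0 ? cl : 0.0);
  out[1] = prox * (cr > 0.0 ? cr : 0.0);
}

static inline double clampd(double x, double lo, double hi) {
  return std::min(std::max(x, lo), hi);
}

// [[Rcpp::export]]
List run_round_cpp(NumericVector pose_a0, NumericVector pose_b0,
                   NumericVector spot_high, NumericVector spot_low,
                   bool a_high_active, bool a_low_active,
                   bool b_high_active, bool b_low_active,
                   double f, double range_high, double range_low,
                   double sensor_range_agent,
                   double halfangle, double dt, double speed_scale,
                   double wheelbase, double agent_radius,
                   double width, double height, double reach_radius,
                   int max_steps, double noise_sd,
                   double m_min, double m_max, bool record) {
  double pa[3] = {pose_a0[0], pose_a0[1], pose_a0[2]};
  double pb[3] = {pose_b0[0], pose_b0[1], pose_b0[2]};
  double shx = spot_high[0], shy = spot_high[1];
  double slx = spot_low[0], sly = spot_low[1];

  NumericMatrix traj;
  if (record) traj = NumericMatrix(max_steps, 6);

  int steps = 0;
  bool timeout = false;
  LogicalVector reached(4, false); // a_high, b_high, a_low, b_low

  double sH[2], sL[2], sA[2];
  while (steps < max_steps) {
    // sensors and command, agent a then agent b (poses at step start)
    double cmd[4];
    for (int who = 0; who < 2; ++who) {
      double *self = who == 0 ? pa : pb;
      double *other = who == 0 ? pb : pa;
      bool hi_on = who == 0 ? a_high_active : b_high_active;
      bool lo_on = who == 0 ? a_low_active : b_low_active;
      sensor_pair(self[0], self[1], self[2], shx, shy, range_high,
                  halfangle, sH);
      sensor_pair(self[0], self[1], self[2], slx, sly, range_low,
                  halfangle, sL);
      sensor_pair(self[0], self[1], self[2], other[0], other[1],
                  sensor_range_agent, halfangle, sA);
      double dl = sA[0] - sA[1];
      if (hi_on) dl = dl + sH[1] - sH[0];
      if (lo_on) dl = dl + sL[1] - sL[0];
      double ml = clampd(f + dl, m_min, m_max);
      double mr = clampd(f - dl, m_min, m_max);
      ml = clampd(ml + ::Rf_rnorm(0.0, noise_sd), m_min, m_max);
      mr = clampd(mr + ::Rf_rnorm(0.0, noise_sd), m_min, m_max);
      cmd[2 * who] = ml;
      cmd[2 * who + 1] = mr;
    }
    // both agents move simultaneously (Euler step on the old poses)
    for (int who = 0; who < 2; ++who) {
      double *p = who == 0 ? pa : pb;
      double ml = cmd[2 * who], mr = cmd[2 * who + 1];
      double v = speed_scale * (ml + mr) / 2.0;
      double om = speed_scale * (mr - ml) / wheelbase;
      double x = p[0] + v * std::cos(p[2]) * dt;
      double y = p[1] + v * std::sin(p[2]) * dt;
      p[2] = wrap_angle(p[2] + om * dt);
      p[0] = clampd(x, agent_radius, width - agent_radius);
      p[1] = clampd(y, agent_radius, height - agent_radius);
    }
    if (record) {
      traj(steps, 0) = pa[0]; traj(steps, 1) = pa[1]; traj(steps, 2) = pa[2];
      traj(steps, 3) = pb[0]; traj(steps, 4) = pb[1]; traj(steps, 5) = pb[2];
    }
    ++steps;
    double dah = std::sqrt((pa[0]-shx)*(pa[0]-shx) + (pa[1]-shy)*(pa[1]-shy));
    double dbh = std::sqrt((pb[0]-shx)*(pb[0]-shx) + (pb[1]-shy)*(pb[1]-shy));
    double dal = std::sqrt((pa[0]-slx)*(pa[0]-slx) + (pa[1]-sly)*(pa[1]-sly));
    double dbl_ = std::sqrt((pb[0]-slx)*(pb[0]-slx) + (pb[1]-sly)*(pb[1]-sly));
    reached[0] = dah <= reach_radius;
    reached[1] = dbh <= reach_radius;
    reached[2] = dal <= reach_radius;
    reached[3] = dbl_ <= reach_radius;
    if (reached[0] || reached[1] || reached[2] || reached[3]) break;
    if (steps >= max_steps) { timeout = true; break; }
  }

  List out = List::create(
    _["steps"] = steps, _["timeout"] = timeout, _["reached"] = reached,
    _["pose_a"] = NumericVector::create(pa[0], pa[1], pa[2]),
    _["pose_b"] = NumericVector::create(pb[0], pb[1], pb[2]));
  if (record) out["traj"] = traj(Range(0, steps - 1), Range(0, 5));
  return out;
}
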