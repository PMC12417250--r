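#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  // map angle to [-pi, pi); floor-based so only old libm symbols are used
  double t = (a + M_PI) / (2.0 * M_PI);
  return (a + M_PI) - 2.0 * M_PI * std::floor(t) - M_PI;
}

// Correlated random walk on a bounded plane with landmark attraction,
// a pause process and a revisit bias. Uses R's RNG stream so results are
// reproducible under set.seed(). Returns an (n_steps + 1) x 2 matrix of
// positions; the first row is the spawn point.
//
// Steering: heading relaxes toward the current goal landmark at rate
// `attraction` (1/s), plus Gaussian turn noise with sd turn_sd * sqrt(dt)
// (a diffusive heading, so turn_sd has units rad / sqrt(s)). When the goal
// landmark is reached (within landmark_radius) it is marked visited and a
// new goal is drawn: with probability revisit_bias a uniformly chosen
// already-visited landmark, otherwise the nearest unvisited one (or a
// uniform landmark when none remain unvisited).
// [[Rcpp::export]]
NumericMatrix crw_simulate(int n_steps, double dt,
                           double x0, double y0,
                           double xmin, double xmax,
                           double ymin, double ymax,
                           NumericVector lm_x, NumericVector lm_y,
                           double landmark_radius,
                           double speed_mean, double speed_cv,
                           double pause_rate, double pause_mean,
                           double turn_sd, double attraction,
                           double revisit_bias) {
  int n_lm = lm_x.size();
  NumericMatrix out(n_steps + 1, 2);
  std::vector<int> visited(n_lm, 0);
  int n_visited = 0;

  double x = x0, y = y0;
  out(0, 0) = x; out(0, 1) = y;
  double heading = R::runif(-M_PI, M_PI);
  double pause_left = 0.0;
  double sqdt = std::sqrt(dt);
  double gain = attraction * dt;
  if (gain > 1.0) gain = 1.0;

  // initial goal: nearest landmark
  int goal = -1;
  double best = R_PosInf;
  for (int j = 0; j < n_lm; ++j) {
    double d = (lm_x[j] - x) * (lm_x[j] - x) + (lm_y[j] - y) * (lm_y[j] - y);
    if (d < best) { best = d; goal = j; }
  }

  for (int i = 1; i <= n_steps; ++i) {
    if (pause_left > 0.0) {
      pause_left -= dt;
      out(i, 0) = x; out(i, 1) = y;
      continue;
    }
    if (pause_rate > 0.0 && R::unif_rand() < pause_rate * dt) {
      pause_left = R::rexp(pause_mean);
      out(i, 0) = x; out(i, 1) = y;
      continue;
    }
    if (goal >= 0) {
      double ta = std::atan2(lm_y[goal] - y, lm_x[goal] - x);
      heading += gain * wrap_pi(ta - heading);
    }
    heading += R::norm_rand() * turn_sd * sqdt;
    heading = wrap_pi(heading);
    double speed = speed_mean * (1.0 + speed_cv * R::norm_rand());
    if (speed < 0.0) speed = 0.0;
    x += std::cos(heading) * speed * dt;
    y += std::sin(heading) * speed * dt;
    // reflect at bounds, flipping the heading component
    if (x < xmin) { x = 2.0 * xmin - x; heading = wrap_pi(M_PI - heading); }
    if (x > xmax) { x = 2.0 * xmax - x; heading = wrap_pi(M_PI - heading); }
    if (y < ymin) { y = 2.0 * ymin - y; heading = -heading; }
    if (y > ymax) { y = 2.0 * ymax - y; heading = -heading; }
    out(i, 0) = x; out(i, 1) = y;

    if (goal >= 0) {
      double dg = std::sqrt((lm_x[goal] - x) * (lm_x[goal] - x) +
                            (lm_y[goal] - y) * (lm_y[goal] - y));
      if (dg < landmark_radius) {
        if (!visited[goal]) { visited[goal] = 1; ++n_visited; }
        bool revisit = n_visited > 0 && R::unif_rand() < revisit_bias;
        if (revisit) {
          int pick = (int)std::floor(R::unif_rand() * n_visited);
          if (pick >= n_visited) pick = n_visited - 1;
          int seen = 0;
          for (int j = 0; j < n_lm; ++j) {
            if (visited[j]) { if (seen == pick) { goal = j; break; } ++seen; }
          }
        } else if (n_visited < n_lm) {
          best = R_PosInf; int g = -1;
          for (int j = 0; j < n_lm; ++j) {
            if (visited[j]) continue;
            double d = (lm_x[j] - x) * (lm_x[j] - x) +
                       (lm_y[j] - y) * (lm_y[j] - y);
            if (d < best) { best = d; g = j; }
          }
          goal = g;
        } else {
          int pick = (int)std::floor(R::unif_rand() * n_lm);
          if (pick >= n_lm) pick = n_lm - 1;
          goal = pick;
        }
      }
    }
  }
  return out;
}

// Divider (Richardson) walk: number of ruler steps of length delta needed
// to traverse the polyline, stepping chord-wise. The trailing remainder is
// counted fractionally so N(delta) varies smoothly with delta.
// [[Rcpp::export]]
double divider_count(NumericVector x, NumericVector y, double delta) {
  int n = x.size();
  if (n < 2 || delta <= 0.0) return NA_REAL;
  double px = x[0], py = y[0];     // current ruler anchor
  double sx = x[0], sy = y[0];     // start of the remaining part of segment j
  double count = 0.0;
  int j = 1;
  while (j < n) {
    double de = std::sqrt((x[j] - px) * (x[j] - px) +
                          (y[j] - py) * (y[j] - py));
    if (de < delta) {
      // distance along a straight segment is convex, so if both the segment
      // start (invariant: < delta from p) and its end are closer than delta
      // the ruler circle is not crossed inside it
      sx = x[j]; sy = y[j];
      ++j;
      continue;
    }
    // first crossing of the delta-circle around p on segment (s -> v_j):
    // solve |s + t*u - p|^2 = delta^2 for the positive root
    double ux = x[j] - sx, uy = y[j] - sy;
    double wx = sx - px, wy = sy - py;
    double a = ux * ux + uy * uy;
    double b = 2.0 * (wx * ux + wy * uy);
    double c = wx * wx + wy * wy - delta * delta;  // < 0 by the invariant
    double t;
    if (a <= 0.0) {
      t = 0.0;
    } else {
      double disc = b * b - 4.0 * a * c;
      t = (-b + std::sqrt(std::max(disc, 0.0))) / (2.0 * a);
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
    }
    px = sx + t * ux; py = sy + t * uy;
    sx = px; sy = py;
    count += 1.0;
    // stay on segment j: more ruler steps may fit inside it
  }
  double rem = std::sqrt((x[n - 1] - px) * (x[n - 1] - px) +
                         (y[n - 1] - py) * (y[n - 1] - py));
  return count + rem / delta;
}
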