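// Per-trial kinematics engine for the vFGN simulator.
//
// The navigator moves at constant speed with a bounded turn rate on a 2D
// disk.  Three movement modes cover the shipped policies:
//   0 "explore": correlated random walk, heading perturbed by Gaussian step
//     noise, reflected at the arena wall;
//   1 "seek": turn-rate-limited approach to a target point, then an
//     outward Archimedean spiral local search around it (pitch = goal
//     radius); when the spiral radius exceeds a cap the navigator returns
//     to the target and spirals again;
//   2 "hold": remain at the start (timeout baseline).
//
// All randomness comes from R's RNG (RNGScope), so results are fully
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// reflect direction d about the wall tangent at position p (unit normal n)
static inline void reflect(double &dx, double &dy, double px, double py) {
  double r = std::sqrt(px * px + py * py);
  if (r <= 0) return;
  double nx = px / r, ny = py / r;
  double dot = dx * nx + dy * ny;
  dx -= 2.0 * dot * nx;
  dy -= 2.0 * dot * ny;
}

// [[Rcpp::export]]
List sim_search_cpp(NumericVector start, double heading0, int mode,
                    NumericVector target, NumericVector goal_center,
                    double goal_radius, bool goal_stop, bool reveal_after,
                    double arena_radius, double speed, double dt,
                    double search_limit, double heading_sd, double turn_max,
                    double spiral_pitch, double spiral_rmax) {
  const int n_search = (int)std::ceil(search_limit / dt);
  const int max_extra = (int)std::ceil(6.0 * arena_radius / std::max(speed, 1e-9) / dt);
  const int cap = n_search + (reveal_after ? max_extra : 0) + 2;

  std::vector<double> xs, ys;
  xs.reserve(cap);
  ys.reserve(cap);

  double x = start[0], y = start[1];
  double h = heading0 * DEG;
  xs.push_back(x);
  ys.push_back(y);

  const double gx = goal_center[0], gy = goal_center[1];
  const double step = speed * dt;
  const double turn_cap = turn_max * DEG * dt;
  const double hsd = heading_sd * DEG;
  const double wall = arena_radius - 1e-9;

  bool found = false;
  int entry = 0;        // 1-based sample index of first goal entry (search)
  int post_start = 0;   // 1-based sample index where post-reveal begins

  // spiral state (mode 1)
  bool spiraling = false;
  double theta = 0.0;
  const double b = spiral_pitch / (2.0 * M_PI); // r = b * theta

  {
    // already on the goal at the start?  (guarded against in well-formed
    // trials, but keep the run-length convention consistent)
    double d0 = std::sqrt((x - gx) * (x - gx) + (y - gy) * (y - gy));
    if (goal_stop && d0 <= goal_radius) {
      found = true;
      entry = 1;
    }
  }

  int i = 0;
  while (i < n_search && !(found && goal_stop)) {
    ++i;
    if (mode == 2) {            // hold
      xs.push_back(x);
      ys.push_back(y);
      continue;
    }
    if (mode == 0) {            // correlated random walk
      h += R::rnorm(0.0, hsd);
      double dx = std::cos(h), dy = std::sin(h);
      double nx = x + step * dx, ny = y + step * dy;
      if (nx * nx + ny * ny > wall * wall) {
        reflect(dx, dy, x, y);
        h = std::atan2(dy, dx);
        nx = x + step * dx;
        ny = y + step * dy;
        double r2 = std::sqrt(nx * nx + ny * ny);
        if (r2 > wall) {        // still outside (corner case): clip to wall
          nx *= wall / r2;
          ny *= wall / r2;
        }
      }
      x = nx;
      y = ny;
    } else {                    // seek: approach target, then spiral
      double tx = target[0], ty = target[1];
      if (!spiraling) {
        double ddx = tx - x, ddy = ty - y;
        double dist = std::sqrt(ddx * ddx + ddy * ddy);
        if (dist <= step) {
          spiraling = true;
          theta = 0.0;
          x = tx;
          y = ty;
        } else {
          double want = std::atan2(ddy, ddx);
          double dh = std::remainder(want - h, 2.0 * M_PI);
          if (dh > turn_cap) dh = turn_cap;
          if (dh < -turn_cap) dh = -turn_cap;
          h += dh;
          x += step * std::cos(h);
          y += step * std::sin(h);
        }
      }
      if (spiraling) {
        double r_s = b * theta;
        double dtheta = step / std::max(r_s, b);
        theta += dtheta;
        r_s = b * theta;
        if (r_s > spiral_rmax) { // restart the local search from the target
          spiraling = false;
          theta = 0.0;
          double ddx = tx - x, ddy = ty - y;
          h = std::atan2(ddy, ddx);
        } else {
          x = tx + r_s * std::cos(theta);
          y = ty + r_s * std::sin(theta);
          h = theta + M_PI / 2.0; // tangent heading
        }
      }
      double rr = std::sqrt(x * x + y * y);
      if (rr > wall) {          // clip to the wall (wall-following contract)
        x *= wall / rr;
        y *= wall / rr;
      }
    }
    xs.push_back(x);
    ys.push_back(y);
    if (!found) {
      double d = std::sqrt((x - gx) * (x - gx) + (y - gy) * (y - gy));
      if (d <= goal_radius) {
        found = true;
        entry = (int)xs.size();
      }
    }
  }

  // timeout with an active goal: the goal is revealed and the navigator
  // walks straight to it; these samples are flagged post-reveal and are
  // excluded from all metrics
  bool reveal = false;
  if (reveal_after && !found) {
    reveal = true;
    post_start = (int)xs.size() + 1;
    int extra = 0;
    while (extra < max_extra) {
      ++extra;
      double ddx = gx - x, ddy = gy - y;
      double dist = std::sqrt(ddx * ddx + ddy * ddy);
      if (dist <= goal_radius) break;
      double want = std::atan2(ddy, ddx);
      h = want;
      x += step * std::cos(h);
      y += step * std::sin(h);
      xs.push_back(x);
      ys.push_back(y);
      double d = std::sqrt((x - gx) * (x - gx) + (y - gy) * (y - gy));
      if (d <= goal_radius) break;
    }
  }

  return List::create(_["x"] = NumericVector(xs.begin(), xs.end()),
                      _["y"] = NumericVector(ys.begin(), ys.end()),
                      _["found"] = found, _["entry"] = entry,
                      _["reveal"] = reveal, _["post_start"] = post_start);
}
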