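#include <Rcpp.h>
using namespace Rcpp;

// Frame-level simulation of one street attempt under the look-ahead steering
// policy. Mirrors the R reference implementation (simulate_street +
// steering_policy) operation for operation, including the windowed
// nearest-neighbour search and one standard-normal draw per frame, so that
// the two paths produce identical trajectories under the same R RNG seed.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// nearest vertex of the dense centreline within a +-window around `from`
// (from < 0 means full scan); returns index, writes dist2
static inline int nearest_idx(const double* xs, const double* ys, int n,
                              double px, double py, int from, int window,
                              double& best_d2) {
  int lo = 0, hi = n - 1;
  if (from >= 0) {
    lo = from - window; if (lo < 0) lo = 0;
    hi = from + window; if (hi > n - 1) hi = n - 1;
  }
  int best = lo;
  best_d2 = R_PosInf;
  for (int i = lo; i <= hi; ++i) {
    double dx = xs[i] - px, dy = ys[i] - py;
    double d2 = dx * dx + dy * dy;
    if (d2 < best_d2) { best_d2 = d2; best = i; }
  }
  return best;
}

// [[Rcpp::export(name = ".sim_street_cpp")]]
List sim_street_cpp(NumericMatrix dense, NumericVector cumlen,
                    double width, bool straight,
                    double dirx, double diry,
                    double accel, double vmax, double end_zone_fraction,
                    int frame_cap,
                    double speed, double sigma_deg, double noise_floor_deg,
                    double remap_mult, double difficulty_gain,
                    int look_steps, int window,
                    bool record) {
  const int n = dense.nrow();
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) { xs[i] = dense(i, 0); ys[i] = dense(i, 1); }
  const double total_len = cumlen[n - 1];
  const double goal_arc = (1.0 - end_zone_fraction) * total_len;
  const double half_w = width / 2.0;
  const double startx = xs[0], starty = ys[0];

  // unit vector along the ideal line for straight-street perpendicular error
  double ux = 0, uy = 0;
  if (straight) {
    double ddx = xs[n - 1] - startx, ddy = ys[n - 1] - starty;
    double L = std::sqrt(ddx * ddx + ddy * ddy);
    ux = ddx / L; uy = ddy / L;
  }

  double px = startx, py = starty, vx = 0.0, vy = 0.0;
  double d2;
  int idx = nearest_idx(xs.data(), ys.data(), n, px, py, -1, window, d2);
  double nn_dist = std::sqrt(d2);

  int n_resets = 0, onset = -1, end_frame = -1;
  bool completed = false;
  double sum_sq = 0.0;
  long n_scored = 0;

  NumericMatrix traj = record ? NumericMatrix(frame_cap, 9)
                              : NumericMatrix(0, 0);
  int nrec = 0;

  RNGScope scope;

  for (int frame = 1; frame <= frame_cap; ++frame) {
    // --- steering policy ---
    int tgt = idx + look_steps; if (tgt > n - 1) tgt = n - 1;
    double kx = (xs[tgt] - px) * dirx;
    double ky = (ys[tgt] - py) * diry;
    // raw heading may leave [0, pi/2]: negative (or > pi/2) values encode
    // the corrective "ease off this axis" signal when the cursor has
    // drifted across the ideal line; only the post-noise heading is clamped
    double phi = std::atan2(ky, kx);
    // local tangent angle (first quadrant) for the angle-difficulty term
    int i0 = idx - 1; if (i0 < 0) i0 = 0;
    int i1 = idx + 1; if (i1 > n - 1) i1 = n - 1;
    double ta = std::atan2(std::fabs(ys[i1] - ys[i0]),
                           std::fabs(xs[i1] - xs[i0]));
    double diff_mult = (1.0 - difficulty_gain) +
        difficulty_gain * std::fabs(std::sin(4.0 * ta));
    double sigma = (sigma_deg * diff_mult + noise_floor_deg) * remap_mult;
    double eps = norm_rand() * sigma * M_PI / 180.0;
    double phin = clampd(phi + eps, 0.0, M_PI_2);
    // zero sub-epsilon demands: cos(pi/2) is ~6e-17, not 0, and a spurious
    // positive demand at zero velocity would press the key every frame
    double dem_h = speed * std::cos(phin); if (dem_h < 1e-9) dem_h = 0.0;
    double dem_v = speed * std::sin(phin); if (dem_v < 1e-9) dem_v = 0.0;
    bool key_h = vx < dem_h;
    bool key_v = vy < dem_v;

    // --- control law step ---
    vx = clampd(vx + (key_h ? accel : -accel), 0.0, vmax);
    vy = clampd(vy + (key_v ? accel : -accel), 0.0, vmax);
    px += vx * dirx;
    py += vy * diry;

    idx = nearest_idx(xs.data(), ys.data(), n, px, py, idx, window, d2);
    nn_dist = std::sqrt(d2);
    bool reset = nn_dist > half_w;

    if (onset < 0 && (vx > 0 || vy > 0)) onset = frame;
    if (onset >= 0) {
      double err = straight
        ? std::fabs((px - startx) * uy - (py - starty) * ux)
        : nn_dist;
      sum_sq += err * err;
      ++n_scored;
    }
    if (record && nrec < frame_cap) {
      traj(nrec, 0) = frame; traj(nrec, 1) = px; traj(nrec, 2) = py;
      traj(nrec, 3) = vx; traj(nrec, 4) = vy;
      traj(nrec, 5) = key_h; traj(nrec, 6) = key_v;
      traj(nrec, 7) = reset; traj(nrec, 8) = nn_dist;
      ++nrec;
    }

    if (reset) {
      ++n_resets;
      px = startx; py = starty; vx = 0.0; vy = 0.0;
      idx = 0; nn_dist = 0.0;
    } else if (cumlen[idx] >= goal_arc) {
      completed = true;
      end_frame = frame;
      break;
    }
  }

  List out = List::create(
    _["completed"] = completed,
    _["n_resets"] = n_resets,
    _["onset_frame"] = onset < 0 ? NA_INTEGER : onset,
    _["end_frame"] = completed ? end_frame : NA_INTEGER,
    _["sum_sq"] = sum_sq,
    _["n_scored"] = (double)n_scored);
  if (record) {
    out["frames"] = traj(Range(0, nrec > 0 ? nrec - 1 : 0),
                         Range(0, 8));
    out["nrec"] = nrec;
  }
  return out;
}
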