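#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time zonal attraction/repulsion shoal dynamics for one session.
//
// Per fish and subframe the velocity is the sum of: attraction toward the
// shoal centroid scaled by (1 + kappa * theta), short-range pairwise
// repulsion inside rep_radius, attraction toward the nearest wall
// (w_wall_base + w_wall * theta; baseline thigmotaxis plus its stress
// component), Gaussian velocity noise, and rare large random impulses
// ("erratic bursts") with per-subframe probability
// p_err = p0 * (1 + beta * theta).
//
// Each fish switches between a cohesive and an independent behavioural
// state: cohesive fish leave at rate detach_rate * (1 - theta) per second
// (relaxed shoals have wanderers; acutely stressed shoals cohere), return
// at return_rate, and in the independent state feel only indep_att times
// the centroid attraction. State residence times of a few seconds keep the
// 10 s analysis frames close to independent draws from the stationary
// group configuration.
//
// Depth follows a downward drift (depth_w0 + depth_w1 * theta) plus noise.
// Positions reflect at the tank walls, bottom and water surface.
//
// Returns an (n_steps + 1) x (3 * n_fish) matrix: columns [0, n) are x,
// [n, 2n) are y, [2n, 3n) are z; row r is the state after r steps.
// [[Rcpp::export]]
NumericMatrix simulate_shoal_core(NumericMatrix init,   // n_fish x 3 (x, y, z)
                                  int n_steps, double dt,
                                  double tank_l, double tank_w, double depth,
                                  double theta,
                                  double w_att, double kappa,
                                  double w_rep, double rep_radius,
                                  double w_wall, double w_wall_base,
                                  double detach_rate, double return_rate,
                                  double indep_att,
                                  double depth_w0, double depth_w1,
                                  double sigma_xy, double sigma_z,
                                  double p0_err, double beta_err,
                                  double burst_speed) {
  const int n = init.nrow();
  NumericMatrix out(n_steps + 1, 3 * n);
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n);
  std::vector<int> indep(n, 0);
  for (int i = 0; i < n; ++i) {
    x[i] = init(i, 0);
    y[i] = init(i, 1);
    z[i] = init(i, 2);
    out(0, i) = x[i];
    out(0, n + i) = y[i];
    out(0, 2 * n + i) = z[i];
  }
  const double att = w_att * (1.0 + kappa * theta);
  const double p_err = p0_err * (1.0 + beta_err * theta);
  const double z_drift = depth_w0 + depth_w1 * theta;
  const double wall_pull = w_wall_base + w_wall * theta;
  const double p_detach = detach_rate * (1.0 - theta) * dt;
  const double p_return = return_rate * dt;

  // start states at their stationary distribution
  if (p_detach + p_return > 0.0) {
    double p_ind = p_detach / (p_detach + p_return);
    for (int i = 0; i < n; ++i) indep[i] = (R::unif_rand() < p_ind) ? 1 : 0;
  }

  for (int t = 1; t <= n_steps; ++t) {
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; }
    cx /= n; cy /= n;

    for (int i = 0; i < n; ++i) {
      if (indep[i]) {
        if (R::unif_rand() < p_return) indep[i] = 0;
      } else {
        if (R::unif_rand() < p_detach) indep[i] = 1;
      }
      double a_i = indep[i] ? att * indep_att : att;
      double vxi = a_i * (cx - x[i]);
      double vyi = a_i * (cy - y[i]);
      // short-range repulsion
      if (w_rep > 0.0) {
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < rep_radius && d > 1e-12) {
            double s = w_rep * (rep_radius - d) / d;
            vxi += s * dx;
            vyi += s * dy;
          }
        }
      }
      // attraction toward the fish's nearest wall
      if (wall_pull > 0.0) {
        double dl = x[i], dr = tank_l - x[i], db = y[i], dtp = tank_w - y[i];
        double m = std::min(std::min(dl, dr), std::min(db, dtp));
        if (m == dl)       vxi -= wall_pull;
        else if (m == dr)  vxi += wall_pull;
        else if (m == db)  vyi -= wall_pull;
        else               vyi += wall_pull;
      }
      if (sigma_xy > 0.0) {
        vxi += R::rnorm(0.0, sigma_xy);
        vyi += R::rnorm(0.0, sigma_xy);
      }
      // erratic burst: large impulse in a random direction
      if (p_err > 0.0 && R::unif_rand() < p_err) {
        double ang = R::unif_rand() * 2.0 * M_PI;
        vxi += burst_speed * std::cos(ang);
        vyi += burst_speed * std::sin(ang);
      }
      vx[i] = vxi;
      vy[i] = vyi;
    }

    for (int i = 0; i < n; ++i) {
      double nx = x[i] + vx[i] * dt;
      double ny = y[i] + vy[i] * dt;
      double nz = z[i] + (-z_drift + (sigma_z > 0.0 ? R::rnorm(0.0, sigma_z) : 0.0)) * dt;
      // reflect into bounds
      for (int k = 0; k < 8 && (nx < 0.0 || nx > tank_l); ++k)
        nx = nx < 0.0 ? -nx : 2.0 * tank_l - nx;
      for (int k = 0; k < 8 && (ny < 0.0 || ny > tank_w); ++k)
        ny = ny < 0.0 ? -ny : 2.0 * tank_w - ny;
      for (int k = 0; k < 8 && (nz < 0.0 || nz > depth); ++k)
        nz = nz < 0.0 ? -nz : 2.0 * depth - nz;
      if (!std::isfinite(nx) || !std::isfinite(ny) || !std::isfinite(nz))
        stop("shoal simulation produced a non-finite position; parameters unstable");
      nx = std::min(std::max(nx, 0.0), tank_l);
      ny = std::min(std::max(ny, 0.0), tank_w);
      nz = std::min(std::max(nz, 0.0), depth);
      x[i] = nx; y[i] = ny; z[i] = nz;
      out(t, i) = nx;
      out(t, n + i) = ny;
      out(t, 2 * n + i) = nz;
    }
  }
  return out;
}
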