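#include <Rcpp.h>
using namespace Rcpp;

// Wall-hindrance factors. Units: h, a in micrometres.
// Parallel: 5th-order Faxen series in beta = a/(a+h), clamped below at `floor_par`.
static inline double f_parallel(double h, double a, double floor_par) {
  double b = a / (a + h);
  double f = 1.0 - (9.0 / 16.0) * b + 0.125 * b * b * b -
             (45.0 / 256.0) * b * b * b * b - (1.0 / 16.0) * b * b * b * b * b;
  return f < floor_par ? floor_par : f;
}

// Perpendicular: Brenner-type rational approximation (exact limits h->0: h/a, h->inf: 1).
static inline double f_perp(double h, double a) {
  double num = 6.0 * h * h + 2.0 * a * h;
  double den = 6.0 * h * h + 9.0 * a * h + 2.0 * a * a;
  return num / den;
}

static inline double f_perp_prime(double h, double a) {
  double num = 6.0 * h * h + 2.0 * a * h;
  double den = 6.0 * h * h + 9.0 * a * h + 2.0 * a * a;
  double dnum = 12.0 * h + 2.0 * a;
  double dden = 12.0 * h + 9.0 * a;
  return (dnum * den - num * dden) / (den * den);
}

// [[Rcpp::export]]
double f_parallel_cpp(double h, double a, double floor_par) {
  return f_parallel(h, a, floor_par);
}

// [[Rcpp::export]]
double f_perp_cpp(double h, double a) { return f_perp(h, a); }

// Single-particle Brownian dynamics with Markov binding kinetics.
//
// State codes: 0 unbound, 1 bound_specific, 2 bound_nonspecific, 3 bound_multivalent.
// Unbound: height h evolves by overdamped Euler-Maruyama with the Ito drift
//   correction D'_perp(h) - D_perp(h)/hB (stationary law stays exponential with
//   mean hB), reflected at h = 0; lateral steps have variance 2*D0*f_par(h)*dt.
// Bound: lateral position is an Ornstein-Uhlenbeck process around the anchor with
//   stationary sd lc and correlation time tau_c; h is frozen at the binding height.
// Switching: per-substep competing-risk draws with exponential clocks.
// Uses R's RNG so set.seed() in R controls reproducibility.
// [[Rcpp::export]]
List sim_particle_cpp(int n_frames, double dt_frame, int substeps,
                      double D0, double a, double hB, double floor_par,
                      double k_on_specific, double k_ns,
                      double k_off, double k_off_ns,
                      double p_multi, double k_off_multi,
                      bool height_gated, double reach,
                      double lc, double tau_c, double sigma_loc,
                      double x0, double y0, double h0) {
  NumericVector x_obs(n_frames), y_obs(n_frames), x_true(n_frames),
      y_true(n_frames), h_out(n_frames);
  IntegerVector state_out(n_frames);

  double dt = dt_frame / substeps;
  double rho = std::exp(-dt / tau_c);
  double ou_sd = lc * std::sqrt(1.0 - rho * rho);

  double x = x0, y = y0, h = h0;
  int state = 0;
  double ax = 0.0, ay = 0.0;  // anchor while bound

  for (int i = 0; i < n_frames; ++i) {
    for (int s = 0; s < substeps; ++s) {
      if (state == 0) {
        // height update (Ito drift keeps the barometric stationary law)
        double Dp = D0 * f_perp(h, a);
        double drift = D0 * f_perp_prime(h, a) - Dp / hB;
        h += drift * dt + std::sqrt(2.0 * Dp * dt) * R::norm_rand();
        if (h < 0) h = -h;
        double Dl = D0 * f_parallel(h, a, floor_par);
        double sd = std::sqrt(2.0 * Dl * dt);
        x += sd * R::norm_rand();
        y += sd * R::norm_rand();
        // binding attempt
        double k_sp = k_on_specific * ((!height_gated || h < reach) ? 1.0 : 0.0);
        double k_tot = k_sp + k_ns;
        if (k_tot > 0 && R::unif_rand() < -std::expm1(-k_tot * dt)) {
          state = (R::unif_rand() < k_sp / k_tot) ? 1 : 2;
          ax = x;
          ay = y;
        }
      } else {
        // confined OU motion around the anchor
        x = ax + rho * (x - ax) + ou_sd * R::norm_rand();
        y = ay + rho * (y - ay) + ou_sd * R::norm_rand();
        double k_exit, k_up = 0.0;
        if (state == 1) {
          k_exit = k_off;
          k_up = p_multi;  // rate (1/s) of forming a second bond
        } else if (state == 2) {
          k_exit = k_off_ns;
        } else {
          k_exit = k_off_multi;
        }
        double k_tot = k_exit + k_up;
        if (k_tot > 0 && R::unif_rand() < -std::expm1(-k_tot * dt)) {
          if (state == 1 && k_up > 0 && R::unif_rand() < k_up / k_tot) {
            state = 3;
          } else {
            state = 0;
          }
        }
      }
    }
    x_true[i] = x;
    y_true[i] = y;
    h_out[i] = h;
    state_out[i] = state;
    x_obs[i] = x + sigma_loc * R::norm_rand();
    y_obs[i] = y + sigma_loc * R::norm_rand();
  }

  return List::create(_["x"] = x_obs, _["y"] = y_obs, _["x_true"] = x_true,
                      _["y_true"] = y_true, _["h"] = h_out,
                      _["state"] = state_out);
}

// Sliding-window diffusivity from the origin-constrained MSD slope.
// For each window of `W` frames, MSD over lags 1..L is averaged with overlapping
// pairs and the through-origin least-squares slope over lag times gives 4*D.
// Negative slopes are clipped to zero (static localization error); the number of
// clipped windows is returned.
// [[Rcpp::export]]
List windowed_diffusivity_cpp(NumericVector x, NumericVector y, int W, int L,
                              double dt) {
  int n = x.size();
  int nw = n - W + 1;
  NumericVector D(nw);
  int n_clipped = 0;

  // precompute squared displacements per lag
  std::vector<std::vector<double>> sq(L);
  for (int v = 1; v <= L; ++v) {
    sq[v - 1].resize(n - v);
    for (int i = 0; i < n - v; ++i) {
      double dx = x[i + v] - x[i], dy = y[i + v] - y[i];
      sq[v - 1][i] = dx * dx + dy * dy;
    }
  }
  // rolling sums per lag
  double sum_t2 = 0.0;
  for (int v = 1; v <= L; ++v) sum_t2 += (double)v * v * dt * dt;

  std::vector<double> roll(L);
  for (int j = 0; j < nw; ++j) {
    double num = 0.0;
    for (int v = 1; v <= L; ++v) {
      int m = W - v;  // pairs fully inside the window
      if (j == 0) {
        double s = 0.0;
        for (int i = 0; i < m; ++i) s += sq[v - 1][i];
        roll[v - 1] = s;
      } else {
        roll[v - 1] += sq[v - 1][j + m - 1] - sq[v - 1][j - 1];
      }
      double msd = roll[v - 1] / m;
      num += msd * v * dt;
    }
    double slope = num / sum_t2;
    if (slope < 0) {
      slope = 0;
      ++n_clipped;
    }
    D[j] = slope / 4.0;
  }
  return List::create(_["D"] = D, _["n_clipped"] = n_clipped);
}
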