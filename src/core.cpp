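#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Virtual-trajectory generator. Draws from R's RNG so that set.seed() on the
// R side makes runs reproducible. shape: 0 = circle, 1 = square.
// Returns an (n_steps + 1) x 2 matrix of positions in metres.
// [[Rcpp::export]]
NumericMatrix trajectory_cpp(int shape, double extent, int n_steps,
                             double step_max, double turn_halfwidth,
                             double boundary_zone, int max_tries) {
  NumericMatrix out(n_steps + 1, 2);
  const double cx = extent / 2.0, cy = extent / 2.0;
  const double r = extent / 2.0;
  double x = cx, y = cy;
  out(0, 0) = x;
  out(0, 1) = y;
  // persistent absolute heading, measured clockwise from +y (x advances with
  // sin, y with cos); initial heading is a free draw
  double heading = unif_rand() * 2.0 * M_PI;
  for (int t = 1; t <= n_steps; ++t) {
    bool near_wall;
    if (shape == 0) {
      double dc = std::sqrt((x - cx) * (x - cx) + (y - cy) * (y - cy));
      near_wall = (r - dc) <= boundary_zone;
    } else {
      double dmin = std::min(std::min(x, extent - x), std::min(y, extent - y));
      near_wall = dmin <= boundary_zone;
    }
    int tries = 0;
    double nx, ny, h_new;
    for (;;) {
      if (++tries > max_tries)
        stop("trajectory generation stuck at (%.4f, %.4f): %d rejected steps",
             x, y, max_tries);
      double d = unif_rand() * step_max;
      if (near_wall) {
        h_new = unif_rand() * 2.0 * M_PI;   // sharp turns near the wall
      } else {
        h_new = heading + (unif_rand() * 2.0 - 1.0) * turn_halfwidth;
      }
      nx = x + d * std::sin(h_new);
      ny = y + d * std::cos(h_new);
      bool inside;
      if (shape == 0) {
        inside = (nx - cx) * (nx - cx) + (ny - cy) * (ny - cy) <= r * r;
      } else {
        inside = nx >= 0.0 && nx <= extent && ny >= 0.0 && ny <= extent;
      }
      if (inside) break;
    }
    x = nx;
    y = ny;
    heading = h_new;
    out(t, 0) = x;
    out(t, 1) = y;
  }
  return out;
}

// Centre-shifted Mexican-hat (difference-of-Gaussians) recurrent weights on
// the n x n torus. theta[j] in 0..3 codes E, N, W, S preferred directions.
// Neuron j sits at lattice coordinate (col, row) = (j %% n, j %/% n).
// [[Rcpp::export]]
NumericMatrix build_weights_cpp(int n, double beta, double gam, double a,
                                double l, IntegerVector theta) {
  const int N = n * n;
  if (theta.size() != N) stop("theta must have n^2 entries");
  NumericMatrix W(N, N);
  const double exv[4] = {1.0, 0.0, -1.0, 0.0};
  const double eyv[4] = {0.0, 1.0, 0.0, -1.0};
  const double half = n / 2.0;
  for (int j = 0; j < N; ++j) {
    const double xj = j % n, yj = j / n;
    const double sx = l * exv[theta[j]], sy = l * eyv[theta[j]];
    double* col = &W(0, j);
    for (int i = 0; i < N; ++i) {
      double dx = (i % n) - xj;
      double dy = (i / n) - yj;
      // minimum-image displacement, each component in (-n/2, n/2]
      if (dx > half) dx -= n; else if (dx <= -half) dx += n;
      if (dy > half) dy -= n; else if (dy <= -half) dy += n;
      const double ddx = dx - sx, ddy = dy - sy;
      const double r2 = ddx * ddx + ddy * ddy;
      col[i] = a * std::exp(-gam * r2) - std::exp(-beta * r2);
    }
  }
  return W;
}

// Single-neuron response to an arbitrary input series (chirp, pulse, ...).
// kind: 0 integrator (tau ds/dt = -s + c, no rectification),
//       1 phenomenological resonator (h = R * s * |ds/dt|^eps),
//       2 mechanistic resonator (slow negative feedback m, no rectification).
// [[Rcpp::export]]
NumericVector single_neuron_cpp(int kind, NumericVector input, double dt,
                                double tau, double epsilon, double Rscale,
                                bool deriv_rectified, double g, double k,
                                double S_half, double tau_m) {
  const int T = input.size();
  NumericVector out(T);
  if (kind == 0 || kind == 1) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      const double sprev = s;
      s += (dt / tau) * (input[t] - s);
      if (kind == 0) {
        out[t] = s;
      } else {
        double du = (s - sprev) / dt;
        du = deriv_rectified ? std::max(du, 0.0) : std::fabs(du);
        out[t] = Rscale * s * std::pow(du, epsilon);
      }
    }
  } else if (kind == 2) {
    double S = 0.0;
    double m = 1.0 / (1.0 + std::exp((S_half - S) / k));
    for (int t = 0; t < T; ++t) {
      const double minf = 1.0 / (1.0 + std::exp((S_half - S) / k));
      const double Snew = S + (dt / tau) * (-S - g * m + input[t]);
      m += (dt / tau_m) * (minf - m);
      S = Snew;
      out[t] = S;
    }
  } else {
    stop("unknown neuron kind %d", kind);
  }
  return out;
}

// Recurrent drive D = W * S for a small number of trial columns, streaming
// W from memory exactly once per step (a BLAS gemm with a very skinny
// right-hand side falls back to one gemv per column, re-streaming W).
static void recurrent_drive(const arma::fmat& W, const arma::fmat& S,
                            arma::fmat& D) {
  const arma::uword N = W.n_rows, K = S.n_cols;
  D.zeros(N, K);
  for (arma::uword k = 0; k < N; ++k) {
    const float* w = W.colptr(k);
    for (arma::uword j = 0; j < K; ++j) {
      const float s = S(k, j);
      if (s == 0.0f) continue;
      float* d = D.colptr(j);
      for (arma::uword i = 0; i < N; ++i) d[i] += w[i] * s;
    }
  }
}

// Flush tiny magnitudes to zero: rectified units decay geometrically, and
// letting them underflow into denormals both stalls the FPU and defeats
// the zero-skip in recurrent_drive.
static inline void flush_denormals(arma::fmat& S) {
  S.transform([](float x) { return std::fabs(x) < 1e-20f ? 0.0f : x; });
}

// Full network integration. Trials (independent initial conditions sharing
// every other parameter) run as columns of S so the recurrent drive streams
// the weight matrix once per step for all trials. Single precision: the
// per-step memory traffic on W dominates run time and the dynamics are
// insensitive to precision beyond float.
//
// kind: 0 integrator, 1 phenomenological resonator, 2 mechanistic resonator.
// vx, vy: per-step displacement (m) aligned with trajectory samples; the
//         entry at t drives the step into position t (entry 0 unused).
// pix:    0-based pixel index per trajectory sample (-1 = skip accumulation).
// record_idx, map_idx: 0-based neuron indices.
// [[Rcpp::export]]
List simulate_cpp(NumericMatrix W_, NumericMatrix S0_, int kind,
                  NumericVector tau, NumericVector alpha, NumericVector ex,
                  NumericVector ey, NumericVector vx, NumericVector vy,
                  double dt, int settle_steps, double epsilon, double Rscale,
                  bool recur_internal, double deriv_tau, double g,
                  double kslope, double S_half,
                  double tau_m, IntegerVector record_idx,
                  IntegerVector map_idx, IntegerVector pix, int n_pix,
                  bool record_m) {
  const int N = W_.nrow();
  const int K = S0_.ncol();
  const int T = vx.size();
  if (W_.ncol() != N) stop("W must be square");
  if (S0_.nrow() != N) stop("S0 must have one row per neuron");
  if ((int)pix.size() != T) stop("pix must align with the velocity series");

  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(W_.begin(), N, N, false));
  arma::fvec dOt(N), al(N), exf(N), eyf(N);
  for (int i = 0; i < N; ++i) {
    if (tau[i] <= 0) stop("tau must be positive");
    dOt[i] = (float)(dt / tau[i]);
    al[i] = (float)alpha[i];
    exf[i] = (float)ex[i];
    eyf[i] = (float)ey[i];
  }

  arma::fmat S(N, K), u, m, dsm;
  const bool smooth_deriv = deriv_tau > 0.0;
  const float ema = smooth_deriv ? (float)(dt / deriv_tau) : 1.0f;
  for (int k2 = 0; k2 < K; ++k2)
    for (int i = 0; i < N; ++i) S(i, k2) = (float)S0_(i, k2);
  if (kind == 1) {
    u = S;  // internal low-pass state; S holds the redefined output
    dsm.zeros(N, K);
  } else if (kind == 2) {
    m = S;  // feedback state starts at its steady state m_inf(S0)
    m.transform([&](float s) {
      return (float)(1.0 / (1.0 + std::exp((S_half - s) / kslope)));
    });
  }

  const int n_rec = record_idx.size();
  const int n_map = map_idx.size();
  List traces(K), acc_list(K), m_traces(K);
  std::vector<arma::mat> tr(K), acc(K), mtr(K);
  for (int k2 = 0; k2 < K; ++k2) {
    if (n_rec > 0) tr[k2].zeros(T, n_rec);
    if (n_map > 0) acc[k2].zeros(n_pix, n_map);
    if (record_m && kind == 2 && n_rec > 0) mtr[k2].zeros(T, n_rec);
  }

  arma::fvec B(N);
  const float eps_f = (float)epsilon, R_f = (float)Rscale;
  const float g_f = (float)g, dt_f = (float)dt;
  const float dt_over_taum = (float)(dt / tau_m);

  auto step = [&](float vxt, float vyt) {
    for (int i = 0; i < N; ++i)
      B[i] = 1.0f + al[i] * (exf[i] * vxt + eyf[i] * vyt);
    if (kind == 0) {
      arma::fmat D(N, K);
      recurrent_drive(Wf, S, D);
      D.each_col() += B;
      D.transform([](float x) { return x > 0.0f ? x : 0.0f; });
      D -= S;
      D.each_col() %= dOt;
      S += D;
      flush_denormals(S);
    } else if (kind == 1) {
      arma::fmat D(N, K);
      recurrent_drive(Wf, recur_internal ? u : S, D);
      D.each_col() += B;
      D.transform([](float x) { return x > 0.0f ? x : 0.0f; });
      D -= u;
      D.each_col() %= dOt;   // D now holds u_new - u
      u += D;
      flush_denormals(u);
      // redefined activity: R * u * |du/dt|^eps (falls back to u when
      // eps = 0); the derivative is optionally low-pass filtered to damp
      // per-step velocity noise before the fractional power
      if (smooth_deriv) {
        dsm += ema * (D / dt_f - dsm);
        S = R_f * (u % arma::pow(arma::abs(dsm), eps_f));
      } else {
        S = R_f * (u % arma::pow(arma::abs(D) / dt_f, eps_f));
      }
      flush_denormals(S);
    } else {
      arma::fmat MI = S;
      MI.transform([&](float s) {
        return (float)(1.0 / (1.0 + std::exp((S_half - s) / kslope)));
      });
      arma::fmat D(N, K);
      recurrent_drive(Wf, S, D);
      D.each_col() += B;
      D.transform([](float x) { return x > 0.0f ? x : 0.0f; });
      D -= S;
      D -= g_f * m;
      D.each_col() %= dOt;
      S += D;
      flush_denormals(S);
      m += dt_over_taum * (MI - m);
    }
  };

  for (int t = 0; t < settle_steps; ++t) {
    step(0.0f, 0.0f);
    if (t % 200 == 0 && (!S.is_finite() || arma::abs(S).max() > 1e6f))
      stop("network activity diverged during settling (step %d)", t);
  }
  NumericMatrix S_settled(N, K);
  for (int k2 = 0; k2 < K; ++k2)
    for (int i = 0; i < N; ++i) S_settled(i, k2) = S(i, k2);

  auto record = [&](int t) {
    for (int k2 = 0; k2 < K; ++k2) {
      for (int j = 0; j < n_rec; ++j) {
        tr[k2](t, j) = S(record_idx[j], k2);
        if (record_m && kind == 2) mtr[k2](t, j) = m(record_idx[j], k2);
      }
      if (n_map > 0 && pix[t] >= 0) {
        for (int j = 0; j < n_map; ++j)
          acc[k2](pix[t], j) += S(map_idx[j], k2);
      }
    }
  };

  record(0);
  for (int t = 1; t < T; ++t) {
    step((float)vx[t], (float)vy[t]);
    if (t % 200 == 0 && (!S.is_finite() || arma::abs(S).max() > 1e6f))
      stop("network activity diverged at step %d (max |S| = %g)", t,
           (double)arma::abs(S).max());
    record(t);
  }
  if (!S.is_finite()) stop("network activity diverged (non-finite state)");

  for (int k2 = 0; k2 < K; ++k2) {
    if (n_rec > 0) traces[k2] = wrap(tr[k2]);
    if (n_map > 0) acc_list[k2] = wrap(acc[k2]);
    if (record_m && kind == 2 && n_rec > 0) m_traces[k2] = wrap(mtr[k2]);
  }
  NumericMatrix S_final(N, K);
  for (int k2 = 0; k2 < K; ++k2)
    for (int i = 0; i < N; ++i) S_final(i, k2) = S(i, k2);

  return List::create(_["trace"] = traces, _["act"] = acc_list,
                      _["m_trace"] = m_traces, _["S_settled"] = S_settled,
                      _["S_final"] = S_final);
}
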