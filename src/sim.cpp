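#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Delayed stochastic Heun integrator for the two-dimensional neural-mass
// oscillator network:
//   dV_i = ts*(W_i + 3 V_i^2 - V_i^3 + gamma * I_i) dt + noise_std dXi
//   dW_i = ts*(-W_i - 10 V_i) dt               + noise_std dEta
//   I_i(t) = sum_j A_ij S(V_j(t - tau_ij)),  S(v) = 1/(1+exp(-sigma (v - m)))
// Coupling is evaluated from a circular history buffer of firing rates; both
// Heun stages read the buffer only (delays are >= 1 step), so the delayed
// current at t and t+dt is exact.  The same Gaussian increment is used in the
// predictor and corrector, as the stochastic Heun scheme requires.
//
// src_idx / src_w / src_d give, for each target region i, the source indices
// (0-based), weights and integer delay steps of its non-zero afferents.

static inline double sigmoid_rate(double v, double sigma, double m) {
  return 1.0 / (1.0 + std::exp(-sigma * (v - m)));
}

// [[Rcpp::export(name = ".heun_delay_cpp")]]
List heun_delay_cpp(List src_idx, List src_w, List src_d,
                    int n, double gamma, double sigma, double m,
                    double timescale, double dt, int n_steps,
                    int transient_steps, int store_every,
                    double noise_std,
                    NumericVector v0, NumericVector w0,
                    int max_delay_steps) {
  const double sqdt = std::sqrt(dt);
  const int H = max_delay_steps + 2;          // history buffer length (steps)
  std::vector<double> buf((size_t)H * n);     // column-major: buf[j*H + h]
  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> W(w0.begin(), w0.end());
  std::vector<double> It(n), Itp(n);          // current at t and t+dt
  std::vector<double> nV(n), nW(n), Vp(n), Wp(n), f1V(n), f1W(n);

  // flatten the afferent lists into CSR-style arrays
  std::vector<int> rowptr(n + 1, 0);
  std::vector<int> esrc, edly;
  std::vector<double> ewgt;
  for (int i = 0; i < n; ++i) {
    std::vector<int> ji = as<std::vector<int> >(src_idx[i]);
    std::vector<double> wi = as<std::vector<double> >(src_w[i]);
    std::vector<int> di = as<std::vector<int> >(src_d[i]);
    for (size_t e = 0; e < ji.size(); ++e) {
      if (di[e] < 1 || di[e] > max_delay_steps)
        stop("delay steps out of buffer range");
      esrc.push_back(ji[e]); ewgt.push_back(wi[e]); edly.push_back(di[e]);
    }
    rowptr[i + 1] = (int)esrc.size();
  }
  const int *psrc = esrc.data(), *pdly = edly.data();
  const double *pwgt = ewgt.data();
  double *pbuf = buf.data();

  // history initialised at the initial state
  for (int j = 0; j < n; ++j) {
    double s0 = sigmoid_rate(V[j], sigma, m);
    for (int h = 0; h < H; ++h) pbuf[(size_t)j * H + h] = s0;
  }

  int n_keep = (n_steps - transient_steps) / store_every;
  NumericMatrix Vout(n_keep, n), Wout(n_keep, n), Iout(n_keep, n);
  int kept = 0;

  // I at step 0 (history is flat so a plain gather is exact)
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int e = rowptr[i]; e < rowptr[i + 1]; ++e)
      acc += pwgt[e] * pbuf[(size_t)psrc[e] * H];
    It[i] = acc;
  }

  for (int t = 0; t < n_steps; ++t) {
    // delayed current at t+1 (all needed rates are already in the buffer);
    // hp = (t+1) mod H, per-edge row hp - d wrapped branchlessly
    const int hp = (t + 1) % H;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int e = rowptr[i]; e < rowptr[i + 1]; ++e) {
        int h = hp - pdly[e];
        h += H & (h >> 31);               // add H when negative
        acc += pwgt[e] * pbuf[(size_t)psrc[e] * H + h];
      }
      Itp[i] = acc;
    }

    for (int i = 0; i < n; ++i) nV[i] = noise_std * sqdt * norm_rand();
    for (int i = 0; i < n; ++i) nW[i] = noise_std * sqdt * norm_rand();

    for (int i = 0; i < n; ++i) {
      double v = V[i], w = W[i];
      f1V[i] = timescale * (w + 3.0 * v * v - v * v * v + gamma * It[i]);
      f1W[i] = timescale * (-w - 10.0 * v);
      Vp[i] = v + f1V[i] * dt + nV[i];
      Wp[i] = w + f1W[i] * dt + nW[i];
    }
    for (int i = 0; i < n; ++i) {
      double vp = Vp[i], wp = Wp[i];
      double f2V = timescale * (wp + 3.0 * vp * vp - vp * vp * vp + gamma * Itp[i]);
      double f2W = timescale * (-wp - 10.0 * vp);
      V[i] += 0.5 * (f1V[i] + f2V) * dt + nV[i];
      W[i] += 0.5 * (f1W[i] + f2W) * dt + nW[i];
    }

    // write rates for step t+1 and roll the current forward
    for (int j = 0; j < n; ++j)
      pbuf[(size_t)j * H + hp] = sigmoid_rate(V[j], sigma, m);
    std::swap(It, Itp);

    if (((t + 1) % 1000) == 0 || t + 1 == n_steps) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]) || std::fabs(V[i]) > 1e6)
          stop("numerical blow-up at step %d (t = %g): region %d, sigma = %g, gamma = %g, dt = %g",
               t + 1, (t + 1) * dt, i + 1, sigma, gamma, dt);
    }

    int rel = t + 1 - transient_steps;
    if (rel > 0 && (rel % store_every) == 0 && kept < n_keep) {
      for (int i = 0; i < n; ++i) {
        Vout(kept, i) = V[i]; Wout(kept, i) = W[i]; Iout(kept, i) = It[i];
      }
      ++kept;
    }
  }

  return List::create(_["V"] = Vout, _["W"] = Wout, _["I"] = Iout);
}

// Balloon-Windkessel hemodynamic forward model (four states per region:
// vasodilatory signal s, inflow f, venous volume v, deoxyhemoglobin q),
// driven by neural activity z and integrated with Euler steps at dt seconds.
// BOLD is returned in percent signal change, sampled every sample_every steps.
// [[Rcpp::export(name = ".balloon_windkessel_cpp")]]
NumericMatrix balloon_windkessel_cpp(NumericMatrix z, double dt,
                                     double kappa, double gammaf, double tau,
                                     double alpha, double rho0, double V0,
                                     int sample_every) {
  const int T = z.nrow(), n = z.ncol();
  const double k1 = 7.0 * rho0, k2 = 2.0, k3 = 2.0 * rho0 - 0.2;
  const double ia = 1.0 / alpha;
  std::vector<double> s(n, 0.0), f(n, 1.0), v(n, 1.0), q(n, 1.0);
  int n_keep = T / sample_every;
  NumericMatrix out(n_keep, n);
  int kept = 0;
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      double fi = f[i] > 1e-6 ? f[i] : 1e-6;
      double vi = v[i] > 1e-6 ? v[i] : 1e-6;
      double E  = 1.0 - std::pow(1.0 - rho0, 1.0 / fi);
      double fv = std::pow(vi, ia);
      double ds = z(t, i) - kappa * s[i] - gammaf * (fi - 1.0);
      double df = s[i];
      double dv = (fi - fv) / tau;
      double dq = (fi * E / rho0 - fv * q[i] / vi) / tau;
      s[i] += dt * ds; f[i] += dt * df; v[i] += dt * dv; q[i] += dt * dq;
      if (!std::isfinite(s[i]) || !std::isfinite(q[i]))
        stop("hemodynamic model became non-finite at sample %d, region %d", t + 1, i + 1);
    }
    if (((t + 1) % sample_every) == 0 && kept < n_keep) {
      for (int i = 0; i < n; ++i) {
        double vi = v[i] > 1e-6 ? v[i] : 1e-6;
        out(kept, i) = 100.0 * V0 *
          (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / vi) + k3 * (1.0 - vi));
      }
      ++kept;
    }
  }
  return out;
}
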