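#include <Rcpp.h>
using namespace Rcpp;

// Theta-neuron integration of the nondimensional QIF network.
//
// Each neuron obeys tau du/dt = (u^2 - 1)/2 + a_j + b_j u with
//   a_j = Ihat_j + (ge_j s_e + gn_j s_n) Vex + gi_j s_i Vin
//   b_j = -(ge_j s_e + gn_j s_n + gi_j s_i),
// integrated in the phase variable u = tan(theta/2), where the dynamics
//   tau dtheta/dt = -cos(theta) + b_j sin(theta) + a_j (1 + cos(theta))
// are globally smooth and the spike (u -> +inf, reset -inf) is the exact
// phase crossing theta = pi. Fixed-step RK4; gates held constant within a
// step; spikes detected after the step and gate increments (1/N per spike)
// applied at the step end, order-independent for simultaneous spikes.

static inline double theta_rhs(double th, double a, double b, double inv_tau) {
  double c = std::cos(th);
  return inv_tau * (-c + b * std::sin(th) + a * (1.0 + c));
}

List simulate_qif_cpp(NumericVector theta0, NumericVector ge, NumericVector gn,
                      NumericVector gi, NumericVector Ihat, int N_e,
                      double tau, double Vex, double Vin,
                      double tau_e, double tau_i, double tau_n, double a_n,
                      double dt, int n_steps, int record_every,
                      double s_e0, double s_i0, double s_n0) {
  const int N = theta0.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  double s_e = s_e0, s_i = s_i0, s_n = s_n0;
  const double inv_tau = 1.0 / tau;
  /* Population-normalized gate increments: with them the gating drive is
   * exactly the population mean rate, matching the macroscopic gating
   * equations ds_e/dt = -s_e/tau_e + r_e for any N_e:N_i split. */
  const double inc_e = 1.0 / (double)N_e;
  const double inc_i = 1.0 / (double)(N - N_e);

  std::vector<double> spike_t, trace_t, trace_se, trace_si, trace_sn;
  std::vector<int> spike_id;
  spike_t.reserve(n_steps / 4);
  spike_id.reserve(n_steps / 4);

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    if (record_every > 0 && step % record_every == 0) {
      trace_t.push_back(t);
      trace_se.push_back(s_e);
      trace_si.push_back(s_i);
      trace_sn.push_back(s_n);
    }
    // gates: smooth part (decay / NMDA logistic), RK4 on the 3D subsystem
    {
      double k1e = -s_e / tau_e, k1i = -s_i / tau_i,
             k1n = a_n * s_e * (1 - s_n) - s_n / tau_n;
      double e2 = s_e + 0.5 * dt * k1e, i2 = s_i + 0.5 * dt * k1i,
             n2 = s_n + 0.5 * dt * k1n;
      double k2e = -e2 / tau_e, k2i = -i2 / tau_i,
             k2n = a_n * e2 * (1 - n2) - n2 / tau_n;
      double e3 = s_e + 0.5 * dt * k2e, i3 = s_i + 0.5 * dt * k2i,
             n3 = s_n + 0.5 * dt * k2n;
      double k3e = -e3 / tau_e, k3i = -i3 / tau_i,
             k3n = a_n * e3 * (1 - n3) - n3 / tau_n;
      double e4 = s_e + dt * k3e, i4 = s_i + dt * k3i,
             n4 = s_n + dt * k3n;
      double k4e = -e4 / tau_e, k4i = -i4 / tau_i,
             k4n = a_n * e4 * (1 - n4) - n4 / tau_n;
      // neurons see the step-start gate values; update gates after
      double se_new = s_e + dt / 6.0 * (k1e + 2 * k2e + 2 * k3e + k4e);
      double si_new = s_i + dt / 6.0 * (k1i + 2 * k2i + 2 * k3i + k4i);
      double sn_new = s_n + dt / 6.0 * (k1n + 2 * k2n + 2 * k3n + k4n);

      int ne_sp = 0, ni_sp = 0;
      for (int j = 0; j < N; ++j) {
        double exg = ge[j] * s_e + gn[j] * s_n;
        double a = Ihat[j] + exg * Vex + gi[j] * s_i * Vin;
        double b = -(exg + gi[j] * s_i);
        double th0 = th[j];
        double k1 = theta_rhs(th0, a, b, inv_tau);
        double k2 = theta_rhs(th0 + 0.5 * dt * k1, a, b, inv_tau);
        double k3 = theta_rhs(th0 + 0.5 * dt * k2, a, b, inv_tau);
        double k4 = theta_rhs(th0 + dt * k3, a, b, inv_tau);
        double th1 = th0 + dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
        if (!std::isfinite(th1))
          stop("non-finite neuron state at t = %f ms (neuron %d)", t, j + 1);
        if (th1 >= M_PI) {           // phase crossing = spike, exact reset
          th1 -= 2.0 * M_PI;
          spike_t.push_back(t + dt);
          spike_id.push_back(j + 1);
          if (j < N_e) ++ne_sp; else ++ni_sp;
        }
        th[j] = th1;
      }
      s_e = se_new + inc_e * ne_sp;
      s_i = si_new + inc_i * ni_sp;
      s_n = sn_new;
    }
  }
  return List::create(
    _["spike_times"] = wrap(spike_t), _["spike_ids"] = wrap(spike_id),
    _["trace_t"] = wrap(trace_t), _["s_e"] = wrap(trace_se),
    _["s_i"] = wrap(trace_si), _["s_n"] = wrap(trace_sn),
    _["theta_final"] = wrap(th),
    _["s_final"] = NumericVector::create(s_e, s_i, s_n));
}

// .Call wrapper (registered in init.c)
extern "C" SEXP pingmf_simulate_qif(SEXP theta0, SEXP ge, SEXP gn, SEXP gi,
                                    SEXP Ihat, SEXP N_e, SEXP tau, SEXP Vex,
                                    SEXP Vin, SEXP tau_e, SEXP tau_i,
                                    SEXP tau_n, SEXP a_n, SEXP dt,
                                    SEXP n_steps, SEXP record_every,
                                    SEXP s_e0, SEXP s_i0, SEXP s_n0) {
  BEGIN_RCPP
  return wrap(simulate_qif_cpp(
      as<NumericVector>(theta0), as<NumericVector>(ge), as<NumericVector>(gn),
      as<NumericVector>(gi), as<NumericVector>(Ihat), as<int>(N_e),
      as<double>(tau), as<double>(Vex), as<double>(Vin), as<double>(tau_e),
      as<double>(tau_i), as<double>(tau_n), as<double>(a_n), as<double>(dt),
      as<int>(n_steps), as<int>(record_every), as<double>(s_e0),
      as<double>(s_i0), as<double>(s_n0)));
  END_RCPP
}
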