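# Shared fixtures: small parameter sets built in code.

# A deterministic homogeneous single-population setup: no coupling, no
# heterogeneity, drive Ihat to the excitatory population only.
uncoupled_params <- function(Ihat = 2, tau = 10) {
  mf_params(tau = tau,
            kinetics = synapse_kinetics(),
            coupling = coupling_params(),
            drive = drive_params(Ibar_e = Ihat, Delta_e = 0,
                                 Ibar_i = 0, Delta_i = 0))
}

# Closed-form firing rate of a homogeneous QIF population with tonic drive:
# sqrt(2*Ihat - 1) / (2*pi*tau) above threshold (Ihat > 1/2), else 0.
qif_rate_closed_form <- function(Ihat, tau) {
  ifelse(Ihat > 0.5, sqrt(pmax(2 * Ihat - 1, 0)) / (2 * pi * tau), 0)
}

# Independent oracle for the same rate: numeric quadrature of the period
# T = integral du / [((u^2 - 1)/2 + Ihat)/tau] over the whole real line.
qif_rate_quadrature <- function(Ihat, tau) {
  if (Ihat <= 0.5) return(0)
  f <- function(u) tau / ((u^2 - 1) / 2 + Ihat)
  Tper <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  1 / Tper
}

# Random valid biophysics for roundtrip tests.
random_biophys <- function() {
  Vl <- runif(1, -80, -55)
  VT <- Vl + runif(1, 5, 30)
  biophys_params(C = runif(1, 0.5, 2), gl = runif(1, 0.05, 0.3),
                 Vl = Vl, VT = VT,
                 Vex = VT + runif(1, 10, 60),
                 Vin = Vl - runif(1, 0, 15))
}
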