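#' Mean-field state of the PING circuit
#'
#' The seven macroscopic variables of the exact mean-field reduction:
#' population firing rates \code{r_e}, \code{r_i} (1/ms), mean
#' nondimensional potentials \code{u_e}, \code{u_i}, and the global gating
#' fractions \code{s_e} (AMPA), \code{s_i} (GABA), \code{s_n} (NMDA).
#'
#' @param r_e,u_e,s_e Excitatory rate, mean potential, AMPA gate.
#' @param r_i,u_i,s_i Inhibitory rate, mean potential, GABA gate.
#' @param s_n NMDA gate (logistic, in [0, 1]).
#' @return Named numeric vector of class \code{"mf_state"} with the
#'   canonical ordering \code{(r_e, u_e, s_e, r_i, u_i, s_i, s_n)}.
#' @export
mean_field_state <- function(r_e = 1e-3, u_e = -1, s_e = 0,
                             r_i = 1e-3, u_i = -1, s_i = 0, s_n = 0) {
  x <- c(r_e = as.numeric(r_e), u_e = as.numeric(u_e), s_e = as.numeric(s_e),
         r_i = as.numeric(r_i), u_i = as.numeric(u_i), s_i = as.numeric(s_i),
         s_n = as.numeric(s_n))
  if (any(!is.finite(x))) stop("mean-field state must be finite")
  structure(x, class = c("mf_state", "numeric"))
}

.state_names <- c("r_e", "u_e", "s_e", "r_i", "u_i", "s_i", "s_n")

# Core right-hand side on a bare numeric state x (canonical order) and the
# flattened parameter vector q from .flat_params(). Kept free of S3 dispatch
# and name lookups: it is called ~1e5 times per trajectory.
.mf_rhs_core <- function(x, q) {
  re <- x[1L]; ue <- x[2L]; se <- x[3L]
  ri <- x[4L]; ui <- x[5L]; si <- x[6L]; sn <- x[7L]
  tau <- q[["tau"]]; Vex <- q[["Vex"]]; Vin <- q[["Vin"]]
  aExE <- abs(ue - Vex); aInE <- abs(ue - Vin)
  aExI <- abs(ui - Vex); aInI <- abs(ui - Vin)
  sExE <- sign(Vex - ue); sInE <- sign(Vin - ue)
  sExI <- sign(Vex - ui); sInI <- sign(Vin - ui)
  Ae <- q[["gee"]]*se + q[["gei"]]*si + q[["gen"]]*sn
  Ai <- q[["gie"]]*se + q[["gii"]]*si + q[["gin"]]*sn
  He <- q[["De"]] + q[["cee"]]*se*aExE + q[["cei"]]*si*aInE + q[["cen"]]*sn*aExE
  Hi <- q[["Di"]] + q[["cie"]]*se*aExI + q[["cii"]]*si*aInI + q[["cin"]]*sn*aExI
  Ge <- (q[["cee"]]*se + q[["cen"]]*sn)*sExE + q[["cei"]]*si*sInE
  Gi <- (q[["cie"]]*se + q[["cin"]]*sn)*sExI + q[["cii"]]*si*sInI
  c((re*ue - Ae*re)/tau + He/(2*pi*tau^2),
    (0.5*(ue^2 - 1) + q[["Ie"]] - q[["gee"]]*se*(ue - Vex) -
       q[["gei"]]*si*(ue - Vin) - q[["gen"]]*sn*(ue - Vex))/tau -
      2*pi^2*tau*re^2 + 2*pi*re*Ge,
    -se/q[["taue"]] + re,
    (ri*ui - Ai*ri)/tau + Hi/(2*pi*tau^2),
    (0.5*(ui^2 - 1) + q[["Ii"]] - q[["gie"]]*se*(ui - Vex) -
       q[["gii"]]*si*(ui - Vin) - q[["gin"]]*sn*(ui - Vex))/tau -
      2*pi^2*tau*ri^2 + 2*pi*ri*Gi,
    -si/q[["taui"]] + ri,
    q[["an"]]*se*(1 - sn) - sn/q[["taun"]])
}

# Analytic Jacobian of .mf_rhs_core; piecewise-smooth (the |.| and sgn terms
# have kinks only on the measure-zero manifolds u = Vhat_ex, u = Vhat_in).
.mf_jac_core <- function(x, q) {
  re <- x[1L]; ue <- x[2L]; se <- x[3L]
  ri <- x[4L]; ui <- x[5L]; si <- x[6L]; sn <- x[7L]
  tau <- q[["tau"]]; Vex <- q[["Vex"]]; Vin <- q[["Vin"]]
  gee <- q[["gee"]]; gei <- q[["gei"]]; gen <- q[["gen"]]
  gie <- q[["gie"]]; gii <- q[["gii"]]; gin <- q[["gin"]]
  cee <- q[["cee"]]; cei <- q[["cei"]]; cen <- q[["cen"]]
  cie <- q[["cie"]]; cii <- q[["cii"]]; cin <- q[["cin"]]
  aExE <- abs(ue - Vex); aInE <- abs(ue - Vin)
  aExI <- abs(ui - Vex); aInI <- abs(ui - Vin)
  sExE <- sign(Vex - ue); sInE <- sign(Vin - ue)
  sExI <- sign(Vex - ui); sInI <- sign(Vin - ui)
  Ae <- gee*se + gei*si + gen*sn
  Ai <- gie*se + gii*si + gin*sn
  Ge <- (cee*se + cen*sn)*sExE + cei*si*sInE
  Gi <- (cie*se + cin*sn)*sExI + cii*si*sInI
  tpt2 <- 2*pi*tau^2
  J <- matrix(0, 7L, 7L, dimnames = list(.state_names, .state_names))
  J[1L,1L] <- (ue - Ae)/tau
  J[1L,2L] <- re/tau + (cee*se*sign(ue-Vex) + cei*si*sign(ue-Vin) + cen*sn*sign(ue-Vex))/tpt2
  J[1L,3L] <- -gee*re/tau + cee*aExE/tpt2
  J[1L,6L] <- -gei*re/tau + cei*aInE/tpt2
  J[1L,7L] <- -gen*re/tau + cen*aExE/tpt2
  J[2L,1L] <- -4*pi^2*tau*re + 2*pi*Ge
  J[2L,2L] <- (ue - gee*se - gei*si - gen*sn)/tau
  J[2L,3L] <- -gee*(ue - Vex)/tau + 2*pi*re*cee*sExE
  J[2L,6L] <- -gei*(ue - Vin)/tau + 2*pi*re*cei*sInE
  J[2L,7L] <- -gen*(ue - Vex)/tau + 2*pi*re*cen*sExE
  J[3L,1L] <- 1; J[3L,3L] <- -1/q[["taue"]]
  J[4L,4L] <- (ui - Ai)/tau
  J[4L,5L] <- ri/tau + (cie*se*sign(ui-Vex) + cii*si*sign(ui-Vin) + cin*sn*sign(ui-Vex))/tpt2
  J[4L,3L] <- -gie*ri/tau + cie*aExI/tpt2
  J[4L,6L] <- -gii*ri/tau + cii*aInI/tpt2
  J[4L,7L] <- -gin*ri/tau + cin*aExI/tpt2
  J[5L,4L] <- -4*pi^2*tau*ri + 2*pi*Gi
  J[5L,5L] <- (ui - gie*se - gii*si - gin*sn)/tau
  J[5L,3L] <- -gie*(ui - Vex)/tau + 2*pi*ri*cie*sExI
  J[5L,6L] <- -gii*(ui - Vin)/tau + 2*pi*ri*cii*sInI
  J[5L,7L] <- -gin*(ui - Vex)/tau + 2*pi*ri*cin*sExI
  J[6L,4L] <- 1; J[6L,6L] <- -1/q[["taui"]]
  J[7L,3L] <- q[["an"]]*(1 - sn)
  J[7L,7L] <- -q[["an"]]*se - 1/q[["taun"]]
  J
}

#' Time derivative of the mean-field state
#'
#' Evaluates the closed seven-dimensional macroscopic system obtained from
#' the Lorentzian (Ott-Antonsen) ansatz: for each population the rate
#' equation carries the heterogeneity source
#' \eqn{(\hat\Delta + \sum \hat\gamma\, s\, |u - \hat V|)/(2\pi\tau^2)},
#' the mean-potential equation carries \eqn{-2\pi^2 \tau r^2} and the
#' \eqn{2\pi r \sum \hat\gamma\, s\, \mathrm{sgn}(\hat V - u)} coupling, and
#' the gates follow \eqn{s_e' = -s_e/\tau_e + r_e},
#' \eqn{s_i' = -s_i/\tau_i + r_i},
#' \eqn{s_n' = a_n s_e (1 - s_n) - s_n/\tau_n}.
#'
#' @param x State vector (\code{\link{mean_field_state}} or bare numeric(7)
#'   in canonical order).
#' @param p An \code{\link{mf_params}} object.
#' @return Named numeric(7): the time derivative (1/ms).
#' @export
mean_field_rhs <- function(x, p) {
  stopifnot(length(x) == 7L)
  d <- .mf_rhs_core(as.numeric(x), .flat_params(p))
  names(d) <- .state_names
  d
}

#' Integrate the mean-field system
#'
#' Adaptive-step integration (deSolve) with dense output at \code{dt_out}.
#' Trajectories of interest keep both mean potentials strictly between the
#' reduced reversals; a crossing (where the right-hand side is nonsmooth) is
#' detected after the fact and reported as a warning.
#'
#' @param p An \code{\link{mf_params}} object.
#' @param x0 Initial state; default \code{\link{mean_field_state}()} (small
#'   positive rates, potentials at rest, gates closed).
#' @param duration Total integration time (ms).
#' @param dt_out Output sampling interval (ms).
#' @param rtol,atol Integrator tolerances.
#' @param method deSolve method (default \code{"lsoda"}).
#' @return Data frame of class \code{"mf_trajectory"} with columns
#'   \code{t, r_e, u_e, s_e, r_i, u_i, s_i, s_n}; rates are in 1/ms
#'   (multiply by 1000 for Hz).
#' @export
integrate_mean_field <- function(p, x0 = mean_field_state(), duration = 3000,
                                 dt_out = 1, rtol = 1e-8, atol = 1e-10,
                                 method = "lsoda") {
  stopifnot(duration > 0, dt_out > 0)
  q <- .flat_params(p)
  y0 <- as.numeric(x0)
  times <- seq(0, duration, by = dt_out)
  sol <- deSolve::ode(
    y = y0, times = times, parms = unname(q),
    func = "mf_derivs", jacfunc = "mf_jac", initfunc = "mf_initmod",
    dllname = "pingmf",
    jactype = "fullusr", method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("mean-field integration failed at t = %.3f ms",
                 sol[nrow(sol), 1L]))
  out <- as.data.frame(sol)
  names(out) <- c("t", .state_names)
  # The |u - Vhat| and sgn(Vhat - u) terms make the RHS nonsmooth at a
  # reversal crossing only when the matching heterogeneity half-width is
  # nonzero. The sign machinery of the reduction handles crossings exactly
  # (they are part of the model); they are logged in the
  # "reversal_crossings" attribute so integration accuracy near the kinks
  # can be audited.
  cp <- p$coupling
  crossings <- c(
    e_ex = if (cp$gamma_e_ampa > 0 || cp$gamma_e_nmda > 0)
      sum(out$u_e >= p$Vhat_ex) else 0L,
    e_in = if (cp$gamma_e_gaba > 0) sum(out$u_e <= p$Vhat_in) else 0L,
    i_ex = if (cp$gamma_i_ampa > 0 || cp$gamma_i_nmda > 0)
      sum(out$u_i >= p$Vhat_ex) else 0L,
    i_in = if (cp$gamma_i_gaba > 0) sum(out$u_i <= p$Vhat_in) else 0L)
  if (min(out$r_e, out$r_i) < -1e-9)
    warning("firing rate fell below -1e-9 (integration tolerance exceeded)")
  structure(out, class = c("mf_trajectory", "data.frame"), params = p,
            dt_out = dt_out, reversal_crossings = crossings)
}

#' Write a mean-field trajectory to CSV
#'
#' Writes columns \code{(t, r_e, u_e, s_e, r_i, u_i, s_i, s_n,
#' r_e_hz, r_i_hz)}, rates both in model units (1/ms) and Hz.
#'
#' @param traj An \code{mf_trajectory}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$r_e_hz <- df$r_e * 1000
  df$r_i_hz <- df$r_i * 1000
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
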