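#' Biophysical parameters of the QIF membrane equation
#'
#' Bundles the dimensional constants of the quadratic integrate-and-fire
#' membrane model
#' \deqn{C \frac{dV}{dt} = g_l \frac{(V - V_l)(V - V_T)}{V_T - V_l} + I_{appl} - I_{syn},}
#' with spike cutoff \code{Vspike} and reset \code{VR} (\code{Inf}/\code{-Inf}
#' in the theoretical limit, where the QIF neuron is equivalent to the theta
#' neuron).
#'
#' @param C Membrane capacitance (uF/cm^2).
#' @param gl Leak conductance (mS/cm^2).
#' @param Vl Leak reversal potential (mV).
#' @param VT Threshold potential (mV); must exceed \code{Vl}.
#' @param Vex Excitatory (AMPA/NMDA) reversal potential (mV).
#' @param Vin Inhibitory (GABA) reversal potential (mV).
#' @param Vspike Spike cutoff (mV); \code{Inf} for the theta-neuron limit.
#' @param VR Reset potential (mV); \code{-Inf} for the theta-neuron limit.
#'
#' @return An object of class \code{"biophys_params"}.
#' @examples
#' bp <- biophys_params()
#' bp$VT - bp$Vl
#' @export
biophys_params <- function(C = 1, gl = 0.1, Vl = -65, VT = -50,
                           Vex = 0, Vin = -70, Vspike = Inf, VR = -Inf) {
  stopifnot(is.numeric(C), is.numeric(gl), C > 0, gl > 0)
  if (VT == Vl) stop("invalid biophysics: VT == Vl (nondimensionalization divides by VT - Vl)")
  if (!(Vl < VT)) stop("invalid biophysics: require Vl < VT")
  if (!(Vin <= Vl)) stop("invalid biophysics: require Vin <= Vl")
  if (!(VT < Vex)) stop("invalid biophysics: require VT < Vex")
  structure(list(C = C, gl = gl, Vl = Vl, VT = VT, Vex = Vex, Vin = Vin,
                 Vspike = Vspike, VR = VR),
            class = "biophys_params")
}

#' Synaptic gating kinetics
#'
#' Decay time constants of the exponential AMPA/GABA gates, the NMDA decay
#' time and the NMDA activation rate of the logistic gate
#' \eqn{ds_n/dt = a_n s_e (1 - s_n) - s_n/\tau_n}.
#'
#' @param tau_e AMPA decay time constant (ms).
#' @param tau_n NMDA decay time constant (ms); must exceed \code{tau_e}
#'   (NMDA kinetics are markedly slower than AMPA).
#' @param tau_i GABA decay time constant (ms).
#' @param a_n NMDA activation rate (1/ms).
#'
#' @return An object of class \code{"synapse_kinetics"}.
#' @export
synapse_kinetics <- function(tau_e = 2, tau_n = 100, tau_i = 8, a_n = 0.5) {
  vals <- c(tau_e = tau_e, tau_n = tau_n, tau_i = tau_i, a_n = a_n)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("synapse kinetics must all be positive and finite")
  if (!(tau_n > tau_e))
    stop("invalid kinetics: tau_n must exceed tau_e (NMDA slower than AMPA)")
  structure(as.list(vals), class = "synapse_kinetics")
}

.coupling_fields <- c("gbar_e_ampa", "gbar_e_nmda", "gbar_e_gaba",
                      "gbar_i_ampa", "gbar_i_nmda", "gbar_i_gaba",
                      "gamma_e_ampa", "gamma_e_nmda", "gamma_e_gaba",
                      "gamma_i_ampa", "gamma_i_nmda", "gamma_i_gaba")

#' Synaptic coupling parameters (Lorentzian modes and half-widths)
#'
#' Per postsynaptic population (\code{e} = excitatory RSEs, \code{i} =
#' fast-spiking interneurons) and per receptor class, the mode \code{gbar_*}
#' and half-width \code{gamma_*} of the Lorentzian distribution of synaptic
#' conductances, in units of the leak conductance. The three pathways
#' manipulated in the gamma-deficit analyses carry field aliases:
#' E-to-I AMPA strength is \code{gbar_i_ampa}, E-to-I NMDA strength is
#' \code{gbar_i_nmda}, and I-to-E GABA strength is \code{gbar_e_gaba}
#' (with matching \code{gamma_*} half-widths).
#'
#' @param gbar_e_ampa,gbar_e_nmda,gbar_e_gaba Modes onto RSEs (g/gl).
#' @param gbar_i_ampa,gbar_i_nmda,gbar_i_gaba Modes onto FSIs (g/gl).
#' @param gamma_e_ampa,gamma_e_nmda,gamma_e_gaba Half-widths onto RSEs.
#' @param gamma_i_ampa,gamma_i_nmda,gamma_i_gaba Half-widths onto FSIs.
#'
#' @return An object of class \code{"coupling_params"}.
#' @export
coupling_params <- function(gbar_e_ampa = 0, gbar_e_nmda = 0, gbar_e_gaba = 0,
                            gbar_i_ampa = 0, gbar_i_nmda = 0, gbar_i_gaba = 0,
                            gamma_e_ampa = 0, gamma_e_nmda = 0, gamma_e_gaba = 0,
                            gamma_i_ampa = 0, gamma_i_nmda = 0, gamma_i_gaba = 0) {
  vals <- c(gbar_e_ampa = gbar_e_ampa, gbar_e_nmda = gbar_e_nmda,
            gbar_e_gaba = gbar_e_gaba, gbar_i_ampa = gbar_i_ampa,
            gbar_i_nmda = gbar_i_nmda, gbar_i_gaba = gbar_i_gaba,
            gamma_e_ampa = gamma_e_ampa, gamma_e_nmda = gamma_e_nmda,
            gamma_e_gaba = gamma_e_gaba, gamma_i_ampa = gamma_i_ampa,
            gamma_i_nmda = gamma_i_nmda, gamma_i_gaba = gamma_i_gaba)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("coupling modes and half-widths must be finite and >= 0")
  structure(as.list(vals), class = "coupling_params")
}

#' Tonic drive parameters
#'
#' Lorentzian mode and half-width of the applied current per population,
#' nondimensionalized as \eqn{\hat I = 2 I / (g_l (V_T - V_l))}. In the
#' reference circuit the tonic drive targets the excitatory population only,
#' so \code{Ibar_i = Delta_i = 0}.
#'
#' @param Ibar_e,Delta_e Mode and half-width of the drive to RSEs.
#' @param Ibar_i,Delta_i Mode and half-width of the drive to FSIs.
#'
#' @return An object of class \code{"drive_params"}.
#' @export
drive_params <- function(Ibar_e = 2, Delta_e = 0.02, Ibar_i = 0, Delta_i = 0) {
  if (Delta_e < 0 || Delta_i < 0) stop("drive half-widths must be >= 0")
  structure(list(Ibar_e = Ibar_e, Delta_e = Delta_e,
                 Ibar_i = Ibar_i, Delta_i = Delta_i),
            class = "drive_params")
}

#' Nondimensionalize the QIF biophysics
#'
#' Applies the affine change of variables
#' \eqn{V = (V_T + V_l)/2 + u (V_T - V_l)/2}, which maps rest and threshold
#' to \eqn{u = \mp 1}, yielding the reduced constants
#' \deqn{\hat V_{ex} = \frac{2 (V_{ex} - (V_T + V_l)/2)}{V_T - V_l}, \quad
#'       \hat I = \frac{2 I_{appl}}{g_l (V_T - V_l)}, \quad
#'       \tau = C / g_l, \quad \hat g_x = g_x / g_l.}
#'
#' @param bp A \code{\link{biophys_params}} object.
#' @param I_appl Applied current (same units as \code{gl * mV}).
#' @param kinetics,coupling,drive Optional kinetics/coupling/drive blocks to
#'   attach; coupling conductances and \code{drive} values are taken as
#'   already expressed in units of \code{gl}.
#'
#' @return An object of class \code{"mf_params"} with fields \code{tau},
#'   \code{Vhat_ex}, \code{Vhat_in}, \code{Ihat}, plus the attached blocks
#'   and the originating biophysics.
#' @seealso \code{\link{dimensionalize}} for the exact inverse.
#' @export
nondimensionalize <- function(bp, I_appl = 0,
                              kinetics = synapse_kinetics(),
                              coupling = coupling_params(),
                              drive = drive_params()) {
  stopifnot(inherits(bp, "biophys_params"))
  dV <- bp$VT - bp$Vl
  if (dV == 0) stop("cannot nondimensionalize: VT equals Vl")
  mid <- (bp$VT + bp$Vl) / 2
  mf_params(
    tau = bp$C / bp$gl,
    Vhat_ex = 2 * (bp$Vex - mid) / dV,
    Vhat_in = 2 * (bp$Vin - mid) / dV,
    Ihat = 2 * I_appl / (bp$gl * dV),
    kinetics = kinetics, coupling = coupling, drive = drive,
    biophysics = bp)
}

#' Recover dimensional biophysics from reduced parameters
#'
#' Exact algebraic inverse of \code{\link{nondimensionalize}} given the
#' scale anchors \code{gl}, \code{Vl} and \code{VT} (the reduction quotients
#' them out, so they must be supplied; they default to the values stored in
#' the \code{mf_params} object).
#'
#' @param p An \code{\link{mf_params}} object.
#' @param gl,Vl,VT Scale anchors of the reduction.
#' @return A list with \code{biophysics} (\code{biophys_params}) and
#'   \code{I_appl}.
#' @export
dimensionalize <- function(p, gl = p$biophysics$gl, Vl = p$biophysics$Vl,
                           VT = p$biophysics$VT) {
  stopifnot(inherits(p, "mf_params"))
  dV <- VT - Vl
  mid <- (VT + Vl) / 2
  bp <- biophys_params(
    C = p$tau * gl, gl = gl, Vl = Vl, VT = VT,
    Vex = mid + p$Vhat_ex * dV / 2,
    Vin = mid + p$Vhat_in * dV / 2)
  list(biophysics = bp, I_appl = p$Ihat * gl * dV / 2)
}

#' Reduced (nondimensional) mean-field parameter set
#'
#' The complete parameter set consumed by both the spiking network and the
#' mean-field reduction: membrane time constant \code{tau} (ms),
#' nondimensional reversals, drive, synaptic kinetics and Lorentzian
#' coupling statistics.
#'
#' @param tau Membrane time constant C/gl (ms).
#' @param Vhat_ex,Vhat_in Nondimensional excitatory/inhibitory reversals.
#' @param Ihat Nondimensional tonic drive to RSEs (alias for
#'   \code{drive$Ibar_e}; if both are given they must agree).
#' @param kinetics A \code{\link{synapse_kinetics}} object.
#' @param coupling A \code{\link{coupling_params}} object.
#' @param drive A \code{\link{drive_params}} object.
#' @param biophysics Optional originating \code{\link{biophys_params}}.
#'
#' @return An object of class \code{"mf_params"}.
#' @export
mf_params <- function(tau = 10, Vhat_ex = 23/3, Vhat_in = -5/3, Ihat = NULL,
                      kinetics = synapse_kinetics(),
                      coupling = coupling_params(),
                      drive = drive_params(),
                      biophysics = biophys_params()) {
  stopifnot(inherits(kinetics, "synapse_kinetics"),
            inherits(coupling, "coupling_params"),
            inherits(drive, "drive_params"))
  if (tau <= 0) stop("tau must be positive")
  if (!(Vhat_in < -1 && 1 < Vhat_ex))
    stop("reduced reversals must satisfy Vhat_in < -1 < +1 < Vhat_ex")
  if (!is.null(Ihat)) drive$Ibar_e <- Ihat
  structure(list(tau = tau, Vhat_ex = Vhat_ex, Vhat_in = Vhat_in,
                 Ihat = drive$Ibar_e,
                 kinetics = kinetics, coupling = coupling, drive = drive,
                 biophysics = biophysics),
            class = "mf_params")
}

#' @export
print.mf_params <- function(x, ...) {
  cat("Reduced PING parameters\n")
  cat(sprintf("  tau = %.4g ms, Vhat_ex = %.4g, Vhat_in = %.4g\n",
              x$tau, x$Vhat_ex, x$Vhat_in))
  cat(sprintf("  drive: Ibar_e = %.4g (Delta_e = %.4g), Ibar_i = %.4g (Delta_i = %.4g)\n",
              x$drive$Ibar_e, x$drive$Delta_e, x$drive$Ibar_i, x$drive$Delta_i))
  k <- x$kinetics
  cat(sprintf("  kinetics: tau_e = %.4g, tau_i = %.4g, tau_n = %.4g ms, a_n = %.4g /ms\n",
              k$tau_e, k$tau_i, k$tau_n, k$a_n))
  cp <- x$coupling
  cat(sprintf("  pathways: E->I ampa %.4g (gamma %.4g), E->I nmda %.4g (gamma %.4g), I->E gaba %.4g (gamma %.4g)\n",
              cp$gbar_i_ampa, cp$gamma_i_ampa, cp$gbar_i_nmda,
              cp$gamma_i_nmda, cp$gbar_e_gaba, cp$gamma_e_gaba))
  invisible(x)
}

#' Modify one named parameter of an mf_params object
#'
#' Resolves a flat parameter name (e.g. \code{"gbar_i_ampa"},
#' \code{"Ibar_e"}, \code{"tau_i"}, \code{"tau"}) against the nested blocks
#' of an \code{mf_params} object and sets it.
#'
#' @param p An \code{mf_params} object.
#' @param name Flat field name.
#' @param value New numeric value.
#' @return The modified \code{mf_params} object.
#' @export
set_param <- function(p, name, value) {
  stopifnot(inherits(p, "mf_params"), is.numeric(value), length(value) == 1)
  value <- unname(value)
  if (name == "Ihat") name <- "Ibar_e"
  for (block in c("coupling", "drive", "kinetics")) {
    if (name %in% names(p[[block]])) {
      p[[block]][[name]] <- value
      if (name == "Ibar_e") p$Ihat <- value   # Ihat aliases drive$Ibar_e
      return(p)
    }
  }
  if (name %in% c("tau", "Vhat_ex", "Vhat_in")) {
    p[[name]] <- value
    return(p)
  }
  stop(sprintf("unknown parameter '%s'", name))
}

#' Read one named parameter of an mf_params object
#' @param p An \code{mf_params} object.
#' @param name Flat field name as in \code{\link{set_param}}.
#' @return Numeric value.
#' @export
get_param <- function(p, name) {
  if (name == "Ihat") name <- "Ibar_e"
  for (block in c("coupling", "drive", "kinetics"))
    if (name %in% names(p[[block]])) return(p[[block]][[name]])
  if (name %in% c("tau", "Vhat_ex", "Vhat_in")) return(p[[name]])
  stop(sprintf("unknown parameter '%s'", name))
}

#' Seeded Lorentzian (Cauchy) sampling for quenched heterogeneity
#'
#' Draws \code{n} values \code{mode + half_width * tan(pi * (U - 1/2))} with
#' seeded uniform \code{U}; the heavy-tailed Lorentzian is the distribution
#' under which the population integrals of the mean-field reduction close
#' exactly by residue calculus. Draws may be negative (the theory integrates
#' over the whole real line); \code{truncate_at_zero = TRUE} clips draws at
#' zero, which breaks the exact correspondence with the reduction and is
#' off by default.
#'
#' @param mode Location (mode/median) of the distribution.
#' @param half_width Half-width at half-maximum (scale); must be >= 0.
#' @param n Number of draws.
#' @param seed Optional integer seed; identical seeds give identical draws.
#'   The caller's RNG state is left untouched.
#' @param truncate_at_zero Clip negative draws to zero (theory-breaking).
#' @return Numeric vector of length \code{n}.
#' @examples
#' sample_lorentzian(2, 0.5, 5, seed = 1)
#' @export
sample_lorentzian <- function(mode, half_width, n, seed = NULL,
                              truncate_at_zero = FALSE) {
  if (half_width < 0) stop("half_width must be >= 0")
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  x <- mode + half_width * tan(pi * (stats::runif(n) - 0.5))
  if (truncate_at_zero) x <- pmax(x, 0)
  x
}

# Flatten an mf_params object to the named vector used by the RHS/Jacobian
# kernels. Single source of truth for the internal naming.
.flat_params <- function(p) {
  cp <- p$coupling; k <- p$kinetics; d <- p$drive
  c(tau = p$tau, Vex = p$Vhat_ex, Vin = p$Vhat_in,
    Ie = d$Ibar_e, Ii = d$Ibar_i, De = d$Delta_e, Di = d$Delta_i,
    gee = cp$gbar_e_ampa, gen = cp$gbar_e_nmda, gei = cp$gbar_e_gaba,
    gie = cp$gbar_i_ampa, gin = cp$gbar_i_nmda, gii = cp$gbar_i_gaba,
    cee = cp$gamma_e_ampa, cen = cp$gamma_e_nmda, cei = cp$gamma_e_gaba,
    cie = cp$gamma_i_ampa, cin = cp$gamma_i_nmda, cii = cp$gamma_i_gaba,
    taue = k$tau_e, taui = k$tau_i, taun = k$tau_n, an = k$a_n)
}
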