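#' Healthy-state parameter values of the three manipulated pathways
#'
#' The gamma-power-optimal parameter set representing the healthy cortical
#' state: E-to-I AMPA and NMDA strengths at their 1:10 NMDA:AMPA ratio,
#' I-to-E GABA strength, and the two E-to-I heterogeneity half-widths at
#' the low end of their linear range.
#'
#' @return Named numeric vector over the five scaled parameters.
#' @export
healthy_state <- function() {
  c(gbar_i_ampa = 1.3, gbar_i_nmda = 0.13, gbar_e_gaba = 0.6,
    gamma_i_ampa = 0.01, gamma_i_nmda = 0.01)
}

#' Apply a uniform percent difference to derive a disease state
#'
#' Strength parameters (conductance modes) are reduced by \code{pct}
#' percent; variability parameters (half-widths) are increased by the same
#' percent, matching the directionality of the postmortem findings (lower
#' synaptic strength, greater cell-to-cell variability).
#'
#' @param healthy Named vector as returned by \code{\link{healthy_state}}.
#' @param pct Percent difference in [0, 100].
#' @return Named vector of disease-state values.
#' @examples
#' apply_percent_difference(healthy_state(), 20)
#' @export
apply_percent_difference <- function(healthy = healthy_state(), pct = 20) {
  stopifnot(pct >= 0, pct <= 100)
  out <- healthy
  strengths <- grepl("^gbar_", names(out))
  out[strengths] <- out[strengths] * (1 - pct / 100)
  out[!strengths] <- out[!strengths] * (1 + pct / 100)
  out
}

#' Linear healthy-to-disease interpolation
#'
#' The scaling \eqn{x(\lambda) = x_h + \lambda (x_{sz} - x_h)}, so that
#' \eqn{\lambda = 0} is the healthy value and \eqn{\lambda = 1} the disease
#' value exactly.
#'
#' @param x_h Healthy value(s).
#' @param x_sz Disease value(s).
#' @param lam Interpolation factor in [0, 1] (values outside extrapolate).
#' @return Interpolated value(s).
#' @export
lambda_scale <- function(x_h, x_sz, lam) x_h + lam * (x_sz - x_h)

# The three single-alteration conditions and the combined condition: which
# of the five scaled parameters each moves.
.condition_fields <- list(
  ei_strength = c("gbar_i_ampa", "gbar_i_nmda"),
  ei_variability = c("gamma_i_ampa", "gamma_i_nmda"),
  ie_strength = "gbar_e_gaba",
  combined = c("gbar_i_ampa", "gbar_i_nmda", "gbar_e_gaba",
               "gamma_i_ampa", "gamma_i_nmda"))

#' Apply a disease condition to a parameter set
#'
#' Moves the parameters of one alteration condition from their healthy
#' values toward the \code{pct}-difference disease values by \code{lam}
#' (both endpoints exact), leaving all other parameters untouched. The
#' E-to-I strength condition moves the AMPA and NMDA modes together
#' (preserving their 1:10 ratio) and the variability condition moves both
#' E-to-I half-widths together; the I-to-E half-width stays at its healthy
#' value in every condition.
#'
#' @param p An \code{\link{mf_params}} object at the healthy state.
#' @param condition One of \code{"ei_strength"}, \code{"ei_variability"},
#'   \code{"ie_strength"}, \code{"combined"}.
#' @param pct Percent difference defining the disease state.
#' @param lam Interpolation factor (default 1: full disease value).
#' @param healthy Healthy values (defaults to \code{\link{healthy_state}}).
#' @return Modified \code{mf_params}.
#' @export
apply_condition <- function(p, condition = names(.condition_fields),
                            pct = 20, lam = 1, healthy = healthy_state()) {
  condition <- match.arg(condition)
  sz <- apply_percent_difference(healthy, pct)
  for (f in .condition_fields[[condition]])
    p <- set_param(p, f, lambda_scale(healthy[[f]], sz[[f]], lam))
  p
}

#' Grid search for the gamma-power-optimal healthy state
#'
#' Evaluates gamma power over a grid of E-to-I AMPA strength (with the NMDA
#' mode tied at \code{ratio} times the AMPA mode) by I-to-E GABA strength,
#' with all heterogeneity half-widths of the manipulated pathways fixed at
#' 0.01, and returns the argmax together with the full power surface. Ties
#' are broken toward smaller parameter values (row-major first maximum on
#' the ascending grids).
#'
#' @param p An \code{\link{mf_params}} object providing all other
#'   parameters.
#' @param gie_grid Grid for \code{gbar_i_ampa} (ascending).
#' @param gei_grid Grid for \code{gbar_e_gaba} (ascending).
#' @param ratio NMDA:AMPA tie (default 0.1).
#' @param duration Integration time per grid point (ms).
#' @return List with \code{optimum} (named vector: gbar_i_ampa,
#'   gbar_i_nmda, gbar_e_gaba, power), \code{surface} (matrix power
#'   [gie x gei]), and the grids.
#' @export
healthy_state_search <- function(p,
                                 gie_grid = seq(0, 5, by = 0.05),
                                 gei_grid = seq(0, 1.5, by = 0.02),
                                 ratio = 0.1, duration = 4500) {
  stopifnot(!is.unsorted(gie_grid), !is.unsorted(gei_grid))
  for (f in c("gamma_i_ampa", "gamma_i_nmda", "gamma_e_gaba"))
    p <- set_param(p, f, 0.01)
  surf <- matrix(NA_real_, length(gie_grid), length(gei_grid))
  for (i in seq_along(gie_grid)) {
    pi_ <- set_param(p, "gbar_i_ampa", gie_grid[i])
    pi_ <- set_param(pi_, "gbar_i_nmda", ratio * gie_grid[i])
    for (j in seq_along(gei_grid)) {
      pij <- set_param(pi_, "gbar_e_gaba", gei_grid[j])
      # integration failure at an extreme corner counts as no oscillation
      surf[i, j] <- tryCatch(
        suppressWarnings(mf_gamma_power(pij, duration = duration)$gamma_power),
        error = function(e) 0)
    }
  }
  if (all(surf == 0)) warning("no oscillation anywhere on the grid")
  k <- which.max(surf)  # first (smallest-index) maximum: documented tie-break
  i <- (k - 1) %% length(gie_grid) + 1
  j <- (k - 1) %/% length(gie_grid) + 1
  list(optimum = c(gbar_i_ampa = gie_grid[i],
                   gbar_i_nmda = ratio * gie_grid[i],
                   gbar_e_gaba = gei_grid[j], power = surf[i, j]),
       surface = surf, gie_grid = gie_grid, gei_grid = gei_grid)
}

#' Synergy analysis of combined synaptic alterations
#'
#' For each percent difference, computes gamma power in the four disease
#' conditions (E-to-I strength alone, E-to-I variability alone, I-to-E
#' strength alone, and all combined) with identical integrator and spectral
#' settings, expresses each as a percent deficit relative to the healthy
#' baseline, and compares the combined deficit with the additive prediction
#' (the sum of the three individual deficits). A fold ratio above 1 marks a
#' super-additive (synergistic) interaction; it is undefined (NA) when the
#' additive prediction is not positive. Conditions whose oscillation dies
#' are reported as 100\% deficit.
#'
#' @param p An \code{\link{mf_params}} object at the healthy state.
#' @param pct_grid Percent differences to evaluate.
#' @param duration Integration time per condition (ms).
#' @param healthy Healthy values of the five scaled parameters.
#' @return Data frame of class \code{"synergy_result"} with columns
#'   \code{pct, power_baseline, deficit_ei, deficit_var, deficit_ie,
#'   additive, combined, fold_ratio}.
#' @export
synergy_analysis <- function(p, pct_grid = seq(0, 40, by = 2.5),
                             duration = 4500, healthy = healthy_state()) {
  for (f in names(healthy)) p <- set_param(p, f, healthy[[f]])
  P_h <- mf_gamma_power(p, duration = duration)$gamma_power
  if (P_h <= 0) stop("baseline (healthy) gamma power is zero")
  pow <- function(pp) mf_gamma_power(pp, duration = duration)$gamma_power
  deficit <- function(P_c) 100 * (P_h - P_c) / P_h
  rows <- lapply(pct_grid, function(pct) {
    d <- vapply(c("ei_strength", "ei_variability", "ie_strength", "combined"),
                function(cond)
                  deficit(pow(apply_condition(p, cond, pct = pct,
                                              healthy = healthy))),
                numeric(1))
    additive <- sum(d[1:3])
    data.frame(pct = pct, power_baseline = P_h,
               deficit_ei = d[[1]], deficit_var = d[[2]],
               deficit_ie = d[[3]], additive = additive,
               combined = d[[4]],
               fold_ratio = if (additive > 0) d[[4]] / additive else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("synergy_result", "data.frame"))
}
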