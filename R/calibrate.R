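#' Evaluate a one-dimensional landmark of the gamma surface
#'
#' Computes one quotable feature of the model's one-parameter structure:
#' either the parameter value of a Hopf bifurcation found by
#' equilibrium continuation and eigenvalue bisection (\code{type = "hopf"}),
#' or the location of the gamma-power maximum along a parameter sweep
#' (\code{type = "argmax"}, coarse grid followed by local refinement).
#'
#' @param p An \code{\link{mf_params}} object defining all other
#'   parameters.
#' @param param Parameter to sweep.
#' @param from,to Sweep range.
#' @param type \code{"hopf"} or \code{"argmax"}.
#' @param n_grid Continuation/sweep resolution.
#' @param which For \code{"hopf"}: which crossing to report if several
#'   (\code{"first"} in sweep order, default).
#' @param duration Integration time per point for \code{"argmax"}.
#' @param refine_steps Local grid-refinement rounds for \code{"argmax"}.
#' @return The landmark value (numeric, NA if not found).
#' @export
compute_landmark <- function(p, param, from, to,
                             type = c("hopf", "argmax"),
                             n_grid = if (type == "hopf") 120 else 25,
                             which = "first", duration = 4500,
                             refine_steps = 2) {
  type <- match.arg(type)
  if (type == "hopf") {
    pts <- tryCatch(
      hopf_scan_1d(p, param,
                   lo = min(from, to), hi = max(from, to), n_grid = n_grid),
      error = function(e) list())
    if (!length(pts)) return(NA_real_)
    vals <- vapply(pts, function(h) h$value, numeric(1))
    if (from > to) vals <- sort(vals, decreasing = TRUE) else vals <- sort(vals)
    return(vals[1])
  }
  # argmax of gamma power, coarse-to-fine
  lo <- min(from, to); hi <- max(from, to)
  for (r in seq_len(refine_steps + 1)) {
    grid <- seq(lo, hi, length.out = n_grid)
    pw <- vapply(grid, function(v)
      mf_gamma_power(set_param(p, param, v), duration = duration)$gamma_power,
      numeric(1))
    k <- which.max(pw)
    if (all(pw == 0)) return(NA_real_)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
    n_grid <- 11
  }
  (lo + hi) / 2
}

#' Calibrate free baseline constants against printed landmarks
#'
#' The model's Results-level numbers are conditional on baseline constants
#' (drive, synaptic kinetics, heterogeneity of the drive, recurrent
#' couplings) that are not themselves quotable; this routine fits a chosen
#' subset of them by least squares on the log scale so that the
#' one-dimensional landmarks of the gamma surface (Hopf locations and/or
#' power-maximum locations) match their target values. Residuals are
#' reported for every target. Nelder-Mead is used on log-transformed
#' positive constants; landmarks that disappear during a step incur a fixed
#' penalty, which keeps the search inside the oscillatory regime.
#'
#' @param p Starting \code{\link{mf_params}} object.
#' @param targets List of target specs, each a list with fields
#'   \code{param}, \code{from}, \code{to}, \code{type} ("hopf"/"argmax"),
#'   \code{value} (the target), and optional \code{weight}.
#' @param free Character vector of free constant names (flat names, e.g.
#'   \code{c("Ibar_e", "tau_i")}); empty set returns \code{p} unchanged
#'   with a residual report.
#' @param lower,upper Named bounds for the free constants (defaults: a
#'   factor of 5 around the starting values).
#' @param maxit Nelder-Mead iteration budget.
#' @param n_grid,duration Passed to \code{\link{compute_landmark}}.
#' @return List with \code{params} (calibrated \code{mf_params}),
#'   \code{residuals} (data frame: target, fitted, value, rel_error),
#'   \code{converged}, \code{objective}.
#' @export
calibrate_reference <- function(p, targets, free = character(),
                                lower = NULL, upper = NULL, maxit = 400,
                                n_grid = 120, duration = 4500) {
  stopifnot(length(targets) >= 1)
  eval_landmarks <- function(pp) vapply(targets, function(tg)
    compute_landmark(pp, tg$param, tg$from, tg$to, type = tg$type,
                     n_grid = n_grid, duration = duration), numeric(1))
  resid_table <- function(pp) {
    fit <- eval_landmarks(pp)
    data.frame(
      param = vapply(targets, `[[`, "", "param"),
      type = vapply(targets, `[[`, "", "type"),
      target = vapply(targets, `[[`, 0, "value"),
      fitted = fit,
      rel_error = (fit - vapply(targets, `[[`, 0, "value")) /
        vapply(targets, `[[`, 0, "value"))
  }
  if (!length(free)) {
    rt <- resid_table(p)
    return(list(params = p, residuals = rt, converged = TRUE,
                objective = sum(rt$rel_error^2, na.rm = TRUE)))
  }
  x0 <- vapply(free, function(f) get_param(p, f), numeric(1))
  if (any(x0 <= 0))
    stop("calibration free constants must be positive (fitted on log scale)")
  lb <- log(if (is.null(lower)) x0 / 5 else lower[free])
  ub <- log(if (is.null(upper)) x0 * 5 else upper[free])
  w <- vapply(targets, function(tg) tg$weight %||% 1, numeric(1))
  tv <- vapply(targets, `[[`, 0, "value")
  objfun <- function(theta) {
    if (any(theta < lb) || any(theta > ub))
      return(1e3 + sum(pmax(theta - ub, 0)^2 + pmax(lb - theta, 0)^2))
    pp <- p
    for (i in seq_along(free)) pp <- set_param(pp, free[i], exp(theta[i]))
    fit <- suppressWarnings(eval_landmarks(pp))
    sum(ifelse(is.na(fit), 4, w * log(fit / tv)^2))
  }
  opt <- if (length(free) == 1)
    stats::optim(unname(log(x0)), objfun, method = "Brent",
                 lower = lb, upper = ub, control = list(maxit = maxit))
  else
    stats::optim(log(x0), objfun, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
  for (i in seq_along(free)) p <- set_param(p, free[i], exp(opt$par[i]))
  list(params = p, residuals = resid_table(p),
       converged = opt$convergence == 0, objective = opt$value)
}
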