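#' Analytic Jacobian of the mean-field system
#'
#' Piecewise-analytic 7x7 derivative of \code{\link{mean_field_rhs}} with
#' respect to the state. The absolute-value and sign terms of the rate and
#' potential equations are differentiable away from the switching manifolds
#' \eqn{u = \hat V_{ex}} and \eqn{u = \hat V_{in}}; evaluation within
#' \code{manifold_tol} of a manifold is reported.
#'
#' @param p An \code{\link{mf_params}} object.
#' @param x State vector (canonical order).
#' @param manifold_tol Proximity tolerance for the switching manifolds.
#' @return 7x7 matrix with row/column names in canonical state order.
#' @export
mf_jacobian <- function(p, x, manifold_tol = 1e-8) {
  stopifnot(length(x) == 7L)
  x <- as.numeric(x)
  d <- min(abs(x[c(2L, 5L)] - p$Vhat_ex), abs(x[c(2L, 5L)] - p$Vhat_in))
  if (d < manifold_tol)
    warning(sprintf(
      "state within %.2g of a switching manifold (|u - Vhat| = %.2g); Jacobian one-sided",
      manifold_tol, d))
  .mf_jac_core(x, .flat_params(p))
}

# Canonical initial guesses for equilibrium search: an active PING state and
# a near-rest state.
.eq_guesses <- function() list(
  c(0.02, -0.5, 0.04, 0.02, -0.5, 0.16, 0.5),
  c(0.05, -0.2, 0.10, 0.05, -0.2, 0.40, 0.8),
  c(1e-3, -1.0, 1e-3, 1e-3, -1.0, 1e-3, 0.01))

.newton_eq <- function(q, guess, tol = 1e-12, max_iter = 100) {
  x <- as.numeric(guess)
  for (i in seq_len(max_iter)) {
    f <- .mf_rhs_core(x, q)
    if (!all(is.finite(f))) return(NULL)
    if (sqrt(sum(f^2)) < tol) return(x)
    J <- .mf_jac_core(x, q)
    dx <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * dx
      fn <- .mf_rhs_core(xn, q)
      if (all(is.finite(fn)) && sum(fn^2) < sum(f^2)) break
      lam <- lam / 2
      if (lam < 1e-6) { xn <- x - dx; break }
    }
    x <- xn
  }
  if (sqrt(sum(.mf_rhs_core(x, q)^2)) < 1e-10) x else NULL
}

#' Find an equilibrium of the mean-field system
#'
#' Damped Newton iteration with the analytic Jacobian. The returned state
#' satisfies \code{||RHS|| < 1e-10}; if no starting guess converges within
#' the iteration budget, \code{NULL} is returned.
#'
#' @param p An \code{\link{mf_params}} object.
#' @param guess Optional starting state; when omitted, a small set of
#'   canonical guesses (active PING state, near-rest state) is tried.
#' @param tol Convergence tolerance on the RHS norm.
#' @param max_iter Newton iteration budget per guess.
#' @return A \code{\link{mean_field_state}} (with attribute
#'   \code{rhs_norm}), or \code{NULL} on non-convergence.
#' @export
find_equilibrium <- function(p, guess = NULL, tol = 1e-12, max_iter = 100) {
  q <- .flat_params(p)
  guesses <- if (is.null(guess)) .eq_guesses() else list(as.numeric(guess))
  for (g in guesses) {
    x <- .newton_eq(q, g, tol = tol, max_iter = max_iter)
    if (!is.null(x)) {
      st <- mean_field_state(x[1], x[2], x[3], x[4], x[5], x[6], x[7])
      attr(st, "rhs_norm") <- sqrt(sum(.mf_rhs_core(x, q)^2))
      return(st)
    }
  }
  NULL
}

# Leading complex eigenvalue pair of the Jacobian at state x.
.leading_pair <- function(q, x) {
  ev <- eigen(.mf_jac_core(as.numeric(x), q), only.values = TRUE)$values
  cp <- ev[abs(Im(ev)) > 1e-8]
  if (!length(cp)) return(list(mre = -Inf, omega = NA_real_))
  k <- which.max(Re(cp))
  list(mre = Re(cp[k]), omega = abs(Im(cp[k])))
}

# Continue the equilibrium from its value at `from` to each value of `grid`,
# returning equilibria and leading-pair info. Lost branches end the scan.
.continue_scan <- function(p, name, grid, eq0) {
  q0 <- .flat_params(p)
  idx <- which(names(q0) == .flat_name(name))
  res <- vector("list", length(grid))
  g <- as.numeric(eq0)
  for (i in seq_along(grid)) {
    q <- q0; q[idx] <- grid[i]
    eq <- .newton_eq(q, g)
    if (is.null(eq)) break
    g <- eq
    lp <- .leading_pair(q, eq)
    res[[i]] <- list(value = grid[i], eq = eq, mre = lp$mre, omega = lp$omega)
  }
  res[!vapply(res, is.null, logical(1))]
}

# Map a public parameter name to the flat-vector name.
.flat_name <- function(name) {
  map <- c(gbar_e_ampa = "gee", gbar_e_nmda = "gen", gbar_e_gaba = "gei",
           gbar_i_ampa = "gie", gbar_i_nmda = "gin", gbar_i_gaba = "gii",
           gamma_e_ampa = "cee", gamma_e_nmda = "cen", gamma_e_gaba = "cei",
           gamma_i_ampa = "cie", gamma_i_nmda = "cin", gamma_i_gaba = "cii",
           Ibar_e = "Ie", Ibar_i = "Ii", Delta_e = "De", Delta_i = "Di",
           tau_e = "taue", tau_i = "taui", tau_n = "taun", a_n = "an",
           tau = "tau", Vhat_ex = "Vex", Vhat_in = "Vin")
  if (!name %in% names(map)) stop(sprintf("unknown parameter '%s'", name))
  unname(map[name])
}

# Bisect a bracketed eigenvalue crossing; refines the parameter interval to
# `tol` and then polishes until the certificate |Re lambda| < cert_tol holds.
.hopf_bisect <- function(p, name, lo, hi, eq_lo, tol = 1e-5,
                         cert_tol = 1e-6, max_iter = 80) {
  q0 <- .flat_params(p)
  idx <- which(names(q0) == .flat_name(name))
  f <- function(v, g) {
    q <- q0; q[idx] <- v
    eq <- .newton_eq(q, g)
    if (is.null(eq)) return(NULL)
    c(list(eq = eq), .leading_pair(q, eq))
  }
  a <- f(lo, eq_lo); b <- f(hi, eq_lo)
  if (is.null(a) || is.null(b) || sign(a$mre) == sign(b$mre)) return(NULL)
  mid <- NULL
  for (i in seq_len(max_iter)) {
    v <- (lo + hi) / 2
    mid <- f(v, a$eq)
    if (is.null(mid)) return(NULL)
    if (hi - lo < tol && abs(mid$mre) < cert_tol) break
    if (sign(mid$mre) == sign(a$mre)) { lo <- v; a <- mid } else { hi <- v; b <- mid }
  }
  slope <- (b$mre - a$mre) / (hi - lo + .Machine$double.eps)
  list(value = (lo + hi) / 2, eq = mid$eq, mre = mid$mre, omega = mid$omega,
       direction = if (slope > 0) "onset" else "offset")
}

.as_hopf_point <- function(h, name) {
  structure(list(
    parameter = name,
    value = h$value,
    state = mean_field_state(h$eq[1], h$eq[2], h$eq[3], h$eq[4], h$eq[5],
                             h$eq[6], h$eq[7]),
    eigenvalue = complex(real = h$mre, imaginary = h$omega),
    frequency_hz = h$omega / (2 * pi) * 1000,
    direction = h$direction),
    class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat(sprintf("Hopf point (%s): %s = %.6g, Re(lambda) = %.2e, f = %.2f Hz\n",
              x$direction, x$parameter, x$value, Re(x$eigenvalue),
              x$frequency_hz))
  invisible(x)
}

#' One-parameter Hopf scan
#'
#' Continues the equilibrium of the mean-field system across a parameter
#' grid (each converged solution seeds the next), brackets every sign
#' change of the leading complex eigenvalue pair's real part, and refines
#' each by bisection until the parameter interval is below \code{tol} and
#' the eigenvalue certificate \code{|Re lambda| < cert_tol} holds. Both
#' onset and offset points of an inverted-U are reported, in grid order.
#'
#' @param p An \code{\link{mf_params}} object (defines all non-swept
#'   parameters).
#' @param name Parameter to sweep (flat name, e.g. \code{"gbar_i_ampa"}).
#' @param lo,hi Sweep range.
#' @param n_grid Continuation grid resolution.
#' @param tol Bisection tolerance in parameter units.
#' @param cert_tol Eigenvalue certificate tolerance.
#' @param eq0 Optional starting equilibrium at \code{lo}; found
#'   automatically otherwise (continuing from the equilibrium at the
#'   parameter's current value in \code{p}).
#' @return List of \code{hopf_point} objects (possibly empty).
#' @export
hopf_scan_1d <- function(p, name, lo, hi, n_grid = 200, tol = 1e-5,
                         cert_tol = 1e-6, eq0 = NULL) {
  stopifnot(lo < hi)
  cur <- get_param(p, name)
  if (is.null(eq0)) {
    eqc <- find_equilibrium(p)
    if (is.null(eqc)) stop("no equilibrium at the reference parameters")
    # bridge from the current parameter value to lo
    bridge <- .continue_scan(p, name, seq(cur, lo, length.out = 50), eqc)
    if (!length(bridge) || abs(bridge[[length(bridge)]]$value - lo) > 1e-12)
      stop(sprintf("equilibrium branch lost while continuing %s to %.4g",
                   name, lo))
    eq0 <- bridge[[length(bridge)]]$eq
  }
  grid <- seq(lo, hi, length.out = n_grid)
  scan <- .continue_scan(p, name, grid, eq0)
  if (length(scan) < length(grid))
    warning(sprintf("equilibrium branch lost at %s = %.6g; scan truncated",
                    name, if (length(scan)) scan[[length(scan)]]$value else lo))
  out <- list()
  for (i in seq_len(length(scan) - 1)) {
    a <- scan[[i]]; b <- scan[[i + 1]]
    if (is.finite(a$mre) && is.finite(b$mre) && sign(a$mre) != sign(b$mre)) {
      h <- .hopf_bisect(p, name, a$value, b$value, a$eq, tol = tol,
                        cert_tol = cert_tol)
      if (!is.null(h)) out[[length(out) + 1]] <- .as_hopf_point(h, name)
    }
  }
  out
}

#' Two-parameter Hopf curve
#'
#' For each value of the x parameter, performs a certified one-dimensional
#' Hopf scan in the y parameter and records every crossing as a vertex.
#' x values where no crossing exists are recorded as gaps (absent rows),
#' never interpolated.
#'
#' @param p An \code{\link{mf_params}} object (defines the context: the
#'   fixed third parameter's value).
#' @param x_name,x_grid x parameter and its grid.
#' @param y_name,y_lo,y_hi y parameter and scan range.
#' @param n_grid Continuation resolution of each y scan.
#' @param tol,cert_tol As in \code{\link{hopf_scan_1d}}.
#' @param context Optional label (e.g. \code{"healthy"}, \code{"sz"}).
#' @return An object of class \code{"hopf_curve"}: data frame with columns
#'   \code{x, y, re_lambda, omega, direction} (one row per certified
#'   vertex) plus attributes \code{x_name}, \code{y_name}, \code{context}.
#' @export
hopf_curve_2d <- function(p, x_name, x_grid, y_name, y_lo, y_hi,
                          n_grid = 120, tol = 1e-4, cert_tol = 1e-6,
                          context = NA_character_) {
  rows <- list()
  for (xv in x_grid) {
    px <- set_param(p, x_name, xv)
    pts <- tryCatch(
      hopf_scan_1d(px, y_name, y_lo, y_hi, n_grid = n_grid, tol = tol,
                   cert_tol = cert_tol),
      error = function(e) list())
    for (h in pts)
      rows[[length(rows) + 1]] <- data.frame(
        x = xv, y = h$value, re_lambda = Re(h$eigenvalue),
        omega = Im(h$eigenvalue), direction = h$direction)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(), y = numeric(), re_lambda = numeric(),
               omega = numeric(), direction = character())
  structure(df, class = c("hopf_curve", "data.frame"),
            x_name = x_name, y_name = y_name, context = context)
}

#' Area of the oscillation-supporting region on a parameter grid
#'
#' Counts the cells of an (x, y) grid whose equilibrium is unstable through
#' a complex pair (positive real part) with an emergent frequency inside the
#' analysis band, i.e. lie inside the gamma-supporting Hopf region, and
#' converts the count to an area. Used to compare how the oscillatory
#' region shrinks between parameter contexts. The band filter excludes
#' instabilities outside the rhythm of interest (e.g. the fast
#' interneuron-driven oscillation that appears at strong tonic FSI drive).
#'
#' @param p An \code{\link{mf_params}} object.
#' @param x_name,x_grid,y_name,y_grid Grid specification.
#' @param band Frequency band (Hz) an instability must fall in to count;
#'   \code{NULL} counts every complex instability.
#' @return List with \code{area} (same units as x*y), \code{fraction} of
#'   grid cells oscillatory, and the logical \code{mask} matrix.
#' @export
oscillatory_area <- function(p, x_name, x_grid, y_name, y_grid,
                             band = c(30, 100)) {
  mask <- matrix(FALSE, length(x_grid), length(y_grid))
  for (i in seq_along(x_grid)) {
    px <- set_param(p, x_name, x_grid[i])
    eq <- find_equilibrium(px)
    scan <- if (is.null(eq)) list() else .continue_scan(
      set_param(px, y_name, y_grid[1]), y_name, y_grid,
      .bridge_eq(px, y_name, y_grid[1], eq))
    vals <- vapply(scan, function(s) s$mre, numeric(1))
    freqs <- vapply(scan, function(s) s$omega / (2 * pi) * 1000, numeric(1))
    ok <- vals > 0
    if (!is.null(band)) ok <- ok & freqs >= band[1] & freqs <= band[2]
    n <- length(vals)
    if (n) mask[i, seq_len(n)] <- ok
  }
  dx <- mean(diff(x_grid)); dy <- mean(diff(y_grid))
  list(area = sum(mask) * dx * dy, fraction = mean(mask), mask = mask)
}

# continue an equilibrium from the current value of `name` to target value
.bridge_eq <- function(p, name, target, eq) {
  cur <- get_param(p, name)
  if (abs(cur - target) < 1e-14) return(as.numeric(eq))
  br <- .continue_scan(p, name, seq(cur, target, length.out = 40), eq)
  if (!length(br)) return(as.numeric(eq))
  br[[length(br)]]$eq
}

#' Limit-cycle amplitude of the excitatory rate
#'
#' Integrates past the transient and reports the peak-to-trough span of
#' \code{r_e} over the final analysis window: the time-domain amplitude
#' metric used for bifurcation-diagram ordinates. Values at or below the
#' noise floor indicate the equilibrium side of a Hopf point.
#'
#' @param p An \code{\link{mf_params}} object.
#' @param duration Total integration (ms).
#' @param window Final analysis window (ms).
#' @param x0 Initial state.
#' @param noise_floor Amplitude resolution.
#' @return List with \code{min}, \code{max}, \code{amplitude} (1/ms) and
#'   \code{oscillating} (amplitude above floor).
#' @export
oscillation_amplitude <- function(p, duration = 3000, window = 1000,
                                  x0 = mean_field_state(),
                                  noise_floor = 1e-7) {
  traj <- integrate_mean_field(p, x0 = x0, duration = duration, dt_out = 0.5)
  tail <- traj[traj$t >= duration - window, ]
  amp <- max(tail$r_e) - min(tail$r_e)
  list(min = min(tail$r_e), max = max(tail$r_e), amplitude = amp,
       oscillating = amp > noise_floor)
}
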