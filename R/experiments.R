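# Simple content hash (polynomial rolling hash over the serialized object)
# used for run provenance; stable across sessions for identical
# configurations.
.config_hash <- function(obj) {
  bytes <- as.double(serialize(obj, NULL, version = 2))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

.write_manifest <- function(out_dir, command, config, seed, files) {
  jsonlite::write_json(
    list(command = command,
         config_hash = .config_hash(config),
         seed = seed,
         tool_version = as.character(utils::packageVersion("pingmf")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = files),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Run a named end-to-end experiment
#'
#' Executes one of the package's standard experiments with frozen defaults
#' and writes canonical CSV/JSON outputs plus a run manifest (config hash,
#' seed, tool version, timestamps) to \code{out_dir}:
#' \describe{
#'   \item{fig1_validation}{Spiking network vs mean-field comparison:
#'     rate traces, spectra, peak frequencies.}
#'   \item{fig2_sweeps}{1D gamma-power sweeps and Hopf points for the three
#'     synaptic strength parameters.}
#'   \item{fig3_sweeps}{1D sweeps and Hopf points for the two E-to-I
#'     heterogeneity half-widths.}
#'   \item{fig4_synergy}{The four-condition deficit table across a percent
#'     grid, with additive prediction and fold ratio.}
#'   \item{fig5_hopf2d}{Two-parameter Hopf curves in healthy and disease
#'     contexts with oscillatory-area comparison.}
#' }
#'
#' @param name Experiment name (see above); unknown names raise an error
#'   enumerating the valid ones.
#' @param config An \code{\link{mf_params}} object (healthy state);
#'   defaults to the calibrated reference configuration.
#' @param out_dir Output directory (created).
#' @param seed Integer seed for the stochastic parts (network draws).
#' @param fast Reduce grid resolutions and durations (smoke-test scale).
#' @return Invisible list of output file paths.
#' @export
run_experiment <- function(name, config = reference_config(),
                           out_dir = name, seed = 1, fast = FALSE) {
  valid <- c("fig1_validation", "fig2_sweeps", "fig3_sweeps",
             "fig4_synergy", "fig5_hopf2d")
  if (!name %in% valid)
    stop("unknown experiment '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(
    name,
    fig1_validation = .exp_fig1(config, out_dir, seed, fast),
    fig2_sweeps = .exp_sweeps(config, out_dir, fast,
                              list(list("gbar_i_ampa", 0.02, 6),
                                   list("gbar_i_nmda", 0.0, 0.4),
                                   list("gbar_e_gaba", 0.02, 2.5))),
    fig3_sweeps = .exp_sweeps(config, out_dir, fast,
                              list(list("gamma_i_ampa", 0.01, 2.5),
                                   list("gamma_i_nmda", 0.01, 0.12))),
    fig4_synergy = .exp_synergy(config, out_dir, fast),
    fig5_hopf2d = .exp_hopf2d(config, out_dir, fast))
  .write_manifest(out_dir, name, config, seed, files)
  invisible(c(files, file.path(out_dir, "manifest.json")))
}

.exp_fig1 <- function(config, out_dir, seed, fast) {
  dur <- if (fast) 1200 else 2500
  net <- build_network(config, N_e = if (fast) 200 else 800,
                       N_i = if (fast) 50 else 200, seed = seed)
  rec <- simulate_network(net, duration = dur)
  rate_e <- population_rate(rec, "e", bin = 1, smooth_width = 2)
  traj <- integrate_mean_field(config, duration = dur, dt_out = 1)
  comp <- data.frame(t = rate_e$t, rate_net = rate_e$rate,
                     rate_mf = traj$r_e[match(rate_e$t, traj$t)])
  f1 <- file.path(out_dir, "rates_comparison.csv")
  utils::write.csv(comp, f1, row.names = FALSE)
  disc <- if (fast) 300 else 500
  gm_net <- gamma_metrics(power_spectrum(rate_e$rate, 1000, disc,
                                         min_signal_s = 0.5))
  gm_mf <- gamma_metrics(power_spectrum(traj$r_e, 1000, disc,
                                        min_signal_s = 0.5))
  f2 <- file.path(out_dir, "gamma_summary.json")
  jsonlite::write_json(
    list(network = gm_net, meanfield = gm_mf,
         peak_frequency_diff_hz = abs(gm_net$peak_frequency -
                                        gm_mf$peak_frequency)),
    f2, auto_unbox = TRUE, digits = NA, null = "null")
  c(f1, f2)
}

.exp_sweeps <- function(config, out_dir, fast, sweeps) {
  files <- character()
  for (sw in sweeps) {
    nm <- sw[[1]]
    grid <- seq(sw[[2]], sw[[3]], length.out = if (fast) 15 else 60)
    rows <- lapply(grid, function(v) {
      pp <- set_param(config, nm, v)
      gm <- mf_gamma_power(pp, duration = if (fast) 2000 else 4500)
      amp <- oscillation_amplitude(pp, duration = if (fast) 1500 else 3000)
      eq <- find_equilibrium(pp)
      mre <- if (is.null(eq)) NA_real_ else
        .leading_pair(.flat_params(pp), eq)$mre
      data.frame(value = v, gamma_power = gm$gamma_power,
                 peak_frequency = gm$peak_frequency,
                 amplitude = amp$amplitude, max_re_lambda = mre)
    })
    df <- do.call(rbind, rows)
    f <- file.path(out_dir, paste0("sweep_", nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    hp <- hopf_scan_1d(config, nm, sw[[2]], sw[[3]],
                       n_grid = if (fast) 60 else 200)
    fj <- file.path(out_dir, paste0("hopf_", nm, ".json"))
    jsonlite::write_json(
      lapply(hp, function(h) list(parameter = h$parameter, value = h$value,
                                  re_lambda = Re(h$eigenvalue),
                                  frequency_hz = h$frequency_hz,
                                  direction = h$direction)),
      fj, auto_unbox = TRUE, digits = NA)
    files <- c(files, f, fj)
  }
  files
}

.exp_synergy <- function(config, out_dir, fast) {
  pg <- if (fast) c(0, 10, 20, 30) else seq(0, 40, by = 2.5)
  sy <- synergy_analysis(config, pct_grid = pg,
                         duration = if (fast) 2500 else 4500)
  f <- file.path(out_dir, "synergy.csv")
  utils::write.csv(as.data.frame(sy), f, row.names = FALSE)
  f
}

.exp_hopf2d <- function(config, out_dir, fast) {
  nx <- if (fast) 8 else 40
  setups <- list(
    list(third = "ei_strength", x = "gbar_e_gaba", xg = seq(0.05, 2, length.out = nx),
         y = "gamma_i_ampa", ylo = 0.005, yhi = 3),
    list(third = "ie_strength", x = "gbar_i_ampa", xg = seq(0.05, 5, length.out = nx),
         y = "gamma_i_ampa", ylo = 0.005, yhi = 3),
    list(third = "ei_variability", x = "gbar_i_ampa", xg = seq(0.05, 5, length.out = nx),
         y = "gbar_e_gaba", ylo = 0.01, yhi = 2.5))
  files <- character()
  for (st in setups) {
    for (state in c("healthy", "sz")) {
      pc <- if (state == "healthy") config else
        apply_condition(config, st$third, pct = 20)
      cv <- hopf_curve_2d(pc, st$x, st$xg, st$y, st$ylo, st$yhi,
                          n_grid = if (fast) 40 else 120,
                          context = paste(st$third, state))
      f <- file.path(out_dir,
                     sprintf("hopf2d_%s_%s.csv", st$third, state))
      utils::write.csv(as.data.frame(cv), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  files
}
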