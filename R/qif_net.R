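#' Build a finite-size QIF PING network
#'
#' Constructs an all-to-all network of \code{N_e} regular-spiking excitatory
#' (RSE) and \code{N_i} fast-spiking inhibitory (FSI) QIF neurons with
#' quenched Lorentzian heterogeneity: each neuron draws its AMPA, NMDA and
#' GABA conductances and its tonic drive once at construction, from the
#' Lorentzian modes and half-widths in \code{params}. Seed-splitting is
#' deterministic: the eight heterogeneity blocks (E conductances x3, E
#' drive, I conductances x3, I drive) use \code{seed + 1 ... seed + 8}, so
#' an identical seed reproduces the network bit-for-bit.
#'
#' @param params An \code{\link{mf_params}} object.
#' @param N_e,N_i Population sizes (the reference network is 800 + 200).
#' @param seed Integer seed for the quenched draws.
#' @param truncate_at_zero Clip negative conductance/drive draws at zero
#'   (theory-breaking; see \code{\link{sample_lorentzian}}).
#' @return An object of class \code{"qif_network"}.
#' @export
build_network <- function(params, N_e = 800, N_i = 200, seed = 1,
                          truncate_at_zero = FALSE) {
  stopifnot(inherits(params, "mf_params"), N_e >= 1, N_i >= 1)
  cp <- params$coupling; dv <- params$drive
  s <- as.integer(seed)
  draw <- function(mode, hw, n, k)
    sample_lorentzian(mode, hw, n, seed = s + k,
                      truncate_at_zero = truncate_at_zero)
  ge <- c(draw(cp$gbar_e_ampa, cp$gamma_e_ampa, N_e, 1L),
          draw(cp$gbar_i_ampa, cp$gamma_i_ampa, N_i, 5L))
  gn <- c(draw(cp$gbar_e_nmda, cp$gamma_e_nmda, N_e, 2L),
          draw(cp$gbar_i_nmda, cp$gamma_i_nmda, N_i, 6L))
  gi <- c(draw(cp$gbar_e_gaba, cp$gamma_e_gaba, N_e, 3L),
          draw(cp$gbar_i_gaba, cp$gamma_i_gaba, N_i, 7L))
  Ih <- c(draw(dv$Ibar_e, dv$Delta_e, N_e, 4L),
          draw(dv$Ibar_i, dv$Delta_i, N_i, 8L))
  # deterministic phase spread at Cauchy quantiles: a smooth, reproducible
  # initial condition consistent with the Lorentzian density shape
  spread <- function(n) 2 * atan(tan(pi * ((seq_len(n) - 0.5) / n - 0.5)))
  theta0 <- c(spread(N_e), spread(N_i))
  structure(list(N_e = N_e, N_i = N_i, ge = ge, gn = gn, gi = gi,
                 Ihat = Ih, theta0 = theta0, params = params, seed = s,
                 s0 = c(0, 0, 0)),
            class = "qif_network")
}

#' @export
print.qif_network <- function(x, ...) {
  cat(sprintf("QIF PING network: %d RSE + %d FSI (seed %d)\n",
              x$N_e, x$N_i, x$seed))
  invisible(x)
}

#' Simulate a QIF PING network
#'
#' Fixed-step RK4 integration in the theta-neuron phase variable
#' \eqn{u = \tan(\theta/2)}, which makes the infinite spike/reset of the
#' theoretical QIF limit exact and turns spike detection into a phase
#' crossing at \eqn{\theta = \pi}. Global synaptic gates are shared by the
#' whole network; a spike of any excitatory (inhibitory) neuron increments
#' \code{s_e} (\code{s_i}) by \code{1/N_e} (\code{1/N_i}) at the end of the
#' step in which it occurs, so the gating drive equals the population mean
#' rate — the normalization under which the finite network converges to the
#' macroscopic gating equations for any population split. The NMDA gate
#' follows
#' \eqn{s_n' = a_n s_e (1 - s_n) - s_n/\tau_n} driven by the global
#' \code{s_e}.
#'
#' @param net A \code{\link{build_network}} object.
#' @param duration Simulation time (ms).
#' @param dt Time step (ms); default 0.01 x the AMPA decay constant.
#' @param record_every Gate-trace recording stride in steps (0 = none).
#' @return An object of class \code{"spike_record"}: list with
#'   \code{spikes} (data frame: \code{time}, \code{neuron},
#'   \code{population}), \code{gates} (data frame of gate traces),
#'   \code{duration}, \code{dt}, and the network.
#' @export
simulate_network <- function(net, duration = 2000,
                             dt = 0.01 * net$params$kinetics$tau_e,
                             record_every = max(1L, round(0.5 / dt))) {
  stopifnot(inherits(net, "qif_network"), dt > 0, duration >= dt)
  k <- net$params$kinetics
  n_steps <- ceiling(duration / dt)
  res <- .Call("pingmf_simulate_qif",
    net$theta0, net$ge, net$gn, net$gi, net$Ihat, as.integer(net$N_e),
    net$params$tau, net$params$Vhat_ex, net$params$Vhat_in,
    k$tau_e, k$tau_i, k$tau_n, k$a_n,
    dt, as.integer(n_steps), as.integer(record_every),
    net$s0[1], net$s0[2], net$s0[3], PACKAGE = "pingmf")
  spikes <- data.frame(
    time = res$spike_times,
    neuron = res$spike_ids,
    population = ifelse(res$spike_ids <= net$N_e, "e", "i"))
  gates <- data.frame(t = res$trace_t, s_e = res$s_e, s_i = res$s_i,
                      s_n = res$s_n)
  structure(list(spikes = spikes, gates = gates, duration = n_steps * dt,
                 dt = dt, network = net),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("Spike record: %d spikes over %.0f ms (%d RSE + %d FSI)\n",
              nrow(x$spikes), x$duration, x$network$N_e, x$network$N_i))
  invisible(x)
}

#' Population firing-rate trace from a spike record
#'
#' Bins spikes of one population into a rate histogram
#' \code{count / (N_pop * bin)} and optionally smooths it with a Gaussian
#' kernel (standard deviation \code{smooth_width}). The unsmoothed rate
#' conserves spikes exactly: \code{sum(rate) * N_pop * bin} equals the
#' population spike count.
#'
#' @param rec A \code{\link{simulate_network}} record.
#' @param population \code{"e"} or \code{"i"}.
#' @param bin Bin width (ms).
#' @param smooth_width Gaussian kernel SD (ms); 0 disables smoothing.
#' @param units \code{"per_ms"} (matches mean-field \code{r}) or
#'   \code{"hz"}.
#' @return Data frame with columns \code{t} (bin centers, ms) and
#'   \code{rate}.
#' @export
population_rate <- function(rec, population = c("e", "i"), bin = 1,
                            smooth_width = 0, units = c("per_ms", "hz")) {
  stopifnot(inherits(rec, "spike_record"), bin > 0)
  population <- match.arg(population)
  units <- match.arg(units)
  n_pop <- if (population == "e") rec$network$N_e else rec$network$N_i
  edges <- seq(0, rec$duration + bin, by = bin)
  st <- rec$spikes$time[rec$spikes$population == population]
  counts <- if (length(st))
    graphics::hist(st, breaks = edges, plot = FALSE)$counts
  else rep(0L, length(edges) - 1L)
  rate <- counts / (n_pop * bin)
  if (smooth_width > 0) {
    half <- ceiling(4 * smooth_width / bin)
    kern <- stats::dnorm(seq(-half, half) * bin, sd = smooth_width)
    kern <- kern / sum(kern)
    rate <- stats::filter(c(rep(rate[1], half), rate,
                            rep(rate[length(rate)], half)),
                          kern, sides = 2)
    rate <- as.numeric(rate)[(half + 1):(half + length(counts))]
  }
  if (units == "hz") rate <- rate * 1000
  data.frame(t = edges[-length(edges)] + bin / 2, rate = rate)
}

#' Write spikes and rate traces to plain-text outputs
#'
#' Spike output is a two-column CSV (\code{time_ms}, \code{neuron_id}) with
#' a JSON sidecar recording population ranges and the seed; rate traces go
#' to a CSV with columns \code{(t, rate_e, rate_i)}.
#'
#' @param rec A \code{spike_record}.
#' @param dir Output directory (created if needed).
#' @param bin,smooth_width Passed to \code{\link{population_rate}}.
#' @return The directory, invisibly.
#' @export
write_spike_record <- function(rec, dir, bin = 1, smooth_width = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(time_ms = rec$spikes$time, neuron_id = rec$spikes$neuron),
    file.path(dir, "spikes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(N_e = rec$network$N_e, N_i = rec$network$N_i,
         e_range = c(1, rec$network$N_e),
         i_range = c(rec$network$N_e + 1, rec$network$N_e + rec$network$N_i),
         seed = rec$network$seed, dt = rec$dt, duration = rec$duration),
    file.path(dir, "spikes.json"), auto_unbox = TRUE, digits = NA)
  re <- population_rate(rec, "e", bin = bin, smooth_width = smooth_width)
  ri <- population_rate(rec, "i", bin = bin, smooth_width = smooth_width)
  utils::write.csv(data.frame(t = re$t, rate_e = re$rate, rate_i = ri$rate),
                   file.path(dir, "rates.csv"), row.names = FALSE)
  invisible(dir)
}
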