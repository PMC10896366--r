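#' Welch power spectral density of a rate trace
#'
#' Mean-subtracted Welch estimate: the trace (after discarding an initial
#' transient) is split into Hann-windowed segments with 50\% overlap, each
#' segment's periodogram is computed, and the one-sided densities are
#' averaged. Deterministic for a fixed input.
#'
#' @param trace Numeric vector: a rate trace sampled uniformly at \code{fs}
#'   (e.g. the \code{r_e} column of an \code{mf_trajectory}, or a smoothed
#'   network population rate).
#' @param fs Sampling frequency (Hz); default 1000 (1 ms sampling).
#' @param transient_discard Initial transient to drop (ms).
#' @param seg_len Welch segment length in samples (power of two advised).
#' @param overlap Fractional segment overlap in [0, 1).
#' @param pad Zero-padding factor for the segment FFTs; padding interpolates
#'   the spectrum so that narrowband peaks are not underestimated between
#'   bin centers (scalloping), which matters when peak density is compared
#'   across a parameter sweep.
#' @param min_signal_s Minimum signal length required after the discard (s).
#' @return An object of class \code{"spectral_result"}: list with
#'   \code{frequencies} (Hz), \code{power} (density, input-units^2/Hz),
#'   \code{fs}, and the estimator settings.
#' @export
power_spectrum <- function(trace, fs = 1000, transient_discard = 500,
                           seg_len = 1024, overlap = 0.5, pad = 4,
                           min_signal_s = 2) {
  stopifnot(is.numeric(trace), fs > 0, overlap >= 0, overlap < 1)
  ndrop <- round(transient_discard * fs / 1000)
  x <- trace[(ndrop + 1):length(trace)]
  if (length(x) < min_signal_s * fs)
    stop(sprintf("trace too short after transient discard: %.2f s < %.2f s",
                 length(x) / fs, min_signal_s))
  if (seg_len > length(x)) seg_len <- 2^floor(log2(length(x)))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, length(x) - seg_len + 1, by = step)
  nfft <- seg_len * max(1L, as.integer(pad))
  nf <- nfft %/% 2
  acc <- numeric(nf + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1)]
    seg <- c((seg - mean(seg)) * w, numeric(nfft - seg_len))
    P <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    half <- P[1:(nf + 1)]
    # one-sided: double everything except DC (and Nyquist)
    half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  structure(list(
    frequencies = fs * (0:nf) / nfft,
    power = acc / length(starts),
    fs = fs,
    settings = list(transient_discard = transient_discard, seg_len = seg_len,
                    overlap = overlap, pad = max(1L, as.integer(pad)),
                    window = "hann", n_segments = length(starts))),
    class = "spectral_result")
}

#' Gamma-band power and peak frequency
#'
#' Summarizes a spectrum by the maximum power density within the gamma band
#' (default 30--100 Hz) and the frequency at which it occurs. Power at or
#' below the noise floor is reported as zero with an undefined (NA) peak
#' frequency.
#'
#' @param spec A \code{\link{power_spectrum}} result.
#' @param band Length-2 numeric: analysis band (Hz); must lie within
#'   Nyquist.
#' @param noise_floor Density below which oscillation is considered absent.
#' @param metric \code{"peak"} (default): maximum density in the band;
#'   \code{"integral"}: band-integrated power (alternative metric).
#' @return List with \code{gamma_power} and \code{peak_frequency} (Hz; NA
#'   when power is at the floor).
#' @export
gamma_metrics <- function(spec, band = c(30, 100), noise_floor = 1e-12,
                          metric = c("peak", "integral")) {
  stopifnot(inherits(spec, "spectral_result"), length(band) == 2,
            band[1] < band[2])
  metric <- match.arg(metric)
  if (band[2] > spec$fs / 2) stop("band exceeds the Nyquist frequency")
  sel <- spec$frequencies >= band[1] & spec$frequencies <= band[2]
  if (!any(sel)) stop("empty band: no spectral estimate inside it")
  pw <- spec$power[sel]
  fq <- spec$frequencies[sel]
  peak <- max(pw)
  gp <- if (metric == "peak") peak else sum(pw) * diff(spec$frequencies[1:2])
  if (peak <= noise_floor)
    return(list(gamma_power = 0, peak_frequency = NA_real_))
  list(gamma_power = gp, peak_frequency = fq[which.max(pw)])
}

#' Gamma power of a mean-field parameter set
#'
#' Convenience pipeline: integrate the mean-field system, take the
#' excitatory rate trace, and compute the gamma-band metrics with frozen
#' spectral settings. All sweep and synergy analyses in the package go
#' through this single function so their powers are directly comparable.
#'
#' @param p An \code{\link{mf_params}} object.
#' @param duration Integration time (ms).
#' @param x0 Initial state (default \code{\link{mean_field_state}()}).
#' @param band Gamma band (Hz).
#' @param transient_discard Transient dropped before the spectrum (ms).
#' @param ... Passed to \code{\link{power_spectrum}}.
#' @return List with \code{gamma_power}, \code{peak_frequency}, and the
#'   \code{spectrum}.
#' @export
mf_gamma_power <- function(p, duration = 4500, x0 = mean_field_state(),
                           band = c(30, 100), transient_discard = 500, ...) {
  traj <- integrate_mean_field(p, x0 = x0, duration = duration, dt_out = 1)
  spec <- power_spectrum(traj$r_e, fs = 1000,
                         transient_discard = transient_discard, ...)
  c(gamma_metrics(spec, band = band), list(spectrum = spec))
}

#' Write a spectrum to CSV with a JSON summary sidecar
#'
#' @param spec A \code{spectral_result}.
#' @param path CSV output path (columns frequency, density); a JSON file
#'   with the gamma metrics and estimator settings is written alongside.
#' @param band Gamma band for the summary.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spec, path, band = c(30, 100)) {
  utils::write.csv(
    data.frame(frequency = spec$frequencies, density = spec$power),
    path, row.names = FALSE)
  gm <- gamma_metrics(spec, band = band)
  jsonlite::write_json(
    list(gamma_power = gm$gamma_power,
         peak_frequency_hz = gm$peak_frequency,
         band = band, settings = spec$settings),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
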