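# Synthesis of the tailored injection-current waveforms: an alpha-frequency
# carrier with a short gamma burst superposed once per alpha cycle, centered on
# a chosen phase interval (peak or trough of the carrier), plus the sham
# ramp-up/ramp-down control.

#' Stimulation parameters
#'
#' Bundle of the tailored-waveform design parameters. Defaults follow the
#' experimental design: a 10 Hz carrier of 1.8 mA peak-to-peak with three
#' cycles of an 80 Hz, 1.2 mA peak-to-peak burst per alpha period, the
#' composite rescaled to 3 mA peak-to-peak; 30 s linear ramps around a 20 min
#' plateau; sampled at 2048 Hz.
#'
#' @param condition `"peak"`, `"trough"` or `"sham"`.
#' @param alpha_freq carrier frequency, Hz.
#' @param gamma_freq burst frequency, Hz (ignored for sham).
#' @param alpha_pkpk carrier component peak-to-peak amplitude, mA.
#' @param gamma_pkpk burst component peak-to-peak amplitude, mA.
#' @param composite_pkpk target peak-to-peak of the composed plateau, mA.
#' @param n_gamma_cycles cycles of `gamma_freq` per burst.
#' @param entrain_interval closed phase interval (radians, sine convention) on
#'   which the burst sits; default [canonical_interval()] for the condition.
#' @param intervals which published interval set to use when
#'   `entrain_interval` is `NULL`: `"discussion"` (default; spans 7/8 of a
#'   half-cycle, fits the 3-cycle burst) or `"methods"` (pi/4-wide; only fits
#'   shorter bursts).
#' @param ramp_s ramp-up and ramp-down duration, s (each).
#' @param plateau_s plateau duration, s.
#' @param fs sampling rate, Hz.
#' @return an object of class `stim_params`.
#' @export
stim_params <- function(condition = c("trough", "peak", "sham"),
                        alpha_freq = 10, gamma_freq = 80,
                        alpha_pkpk = 1.8, gamma_pkpk = 1.2,
                        composite_pkpk = 3.0, n_gamma_cycles = 3,
                        entrain_interval = NULL,
                        intervals = c("discussion", "methods"),
                        ramp_s = 30, plateau_s = 1200, fs = 2048) {
  condition <- match.arg(condition)
  intervals <- match.arg(intervals)
  stopifnot(alpha_freq > 0, composite_pkpk > 0, ramp_s >= 0, plateau_s >= 0)
  if (ramp_s < 0 || plateau_s < 0) stop("durations must be non-negative")
  if (condition == "sham") {
    if (fs <= 2 * alpha_freq) stop("fs must exceed twice the carrier frequency")
  } else {
    stopifnot(gamma_freq > 0, gamma_pkpk > 0, n_gamma_cycles >= 1)
    if (fs <= 2 * gamma_freq)
      stop("fs must exceed twice the gamma frequency (Nyquist)")
    if (is.null(entrain_interval))
      entrain_interval <- canonical_interval(condition, intervals = intervals)
    width_s <- diff(entrain_interval) / (2 * pi) / alpha_freq
    burst_s <- n_gamma_cycles / gamma_freq
    if (burst_s > width_s + 1e-12)
      stop(sprintf(
        "burst (%.4g ms) does not fit in the entrainment interval (%.4g ms)",
        1e3 * burst_s, 1e3 * width_s))
  }
  structure(list(condition = condition, alpha_freq = alpha_freq,
                 gamma_freq = gamma_freq, alpha_pkpk = alpha_pkpk,
                 gamma_pkpk = gamma_pkpk, composite_pkpk = composite_pkpk,
                 n_gamma_cycles = n_gamma_cycles,
                 entrain_interval = entrain_interval, intervals = intervals,
                 ramp_s = ramp_s, plateau_s = plateau_s, fs = fs),
            class = "stim_params")
}

#' Canonical entrainment interval for a stimulation condition
#'
#' Phase intervals of the alpha cycle over which the gamma burst is entrained,
#' under the sine convention (carrier = sin, peak at pi/2, trough at 3*pi/2).
#' The `"discussion"` set is centered on the carrier extrema and wide enough
#' for a three-cycle 80 Hz burst; the narrower `"methods"` set is retained for
#' sensitivity checks.
#'
#' @param condition `"peak"` or `"trough"` (sham has no interval).
#' @param convention phase convention; only `"sine"` is defined.
#' @param intervals `"discussion"` or `"methods"`.
#' @return numeric length-2 vector, radians in [0, 2*pi).
#' @export
canonical_interval <- function(condition = c("trough", "peak"),
                               convention = "sine",
                               intervals = c("discussion", "methods")) {
  condition <- match.arg(condition, c("trough", "peak", "sham"))
  if (condition == "sham") stop("sham stimulation has no entrainment interval")
  convention <- match.arg(convention, "sine")
  intervals <- match.arg(intervals)
  if (intervals == "discussion") {
    switch(condition,
           peak   = c(pi / 16, 15 * pi / 16),
           trough = c(17 * pi / 16, 31 * pi / 16))
  } else {
    switch(condition,
           peak   = c(pi / 8, 3 * pi / 8),
           trough = c(5 * pi / 8, 7 * pi / 8))
  }
}

#' Gamma burst template
#'
#' Hann-tapered sinusoid of exactly `n_gamma_cycles / gamma_freq` seconds.
#' The untapered component has peak-to-peak `gamma_pkpk`; the taper takes the
#' endpoints to 0 so the burst splices into the carrier without
#' discontinuities.
#'
#' @param params a [stim_params()] object (peak or trough).
#' @return list with `samples` (mA), `t` (s) and `duration_s`.
#' @export
synth_burst <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  if (params$condition == "sham") stop("sham stimulation has no gamma burst")
  d <- params$n_gamma_cycles / params$gamma_freq
  if (d > 1 / params$alpha_freq)
    stop("burst longer than one alpha period")
  n <- max(2, round(d * params$fs) + 1)
  t <- seq(0, d, length.out = n)
  u <- t - d / 2
  samples <- (params$gamma_pkpk / 2) * cos(pi * u / d)^2 * sin(2 * pi * params$gamma_freq * u)
  list(samples = samples, t = t, duration_s = d)
}

# Unscaled composite current (mA) at times t (s): alpha carrier plus one
# Hann-tapered gamma burst per alpha cycle, centered at the midpoint of the
# entrainment interval. Evaluated analytically so there is no tiling error
# when fs is not a multiple of alpha_freq.
composite_current <- function(params, t) {
  a <- (params$alpha_pkpk / 2) * sin(2 * pi * params$alpha_freq * t)
  if (params$condition == "sham") return(a)
  Ta <- 1 / params$alpha_freq
  d <- params$n_gamma_cycles / params$gamma_freq
  mid <- mean(params$entrain_interval)
  tc <- mid / (2 * pi) * Ta
  delta <- ((t - tc + Ta / 2) %% Ta) - Ta / 2
  g <- numeric(length(t))
  m <- abs(delta) <= d / 2
  g[m] <- (params$gamma_pkpk / 2) * cos(pi * delta[m] / d)^2 *
    sin(2 * pi * params$gamma_freq * delta[m])
  a + g
}

#' One alpha-period tile of the composed stimulation current
#'
#' The alpha carrier with the burst superposed at the midpoint of the
#' entrainment interval, rescaled so that the steady-state (plateau) composite
#' has peak-to-peak exactly `composite_pkpk`. Rescaling preserves the
#' alpha:gamma component ratio.
#'
#' @param params a [stim_params()] object with condition peak or trough.
#' @return list with `samples` (mA), `t` (s), `scale` applied.
#' @export
compose_cycle <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  if (params$condition == "sham")
    stop("compose_cycle is defined for peak/trough conditions only")
  sc <- composite_scale(params)
  n <- round(params$fs / params$alpha_freq)
  t <- (seq_len(n) - 1) / params$fs
  list(samples = sc * composite_current(params, t), t = t, scale = sc)
}

# Rescale factor taking the raw composite to composite_pkpk peak-to-peak,
# measured on the actual sampling grid over a stretch long enough to cover all
# distinct sample phases (1 s, i.e. alpha_freq full cycles).
composite_scale <- function(params) {
  n <- round(params$fs)
  t <- (seq_len(n) - 1) / params$fs
  raw <- composite_current(params, t)
  params$composite_pkpk / (max(raw) - min(raw))
}

#' Build a full stimulation-session waveform
#'
#' Peak/trough: linear ramp-up (`ramp_s`), plateau (`plateau_s`) and linear
#' ramp-down (`ramp_s`) applied as an envelope over the composed
#' alpha-plus-burst current, rescaled so the plateau peak-to-peak equals
#' `composite_pkpk`. Sham: a pure alpha sinusoid under a triangular envelope
#' reaching `composite_pkpk` peak-to-peak at its apex, active for `2 * ramp_s`,
#' followed by zero current for the remainder of the session.
#'
#' @param params a [stim_params()] object.
#' @return an object of class `tacs_waveform`: list with `samples` (mA), `fs`,
#'   `segments` (data.frame of labeled sample-index ranges) and `params`.
#' @export
build_session <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  fs <- params$fs
  total_s <- 2 * params$ramp_s + params$plateau_s
  n <- round(total_s * fs) + 1
  t <- (seq_len(n) - 1) / fs
  i_up_end <- round(params$ramp_s * fs) + 1
  i_pl_end <- round((params$ramp_s + params$plateau_s) * fs) + 1

  if (params$condition == "sham") {
    env <- numeric(n)
    up <- t <= params$ramp_s
    dn <- t > params$ramp_s & t <= 2 * params$ramp_s
    if (params$ramp_s > 0) {
      env[up] <- t[up] / params$ramp_s
      env[dn] <- (2 * params$ramp_s - t[dn]) / params$ramp_s
    }
    samples <- env * (params$composite_pkpk / 2) *
      sin(2 * pi * params$alpha_freq * t)
    i_dn_end <- round(2 * params$ramp_s * fs) + 1
    segments <- data.frame(
      label = c("ramp_up", "ramp_down", "off"),
      start = c(1L, i_up_end + 1L, i_dn_end + 1L),
      end = c(i_up_end, i_dn_end, n))
    segments <- segments[segments$start <= segments$end, ]
  } else {
    raw <- composite_current(params, t)
    env <- rep(1, n)
    if (params$ramp_s > 0) {
      up <- t < params$ramp_s
      dn <- t > params$ramp_s + params$plateau_s
      env[up] <- t[up] / params$ramp_s
      env[dn] <- pmax(0, (total_s - t[dn]) / params$ramp_s)
    }
    plateau_idx <- seq(i_up_end, i_pl_end)
    rawp <- raw[plateau_idx]
    scale <- params$composite_pkpk / (max(rawp) - min(rawp))
    samples <- env * raw * scale
    segments <- data.frame(
      label = c("ramp_up", "plateau", "ramp_down"),
      start = c(1L, i_up_end + 1L, i_pl_end + 1L),
      end = c(i_up_end, i_pl_end, n))
  }
  samples[1] <- 0
  samples[n] <- 0
  structure(list(samples = samples, fs = fs, segments = segments,
                 params = params),
            class = "tacs_waveform")
}

#' @export
print.tacs_waveform <- function(x, ...) {
  cat(sprintf("tACS waveform: %s condition, %d samples at %g Hz (%.1f s)\n",
              x$params$condition, length(x$samples), x$fs,
              (length(x$samples) - 1) / x$fs))
  cat(sprintf("  peak-to-peak %.4g mA; segments: %s\n",
              max(x$samples) - min(x$samples),
              paste(x$segments$label, collapse = ", ")))
  invisible(x)
}

#' Verify gamma-on-alpha entrainment of a composed waveform
#'
#' Independent check of the composition: band-passes the plateau at the alpha
#' band to get instantaneous phase (sine convention) and at the gamma band to
#' get the amplitude envelope, then returns the envelope-weighted circular
#' mean alpha phase and the weighted mean resultant length.
#'
#' @param w a `tacs_waveform`, or a numeric sample vector (then `fs` required).
#' @param fs sampling rate when `w` is numeric.
#' @param alpha_band,gamma_band analysis bands, Hz.
#' @param max_s at most this many seconds of plateau are analyzed.
#' @param edge_s seconds trimmed from each end before and after filtering.
#' @return list with `preferred_phase` (radians) and `concentration` (0-1).
#' @export
verify_entrainment <- function(w, fs = NULL,
                               alpha_band = c(7, 13), gamma_band = c(70, 90),
                               max_s = 30, edge_s = 1) {
  if (inherits(w, "tacs_waveform")) {
    seg <- w$segments
    pl <- seg[seg$label == "plateau", ]
    if (nrow(pl) != 1) stop("waveform has no plateau segment")
    x <- w$samples[pl$start:pl$end]
    fs <- w$fs
    f_alpha <- w$params$alpha_freq
  } else {
    stopifnot(is.numeric(w), !is.null(fs))
    x <- w
    f_alpha <- mean(alpha_band)
  }
  if (length(x) < 10 * fs / f_alpha)
    stop("plateau too short: need at least 10 alpha periods")
  x <- x[seq_len(min(length(x), round(max_s * fs)))]
  ne <- round(edge_s * fs)
  if (length(x) <= 2 * ne + fs) ne <- 0
  za <- band_analytic(x, fs, alpha_band[1], alpha_band[2])
  zg <- band_analytic(x, fs, gamma_band[1], gamma_band[2])
  keep <- seq.int(ne + 1, length(x) - ne)
  phase <- sine_phase(za[keep])
  env <- Mod(zg[keep])
  # degenerate case: no gamma-band energy at all
  if (sum(env) < 1e-9 * length(env) * (max(abs(x)) + 1e-300))
    return(list(preferred_phase = NA_real_, concentration = 0))
  cm <- circ_mean_w(phase, env)
  list(preferred_phase = cm$mean, concentration = cm$r)
}

#' Export a waveform to CSV with a JSON sidecar
#'
#' Writes a two-column CSV (`time_s`, `current_mA`) and `<path>.json` carrying
#' the stimulation parameters and segment boundaries. [read_waveform()]
#' round-trips losslessly to ~1e-12 mA.
#'
#' @param w a `tacs_waveform`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_waveform <- function(w, path) {
  stopifnot(inherits(w, "tacs_waveform"))
  n <- length(w$samples)
  dt <- data.table::data.table(time_s = (seq_len(n) - 1) / w$fs,
                               current_mA = w$samples)
  data.table::fwrite(dt, path)
  hdr <- list(params = unclass(w$params), fs = w$fs,
              segments = w$segments, n_samples = n)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a waveform written by [export_waveform()]
#'
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return a `tacs_waveform`.
#' @export
read_waveform <- function(path) {
  dt <- data.table::fread(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- hdr$params
  params <- stim_params(condition = p$condition, alpha_freq = p$alpha_freq,
                        gamma_freq = p$gamma_freq, alpha_pkpk = p$alpha_pkpk,
                        gamma_pkpk = p$gamma_pkpk,
                        composite_pkpk = p$composite_pkpk,
                        n_gamma_cycles = p$n_gamma_cycles,
                        entrain_interval = if (p$condition == "sham") NULL
                                           else p$entrain_interval,
                        ramp_s = p$ramp_s, plateau_s = p$plateau_s, fs = p$fs)
  structure(list(samples = dt$current_mA, fs = hdr$fs,
                 segments = as.data.frame(hdr$segments), params = params),
            class = "tacs_waveform")
}

#' Count gamma bursts in a waveform segment
#'
#' Counts local maxima of the gamma-band envelope exceeding half its maximum,
#' separated by a refractory period of half an alpha cycle. Used to check the
#' one-burst-per-alpha-cycle construction.
#'
#' @param x numeric samples.
#' @param fs sampling rate, Hz.
#' @param gamma_band band in Hz.
#' @param alpha_freq carrier frequency, Hz.
#' @return integer burst count.
#' @export
count_bursts <- function(x, fs, gamma_band = c(70, 90), alpha_freq = 10) {
  env <- Mod(band_analytic(x, fs, gamma_band[1], gamma_band[2]))
  thr <- max(env) / 2
  above <- env > thr
  if (!any(above)) return(0L)
  idx <- which(above)
  gaps <- which(diff(idx) > fs / alpha_freq / 2)
  length(gaps) + 1L
}
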