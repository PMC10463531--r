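# EEG/EOG feature pipeline: preprocessing, pre-stimulus epoching with
# amplitude-based artifact rejection, inter-trial phase coherence via Morlet
# wavelets, trial-averaged power spectra, phase-amplitude comodulograms (Tort
# modulation index, with Canolty mean-vector-length as an alternative), window
# of-interest aggregation, and an EOG saccade detector.

#' Preprocess a recording
#'
#' Zero-phase high-pass at `hp_hz` and notch around `notch_hz`. The high-pass
#' is a 4th-order Butterworth, the notch a 2nd-order Butterworth band-stop of
#' bandwidth `notch_hz / notch_q`; both are applied with the squared magnitude
#' response of a forward-backward pass (see [zero_phase_filter()]).
#'
#' @param recording a `recording` (or numeric vector with `fs` given).
#' @param fs sampling rate when `recording` is numeric.
#' @param hp_hz high-pass cutoff, Hz.
#' @param notch_hz notch center frequency, Hz.
#' @param notch_q notch quality factor (center / bandwidth).
#' @return same shape as the input, filtered; filter settings recorded in
#'   `meta$preprocess` when a `recording` is given.
#' @export
preprocess <- function(recording, fs = NULL, hp_hz = 1, notch_hz = 60,
                       notch_q = 30) {
  is_rec <- inherits(recording, "recording")
  x <- if (is_rec) recording$eeg else recording
  fs <- if (is_rec) recording$fs else fs
  stopifnot(!is.null(fs))
  if (fs < 200) stop("fs below 200 Hz: notch filter undefined near Nyquist")
  hp <- signal::butter(4, hp_hz / (fs / 2), type = "high")
  bw <- notch_hz / notch_q
  bs <- signal::butter(2, c(notch_hz - bw / 2, notch_hz + bw / 2) / (fs / 2),
                       type = "stop")
  y <- zero_phase_filter(x, fs, list(hp, bs),
                         cache_key = sprintf("pre_%g_%g_%g", hp_hz, notch_hz,
                                             notch_q))
  if (!is_rec) return(y)
  recording$eeg <- y
  recording$meta$preprocess <- list(hp_hz = hp_hz, hp_order = 4,
                                    notch_hz = notch_hz, notch_q = notch_q,
                                    zero_phase = TRUE)
  recording
}

#' Cut pre-stimulus epochs and reject high-amplitude trials
#'
#' Epochs span `window` (default -1000 to 0 ms) relative to each stimulus
#' onset. Any epoch whose absolute amplitude exceeds `threshold` uV is
#' rejected. Trials whose epoch (plus `pad_s` context on both sides, kept for
#' the wavelet transform) would run off the trace are marked invalid rather
#' than silently dropped.
#'
#' @param recording a preprocessed `recording`.
#' @param events optional event table (default `recording$events`).
#' @param threshold rejection threshold, uV.
#' @param window epoch window relative to onset, s.
#' @param pad_s context padding kept on each side for spectral estimation, s.
#' @return object of class `epoch_set`: `epochs` (kept trials x window
#'   samples), `epochs_padded`, `pad` (samples), `fs`, `window`,
#'   `kept_trial_ids`, `rejected_trial_ids`, `invalid_trial_ids`, `events`,
#'   `meta`.
#' @export
epoch_and_reject <- function(recording, events = NULL, threshold = 100,
                             window = c(-1, 0), pad_s = 0.5) {
  stopifnot(inherits(recording, "recording"))
  if (is.null(events)) events <- recording$events
  fs <- recording$fs
  nwin <- round(diff(window) * fs)
  pad <- round(pad_s * fs)
  n <- length(recording$eeg)
  first <- events$sample + round(window[1] * fs)
  last <- first + nwin - 1
  valid <- (first - pad) >= 1 & (last + pad) <= n
  idx_valid <- which(valid)
  ep_pad <- matrix(0, length(idx_valid), nwin + 2 * pad)
  for (i in seq_along(idx_valid)) {
    j <- idx_valid[i]
    ep_pad[i, ] <- recording$eeg[(first[j] - pad):(last[j] + pad)]
  }
  core <- ep_pad[, pad + seq_len(nwin), drop = FALSE]
  exceeded <- apply(abs(core), 1, max) > threshold
  kept <- idx_valid[!exceeded]
  structure(list(
    epochs = core[!exceeded, , drop = FALSE],
    epochs_padded = ep_pad[!exceeded, , drop = FALSE],
    pad = pad, fs = fs, window = window,
    kept_trial_ids = events$trial[kept],
    rejected_trial_ids = events$trial[idx_valid[exceeded]],
    invalid_trial_ids = events$trial[!valid],
    events = events[kept, , drop = FALSE],
    meta = c(recording$meta, list(threshold = threshold))),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d kept, %d rejected, %d invalid trials; %g Hz, window [%g, %g] s\n",
              length(x$kept_trial_ids), length(x$rejected_trial_ids),
              length(x$invalid_trial_ids), x$fs, x$window[1], x$window[2]))
  invisible(x)
}

# Morlet cycle count: rises linearly from 3 at 1 Hz to 8 at 100 Hz.
morlet_cycles <- function(f) 3 + 5 * (f - 1) / 99

#' Inter-trial phase coherence (Morlet wavelet)
#'
#' For each frequency and time point, ITPC(f, t) = | mean_n exp(i phi_n(f, t)) |
#' over kept trials, where phi_n is the phase of a complex Morlet wavelet
#' transform (frequency-domain Gaussian kernel, analytic). Epochs are
#' transformed with their context padding attached and the padding discarded
#' afterwards to suppress edge artifacts.
#'
#' @param ep an [epoch_and_reject()] `epoch_set` with >= 2 kept trials.
#' @param freqs analysis frequencies, Hz (default 1-100, step 1).
#' @param decim keep every `decim`-th time sample in the output grid.
#' @return object of class `tf_map`: `values` (freqs x times, in [0, 1]),
#'   `freqs`, `times` (s, relative to stimulus onset), `n_trials`.
#' @export
itpc <- function(ep, freqs = 1:100, decim = max(1L, round(ep$fs / 128))) {
  stopifnot(inherits(ep, "epoch_set"))
  ntr <- nrow(ep$epochs_padded)
  if (ntr < 2) stop("ITPC requires at least 2 kept trials")
  fs <- ep$fs
  npad <- ncol(ep$epochs_padded)
  nwin <- ncol(ep$epochs)
  keep_t <- ep$pad + seq(1, nwin, by = decim)
  times <- ep$window[1] + (keep_t - ep$pad - 1) / fs
  fgrid <- (seq_len(npad) - 1) * fs / npad
  # FFT of every trial once (columns = trials)
  TR <- stats::mvfft(t(ep$epochs_padded))
  vals <- matrix(NA_real_, length(freqs), length(keep_t))
  npos <- floor(npad / 2) + 1
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_t <- morlet_cycles(f0) / (2 * pi * f0)
    H <- numeric(npad)
    H[seq_len(npos)] <- 2 * exp(-0.5 * (2 * pi * (fgrid[seq_len(npos)] - f0))^2
                                * sigma_t^2)
    H[1] <- H[1] / 2
    tfr <- stats::mvfft(TR * H, inverse = TRUE) / npad
    ph <- tfr[keep_t, , drop = FALSE]
    ph <- ph / Mod(ph)
    vals[k, ] <- Mod(rowSums(ph)) / ntr
  }
  structure(list(values = vals, freqs = freqs, times = times,
                 n_trials = ntr),
            class = "tf_map")
}

#' Default windows of interest for ITPC statistics
#'
#' Six windows: the 7-13 Hz and 70-90 Hz frequency bands crossed with the
#' three 200 ms pre-stimulus time windows starting at -600, -400 and -200 ms.
#'
#' @return data.frame with `name`, `f_lo`, `f_hi`, `t_lo`, `t_hi`.
#' @export
itpc_windows <- function() {
  fb <- data.frame(f_lo = c(7, 70), f_hi = c(13, 90))
  tb <- data.frame(t_lo = c(-0.6, -0.4, -0.2), t_hi = c(-0.4, -0.2, 0))
  out <- merge(fb, tb)
  out <- out[order(out$f_lo, out$t_lo), ]
  out$name <- sprintf("itpc_%g-%gHz_%g-%gms", out$f_lo, out$f_hi,
                      1e3 * out$t_lo, 1e3 * out$t_hi)
  rownames(out) <- NULL
  out[, c("name", "f_lo", "f_hi", "t_lo", "t_hi")]
}

#' Mean of a time-frequency map over windows of interest
#'
#' @param map a [itpc()] `tf_map`.
#' @param windows data.frame like [itpc_windows()].
#' @return named numeric vector, one mean per window.
#' @export
window_mean <- function(map, windows = itpc_windows()) {
  stopifnot(inherits(map, "tf_map"))
  out <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    fi <- map$freqs >= windows$f_lo[i] & map$freqs <= windows$f_hi[i]
    ti <- map$times >= windows$t_lo[i] & map$times <= windows$t_hi[i]
    if (!any(fi) || !any(ti))
      stop(sprintf("window %d lies outside the map grid", i))
    out[i] <- mean(map$values[fi, ti])
  }
  stats::setNames(out, windows$name)
}

#' Trial-averaged power spectrum of the pre-stimulus window
#'
#' Per-trial periodogram of the 1 s pre-stimulus epoch (1 Hz resolution),
#' averaged over kept trials. Power at bin f is `(2 |X_f| / N)^2 / 2`, i.e.
#' A^2/2 for a sinusoid of amplitude A with an integer number of cycles.
#'
#' @param ep an `epoch_set` with >= 1 kept trial.
#' @return object of class `spectrum_avg`: `power` (uV^2), `freqs` (Hz),
#'   scalars `p10` and `p80`, `n_trials`.
#' @export
power_spectrum <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  ntr <- nrow(ep$epochs)
  if (ntr < 1) stop("no kept trials")
  N <- ncol(ep$epochs)
  X <- stats::mvfft(t(ep$epochs))
  npos <- floor(N / 2) + 1
  P <- (2 * Mod(X[seq_len(npos), , drop = FALSE]) / N)^2 / 2
  P[1, ] <- P[1, ] / 4            # DC is not doubled
  power <- rowMeans(P)
  freqs <- (seq_len(npos) - 1) * ep$fs / N
  at <- function(f) {
    i <- which.min(abs(freqs - f))
    power[i]
  }
  structure(list(power = power, freqs = freqs, p10 = at(10), p80 = at(80),
                 n_trials = ntr),
            class = "spectrum_avg")
}

#' Phase-amplitude comodulogram
#'
#' For each phase frequency (4-20 Hz, step 1) and amplitude frequency
#' (30-100 Hz, step 5), epochs are concatenated, band-passed (brick-wall FFT),
#' and the instantaneous phase (sine convention) and amplitude envelope taken
#' from the analytic signal. With the Tort method, phases are binned into `K`
#' bins, bin-mean amplitudes are normalized to a distribution P, and
#' `MI = (log K - H(P)) / log K`. With `method = "mvl"` the normalized Canolty
#' mean vector length `|mean(A exp(i phi))| / mean(A)` is returned instead.
#'
#' @param ep an `epoch_set`, or a numeric vector with `fs` supplied.
#' @param fs sampling rate when `ep` is numeric.
#' @param f_phase phase-frequency grid centers, Hz.
#' @param f_amp amplitude-frequency grid centers, Hz.
#' @param K number of phase bins (Tort method).
#' @param phase_hbw half-bandwidth of the phase bands, Hz.
#' @param amp_hbw half-bandwidth of the amplitude bands, Hz.
#' @param method `"tort"` or `"mvl"`.
#' @return object of class `comodulogram`: `values` (phase x amplitude grid),
#'   `f_phase`, `f_amp`, `K`, `method`.
#' @export
pac_comodulogram <- function(ep, fs = NULL, f_phase = 4:20,
                             f_amp = seq(30, 100, by = 5), K = 18,
                             phase_hbw = 2, amp_hbw = 15,
                             method = c("tort", "mvl")) {
  method <- match.arg(method)
  if (inherits(ep, "epoch_set")) {
    if (nrow(ep$epochs) < 1) stop("no kept trials")
    x <- as.numeric(t(ep$epochs))
    fs <- ep$fs
  } else {
    stopifnot(is.numeric(ep), !is.null(fs))
    x <- ep
  }
  nyq <- fs / 2
  vals <- matrix(NA_real_, length(f_phase), length(f_amp),
                 dimnames = list(f_phase, f_amp))
  amps <- lapply(f_amp, function(fa)
    Mod(band_analytic(x, fs, max(0.5, fa - amp_hbw), min(nyq, fa + amp_hbw))))
  for (i in seq_along(f_phase)) {
    fp <- f_phase[i]
    ph <- sine_phase(band_analytic(x, fs, max(0.5, fp - phase_hbw),
                                   fp + phase_hbw))
    bin <- pmin(K, floor(ph / (2 * pi / K)) + 1L)
    for (j in seq_along(f_amp)) {
      vals[i, j] <- if (method == "tort") tort_mi(bin, amps[[j]], K)
                    else mvl_pac(ph, amps[[j]])
    }
  }
  structure(list(values = vals, f_phase = f_phase, f_amp = f_amp, K = K,
                 method = method),
            class = "comodulogram")
}

# Tort modulation index from precomputed phase-bin assignments.
tort_mi <- function(bin, amp, K) {
  pk <- vapply(seq_len(K), function(k) {
    a <- amp[bin == k]
    if (length(a) == 0) 0 else mean(a)
  }, numeric(1))
  tot <- sum(pk)
  if (tot <= 0) return(0)
  p <- pk / tot
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz]))
  (log(K) - H) / log(K)
}

mvl_pac <- function(phase, amp) {
  ma <- mean(amp)
  if (ma <= 0) return(0)
  Mod(mean(amp * exp(1i * phase))) / ma
}

#' Mean modulation index over the coupling window of interest
#'
#' Average over comodulogram cells with phase frequency in `phase_win` and
#' amplitude frequency in `amp_win` (defaults: 7-13 Hz x 70-90 Hz, a 7 x 5
#' sub-grid of the standard comodulogram).
#'
#' @param cm a [pac_comodulogram()] result.
#' @param phase_win,amp_win inclusive bounds, Hz.
#' @return scalar mean MI.
#' @export
pac_window_mean <- function(cm, phase_win = c(7, 13), amp_win = c(70, 90)) {
  stopifnot(inherits(cm, "comodulogram"))
  pi_ <- cm$f_phase >= phase_win[1] & cm$f_phase <= phase_win[2]
  ai <- cm$f_amp >= amp_win[1] & cm$f_amp <= amp_win[2]
  mean(cm$values[pi_, ai])
}

#' Detect saccades in an EOG trace
#'
#' Low-passes at `lp_hz`, computes velocity as the amplitude change over a
#' `win_ms` sliding step, thresholds its absolute value, and merges
#' supra-threshold runs closer than `refractory_ms`.
#'
#' @param eog numeric EOG trace, uV.
#' @param fs sampling rate, Hz.
#' @param threshold velocity threshold, uV per `win_ms`.
#' @param win_ms velocity step, ms.
#' @param refractory_ms merge window, ms.
#' @param lp_hz low-pass cutoff, Hz.
#' @return data.frame with `time_s` and `peak_velocity` per detected event.
#' @export
detect_saccades <- function(eog, fs, threshold = 25, win_ms = 10,
                            refractory_ms = 100, lp_hz = 30) {
  lp <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  x <- zero_phase_filter(eog, fs, list(lp))
  w <- max(1L, round(win_ms / 1000 * fs))
  v <- x[(w + 1):length(x)] - x[seq_len(length(x) - w)]
  above <- which(abs(v) > threshold)
  if (length(above) == 0)
    return(data.frame(time_s = numeric(0), peak_velocity = numeric(0)))
  refr <- round(refractory_ms / 1000 * fs)
  grp <- cumsum(c(1, diff(above) > refr))
  out <- lapply(split(above, grp), function(ii) {
    peak <- ii[which.max(abs(v[ii]))]
    data.frame(time_s = (peak + w / 2) / fs, peak_velocity = v[peak])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
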