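# Synthetic data generator: single-channel occipital EEG with 1/f background,
# an alpha rhythm with slowly drifting phase, gamma activity whose amplitude is
# modulated by alpha phase (controllable depth and preferred phase), a
# horizontal EOG channel with optional saccades, amplitude artifacts, and
# 4-AFC behavioral responses with condition x session effects.

#' Synthetic-subject specification
#'
#' Generative parameters for one simulated subject. Amplitudes are in microvolts.
#' `behavior_effect` and `alpha_boost` are 3 x 3 matrices (condition x session,
#' rows `sham/peak/trough`, columns `pre/post0/post10`) giving the additive
#' log-odds shift on accuracy and the multiplicative factor on alpha amplitude.
#'
#' @param alpha_amp alpha (10 Hz) component amplitude, uV.
#' @param gamma_amp gamma (80 Hz) component amplitude, uV.
#' @param pac_depth coupling depth kappa in [0, 1]: 0 = no phase-amplitude
#'   coupling, 1 = gamma fully silenced at the anti-preferred phase.
#' @param pac_phase preferred alpha phase phi0 (radians, sine convention) at
#'   which gamma amplitude is maximal; default 3*pi/2 (alpha troughs).
#' @param noise_1f_scale standard deviation of the 1/f background, uV.
#' @param white_sigma white-noise standard deviation, uV.
#' @param alpha_freq,gamma_freq component frequencies, Hz.
#' @param phase_jitter_sd alpha phase random-walk increment SD, rad/sqrt(s).
#' @param alpha_boost condition x session multiplicative factor on `alpha_amp`.
#' @param behavior_base list with `intercepts` (named by MAR size) and `slope`
#'   (log-odds per deg/s) of the accuracy model.
#' @param behavior_effect condition x session additive log-odds shift.
#' @param subject_sd between-subject SD of the behavioral intercept, log-odds.
#' @param artifact_frac fraction of trials receiving a >100 uV transient.
#' @param artifact_amp artifact transient peak amplitude, uV.
#' @param saccade_rate EOG saccades per minute.
#' @param saccade_amp saccade step amplitude, uV.
#' @param seed integer seed making the subject fully reproducible.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(alpha_amp = 10, gamma_amp = 2, pac_depth = 0.4,
                       pac_phase = 3 * pi / 2, noise_1f_scale = 8,
                       white_sigma = 2, alpha_freq = 10, gamma_freq = 80,
                       phase_jitter_sd = 0.5,
                       alpha_boost = matrix(1, 3, 3, dimnames = cs_dimnames()),
                       behavior_base = list(
                         intercepts = c(`3` = -0.5, `4` = 0.5, `5` = 1.3),
                         slope = 0.002),
                       behavior_effect = matrix(0, 3, 3,
                                                dimnames = cs_dimnames()),
                       subject_sd = 0.4,
                       artifact_frac = 0, artifact_amp = 150,
                       saccade_rate = 0, saccade_amp = 100, seed = 1L) {
  stopifnot(pac_depth >= 0, pac_depth <= 1,
            artifact_frac >= 0, artifact_frac < 1,
            saccade_rate >= 0)
  structure(as.list(environment()), class = "synth_spec")
}

cs_dimnames <- function() {
  list(c("sham", "peak", "trough"), c("pre", "post0", "post10"))
}

#' Preset synthetic-cohort effect structures
#'
#' `"null"`: no condition or session effect anywhere (type-I calibration).
#' `"moderate"`: the trough condition gains +1.0 log-odds of accuracy and a
#' 1.6x alpha-amplitude boost in both post-stimulation sessions; sham and peak
#' are unchanged. `"strong"`: +1.5 log-odds and 2.0x boost. Only the trough
#' post sessions ever deviate, mirroring the hypothesized trough-only effect.
#'
#' @param preset `"null"`, `"moderate"` or `"strong"`.
#' @param ... overrides forwarded to [synth_spec()].
#' @return a `synth_spec`.
#' @export
preset_spec <- function(preset = c("null", "moderate", "strong"), ...) {
  preset <- match.arg(preset)
  eff <- matrix(0, 3, 3, dimnames = cs_dimnames())
  boost <- matrix(1, 3, 3, dimnames = cs_dimnames())
  if (preset == "moderate") {
    eff["trough", c("post0", "post10")] <- 1.0
    boost["trough", c("post0", "post10")] <- 1.6
  } else if (preset == "strong") {
    eff["trough", c("post0", "post10")] <- 1.5
    boost["trough", c("post0", "post10")] <- 2.0
  }
  synth_spec(behavior_effect = eff, alpha_boost = boost, ...)
}

# 1/f-shaped noise: white Gaussian noise shaped in the frequency domain with
# power slope -1 (amplitude ~ f^(-1/2)), rescaled to unit SD.
pink_noise <- function(n, slope = 1) {
  m <- stats::nextn(n, c(2, 3, 5))     # FFT-friendly length, then truncate
  w <- stats::rnorm(m)
  X <- stats::fft(w)
  f <- (seq_len(m) - 1)
  f[f > m / 2] <- m - f[f > m / 2]
  shape <- c(0, f[-1]^(-slope / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE) / m)[seq_len(n)]
  x / stats::sd(x)
}

#' Generate a synthetic EEG recording for one task session
#'
#' EEG = 1/f background + boosted alpha with a random-walk phase + gamma whose
#' amplitude follows `(1 + kappa * cos(phase_alpha - phi0)) / (1 + kappa)` +
#' white noise. Stimulus-onset events are placed at the schedule onsets; the
#' free-running alpha phase walk and the uniformly jittered ISIs ensure onsets
#' are not phase-locked to alpha.
#'
#' @param spec a [synth_spec()].
#' @param schedule a [build_schedule()] schedule (possibly subset).
#' @param condition,session labels selecting the boost/effect cell.
#' @param fs sampling rate, Hz.
#' @param seed overrides `spec$seed` when given.
#' @param pad_s lead-in and tail padding, s (>= 1.5 so the first pre-stimulus
#'   epoch has history).
#' @return object of class `recording`: list with `eeg` (uV), `eog` (NULL
#'   here; see [gen_eog()]), `fs`, `events` (data.frame with `sample`,
#'   `onset_s` and trial metadata) and `meta`.
#' @export
gen_eeg <- function(spec, schedule, condition = "sham", session = "pre",
                    fs = 2048, seed = NULL, pad_s = 1.5) {
  stopifnot(inherits(spec, "synth_spec"), pad_s >= 1.5)
  seed <- if (is.null(seed)) spec$seed else seed
  dur <- pad_s + max(schedule$onset_s + schedule$duration_s) + pad_s
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1) / fs
  boost <- spec$alpha_boost[condition, session]
  x <- with_seed(seed, {
    bg <- spec$noise_1f_scale * pink_noise(n)
    phi <- 2 * pi * spec$alpha_freq * t +
      cumsum(stats::rnorm(n, 0, spec$phase_jitter_sd / sqrt(fs)))
    alpha <- spec$alpha_amp * boost * sin(phi)
    am <- (1 + spec$pac_depth * cos((phi %% (2 * pi)) - spec$pac_phase)) /
      (1 + spec$pac_depth)
    gamma <- spec$gamma_amp * am *
      sin(2 * pi * spec$gamma_freq * t + stats::runif(1, 0, 2 * pi))
    bg + alpha + gamma + stats::rnorm(n, 0, spec$white_sigma)
  })
  ev_sample <- round((pad_s + schedule$onset_s) * fs) + 1
  if (any(ev_sample > n)) stop("recording shorter than the schedule span")
  events <- data.frame(trial = schedule$trial, sample = ev_sample,
                       onset_s = pad_s + schedule$onset_s,
                       speed = schedule$speed, size = schedule$size,
                       gap_dir = schedule$gap_dir,
                       stringsAsFactors = FALSE)
  structure(list(eeg = x, eog = NULL, fs = fs, events = events,
                 meta = list(condition = condition, session = session,
                             seed = seed, pad_s = pad_s, boost = boost)),
            class = "recording")
}

#' Inject high-amplitude artifact transients into chosen trials
#'
#' Adds a Gaussian-envelope transient exceeding the 100 uV rejection threshold
#' inside the pre-stimulus (-1000 to 0 ms) window of a seeded random subset of
#' trials (`spec$artifact_frac`, or exactly `n_trials` when given).
#'
#' @param recording a [gen_eeg()] recording.
#' @param spec the [synth_spec()] used (for `artifact_frac`, `artifact_amp`).
#' @param n_trials exact number of artifact trials (overrides the fraction).
#' @param seed overrides `spec$seed`.
#' @return list with the modified `recording` and `artifact_trials` (ground
#'   truth trial ids, sorted).
#' @export
inject_artifacts <- function(recording, spec, n_trials = NULL, seed = NULL) {
  stopifnot(inherits(recording, "recording"))
  seed <- if (is.null(seed)) spec$seed + 7L else seed
  ntr <- nrow(recording$events)
  k <- if (!is.null(n_trials)) n_trials else round(spec$artifact_frac * ntr)
  if (k == 0)
    return(list(recording = recording, artifact_trials = integer(0)))
  fs <- recording$fs
  picks <- with_seed(seed, list(
    trials = sort(sample.int(ntr, k)),
    at = stats::runif(k, -0.9, -0.1),
    sign = sample(c(-1, 1), k, replace = TRUE)))
  width <- round(0.02 * fs)             # 20 ms Gaussian sigma
  support <- seq(-3 * width, 3 * width)
  bump <- exp(-0.5 * (support / width)^2)
  for (i in seq_len(k)) {
    center <- recording$events$sample[picks$trials[i]] +
      round(picks$at[i] * fs)
    idx <- center + support
    ok <- idx >= 1 & idx <= length(recording$eeg)
    recording$eeg[idx[ok]] <- recording$eeg[idx[ok]] +
      picks$sign[i] * spec$artifact_amp * bump[ok]
  }
  list(recording = recording,
       artifact_trials = recording$events$trial[picks$trials])
}

#' Generate a synthetic horizontal EOG trace
#'
#' Slow baseline drift plus step-like saccades (sigmoidal rise of 10-50 ms) at
#' Poisson times with alternating direction, plus a little measurement noise.
#'
#' @param spec a [synth_spec()].
#' @param duration_s trace duration, s.
#' @param fs sampling rate, Hz.
#' @param seed overrides `spec$seed`.
#' @param drift_amp peak drift amplitude, uV.
#' @return list with `eog` (uV), `fs` and `saccade_times` (s, ground truth).
#' @export
gen_eog <- function(spec, duration_s, fs = 2048, seed = NULL,
                    drift_amp = 30) {
  seed <- if (is.null(seed)) spec$seed + 13L else seed
  n <- ceiling(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    drift <- drift_amp * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi)) +
      drift_amp / 3 * sin(2 * pi * 0.27 * t + stats::runif(1, 0, 2 * pi))
    x <- drift + stats::rnorm(n, 0, 1)
    n_sac <- stats::rpois(1, spec$saccade_rate * duration_s / 60)
    times <- sort(stats::runif(n_sac, 0.5, duration_s - 0.5))
    if (n_sac > 0) {
      rise <- stats::runif(n_sac, 0.010, 0.050)
      dirs <- rep_len(c(1, -1), n_sac)
      for (i in seq_len(n_sac)) {
        step <- dirs[i] * spec$saccade_amp /
          (1 + exp(-(t - times[i]) / (rise[i] / 8)))
        x <- x + step
      }
    }
    list(eog = x, fs = fs, saccade_times = times)
  })
}

#' Generate behavioral responses for one session
#'
#' Accuracy follows a guessing-floored logistic model:
#' `P(correct) = 0.25 + 0.75 * logistic(intercept_size - slope * speed +
#' subject_shift + delta[condition, session])`. Wrong answers are uniform over
#' the remaining three gap directions.
#'
#' @param spec a [synth_spec()].
#' @param schedule a [build_schedule()] schedule.
#' @param condition,session labels selecting the effect cell.
#' @param seed overrides `spec$seed`.
#' @param subject_shift subject-level log-odds intercept shift.
#' @return data.frame with `response`, `correct` and `p_correct` per trial.
#' @export
gen_behavior <- function(spec, schedule, condition = "sham", session = "pre",
                         seed = NULL, subject_shift = 0) {
  seed <- if (is.null(seed)) spec$seed + 29L else seed
  delta <- spec$behavior_effect[condition, session]
  a <- spec$behavior_base$intercepts[as.character(schedule$size)]
  eta <- a - spec$behavior_base$slope * schedule$speed + subject_shift + delta
  p <- 0.25 + 0.75 * stats::plogis(eta)
  dirs <- c("up", "down", "left", "right")
  with_seed(seed, {
    correct <- stats::runif(nrow(schedule)) < p
    response <- ifelse(correct, schedule$gap_dir, NA)
    for (i in which(!correct))
      response[i] <- sample(setdiff(dirs, schedule$gap_dir[i]), 1)
    data.frame(response = response, correct = correct, p_correct = p,
               stringsAsFactors = FALSE)
  })
}

#' Write / read a recording as plain-text TSV
#'
#' Serializes the sample traces and the event table side by side; a small JSON
#' sidecar carries `fs` and metadata. Plain text keeps recordings portable and
#' diffable; for the long traces this trades size for transparency.
#'
#' @param recording a `recording`.
#' @param path base path; writes `<path>_signals.tsv`, `<path>_events.tsv`,
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  sig <- data.table::data.table(eeg = recording$eeg)
  if (!is.null(recording$eog)) sig$eog <- recording$eog
  data.table::fwrite(sig, paste0(path, "_signals.tsv"), sep = "\t")
  data.table::fwrite(recording$events, paste0(path, "_events.tsv"), sep = "\t")
  jsonlite::write_json(list(fs = recording$fs, meta = recording$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sig <- data.table::fread(paste0(path, "_signals.tsv"), sep = "\t")
  events <- as.data.frame(data.table::fread(paste0(path, "_events.tsv"),
                                            sep = "\t"))
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(eeg = sig$eeg,
                 eog = if ("eog" %in% names(sig)) sig$eog else NULL,
                 fs = hdr$fs, events = events, meta = hdr$meta),
            class = "recording")
}
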