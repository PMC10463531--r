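# Cohort-level simulation: schedules, behavior and (optionally) EEG features
# for n subjects x 3 conditions x 3 sessions, returned as the long measure
# table the statistical plan consumes.

#' Simulate a full experimental cohort
#'
#' Generates, per subject x condition x session, a DVA schedule, behavioral
#' responses under the spec's effect structure, and (optionally) a synthetic
#' EEG recording run through the feature pipeline (preprocess, epoch/reject,
#' power spectrum, optionally PAC window mean and ITPC windows). Behavioral
#' accuracy is always computed on the full 144-trial schedule; EEG may be
#' generated for a seeded subset of trials (`n_trials_eeg`) and a lower
#' sampling rate (`fs`) to keep large replicate studies tractable.
#'
#' @param n_subjects behavioral cohort size.
#' @param spec a [synth_spec()] (e.g. from [preset_spec()]); per-subject seeds
#'   and behavioral intercept shifts are derived from `seed`.
#' @param seed master seed for the cohort.
#' @param n_eeg_subjects subjects with usable EEG (default all but one,
#'   mirroring one recording-error exclusion).
#' @param fs EEG sampling rate, Hz.
#' @param n_trials_eeg trials per session entering the EEG simulation.
#' @param features character subset of `c("power", "pac", "itpc")`; empty for
#'   behavior only.
#' @param artifact_frac fraction of EEG trials receiving artifacts.
#' @return list with `measures` (long data.frame: subject, condition, session,
#'   measure, value), `rejections` (per-recording artifact counts) and `seed`.
#' @export
simulate_cohort <- function(n_subjects = 17, spec = preset_spec("moderate"),
                            seed = 1L, n_eeg_subjects = n_subjects - 1,
                            fs = 2048, n_trials_eeg = 144,
                            features = "power", artifact_frac = 0) {
  conditions <- c("sham", "peak", "trough")
  sessions <- c("pre", "post0", "post10")
  seeds <- derive_seeds(seed, n_subjects * 9 * 4 + n_subjects)
  shift <- with_seed(seeds[length(seeds)],
                     stats::rnorm(n_subjects, 0, spec$subject_sd))
  si <- 0
  rows <- list()
  rejections <- list()
  for (s in seq_len(n_subjects)) {
    for (cond in conditions) for (sess in sessions) {
      sd4 <- seeds[si + 1:4]; si <- si + 4
      sched <- build_schedule(sess, seed = sd4[1])
      beh <- gen_behavior(spec, sched, cond, sess, seed = sd4[2],
                          subject_shift = shift[s])
      acc <- score(sched, beh)
      vals <- c(overall = acc$overall, acc$by_size)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, condition = cond, session = sess,
        measure = names(vals), value = as.numeric(vals),
        stringsAsFactors = FALSE)
      if (length(features) > 0 && s <= n_eeg_subjects) {
        es <- sched
        if (n_trials_eeg < nrow(sched)) {
          # seeded subset, compacted: onsets re-cumulated so the simulated
          # recording is genuinely shorter
          keep <- with_seed(sd4[3], sort(sample.int(nrow(sched), n_trials_eeg)))
          es <- sched[keep, , drop = FALSE]
          es$onset_s <- cumsum(es$isi_s) +
            cumsum(c(0, es$duration_s[-nrow(es)]))
        }
        rec <- gen_eeg(spec, es, cond, sess, fs = fs, seed = sd4[4])
        if (artifact_frac > 0) {
          spec2 <- spec; spec2$artifact_frac <- artifact_frac
          rec <- inject_artifacts(rec, spec2, seed = sd4[4] + 1L)$recording
        }
        rec <- preprocess(rec)
        ep <- epoch_and_reject(rec)
        rejections[[length(rejections) + 1]] <- data.frame(
          subject = s, condition = cond, session = sess,
          rejected = length(ep$rejected_trial_ids),
          kept = length(ep$kept_trial_ids))
        fvals <- c()
        if ("power" %in% features) {
          sp <- power_spectrum(ep)
          fvals <- c(fvals, power10 = sp$p10, power80 = sp$p80)
        }
        if ("pac" %in% features) {
          cm <- pac_comodulogram(ep)
          fvals <- c(fvals, pac = pac_window_mean(cm))
        }
        if ("itpc" %in% features) {
          wm <- window_mean(itpc(ep))
          fvals <- c(fvals, wm)
        }
        if (length(fvals))
          rows[[length(rows) + 1]] <- data.frame(
            subject = s, condition = cond, session = sess,
            measure = names(fvals), value = as.numeric(fvals),
            stringsAsFactors = FALSE)
      }
    }
  }
  list(measures = do.call(rbind, rows),
       rejections = if (length(rejections)) do.call(rbind, rejections) else NULL,
       seed = seed)
}
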