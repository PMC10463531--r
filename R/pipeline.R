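# End-to-end orchestration: config validation, the full simulate -> features ->
# statistics pipeline, and the report surfaces (accuracy table, ITPC window
# table, spectra scalars, PAC distribution, stat-plan table).

#' Experiment configuration
#'
#' Defaults mirror the study design: 17 behavioral subjects (16 with usable
#' EEG), 10 Hz alpha / 80 Hz gamma stimulation, 2048 Hz sampling, 144 trials
#' per session. `fs` and `n_trials_eeg` may be reduced for tractable
#' simulation studies.
#'
#' @param preset synthetic-effect preset (see [preset_spec()]).
#' @param n_subjects behavioral cohort size.
#' @param n_eeg_subjects subjects with usable EEG.
#' @param fs EEG sampling rate, Hz.
#' @param n_trials_eeg trials per session entering EEG simulation.
#' @param features EEG features to compute (`"power"`, `"pac"`, `"itpc"`).
#' @param artifact_frac fraction of EEG trials with injected artifacts.
#' @param alpha decision level.
#' @param fdr_scope `"per-measure"` or `"global"`.
#' @param seed master seed.
#' @param alpha_freq,gamma_freq stimulation frequencies, Hz (validated).
#' @param out_dir optional output directory for [run_all()].
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(preset = "moderate", n_subjects = 17,
                              n_eeg_subjects = n_subjects - 1, fs = 2048,
                              n_trials_eeg = 144,
                              features = c("power", "pac", "itpc"),
                              artifact_frac = 0, alpha = 0.05,
                              fdr_scope = "per-measure", seed = 1L,
                              alpha_freq = 10, gamma_freq = 80,
                              out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  validate_config(cfg)
}

#' Validate and normalize an experiment configuration
#'
#' Fills defaults for a plain list, checks ranges and the Nyquist constraint,
#' and returns the normalized config. All violations are reported together.
#'
#' @param config an `experiment_config` or plain named list of overrides.
#' @return the normalized `experiment_config`.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "experiment_config")) {
    known <- names(formals(experiment_config))
    unknown <- setdiff(names(config), known)
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    return(do.call(experiment_config, config))
  }
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(config$preset %in% c("null", "moderate", "strong"),
      "preset must be null/moderate/strong")
  chk(config$n_subjects >= 2, "n_subjects must be >= 2")
  chk(config$n_eeg_subjects >= 0 && config$n_eeg_subjects <= config$n_subjects,
      "n_eeg_subjects out of range")
  chk(config$alpha_freq > 0, "alpha_freq must be positive")
  chk(config$gamma_freq > config$alpha_freq, "gamma_freq must exceed alpha_freq")
  chk(config$fs > 2 * config$gamma_freq,
      "fs must exceed twice gamma_freq (Nyquist)")
  chk(config$n_trials_eeg >= 1 && config$n_trials_eeg <= 144,
      "n_trials_eeg must be in 1..144")
  chk(config$artifact_frac >= 0 && config$artifact_frac < 1,
      "artifact_frac must be in [0, 1)")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(all(config$features %in% c("power", "pac", "itpc")),
      "features must be a subset of power/pac/itpc")
  if (length(errs)) stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  config
}

#' Run the complete simulated experiment
#'
#' Stages: a waveform-synthesis check (build and verify the trough- and
#' peak-condition sessions at short plateau), cohort simulation, the feature
#' pipeline, the statistical plan, and report assembly. Deterministic given
#' the config (which carries the master seed); when `config$out_dir` is set,
#' all report tables are written there as TSV/JSON.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_report`: `accuracy_table`,
#'   `itpc_window_table` (when ITPC was computed), `power_table`, `pac_table`,
#'   `stat_results`, `waveform_check`, `rejections`, `provenance`.
#' @export
run_all <- function(config) {
  config <- validate_config(config)
  spec <- preset_spec(config$preset, alpha_freq = config$alpha_freq,
                      gamma_freq = config$gamma_freq)

  # stage 1: waveform synthesis check (short plateau; verification only)
  wf_check <- lapply(c(trough = "trough", peak = "peak"), function(cond) {
    p <- stim_params(cond, alpha_freq = config$alpha_freq,
                     gamma_freq = config$gamma_freq, ramp_s = 2,
                     plateau_s = 10, fs = max(config$fs, 1024))
    w <- build_session(p)
    v <- verify_entrainment(w)
    target <- mean(canonical_interval(cond))
    list(preferred_phase = v$preferred_phase,
         concentration = v$concentration,
         target_phase = target,
         phase_error = circ_dist(v$preferred_phase, target),
         plateau_pkpk = {
           seg <- w$segments
           pl <- seg[seg$label == "plateau", ]
           max(w$samples[pl$start:pl$end]) - min(w$samples[pl$start:pl$end])
         })
  })

  # stage 2-3: cohort simulation + features
  sim <- simulate_cohort(config$n_subjects, spec, seed = config$seed,
                         n_eeg_subjects = config$n_eeg_subjects,
                         fs = config$fs, n_trials_eeg = config$n_trials_eeg,
                         features = config$features,
                         artifact_frac = config$artifact_frac)

  # stage 4: statistics
  res <- run_stat_plan(sim$measures, alpha = config$alpha,
                       fdr_scope = config$fdr_scope)

  # stage 5: report tables
  meas <- sim$measures
  med_table <- function(which_measures) {
    d <- meas[meas$measure %in% which_measures, ]
    if (nrow(d) == 0) return(NULL)
    out <- stats::aggregate(value ~ measure + condition + session, d, stats::median)
    names(out)[names(out) == "value"] <- "median"
    out[order(out$measure, out$condition, out$session), ]
  }
  accuracy_table <- med_table(c("overall", "size3", "size4", "size5"))
  power_table <- med_table(c("power10", "power80"))
  pac_table <- med_table("pac")
  itpc_ms <- grep("^itpc_", unique(meas$measure), value = TRUE)
  itpc_window_table <- NULL
  if (length(itpc_ms)) {
    fr <- res[res$test == "friedman_session" & res$measure %in% itpc_ms,
              c("measure", "condition", "statistic", "raw_p", "decision")]
    itpc_window_table <- fr[order(fr$measure, fr$condition), ]
  }

  report <- structure(list(
    accuracy_table = accuracy_table,
    power_table = power_table,
    pac_table = pac_table,
    itpc_window_table = itpc_window_table,
    stat_results = res,
    waveform_check = wf_check,
    rejections = sim$rejections,
    provenance = list(config = unclass(config),
                      package_version = as.character(utils::packageVersion("pactacs")))),
    class = "experiment_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) if (!is.null(x))
      data.table::fwrite(as.data.frame(x), file.path(config$out_dir, f),
                         sep = "\t")
    wt(accuracy_table, "accuracy_table.tsv")
    wt(power_table, "power_table.tsv")
    wt(pac_table, "pac_table.tsv")
    wt(itpc_window_table, "itpc_window_table.tsv")
    write_stat_plan(res, file.path(config$out_dir, "stat_results.tsv"),
                    file.path(config$out_dir, "stat_summary.json"))
    jsonlite::write_json(report$provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  cat(sprintf("  stat tests run: %d (%d significant)\n",
              nrow(x$stat_results), sum(x$stat_results$decision, na.rm = TRUE)))
  for (cond in names(x$waveform_check)) {
    wc <- x$waveform_check[[cond]]
    cat(sprintf("  waveform %s: preferred phase %.3f rad (target %.3f), R=%.2f, plateau pk-pk %.3f mA\n",
                cond, wc$preferred_phase, wc$target_phase, wc$concentration,
                wc$plateau_pkpk))
  }
  invisible(x)
}
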