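# The computerized dynamic-visual-acuity (DVA) task: a full-factorial trial
# schedule of moving Landolt-C stimuli and 4-alternative forced-choice scoring.

# Factor level sets of the task design.
dva_factors <- function() {
  list(speed = seq(200, 700, by = 100),
       move_dir = c("LR", "RL"),
       gap_dir = c("up", "down", "left", "right"),
       size = c(3, 4, 5))
}

#' Build one DVA session schedule
#'
#' Enumerates the full 6 (speed) x 2 (movement direction) x 4 (gap direction)
#' x 3 (MAR size) factorial exactly once — 144 trials — and shuffles it with a
#' seeded permutation. Inter-stimulus intervals are drawn uniform on
#' [1.5, 2.5] s; stimulus duration is the +-10 degree sweep divided by speed;
#' onsets are cumulated. Display metadata (240 Hz monitor, 70 cm viewing
#' distance, +-10 degree sweep) is attached as attributes only; nothing is
#' rendered.
#'
#' @param session_label `"pre"`, `"post0"` or `"post10"`.
#' @param seed integer seed controlling the permutation and the ISIs.
#' @return a `data.frame` of class `dva_schedule`, one row per trial, with
#'   columns `trial`, `onset_s`, `duration_s`, `isi_s`, `speed`, `move_dir`,
#'   `gap_dir`, `size`, `session_label`.
#' @export
build_schedule <- function(session_label = c("pre", "post0", "post10"), seed) {
  session_label <- match.arg(session_label)
  stopifnot(is.numeric(seed), length(seed) == 1)
  fct <- dva_factors()
  grid <- expand.grid(speed = fct$speed, move_dir = fct$move_dir,
                      gap_dir = fct$gap_dir, size = fct$size,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  rnd <- with_seed(seed, list(ord = sample.int(n), isi = stats::runif(n, 1.5, 2.5)))
  trials <- grid[rnd$ord, , drop = FALSE]
  sweep_deg <- 20
  dur <- sweep_deg / trials$speed
  onset <- cumsum(rnd$isi) + cumsum(c(0, dur[-n]))
  out <- data.frame(trial = seq_len(n), onset_s = onset, duration_s = dur,
                    isi_s = rnd$isi, trials, session_label = session_label,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "display") <- list(refresh_hz = 240, distance_cm = 70,
                               sweep_deg = c(-10, 10))
  attr(out, "seed") <- seed
  class(out) <- c("dva_schedule", "data.frame")
  out
}

#' Score DVA responses
#'
#' @param schedule a [build_schedule()] schedule.
#' @param responses a data.frame with one row per trial and either a logical
#'   `correct` column or a `response` column in
#'   `c("up","down","left","right")` to be compared with the scheduled gap
#'   direction.
#' @return list with `overall` accuracy, `by_size` (named vector over MAR
#'   sizes) and `n_trials`.
#' @export
score <- function(schedule, responses) {
  if (nrow(responses) != nrow(schedule))
    stop("response count does not match trial count")
  correct <- if ("correct" %in% names(responses)) as.logical(responses$correct)
             else responses$response == schedule$gap_dir
  by_size <- tapply(correct, schedule$size, mean)
  list(overall = mean(correct),
       by_size = stats::setNames(as.numeric(by_size),
                                 paste0("size", names(by_size))),
       n_trials = nrow(schedule))
}

#' Screen subjects for below-chance performance
#'
#' A subject's size-specific analyses are flagged for exclusion when that
#' size's accuracy stays below chance (0.25) in all three sessions of any one
#' stimulation condition. Subjects with missing sessions are flagged as
#' incomplete rather than excluded.
#'
#' @param acc long data.frame with columns `subject`, `condition`, `session`,
#'   `measure` (e.g. `"size3"`) and `accuracy`.
#' @param chance chance level; default 0.25 (4-AFC).
#' @param n_sessions sessions expected per condition; default 3.
#' @return data.frame with one row per subject x measure: `excluded`,
#'   `incomplete`, and the triggering `condition` (or `NA`).
#' @export
screen_exclusions <- function(acc, chance = 0.25, n_sessions = 3) {
  stopifnot(all(c("subject", "condition", "session", "measure", "accuracy")
                %in% names(acc)))
  out <- list()
  for (sub in unique(acc$subject)) for (ms in unique(acc$measure)) {
    d <- acc[acc$subject == sub & acc$measure == ms, ]
    incomplete <- any(tapply(d$session, d$condition,
                             function(s) length(unique(s))) < n_sessions)
    trigger <- NA_character_
    excluded <- FALSE
    if (!incomplete) {
      below <- tapply(d$accuracy, d$condition, function(a) all(a < chance))
      if (any(below)) {
        excluded <- TRUE
        trigger <- names(below)[which(below)[1]]
      }
    }
    out[[length(out) + 1]] <- data.frame(
      subject = sub, measure = ms, excluded = excluded,
      incomplete = incomplete, condition = trigger,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write / read a schedule-with-responses table as TSV
#'
#' BIDS-events-like layout: one row per trial with onset, duration, trial
#' factors and (optionally) response and correctness.
#'
#' @param schedule a `dva_schedule`.
#' @param responses optional response table matched by row.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, responses = NULL) {
  out <- as.data.frame(schedule)
  if (!is.null(responses)) out <- cbind(out, responses)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
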