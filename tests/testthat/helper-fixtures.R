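# Small shared test utilities.

# absolute circular distance (radians)
circ_dist_t <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  min(d, 2 * pi - d)
}

# long-format accuracy record for screen_exclusions
acc_record <- function(subject, condition, sessions = c("pre", "post0", "post10"),
                       measure, accuracy) {
  data.frame(subject = subject, condition = condition, session = sessions,
             measure = measure, accuracy = accuracy, stringsAsFactors = FALSE)
}
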