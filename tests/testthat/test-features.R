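test_that("preprocessing removes DC and line noise and keeps the alpha band", {
  fs <- 1024
  t <- seq(0, 8, by = 1 / fs)
  mid <- seq(2 * fs, 6 * fs)
  dc <- preprocess(rep(50, length(t)), fs = fs)
  expect_lt(abs(mean(dc)), 0.5)
  line <- preprocess(sin(2 * pi * 60 * t), fs = fs)
  expect_lt(20 * log10(max(abs(line[mid]))), -20)
  alpha <- preprocess(sin(2 * pi * 10 * t), fs = fs)
  expect_equal(max(abs(alpha[mid])), 1, tolerance = 0.05)
  expect_error(preprocess(rep(0, 100), fs = 128), "notch")
})

test_that("epoching rejects exactly the supra-threshold trials at the boundary", {
  fs <- 512
  n <- 30 * fs
  eeg <- rep(0.5, n)
  events <- data.frame(trial = 1:4,
                       sample = c(2 * fs, 10 * fs, 18 * fs, 26 * fs))
  # single-sample spikes just above / below threshold inside the window
  eeg[10 * fs - fs %/% 2] <- 100.1
  eeg[18 * fs - fs %/% 2] <- 99.9
  rec <- structure(list(eeg = eeg, fs = fs, events = events, meta = list()),
                   class = "recording")
  ep <- epoch_and_reject(rec)
  expect_equal(ep$rejected_trial_ids, 2)
  expect_setequal(ep$kept_trial_ids, c(1, 3, 4))
  expect_lte(max(abs(ep$epochs)), 100)
  expect_equal(ncol(ep$epochs), fs)
  # an event too close to the trace start is invalid, not dropped silently
  events2 <- rbind(data.frame(trial = 0, sample = round(0.2 * fs)), events)
  rec2 <- structure(list(eeg = eeg, fs = fs, events = events2, meta = list()),
                    class = "recording")
  ep2 <- epoch_and_reject(rec2)
  expect_equal(ep2$invalid_trial_ids, 0)
})

test_that("identical trials give ITPC 1; phase scrambling brings it to the Rayleigh level", {
  fs <- 256
  pad <- round(0.5 * fs)
  one <- sin(2 * pi * 10 * (0:(fs + 2 * pad - 1)) / fs) +
    0.3 * sin(2 * pi * 40 * (0:(fs + 2 * pad - 1)) / fs)
  ep_same <- epoch_set_from_padded(matrix(rep(one, 8), 8, byrow = TRUE), fs)
  m <- itpc(ep_same, freqs = c(5, 10, 40, 80), decim = 4)
  expect_true(all(m$values > 1 - 1e-9))
  # i.i.d. uniform phases at 10 Hz across 100 trials
  set.seed(42)
  trials <- t(sapply(1:100, function(i)
    sin(2 * pi * 10 * (0:(fs + 2 * pad - 1)) / fs + runif(1, 0, 2 * pi))))
  ep_rand <- epoch_set_from_padded(trials, fs)
  m2 <- itpc(ep_rand, freqs = 10, decim = 4)
  expect_equal(mean(m2$values), sqrt(pi) / 2 / sqrt(100), tolerance = 0.25)
})

test_that("ITPC is invariant to per-trial amplitude scaling", {
  fs <- 256
  pad <- round(0.5 * fs)
  set.seed(43)
  trials <- t(sapply(1:12, function(i)
    sin(2 * pi * 11 * (0:(fs + 2 * pad - 1)) / fs + runif(1, 0, 2 * pi)) +
      rnorm(fs + 2 * pad, 0, 0.2)))
  ep1 <- epoch_set_from_padded(trials, fs)
  scales <- runif(12, 0.1, 10)
  ep2 <- epoch_set_from_padded(trials * scales, fs)
  m1 <- itpc(ep1, freqs = c(6, 11, 30), decim = 8)
  m2 <- itpc(ep2, freqs = c(6, 11, 30), decim = 8)
  expect_equal(m1$values, m2$values, tolerance = 1e-6)
})

test_that("window means equal brute-force averages and cover six windows", {
  fs <- 256
  pad <- round(0.5 * fs)
  set.seed(44)
  trials <- matrix(rnorm(6 * (fs + 2 * pad)), 6)
  ep <- epoch_set_from_padded(trials, fs)
  m <- itpc(ep, freqs = 1:100, decim = 4)
  wm <- window_mean(m)
  expect_length(wm, 6)
  w <- itpc_windows()
  for (i in seq_len(6)) {
    fi <- which(m$freqs >= w$f_lo[i] & m$freqs <= w$f_hi[i])
    ti <- which(m$times >= w$t_lo[i] & m$times <= w$t_hi[i])
    brute <- mean(m$values[fi, ti])
    expect_equal(unname(wm[i]), brute)
  }
  const <- m
  const$values[] <- 0.37
  expect_equal(unname(window_mean(const)), rep(0.37, 6))
  bad <- itpc_windows()
  bad$f_lo[1] <- 150; bad$f_hi[1] <- 160
  expect_error(window_mean(m, bad), "outside")
})

test_that("power spectrum is A^2-scaled at the sinusoid bin and flat for white noise", {
  fs <- 256
  pad <- round(0.5 * fs)
  mk <- function(A) {
    tr <- t(sapply(1:4, function(i)
      A * sin(2 * pi * 10 * (0:(fs + 2 * pad - 1)) / fs)))
    power_spectrum(epoch_set_from_padded(tr, fs))
  }
  s1 <- mk(2)
  expect_equal(s1$p10, 2^2 / 2, tolerance = 1e-9)
  expect_lt(s1$power[s1$freqs == 20], 1e-12)
  s2 <- mk(4)
  expect_equal(s2$p10 / s1$p10, 4, tolerance = 0.01)
  set.seed(45)
  wn <- matrix(rnorm(300 * (fs + 2 * pad)), 300)
  sw <- power_spectrum(epoch_set_from_padded(wn, fs))
  band <- sw$power[sw$freqs >= 5 & sw$freqs <= 95]
  expect_lt(10 * log10(max(band) / min(band)), 3)
})

test_that("modulation index hits its analytic limits", {
  # uniform phase-amplitude relation: MI ~ 0 on a 60 s fixture
  fs <- 256
  set.seed(46)
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 80 * t) + rnorm(n, 0, 0.1)
  cm <- pac_comodulogram(x, fs = fs, f_phase = c(8, 10, 12),
                         f_amp = c(70, 80, 90))
  expect_lt(max(cm$values), 0.01)
  # all amplitude concentrated in one phase bin: MI = 1
  expect_equal(pactacs:::tort_mi(rep(1L, 500), rep(2, 500), 18), 1)
  # amplitude uniform over bins: MI = 0
  bins <- rep(1:18, each = 30)
  expect_equal(pactacs:::tort_mi(bins, rep(1, length(bins)), 18), 0)
})

test_that("modulation index is invariant to amplitude scale and phase rotation", {
  fs <- 256
  set.seed(47)
  n <- 30 * fs
  t <- (0:(n - 1)) / fs
  phi <- 2 * pi * 10 * t
  noise <- rnorm(n, 0, 0.05)
  mk <- function(phi0, gain) {
    gain * ((1 + 0.8 * cos(phi - phi0)) / 1.8 * sin(2 * pi * 80 * t) +
              2 * sin(phi) + noise)
  }
  base <- pac_comodulogram(mk(3 * pi / 2, 1), fs = fs, f_phase = 10, f_amp = 80)
  scaled <- pac_comodulogram(mk(3 * pi / 2, 7), fs = fs, f_phase = 10, f_amp = 80)
  rotated <- pac_comodulogram(mk(pi / 2, 1), fs = fs, f_phase = 10, f_amp = 80)
  expect_equal(base$values[1, 1], scaled$values[1, 1], tolerance = 1e-3)
  expect_equal(base$values[1, 1], rotated$values[1, 1], tolerance = 0.15 * base$values[1, 1])
  # mean-vector-length variant responds to the same coupling
  mvl <- pac_comodulogram(mk(3 * pi / 2, 1), fs = fs, f_phase = 10, f_amp = 80,
                          method = "mvl")
  expect_gt(mvl$values[1, 1], 0.1)
})

test_that("PAC window mean covers the 7 x 5 sub-grid", {
  vals <- matrix(0, 17, 15, dimnames = list(4:20, seq(30, 100, 5)))
  cm <- structure(list(values = vals, f_phase = 4:20,
                       f_amp = seq(30, 100, 5), K = 18, method = "tort"),
                  class = "comodulogram")
  expect_equal(pac_window_mean(cm), 0)
  cm$values["10", "80"] <- 35
  expect_equal(pac_window_mean(cm), 1)   # 35 / (7*5)
  cm$values[] <- 0.2
  expect_equal(pac_window_mean(cm), 0.2)
})

test_that("saccade detector ignores flat traces and slow drift", {
  fs <- 512
  expect_equal(nrow(detect_saccades(rep(3, 20 * fs), fs)), 0)
  t <- (0:(60 * fs - 1)) / fs
  drift <- 200 * sin(2 * pi * 0.2 * t)
  expect_equal(nrow(detect_saccades(drift, fs)), 0)
  # ten clean 100 uV steps
  x <- rep(0, 60 * fs)
  at <- seq(5, 50, by = 5) * fs
  for (a in at) x[a:length(x)] <- x[a:length(x)] + 100 * rep_len(c(1, -1), 1)
  x <- rep(0, 60 * fs)
  sgn <- 1
  for (a in at) { x[a:length(x)] <- x[a:length(x)] + sgn * 100; sgn <- -sgn }
  det <- detect_saccades(x, fs)
  expect_gte(nrow(det), 9)
})
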