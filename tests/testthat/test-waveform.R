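test_that("canonical entrainment intervals match the published phase windows", {
  expect_equal(canonical_interval("trough"), c(17 * pi / 16, 31 * pi / 16))
  expect_equal(canonical_interval("peak"), c(pi / 16, 15 * pi / 16))
  # midpoints sit on the carrier extrema under the sine convention
  expect_equal(mean(canonical_interval("trough")), 3 * pi / 2)
  expect_equal(mean(canonical_interval("peak")), pi / 2)
  expect_equal(canonical_interval("peak", intervals = "methods"),
               c(pi / 8, 3 * pi / 8))
  expect_error(canonical_interval("sham"), "no entrainment interval")
})

test_that("the methods-section intervals cannot hold the default burst", {
  expect_error(stim_params("trough", intervals = "methods"), "does not fit")
  # a one-cycle burst fits the pi/4-wide slot exactly
  expect_silent(stim_params("trough", intervals = "methods",
                            n_gamma_cycles = 1))
})

test_that("burst template has the designed duration, amplitude and taper", {
  b <- synth_burst(stim_params("trough"))
  expect_equal(b$duration_s, 3 / 80)        # 37.5 ms
  expect_equal(b$samples[1], 0)
  expect_equal(b$samples[length(b$samples)], 0)
  expect_lte(max(abs(b$samples)), 1.2 / 2 + 1e-12)
  b1 <- synth_burst(stim_params("trough", gamma_freq = 10, n_gamma_cycles = 1,
                                entrain_interval = c(0, 2 * pi)))
  expect_equal(b1$duration_s, 0.1)          # one 10 Hz period
  expect_error(synth_burst(stim_params("sham")), "no gamma burst")
  # a burst longer than one alpha period is rejected at construction
  expect_error(stim_params("trough", gamma_freq = 20, n_gamma_cycles = 3,
                           entrain_interval = c(0, 2 * pi)),
               "does not fit")
})

test_that("session waveform has the designed segment structure and amplitudes", {
  w <- build_session(stim_params("trough", ramp_s = 2, plateau_s = 30))
  seg <- w$segments
  expect_equal(seg$label, c("ramp_up", "plateau", "ramp_down"))
  # contiguous, non-overlapping, covering
  expect_equal(seg$start[-1], seg$end[-nrow(seg)] + 1L)
  expect_equal(seg$start[1], 1L)
  expect_equal(seg$end[nrow(seg)], length(w$samples))
  expect_equal(w$samples[1], 0)
  expect_equal(w$samples[length(w$samples)], 0)
  pl <- w$samples[seg$start[2]:seg$end[2]]
  expect_equal(max(pl) - min(pl), 3.0, tolerance = 1e-12)
  expect_equal((seg$end[2] - seg$start[2]) / w$fs, 30, tolerance = 1e-3)
})

test_that("plateau peak-to-peak equals the composite target across rates", {
  for (fs in c(1024, 1500, 2048, 4096)) {
    w <- build_session(stim_params("trough", ramp_s = 0.5, plateau_s = 4,
                                   fs = fs))
    seg <- w$segments
    pl <- w$samples[seg$start[2]:seg$end[2]]
    expect_equal(max(pl) - min(pl), 3.0, tolerance = 1e-9)
  }
})

test_that("sham session is a 60 s triangular-envelope alpha ramp", {
  w <- build_session(stim_params("sham", plateau_s = 120))
  nz <- which(w$samples != 0)
  expect_lt((max(nz) - min(nz)) / w$fs, 60 + 0.2)
  expect_gt((max(nz) - min(nz)) / w$fs, 60 - 0.2)
  expect_equal(length(w$samples), round(180 * w$fs) + 1)
  # apex cycle reaches the composite peak-to-peak
  apex <- round(30 * w$fs) + 1
  cyc <- w$samples[(apex - round(w$fs / 20)):(apex + round(w$fs / 20))]
  expect_equal(max(cyc) - min(cyc), 3.0, tolerance = 0.01)
})

test_that("sham waveform carries no gamma-band power", {
  w <- build_session(stim_params("sham", plateau_s = 60))
  x <- w$samples[seq_len(round(60 * w$fs))]
  n <- length(x)
  P <- (2 * Mod(stats::fft(x)[seq_len(floor(n / 2) + 1)]) / n)^2
  f <- (seq_len(floor(n / 2) + 1) - 1) * w$fs / n
  p10 <- max(P[f >= 9 & f <= 11])
  pg <- max(P[f >= 70 & f <= 90])
  expect_lt(10 * log10(pg / p10), -40)
})

test_that("one gamma burst rides every alpha cycle", {
  w <- build_session(stim_params("trough", ramp_s = 1, plateau_s = 5))
  seg <- w$segments
  pl <- w$samples[seg$start[2]:seg$end[2]]
  expect_equal(count_bursts(pl, w$fs), 5 * 10)
})

test_that("entrainment verifier recovers the interval midpoint for both conditions", {
  for (cond in c("trough", "peak")) {
    w <- build_session(stim_params(cond, ramp_s = 1, plateau_s = 20))
    v <- verify_entrainment(w)
    expect_lt(circ_dist_t(v$preferred_phase, mean(canonical_interval(cond))),
              pi / 8)
    expect_gt(v$concentration, 0.2)
  }
})

test_that("entrainment recovery holds across random rates and amplitudes", {
  set.seed(404)
  for (i in 1:20) {
    fs <- sample(1024:4096, 1)
    cond <- sample(c("peak", "trough"), 1)
    p <- stim_params(cond, alpha_pkpk = runif(1, 0.5, 3),
                     gamma_pkpk = runif(1, 0.3, 2),
                     composite_pkpk = runif(1, 1, 4), fs = fs)
    tile <- compose_cycle(p)$samples
    x <- rep(tile, 80)
    v <- verify_entrainment(x, fs = fs)
    expect_lt(circ_dist_t(v$preferred_phase, mean(canonical_interval(cond))),
              pi / 8)
  }
})

test_that("a burst-free carrier shows no phase-preferential gamma envelope", {
  fs <- 2048
  x <- sin(2 * pi * 10 * (0:(fs * 10)) / fs)
  v <- verify_entrainment(x, fs = fs)
  expect_lt(v$concentration, 0.05)
})

test_that("waveform export round-trips through CSV + JSON sidecar", {
  w <- build_session(stim_params("trough", ramp_s = 1, plateau_s = 3))
  path <- file.path(tempdir(), "wf.csv")
  export_waveform(w, path)
  w2 <- read_waveform(path)
  expect_equal(w2$samples, w$samples, tolerance = 1e-9)
  expect_equal(w2$params$condition, "trough")
  expect_equal(nrow(data.table::fread(path)), round(5 * w$fs) + 1)
  expect_equal(w2$segments$label, w$segments$label)
  unlink(c(path, paste0(path, ".json")))
})
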