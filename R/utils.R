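# Internal helpers shared across modules: seeded evaluation, analytic signals,
# band-limited filtering in the frequency domain, circular statistics.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state so callers never perturb the session stream. `seed = NULL` runs
#' the code with the ambient RNG.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# Derive a vector of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Analytic signal via the frequency domain
#'
#' Zeroes negative frequencies of the DFT and doubles the positive ones, giving
#' the complex analytic signal whose modulus is the instantaneous amplitude
#' envelope and whose argument is the instantaneous (cosine-referenced) phase.
#'
#' @param x numeric vector.
#' @return complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited analytic signal
#'
#' One-step band-pass plus Hilbert transform: retains only the positive DFT
#' bins inside `[lo, hi]` Hz (doubled), so the result is the analytic signal of
#' the band-passed input. Brick-wall in frequency, exactly zero-phase.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz (`0 < lo < hi <= fs/2`).
#' @return complex vector, same length as `x`.
#' @export
band_analytic <- function(x, fs, lo, hi) {
  stopifnot(lo > 0, hi > lo, hi <= fs / 2)
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  npos <- floor(n / 2) + 1
  keep <- f >= lo & f <= hi & seq_len(n) <= npos
  X <- stats::fft(x)
  Y <- rep(0 + 0i, n)
  Y[keep] <- 2 * X[keep]
  stats::fft(Y, inverse = TRUE) / n
}

# Instantaneous phase under the sine convention: x(t) = sin(phi(t)), so a
# carrier sin(2*pi*f*t) has phase 2*pi*f*t mod 2*pi, peak at pi/2, trough at
# 3*pi/2. The analytic-signal argument is cosine-referenced; shift by +pi/2.
sine_phase <- function(z) (Arg(z) + pi / 2) %% (2 * pi)

# Weighted circular mean and mean resultant length of phases (radians).
circ_mean_w <- function(phase, w = rep(1, length(phase))) {
  s <- sum(w * exp(1i * phase))
  tw <- sum(w)
  if (!is.finite(tw) || tw <= 0) return(list(mean = NA_real_, r = 0))
  list(mean = Arg(s) %% (2 * pi), r = Mod(s) / tw)
}

# Smallest absolute angular distance between two phases (radians).
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Squared magnitude response |H(e^{iw})|^2 of a digital filter b/a at angular
# frequencies w (radians/sample).
butter_mag2 <- function(flt, w) {
  u <- exp(-1i * w)
  horner <- function(coef) {
    acc <- rep(coef[length(coef)] + 0i, length(u))
    for (k in rev(seq_len(length(coef) - 1))) acc <- acc * u + coef[k]
    acc
  }
  Mod(horner(flt$b) / horner(flt$a))^2
}

#' Zero-phase Butterworth filtering via the frequency domain
#'
#' Applies the squared magnitude response of one or more Butterworth designs
#' to the DFT of the signal — the transfer function of forward-backward
#' (filtfilt) application — on a continuity-padded, FFT-friendly extension of
#' the input. Exactly zero phase, no startup transients, O(n log n).
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param filters list of `signal::butter()` designs (elements with `b`, `a`).
#' @return filtered signal, same length as `x`.
#' @keywords internal
zero_phase_filter <- function(x, fs, filters, cache_key = NULL) {
  n <- length(x)
  m <- stats::nextn(2 * n, c(2, 3, 5))
  # mirror + constant extension keeps the circularized signal continuous
  xp <- c(x, rev(x), rep(x[1], m - 2 * n))
  G <- NULL
  key <- if (!is.null(cache_key)) paste(cache_key, m, fs)
  if (!is.null(key)) G <- .response_cache[[key]]
  if (is.null(G)) {
    w <- 2 * pi * (seq_len(m) - 1) / m
    w <- pmin(w, 2 * pi - w)           # fold to [0, pi]
    G <- rep(1, m)
    for (flt in filters) G <- G * butter_mag2(flt, w)
    if (!is.null(key)) .response_cache[[key]] <- G
  }
  Re(stats::fft(stats::fft(xp) * G, inverse = TRUE) / m)[seq_len(n)]
}

# memoized filter responses (keyed by design + length + rate)
.response_cache <- new.env(parent = emptyenv())
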