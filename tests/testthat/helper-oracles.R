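# Independent brute-force oracles. These re-derive each statistic from its
# definition with plain loops, deliberately sharing no code path with the
# package implementations they check.

# ITPC by per-trial spectral phase extraction with explicit loops: for each
# frequency, window the trial's DFT with an analytic Gaussian (Morlet) kernel,
# invert, and average unit phasors across trials.
oracle_itpc <- function(ep, freqs, decim = 1) {
  padded <- ep$epochs_padded
  n <- ncol(padded)
  fs <- ep$fs
  fgrid <- (seq_len(n) - 1) * fs / n
  npos <- floor(n / 2) + 1
  keep_t <- ep$pad + seq(1, ncol(ep$epochs), by = decim)
  ntr <- nrow(padded)
  out <- matrix(0, length(freqs), length(keep_t))
  for (fi in seq_along(freqs)) {
    f0 <- freqs[fi]
    n_cyc <- 3 + 5 * (f0 - 1) / 99
    sig_t <- n_cyc / (2 * pi * f0)
    H <- numeric(n)
    for (k in seq_len(npos))
      H[k] <- 2 * exp(-0.5 * (2 * pi * (fgrid[k] - f0))^2 * sig_t^2)
    H[1] <- H[1] / 2
    acc <- rep(0 + 0i, length(keep_t))
    for (tr in seq_len(ntr)) {
      X <- stats::fft(padded[tr, ])
      z <- stats::fft(X * H, inverse = TRUE)[keep_t] / n
      acc <- acc + z / Mod(z)
    }
    out[fi, ] <- Mod(acc) / ntr
  }
  out
}

# Tort modulation index from first principles: brick-wall band-pass by DFT bin
# masking, Hilbert by zeroing negative frequencies, sine-referenced phase,
# explicit per-bin amplitude means, entropy by summation.
oracle_tort_mi <- function(x, fs, fp, fa, K = 18, phase_hbw = 2, amp_hbw = 15) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  npos <- floor(n / 2) + 1
  analytic_band <- function(lo, hi) {
    X <- stats::fft(x)
    Y <- rep(0 + 0i, n)
    for (k in seq_len(npos))
      if (f[k] >= lo && f[k] <= hi) Y[k] <- 2 * X[k]
    stats::fft(Y, inverse = TRUE) / n
  }
  zp <- analytic_band(max(0.5, fp - phase_hbw), fp + phase_hbw)
  za <- analytic_band(max(0.5, fa - amp_hbw), min(fs / 2, fa + amp_hbw))
  phase <- (Arg(zp) + pi / 2) %% (2 * pi)
  amp <- Mod(za)
  pk <- numeric(K)
  for (k in seq_len(K)) {
    lo <- (k - 1) * 2 * pi / K
    hi <- k * 2 * pi / K
    inbin <- phase >= lo & (phase < hi | (k == K & phase <= 2 * pi))
    pk[k] <- if (any(inbin)) mean(amp[inbin]) else 0
  }
  p <- pk / sum(pk)
  H <- 0
  for (k in seq_len(K)) if (p[k] > 0) H <- H - p[k] * log(p[k])
  (log(K) - H) / log(K)
}

# All permutations of a vector (list of vectors).
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Tie-corrected Friedman statistic written out longhand.
oracle_friedman_stat <- function(R) {
  N <- nrow(R); k <- ncol(R)
  Rj <- colSums(R)
  S <- 0
  for (j in seq_len(k)) S <- S + (Rj[j] - N * (k + 1) / 2)^2
  ties <- 0
  for (i in seq_len(N)) {
    tt <- table(R[i, ])
    ties <- ties + sum(tt^3 - tt)
  }
  C <- 1 - ties / (N * k * (k^2 - 1))
  if (C <= 0) return(0)
  (12 * S / (N * k * (k + 1))) / C
}

# Exhaustive permutation p-value for the Friedman test: every combination of
# within-subject orderings, statistic recomputed from scratch for each.
oracle_friedman_p <- function(x) {
  x <- as.matrix(x)
  N <- nrow(x); k <- ncol(x)
  R <- t(apply(x, 1, rank))
  obs <- oracle_friedman_stat(R)
  P <- all_perms(seq_len(k))
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_along(P)), N)))
  count <- 0
  for (g in seq_len(nrow(grid))) {
    Rp <- matrix(0, N, k)
    for (i in seq_len(N)) Rp[i, ] <- R[i, P[[grid[g, i]]]]
    if (oracle_friedman_stat(Rp) >= obs - 1e-9) count <- count + 1
  }
  count / nrow(grid)
}

# Exhaustive sign-assignment two-sided p for the Wilcoxon signed-rank test.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  signs <- as.matrix(do.call(expand.grid, rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  pge <- mean(Ws >= Wobs - 1e-9)
  ple <- mean(Ws <= Wobs + 1e-9)
  min(1, 2 * min(pge, ple))
}

# Definitional BH step-up adjusted p-values: p_adj(i) = min_{j >= i} n p_(j)/j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in i:n) vals <- c(vals, n * p[o[j]] / j)
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# Assemble an epoch_set directly from a matrix of padded trials (rows).
epoch_set_from_padded <- function(padded, fs, pad_s = 0.5) {
  pad <- round(pad_s * fs)
  nwin <- ncol(padded) - 2 * pad
  stopifnot(nwin > 0)
  structure(list(
    epochs = padded[, pad + seq_len(nwin), drop = FALSE],
    epochs_padded = padded, pad = pad, fs = fs,
    window = c(-nwin / fs, 0),
    kept_trial_ids = seq_len(nrow(padded)),
    rejected_trial_ids = integer(0), invalid_trial_ids = integer(0),
    events = data.frame(trial = seq_len(nrow(padded))),
    meta = list()), class = "epoch_set")
}
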