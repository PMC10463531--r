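# Nonparametric statistics implemented at formula level: tie-corrected
# Friedman test (exact permutation p for small cohorts), Wilcoxon signed-rank
# with exact sign-flip distribution, and Benjamini-Hochberg FDR. The
# Shapiro-Wilk screen delegates to the standard base-R implementation.

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over the standard Shapiro-Wilk test, used only to justify the
#' nonparametric plan.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(unique(x)) == 1) stop("constant sample: W is undefined")
  r <- stats::shapiro.test(x)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Friedman rank test for repeated measures
#'
#' Ranks within each subject (mid-ranks for ties) and computes the
#' tie-corrected statistic
#' `Q = [12 / (N k (k+1))] * sum_j (R_j - N(k+1)/2)^2 / C`, with
#' `C = 1 - sum(t^3 - t) / (N k (k^2 - 1))` over tie groups. The p-value comes
#' from the exact permutation distribution (all `(k!)^N` within-subject
#' orderings) when that enumeration is small enough, otherwise from the
#' chi-squared approximation with `k - 1` df.
#'
#' @param x numeric matrix, subjects x levels (>= 2 subjects, >= 3 levels).
#' @param p_method `"auto"` (exact when `(k!)^N <= exact_limit`), `"exact"` or
#'   `"chisq"`.
#' @param exact_limit enumeration-size cap for `"auto"`.
#' @return list with `statistic` (Q), `df`, `p`, `method`, `n`, `k`.
#' @export
friedman_test <- function(x, p_method = c("auto", "exact", "chisq"),
                          exact_limit = 3e5) {
  p_method <- match.arg(p_method)
  x <- as.matrix(x)
  N <- nrow(x); k <- ncol(x)
  if (k < 3) stop("fewer than 3 levels: use a Wilcoxon signed-rank test")
  if (N < 2) stop("need at least 2 subjects")
  if (anyNA(x)) stop("missing cells: complete cases required")
  R <- t(apply(x, 1, rank))
  stat <- friedman_stat(R, N, k)
  nperm <- factorial(k)^N
  use_exact <- p_method == "exact" ||
    (p_method == "auto" && nperm <= exact_limit)
  if (use_exact) {
    if (nperm > 5e6) stop("exact enumeration too large")
    p <- friedman_exact_p(R, stat)
    method <- "exact permutation"
  } else {
    p <- if (stat == 0 && all(R == (k + 1) / 2)) 1
         else stats::pchisq(stat, k - 1, lower.tail = FALSE)
    method <- "chi-squared approximation"
  }
  list(statistic = stat, df = k - 1, p = p, method = method, n = N, k = k)
}

# Tie-corrected Friedman statistic from a rank matrix.
friedman_stat <- function(R, N = nrow(R), k = ncol(R)) {
  Rj <- colSums(R)
  S <- sum((Rj - N * (k + 1) / 2)^2)
  ties <- sum(apply(R, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  C <- 1 - ties / (N * k * (k^2 - 1))
  if (C <= 0) return(0)
  (12 * S / (N * k * (k + 1))) / C
}

# Exact permutation p: enumerate all products of within-row permutations of
# each row's observed rank multiset. The tie correction is permutation
# invariant, so comparing uncorrected sums of squares is equivalent; the
# corrected statistic is used directly for clarity.
friedman_exact_p <- function(R, stat) {
  N <- nrow(R); k <- ncol(R)
  perms <- perm_matrix(k)            # k! x k index permutations
  np <- nrow(perms)
  # per-row matrices of achievable rank vectors
  rows <- lapply(seq_len(N), function(i) {
    matrix(R[i, ][perms], np, k)
  })
  idx <- rep(1L, N)
  total <- np^N
  Rj_all <- matrix(0, total, k)
  # build the cartesian product incrementally
  reps <- total
  for (i in seq_len(N)) {
    reps <- reps / np
    sel <- rep(rep(seq_len(np), each = reps), length.out = total)
    Rj_all <- Rj_all + rows[[i]][sel, , drop = FALSE]
  }
  S_all <- rowSums((Rj_all - N * (k + 1) / 2)^2)
  ties <- sum(apply(R, 1, function(r) { t <- table(r); sum(t^3 - t) }))
  C <- 1 - ties / (N * k * (k^2 - 1))
  stats_all <- if (C <= 0) rep(0, total)
               else (12 * S_all / (N * k * (k + 1))) / C
  mean(stats_all >= stat - 1e-9)
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0
  for (pos in seq_len(k)) {
    block <- cbind(sub, k)
    if (pos < k) block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                                sub[, pos:(k - 1), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zeros are dropped (classic treatment; `zero_method = "pratt"` ranks them
#' first and then discards their contribution). For `n <= exact_max` the
#' two-sided p-value is exact, from the full sign-flip distribution of the
#' observed (mid-)ranks computed by convolution — equivalent to enumerating
#' all `2^n` sign assignments and valid under ties. Larger samples use the
#' normal approximation with tie and continuity corrections.
#'
#' @param x paired differences, or first sample when `y` is given.
#' @param y optional second sample (`d = x - y`).
#' @param exact_max exact-enumeration cutoff on the number of nonzero pairs.
#' @param zero_method `"drop"` or `"pratt"`.
#' @return list with `statistic` (W, sum of positive ranks), `n` (nonzero
#'   pairs), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25,
                                 zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (all(d == 0)) {
    warning("all differences are zero: p = 1")
    return(list(statistic = 0, n = 0L, p = 1, method = "degenerate"))
  }
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signrank_exact_p(r, W)
    method <- "exact sign-flip distribution"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4   # = n(n+1)(2n+1)/24 minus the tie correction
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, n = n, p = min(1, p), method = method)
}

# Exact two-sided p for the sign-flip distribution of ranks r at observed W:
# counts over all 2^n sign assignments via polynomial convolution. Ranks are
# doubled to make mid-ranks integral.
signrank_exact_p <- function(r, W) {
  r2 <- round(2 * r)
  maxs <- sum(r2)
  f <- numeric(maxs + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1):(maxs + 1)] <- g[(ri + 1):(maxs + 1)] + f[seq_len(maxs + 1 - ri)]
    f <- g
  }
  total <- 2^length(r)
  W2 <- round(2 * W)
  pge <- sum(f[(W2 + 1):(maxs + 1)]) / total
  ple <- sum(f[seq_len(W2 + 1)]) / total
  min(1, 2 * min(pge, ple))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforced:
#' `p_(i)_adj = min_{j >= i} ( n * p_(j) / j )`, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
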