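test_that("Friedman statistic matches the closed form under perfect concordance", {
  x <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  x <- x + seq_len(24) * 1e-9          # break within-row ties, keep order
  f <- friedman_test(x, p_method = "chisq")
  expect_equal(f$statistic, 16)
  expect_lt(f$p, 0.001)
})

test_that("identical values across levels give a zero statistic and p = 1", {
  f <- friedman_test(matrix(5, 6, 3))
  expect_equal(f$statistic, 0)
  expect_equal(f$p, 1)
})

test_that("Friedman validates its input shape", {
  expect_error(friedman_test(matrix(rnorm(10), 5, 2)), "Wilcoxon")
  expect_error(friedman_test(matrix(rnorm(3), 1, 3)), "2 subjects")
  expect_error(friedman_test(matrix(c(1, NA, rnorm(7)), 3, 3)), "complete")
})

test_that("exact Friedman p equals exhaustive enumeration for small cohorts", {
  set.seed(21)
  for (N in c(4, 5)) {
    x <- matrix(rnorm(N * 3), N, 3)
    expect_equal(friedman_test(x, p_method = "exact")$p,
                 oracle_friedman_p(x), tolerance = 1e-12)
  }
  # with ties
  xt <- matrix(c(1, 1, 2, 3, 2, 2, 1, 3, 2, 2, 1, 1), 4, 3)
  expect_equal(friedman_test(xt, p_method = "exact")$p,
               oracle_friedman_p(xt), tolerance = 1e-12)
})

test_that("Friedman agrees with the base-R implementation on untied data", {
  set.seed(22)
  x <- matrix(rnorm(17 * 3), 17, 3)
  f <- friedman_test(x, p_method = "chisq")
  fb <- stats::friedman.test(x)
  expect_equal(f$statistic, unname(fb$statistic))
  expect_equal(f$p, fb$p.value)
})

test_that("Wilcoxon signed-rank handles its boundary cases exactly", {
  expect_equal(wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))$p, 1)
  w <- wilcoxon_signed_rank(1:10)
  expect_equal(w$p, 2 / 2^10)
  expect_equal(w$statistic, 55)
  expect_warning(res <- wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_equal(res$p, 1)
})

test_that("exact Wilcoxon p equals sign-assignment enumeration, ties included", {
  set.seed(23)
  cases <- list(rnorm(8, 0.5), rnorm(10), round(rnorm(9, 0.3) * 4) / 4,
                c(1, 1, -1, 2, 2, -3, 4))
  for (d in cases) {
    d <- d[d != 0]
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_wilcoxon_p(d),
                 tolerance = 1e-12)
  }
  # and base R where no ties allow an exact reference
  d <- rnorm(12, 0.4)
  expect_equal(wilcoxon_signed_rank(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("the normal-approximation branch tracks the exact tail", {
  set.seed(24)
  d <- rnorm(40, 0.3)
  pn <- wilcoxon_signed_rank(d, exact_max = 25)$p
  pe <- wilcoxon_signed_rank(d, exact_max = 50)$p
  expect_lt(abs(pn - pe), 0.02)
  expect_equal(wilcoxon_signed_rank(d, exact_max = 25)$method,
               "normal approximation")
})

test_that("BH adjustment reproduces hand-computed and reference values", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(numeric(0)), numeric(0))
  set.seed(25)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- fdr_bh(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("Shapiro-Wilk screen flags non-normal samples and calibrates under the null", {
  set.seed(26)
  rej <- mean(replicate(200, shapiro_wilk(runif(50))$p < 0.05))
  expect_gt(rej, 0.6)
  pnull <- replicate(200, shapiro_wilk(rnorm(50))$p)
  ks <- suppressWarnings(stats::ks.test(pnull, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(shapiro_wilk(rnorm(30))$W, 1)
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
})

test_that("the stat plan gates post-hocs on the omnibus test", {
  set.seed(27)
  subj <- 1:10
  flat <- expand.grid(subject = subj, condition = c("sham", "peak", "trough"),
                      session = c("pre", "post0", "post10"),
                      stringsAsFactors = FALSE)
  flat$measure <- "overall"
  flat$value <- 0.5 + 0.01 * flat$subject     # identical across sessions
  res <- run_stat_plan(flat)
  expect_false(any(res$test == "wilcoxon_posthoc"))
  expect_true(all(res[res$test == "friedman_session", "statistic"] == 0))
  # a strong session effect opens the gate for that condition only
  eff <- flat
  for (sess in c("post0", "post10")) {
    idx <- eff$condition == "trough" & eff$session == sess
    eff$value[idx] <- eff$value[idx] +
      ifelse(sess == "post0", 0.3, 0.4) + 0.01 * eff$subject[idx]
  }
  res2 <- run_stat_plan(eff)
  ph <- res2[res2$test == "wilcoxon_posthoc", ]
  expect_true(all(ph$condition == "trough"))
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$adj_p >= ph$raw_p - 1e-15))
  pre_rows <- ph$contrast %in% c("pre-post0", "pre-post10")
  expect_true(all(ph$decision[pre_rows]))
})

test_that("the stat plan is invariant to row ordering", {
  set.seed(28)
  d <- expand.grid(subject = 1:8, condition = c("sham", "peak", "trough"),
                   session = c("pre", "post0", "post10"),
                   measure = c("overall", "power10"),
                   stringsAsFactors = FALSE)
  d$value <- runif(nrow(d))
  r1 <- run_stat_plan(d)
  r2 <- run_stat_plan(d[sample(nrow(d)), ])
  key <- function(r) r[order(r$measure, r$condition, r$test, r$contrast), ]
  k1 <- key(r1); k2 <- key(r2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2, ignore_attr = TRUE)
})

test_that("the stat plan skips incomplete cells with a logged reason", {
  d <- expand.grid(subject = 1:6, condition = c("sham", "peak", "trough"),
                   session = c("pre", "post0", "post10"),
                   stringsAsFactors = FALSE)
  d$measure <- "overall"
  set.seed(29)
  d$value <- runif(nrow(d))
  d <- d[!(d$subject == 3 & d$condition == "peak" & d$session == "post0"), ]
  res <- run_stat_plan(d)
  expect_false(any(res$measure == "overall" & res$condition == "peak" &
                     res$test == "friedman_session"))
  expect_match(attr(res, "skipped"), "overall/peak", all = FALSE)
})
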