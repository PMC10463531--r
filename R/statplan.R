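# The full testing scheme over a cohort's behavioral and EEG measures:
# per-condition Friedman over sessions, baseline Friedman over conditions,
# gated Wilcoxon post-hocs, FDR within each measure's contrast family.

#' Run the nonparametric statistical plan
#'
#' For every (measure, condition): a Friedman test over the three sessions.
#' Where the omnibus test is significant at `alpha`, pairwise Wilcoxon
#' signed-rank post-hocs (pre vs post0, pre vs post10, post0 vs post10) are
#' run and FDR-adjusted — by default within each measure x condition family of
#' three contrasts (`fdr_scope = "per-measure"`), optionally over all post-hoc
#' p-values pooled (`"global"`). Baseline measures additionally get a Friedman
#' test over conditions restricted to the pre session.
#'
#' @param measures long data.frame with columns `subject`, `condition`,
#'   `session`, `measure`, `value`; complete cases per measure x condition.
#' @param alpha omnibus gate and decision level.
#' @param fdr_scope `"per-measure"` or `"global"`.
#' @param baseline_measures measures tested across conditions at baseline;
#'   default: every accuracy measure present.
#' @param sessions,conditions level orders.
#' @return data.frame of class `stat_plan_result`: one row per test with
#'   `measure`, `condition`, `test`, `contrast`, `statistic`, `raw_p`,
#'   `adj_p`, `decision`, `n`, and for post-hoc rows `delta`, the median
#'   later-minus-earlier paired difference (the direction of the contrast).
#'   Skipped measures are logged in `attr(, "skipped")`.
#' @export
run_stat_plan <- function(measures, alpha = 0.05,
                          fdr_scope = c("per-measure", "global"),
                          baseline_measures = NULL,
                          sessions = c("pre", "post0", "post10"),
                          conditions = c("sham", "peak", "trough")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(all(c("subject", "condition", "session", "measure", "value")
                %in% names(measures)))
  if (is.null(baseline_measures))
    baseline_measures <- intersect(c("overall", "size3", "size4", "size5"),
                                   unique(measures$measure))
  rows <- list()
  skipped <- character(0)
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  pivot <- function(d, cols, colvar) {
    subs <- sort(unique(d$subject))
    m <- matrix(NA_real_, length(subs), length(cols),
                dimnames = list(subs, cols))
    for (i in seq_len(nrow(d)))
      m[as.character(d$subject[i]), as.character(d[[colvar]][i])] <- d$value[i]
    m
  }

  contrasts <- list(c("pre", "post0"), c("pre", "post10"), c("post0", "post10"))

  for (ms in unique(measures$measure)) {
    for (cond in conditions) {
      d <- measures[measures$measure == ms & measures$condition == cond, ]
      if (nrow(d) == 0) next
      m <- pivot(d, sessions, "session")
      if (anyNA(m)) {
        skipped <- c(skipped, sprintf("%s/%s: incomplete cells", ms, cond))
        next
      }
      fr <- friedman_test(m, p_method = "chisq")
      add(measure = ms, condition = cond, test = "friedman_session",
          contrast = NA, statistic = fr$statistic, raw_p = fr$p,
          adj_p = NA_real_, decision = fr$p < alpha, n = fr$n,
          delta = NA_real_)
      if (fr$p < alpha) {
        ph <- lapply(contrasts, function(ct)
          wilcoxon_signed_rank(m[, ct[1]], m[, ct[2]]))
        praw <- vapply(ph, `[[`, numeric(1), "p")
        padj <- if (fdr_scope == "per-measure") fdr_bh(praw) else praw
        for (i in seq_along(contrasts)) {
          ct <- contrasts[[i]]
          add(measure = ms, condition = cond, test = "wilcoxon_posthoc",
              contrast = paste(ct, collapse = "-"),
              statistic = ph[[i]]$statistic, raw_p = praw[i],
              adj_p = padj[i], decision = padj[i] < alpha, n = ph[[i]]$n,
              # direction of the contrast: median later-minus-earlier change
              delta = stats::median(m[, ct[2]] - m[, ct[1]]))
        }
      }
    }
  }

  for (ms in baseline_measures) {
    d <- measures[measures$measure == ms & measures$session == "pre", ]
    if (nrow(d) == 0) next
    m <- pivot(d, conditions, "condition")
    if (anyNA(m)) {
      skipped <- c(skipped, sprintf("%s baseline: incomplete cells", ms))
      next
    }
    fr <- friedman_test(m, p_method = "chisq")
    add(measure = ms, condition = "all", test = "friedman_baseline",
        contrast = NA, statistic = fr$statistic, raw_p = fr$p,
        adj_p = NA_real_, decision = fr$p < alpha, n = fr$n,
        delta = NA_real_)
  }

  out <- do.call(rbind, rows)
  if (fdr_scope == "global") {
    gi <- which(out$test == "wilcoxon_posthoc")
    if (length(gi)) {
      out$adj_p[gi] <- fdr_bh(out$raw_p[gi])
      out$decision[gi] <- out$adj_p[gi] < alpha
    }
  }
  attr(out, "alpha") <- alpha
  attr(out, "fdr_scope") <- fdr_scope
  attr(out, "skipped") <- skipped
  class(out) <- c("stat_plan_result", "data.frame")
  out
}

#' Write a stat-plan result as TSV plus JSON summary
#'
#' @param res a [run_stat_plan()] result.
#' @param path_tsv,path_json output paths.
#' @return `path_tsv`, invisibly.
#' @export
write_stat_plan <- function(res, path_tsv, path_json = NULL) {
  data.table::fwrite(as.data.frame(res), path_tsv, sep = "\t")
  if (!is.null(path_json)) {
    sig <- res[!is.na(res$decision) & res$decision, ]
    jsonlite::write_json(
      list(alpha = attr(res, "alpha"), fdr_scope = attr(res, "fdr_scope"),
           n_tests = nrow(res),
           significant = sig[, c("measure", "condition", "test", "contrast")],
           skipped = attr(res, "skipped")),
      path_json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path_tsv)
}
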