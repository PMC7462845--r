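# Likelihood-ratio test for nested codon site models (e.g. M7 vs M8).

#' Likelihood-ratio test between nested models
#'
#' Computes the statistic `2 * (lnL1 - lnL0)` and the upper-tail chi-square
#' probability with `df` degrees of freedom (df = 2 for the M7-vs-M8 site
#' model comparison). A negative statistic (alternative fits worse than the
#' null, a numerical artefact) is reported as-is with `p = 1` and a warning.
#'
#' @param lnL0 Log-likelihood of the null (restricted) model.
#' @param lnL1 Log-likelihood of the alternative model.
#' @param df Degrees of freedom (>= 1).
#' @return Object of class `lrt_result`: `lnL0`, `lnL1`, `stat`, `df`, `p`,
#'   `negative_stat` flag.
#' @export
lrt <- function(lnL0, lnL1, df) {
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (lnL1 - lnL0)
  negative <- stat < 0
  if (negative) {
    warning("negative LRT statistic (lnL1 < lnL0); p set to 1")
    p <- 1
  } else {
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  structure(list(lnL0 = lnL0, lnL1 = lnL1, stat = stat, df = df, p = p,
                 negative_stat = negative),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*(lnL1-lnL0) = %.4g on %d df, p = %.4g%s\n",
              x$stat, x$df, x$p,
              if (x$negative_stat) " [negative statistic]" else ""))
  invisible(x)
}

#' Likelihood-ratio tests from a table of log-likelihoods
#'
#' @param tab `data.frame` with columns `gene`, `lnL0`, `lnL1` (e.g. M7 and
#'   M8 log-likelihoods per gene).
#' @param df Degrees of freedom (default 2, the M7-vs-M8 comparison).
#' @return `data.frame` with columns gene, lnL0, lnL1, stat, df, p.
#' @export
lrt_table <- function(tab, df = 2) {
  stopifnot(all(c("gene", "lnL0", "lnL1") %in% names(tab)))
  res <- lapply(seq_len(nrow(tab)), function(i)
    lrt(tab$lnL0[i], tab$lnL1[i], df))
  data.frame(gene = tab$gene,
             lnL0 = tab$lnL0, lnL1 = tab$lnL1,
             stat = vapply(res, `[[`, numeric(1), "stat"),
             df = df,
             p = vapply(res, `[[`, numeric(1), "p"),
             stringsAsFactors = FALSE)
}
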