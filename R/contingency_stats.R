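#' Build a sample-by-region contingency table
#'
#' Converts a [summarize_chiasmata()] summary into an integer matrix of
#' chiasma counts with samples as rows and arm regions as columns, the
#' input expected by [chi_square()] and [pairwise_comparisons()].
#'
#' @param summary a data.frame from [summarize_chiasmata()] (or any frame
#'   with `sample_id`, `n_proximal`, `n_interstitial`, `n_distal`).
#' @return integer matrix with sample row names and region column names.
#' @export
region_contingency <- function(summary) {
  need <- c("sample_id", "n_proximal", "n_interstitial", "n_distal")
  summary <- check_columns(summary, need, "summary")
  m <- as.matrix(summary[, c("n_proximal", "n_interstitial", "n_distal")])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(summary$sample_id, REGION_LEVELS)
  m
}

validate_contingency <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort_validation("contingency table must contain non-negative counts")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort_validation("contingency table needs at least 2 rows and 2 columns")
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    empty <- c(rownames(counts)[rs == 0], colnames(counts)[cs == 0])
    if (is.null(empty) || length(empty) == 0) empty <- "unnamed"
    abort_validation(sprintf(
      "contingency table has empty row/column marginal(s): %s",
      paste(empty, collapse = ", ")))
  }
  counts
}

#' Cramer's V effect size
#'
#' `V = sqrt(chi2 / (n * min(r - 1, c - 1)))`, the \[0, 1\]-scaled effect
#' size for an r x c contingency table. No bias correction is applied.
#'
#' @param chi2 Pearson chi-square statistic (no continuity correction).
#' @param n grand total of the table.
#' @param r,c number of rows and columns.
#' @return Cramer's V in \[0, 1\].
#' @examples
#' cramers_v(20, 20, 2, 2) # 1
#' @export
cramers_v <- function(chi2, n, r, c) {
  stopifnot(chi2 >= 0, n >= 1, r >= 2, c >= 2)
  sqrt(chi2 / (n * min(r - 1, c - 1)))
}

#' Pearson chi-square test of independence with Cramer's V
#'
#' Tests whether the regional distribution of chiasmata differs between
#' samples. Expected counts are `row_total * col_total / n`; the statistic
#' is `sum((O - E)^2 / E)` with `df = (r - 1)(c - 1)` and an upper-tail
#' chi-square p-value. No continuity correction is applied, and the
#' reported Cramer's V is uncorrected — the conventions under which
#' published pairwise effect sizes for these data recompute exactly.
#'
#' @param counts non-negative integer matrix (samples x regions), e.g.
#'   from [region_contingency()]. Every row and column must have a
#'   positive marginal total.
#' @return list of class `chisq_result`: `chi2`, `df`, `p_value`,
#'   `cramers_v`, `n`.
#' @export
chi_square <- function(counts) {
  counts <- validate_contingency(counts)
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  chi2 <- unname(ht$statistic)
  structure(list(chi2 = chi2,
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 cramers_v = cramers_v(chi2, sum(counts), nrow(counts),
                                       ncol(counts)),
                 n = sum(counts)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  p_txt <- if (x$p_value < 1e-300) "< 1e-300" else
    format(x$p_value, digits = 4)
  cat(sprintf("Pearson chi-square: chi2 = %.4g, df = %d, p %s%s, V = %.4f, n = %d\n",
              x$chi2, x$df,
              if (startsWith(p_txt, "<")) "" else "= ", p_txt,
              x$cramers_v, x$n))
  invisible(x)
}

#' Pairwise sample comparisons with Bonferroni correction
#'
#' Runs [chi_square()] on the 2 x c sub-table of every unordered pair of
#' rows. P-values are Bonferroni-adjusted with `m` equal to the number of
#' pairs actually tested (`min(1, p * m)`). If a pair's sub-table has an
#' all-zero column, that column is dropped before testing and the result
#' is flagged in `columns_dropped`.
#'
#' @param counts contingency matrix as for [chi_square()].
#' @param adjustment multiple-testing adjustment; only `"bonferroni"` is
#'   implemented.
#' @return data.frame sorted by descending Cramer's V: `comparison`,
#'   `row_a`, `row_b`, `chi2`, `df`, `p_value`, `p_adjusted`, `cramers_v`,
#'   `n`, `columns_dropped`.
#' @export
pairwise_comparisons <- function(counts, adjustment = "bonferroni") {
  adjustment <- match.arg(adjustment, "bonferroni")
  counts <- validate_contingency(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("row", seq_len(nrow(counts)))
  }
  pairs <- combn(rownames(counts), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    sub <- counts[pr, , drop = FALSE]
    zero_cols <- colSums(sub) == 0
    sub <- sub[, !zero_cols, drop = FALSE]
    res <- chi_square(sub)
    data.frame(comparison = paste(pr, collapse = " vs "),
               row_a = pr[1], row_b = pr[2],
               chi2 = res$chi2, df = res$df,
               p_value = res$p_value,
               p_adjusted = min(1, res$p_value * m),
               cramers_v = res$cramers_v,
               n = res$n,
               columns_dropped = sum(zero_cols),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cramers_v, out$comparison), ]
  rownames(out) <- NULL
  out
}
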