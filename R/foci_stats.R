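#' Per-sample marker focus means and class-share percentages
#'
#' For each sample, summarises the MLH1 (class I crossover) and MUS81
#' (class II crossover) focus counts: cells scored, total signals and mean
#' foci per cell for each marker, the combined mean, and the percentage
#' share of each marker in the combined mean (rounded half-up to integer
#' percent; the shares sum to 100). Means are kept at full precision;
#' round for display with [round_half_up()].
#'
#' @param foci validated focus-count records ([read_foci_table()]).
#' @param sample_ids samples to summarise (default: all, in order of first
#'   appearance).
#' @return data.frame with one row per sample: `sample_id`, `mlh1_cells`,
#'   `mlh1_total`, `mlh1_mean`, `mus81_cells`, `mus81_total`,
#'   `mus81_mean`, `combined_mean`, `mlh1_share`, `mus81_share`.
#' @export
marker_means <- function(foci, sample_ids = NULL) {
  foci <- validate_foci_records(foci)
  if (is.null(sample_ids)) sample_ids <- unique(foci$sample_id)
  rows <- lapply(sample_ids, function(sid) {
    f <- foci[foci$sample_id == sid, ]
    stat <- lapply(FOCI_MARKERS, function(mk) {
      cnt <- f$count[f$marker == mk]
      if (length(cnt) == 0) {
        abort_validation(sprintf("sample %s has no %s cells", sid, mk))
      }
      list(cells = length(cnt), total = sum(cnt), mean = mean(cnt))
    })
    names(stat) <- FOCI_MARKERS
    combined <- stat$MLH1$mean + stat$MUS81$mean
    share <- round_half_up(100 * stat$MLH1$mean / combined, 0)
    data.frame(sample_id = sid,
               mlh1_cells = stat$MLH1$cells, mlh1_total = stat$MLH1$total,
               mlh1_mean = stat$MLH1$mean,
               mus81_cells = stat$MUS81$cells, mus81_total = stat$MUS81$total,
               mus81_mean = stat$MUS81$mean,
               combined_mean = combined,
               mlh1_share = share, mus81_share = 100 - share,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Artificial population of cross-product MLH1/MUS81 ratios
#'
#' MLH1 and MUS81 foci are scored on different slide preparations, so no
#' cell carries both counts. The artificial population pairs every MLH1
#' cell with every MUS81 cell (Cartesian product) and computes the
#' MLH1/MUS81 ratio for each pair, emulating a population in which both
#' markers had been counted in the same cell. Pairs whose MUS81 count is
#' zero have no finite ratio and are excluded (and tallied).
#'
#' @param mlh1_counts integer vector of per-cell MLH1 focus counts.
#' @param mus81_counts integer vector of per-cell MUS81 focus counts.
#' @return list of class `artificial_population`: `ratios` (numeric
#'   vector, MLH1-major order), `n_pairs`, `n_excluded`.
#' @examples
#' artificial_population(c(2, 3), c(1, 2))$ratios # 2, 1, 3, 1.5
#' @export
artificial_population <- function(mlh1_counts, mus81_counts) {
  if (length(mlh1_counts) == 0 || length(mus81_counts) == 0) {
    abort_validation("both marker count vectors must be non-empty")
  }
  grid <- expand.grid(mus81 = mus81_counts, mlh1 = mlh1_counts)
  # MLH1-major order: each MLH1 cell against all MUS81 cells
  keep <- grid$mus81 > 0
  if (!any(keep)) {
    abort_validation("all pairs have MUS81 count 0; no finite ratios")
  }
  structure(list(ratios = grid$mlh1[keep] / grid$mus81[keep],
                 n_pairs = sum(keep),
                 n_excluded = sum(!keep)),
            class = "artificial_population")
}

#' Weighted-mean ratio estimate from an artificial population
#'
#' Aggregates the pair ratios into a single per-cell MLH1/MUS81 ratio
#' estimate, down-weighting extreme pairs. Schemes:
#'
#' * `inverse_ratio` (default): weights `w = 1/r`, making the estimate the
#'   harmonic mean of the ratios, which damps the influence of pairs with
#'   an extreme large ratio. Zero ratios (MLH1 count 0) would give
#'   infinite weight; their `r` is floored at `eps` for weighting.
#' * `inverse_abs_deviation`: `w = 1/(|r - median(r)| + eps)`, symmetric
#'   down-weighting of both tails.
#' * `unweighted`: arithmetic mean.
#'
#' The central 95% percentile interval of the raw pair ratios is reported
#' alongside the estimate.
#'
#' @param population an [artificial_population()] object, or a numeric
#'   vector of ratios.
#' @param weighting weighting scheme (see above).
#' @param eps floor used in the weight denominators (default `1e-9`).
#' @return list of class `ratio_estimate`: `estimate`, `weighting`,
#'   `n_pairs`, `n_excluded`, `percentile_interval` (2.5% and 97.5%
#'   quantiles of the pair ratios).
#' @examples
#' weighted_mean_ratio(c(1, 2, 4))$estimate # harmonic mean, 1.714...
#' @export
weighted_mean_ratio <- function(population,
                                weighting = c("inverse_ratio",
                                              "inverse_abs_deviation",
                                              "unweighted"),
                                eps = 1e-9) {
  weighting <- match.arg(weighting)
  if (inherits(population, "artificial_population")) {
    ratios <- population$ratios
    n_pairs <- population$n_pairs
    n_excluded <- population$n_excluded
  } else {
    ratios <- as.numeric(population)
    n_pairs <- length(ratios)
    n_excluded <- 0L
  }
  if (length(ratios) == 0) {
    abort_validation("no ratios to aggregate")
  }
  w <- switch(weighting,
              inverse_ratio = 1 / pmax(ratios, eps),
              inverse_abs_deviation = 1 / (abs(ratios - median(ratios)) + eps),
              unweighted = rep(1, length(ratios)))
  structure(list(estimate = sum(w * ratios) / sum(w),
                 weighting = weighting,
                 n_pairs = n_pairs,
                 n_excluded = n_excluded,
                 percentile_interval = unname(quantile(ratios,
                                                       c(0.025, 0.975)))),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "MLH1/MUS81 ratio estimate: %.4f (%s; %d pairs, %d excluded; 95%% of pair ratios in [%.3f, %.3f])\n",
    x$estimate, x$weighting, x$n_pairs, x$n_excluded,
    x$percentile_interval[1], x$percentile_interval[2]))
  invisible(x)
}

#' Consistency of slide-based means with the artificial population
#'
#' Because the two markers are scored on separate slides, the simple ratio
#' of slide means (mean MLH1 per cell / mean MUS81 per cell) should be
#' compatible with the distribution of artificial-population pair ratios.
#' The check passes when the slide-based ratio lies inside the central 95%
#' percentile interval of the pair ratios.
#'
#' @param means one row of [marker_means()] output for the sample.
#' @param estimate a [weighted_mean_ratio()] result for the same sample.
#' @return list: `consistent` (logical), `slide_ratio`,
#'   `percentile_interval`, `estimate`.
#' @export
slide_consistency_check <- function(means, estimate) {
  stopifnot(inherits(estimate, "ratio_estimate"))
  if (nrow(means) != 1) {
    abort_validation("supply exactly one sample's marker_means row")
  }
  slide_ratio <- means$mlh1_mean / means$mus81_mean
  iv <- estimate$percentile_interval
  list(consistent = slide_ratio >= iv[1] && slide_ratio <= iv[2],
       slide_ratio = slide_ratio,
       percentile_interval = iv,
       estimate = estimate$estimate)
}

#' Wilcoxon rank-sum comparison of per-cell focus counts
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of per-cell focus
#' counts between two unpaired groups (the markers and species come from
#' distinct slide preparations). The exact null distribution is used when
#' the combined sample size is at most `exact_limit` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is applied.
#'
#' @param counts_a,counts_b numeric vectors of per-cell counts.
#' @param exact_limit maximum combined size for the exact path
#'   (default 12).
#' @return list of class `foci_comparison`: `statistic` (rank-sum W),
#'   `p_value`, `mean_difference` (`mean(a) - mean(b)`, full precision),
#'   `method` (`"exact"` or `"normal"`).
#' @export
compare_counts <- function(counts_a, counts_b, exact_limit = 12) {
  if (length(counts_a) == 0 || length(counts_b) == 0) {
    abort_validation("both groups must contain at least one observation")
  }
  ties <- anyDuplicated(c(counts_a, counts_b)) > 0
  use_exact <- (length(counts_a) + length(counts_b)) <= exact_limit && !ties
  ht <- suppressWarnings(
    wilcox.test(counts_a, counts_b, alternative = "two.sided",
                exact = use_exact, correct = TRUE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 mean_difference = mean(counts_a) - mean(counts_b),
                 method = if (use_exact) "exact" else "normal"),
            class = "foci_comparison")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' All pairwise sample comparisons of one marker's focus counts
#'
#' Runs [compare_counts()] on every unordered sample pair for the given
#' marker and FDR-adjusts the p-values across those tests.
#'
#' @param foci validated focus-count records.
#' @param marker `"MLH1"` or `"MUS81"`.
#' @return data.frame: `marker`, `sample_a`, `sample_b`, `statistic`,
#'   `p_value`, `p_fdr`, `mean_difference`.
#' @export
compare_foci_groups <- function(foci, marker = FOCI_MARKERS) {
  marker <- match.arg(marker)
  foci <- validate_foci_records(foci)
  f <- foci[foci$marker == marker, ]
  sids <- unique(f$sample_id)
  if (length(sids) < 2) {
    abort_validation(sprintf("need at least two samples with %s counts",
                             marker))
  }
  pairs <- combn(sids, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    cmp <- compare_counts(f$count[f$sample_id == pr[1]],
                          f$count[f$sample_id == pr[2]])
    data.frame(marker = marker, sample_a = pr[1], sample_b = pr[2],
               statistic = cmp$statistic, p_value = cmp$p_value,
               mean_difference = cmp$mean_difference,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p_value)
  out <- out[, c("marker", "sample_a", "sample_b", "statistic",
                 "p_value", "p_fdr", "mean_difference")]
  rownames(out) <- NULL
  out
}
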