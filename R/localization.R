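REGION_LEVELS <- c("proximal", "interstitial", "distal")

#' Region boundaries along a chromosome arm
#'
#' The arm (relative coordinates: 0 = centromere, 1 = telomere) is divided
#' into three regions: proximal `[0, lower)`, interstitial
#' `[lower, upper)` and distal `[upper, 1]`. The defaults split the arm
#' into three regions of equal length. Intervals are half-open so that the
#' three regions partition the arm: every position maps to exactly one
#' region.
#'
#' @param lower,upper region break points, `0 < lower < upper < 1`.
#' @return an object of class `region_boundaries`.
#' @examples
#' region_boundaries()          # thirds
#' region_boundaries(0.25, 0.75)
#' @export
region_boundaries <- function(lower = 1 / 3, upper = 2 / 3) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1 ||
      length(upper) != 1 || is.na(lower) || is.na(upper) ||
      !(0 < lower && lower < upper && upper < 1)) {
    abort_config("region boundaries must satisfy 0 < lower < upper < 1")
  }
  structure(list(lower = lower, upper = upper), class = "region_boundaries")
}

#' Classify arm positions into proximal / interstitial / distal regions
#'
#' @param rel_pos numeric vector of relative arm positions in \[0, 1\]
#'   (0 = centromere, 1 = telomere).
#' @param boundaries a [region_boundaries()] object.
#' @return factor with levels `proximal`, `interstitial`, `distal`.
#' @examples
#' classify_position(c(0.1, 0.5, 0.95))
#' classify_position(1 / 3) # interstitial: intervals are half-open
#' @export
classify_position <- function(rel_pos, boundaries = region_boundaries()) {
  stopifnot(inherits(boundaries, "region_boundaries"))
  if (any(is.na(rel_pos)) || any(rel_pos < 0 | rel_pos > 1)) {
    abort_validation("rel_pos must lie in [0, 1]")
  }
  region <- ifelse(rel_pos < boundaries$lower, "proximal",
                   ifelse(rel_pos < boundaries$upper, "interstitial",
                          "distal"))
  factor(region, levels = REGION_LEVELS)
}

#' Per-sample chiasma frequency and regional distribution
#'
#' Computes, for each sample, the number of cells and bivalents scored,
#' the chiasma count per arm region, the regional percentages, and the
#' mean chiasma frequency per cell (total chiasmata / cells scored) —
#' the per-sample summary row of a chiasma-distribution table.
#'
#' Cell membership (and hence the per-cell frequency denominator) comes
#' from the bivalent table, which includes achiasmate univalent pairs;
#' the regional percentages are over chiasmata only.
#'
#' Percentages and the mean frequency are reported rounded half-up to one
#' decimal in the `pct_*` and `mean_chiasma_frequency` columns; the exact
#' values are recoverable from the integer counts (`n_*`, `n_cells`).
#'
#' @param chiasmata validated chiasma records ([read_chiasma_table()]).
#' @param bivalents validated bivalent records; every chiasma's
#'   (sample, cell, bivalent) key must appear here.
#' @param samples optional validated sample metadata used to order rows
#'   and attach display labels.
#' @param boundaries a [region_boundaries()] object.
#' @return data.frame with one row per sample: `sample_id`, `n_cells`,
#'   `n_bivalents`, `n_chiasmata`, `n_proximal`, `n_interstitial`,
#'   `n_distal`, `pct_proximal`, `pct_interstitial`, `pct_distal`,
#'   `mean_chiasma_frequency`.
#' @export
summarize_chiasmata <- function(chiasmata, bivalents, samples = NULL,
                                boundaries = region_boundaries()) {
  chiasmata <- validate_chiasma_records(chiasmata)
  bivalents <- validate_bivalent_records(bivalents)

  biv_key <- paste(bivalents$sample_id, bivalents$cell_id,
                   bivalents$bivalent_id, sep = "\r")
  chi_key <- paste(chiasmata$sample_id, chiasmata$cell_id,
                   chiasmata$bivalent_id, sep = "\r")
  orphan <- which(!(chi_key %in% biv_key))
  if (length(orphan) > 0) {
    abort_validation(bad_rows_msg(
      orphan, "chiasma record",
      "references a bivalent absent from the bivalent table"))
  }

  sample_ids <- unique(bivalents$sample_id)
  if (!is.null(samples)) {
    samples <- validate_sample_records(samples)
    sample_ids <- samples$sample_id[samples$sample_id %in% sample_ids]
  }
  if (length(sample_ids) == 0) {
    abort_validation("no samples present in the bivalent table")
  }

  region <- classify_position(chiasmata$rel_pos, boundaries)
  rows <- lapply(sample_ids, function(sid) {
    biv_s <- bivalents[bivalents$sample_id == sid, ]
    n_cells <- length(unique(biv_s$cell_id))
    if (n_cells < 1) {
      abort_validation(sprintf("sample %s has no scored cells", sid))
    }
    reg_s <- region[chiasmata$sample_id == sid]
    counts <- as.integer(table(reg_s))
    total <- sum(counts)
    pct <- if (total > 0) round_half_up(100 * counts / total, 1) else
      rep(NA_real_, 3)
    data.frame(
      sample_id = sid,
      n_cells = n_cells,
      n_bivalents = nrow(biv_s),
      n_chiasmata = total,
      n_proximal = counts[1], n_interstitial = counts[2],
      n_distal = counts[3],
      pct_proximal = pct[1], pct_interstitial = pct[2], pct_distal = pct[3],
      mean_chiasma_frequency = round_half_up(total / n_cells, 1),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the configuration of a single bivalent
#'
#' Given all chiasmata observed on one bivalent, returns the metaphase-I
#' configuration: `univalent_pair` (no chiasmata), `ring` (at least one
#' chiasma on each arm) or `open` (all chiasmata on a single arm). The
#' subtype annotation lists the region labels per arm (e.g.
#' `"ring: distal+distal"`). A ring whose chiasmata are all proximal is
#' the classic cross-bivalent morphology and is annotated with a `cross:`
#' prefix instead of `ring:`.
#'
#' @param chiasmata chiasma records for one bivalent (all rows sharing one
#'   sample/cell/bivalent key); may have zero rows.
#' @param boundaries a [region_boundaries()] object.
#' @return list with `configuration`, `subtype` and `chiasma_count`.
#' @examples
#' biv <- data.frame(sample_id = "S", cell_id = "c", bivalent_id = "b",
#'                   arm_id = c(1, 2), rel_pos = c(0.9, 0.9))
#' classify_bivalent(biv) # ring: distal+distal
#' @export
classify_bivalent <- function(chiasmata, boundaries = region_boundaries()) {
  n <- nrow(chiasmata)
  if (n == 0) {
    return(list(configuration = "univalent_pair", subtype = "univalent",
                chiasma_count = 0L))
  }
  chiasmata <- validate_chiasma_records(chiasmata)
  key <- unique(paste(chiasmata$sample_id, chiasmata$cell_id,
                      chiasmata$bivalent_id))
  if (length(key) > 1) {
    abort_validation("chiasmata from more than one bivalent supplied")
  }
  region <- classify_position(chiasmata$rel_pos, boundaries)
  arms <- sort(unique(chiasmata$arm_id))
  config <- if (length(arms) == 2) "ring" else "open"
  arm_label <- vapply(arms, function(a) {
    paste(sort(as.character(region[chiasmata$arm_id == a])), collapse = "/")
  }, character(1))
  prefix <- config
  if (config == "ring" && all(region == "proximal")) prefix <- "cross"
  list(configuration = config,
       subtype = paste0(prefix, ": ", paste(arm_label, collapse = "+")),
       chiasma_count = as.integer(n))
}

#' Derive a bivalent table from chiasma records
#'
#' Builds one [classify_bivalent()] row per bivalent. Bivalents with no
#' chiasmata cannot be inferred from chiasma records alone; supply them via
#' `univalents`, a data.frame of `sample_id`, `cell_id`, `bivalent_id`
#' keys for achiasmate pairs (and for any chiasmate cells that would
#' otherwise be lost — every cell that was scored must appear through at
#' least one bivalent).
#'
#' @param chiasmata validated chiasma records.
#' @param univalents optional data.frame of bivalent keys with zero
#'   chiasmata.
#' @param boundaries a [region_boundaries()] object.
#' @return a validated bivalent record data.frame.
#' @export
classify_bivalents <- function(chiasmata, univalents = NULL,
                               boundaries = region_boundaries()) {
  chiasmata <- validate_chiasma_records(chiasmata)
  key <- paste(chiasmata$sample_id, chiasmata$cell_id,
               chiasmata$bivalent_id, sep = "\r")
  idx <- split(seq_len(nrow(chiasmata)), key)
  # preserve first-appearance order
  idx <- idx[order(vapply(idx, min, numeric(1)))]
  rows <- lapply(idx, function(i) {
    cls <- classify_bivalent(chiasmata[i, , drop = FALSE], boundaries)
    data.frame(sample_id = chiasmata$sample_id[i[1]],
               cell_id = chiasmata$cell_id[i[1]],
               bivalent_id = chiasmata$bivalent_id[i[1]],
               is_univalent_pair = FALSE,
               chiasma_count = cls$chiasma_count,
               configuration = cls$configuration,
               subtype = cls$subtype,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (!is.null(univalents) && nrow(univalents) > 0) {
    uni <- data.frame(sample_id = as.character(univalents$sample_id),
                      cell_id = as.character(univalents$cell_id),
                      bivalent_id = as.character(univalents$bivalent_id),
                      is_univalent_pair = TRUE,
                      chiasma_count = 0L,
                      configuration = "univalent_pair",
                      subtype = "univalent",
                      stringsAsFactors = FALSE)
    out <- rbind(out, uni)
  }
  if (is.null(out)) {
    abort_validation("no bivalents to classify")
  }
  validate_bivalent_records(out)
}
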