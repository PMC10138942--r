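# Reference summary counts for the four Allium genotypes used throughout
# the examples, presets and acceptance checks: bulb onion (A. cepa, distal
# chiasma localization), bunching onion (A. fistulosum, proximal
# localization) and their F1 diploid (8F+8C) and F1 triploid (16F+8C)
# hybrids. These are published cytological summary counts; the underlying
# per-cell raw data were not deposited, so analyses start from the counts.

#' Reference Allium chiasma distribution counts
#'
#' Per-sample chiasma counts by arm region, with the number of pollen
#' mother cells and bivalents scored, for *A. cepa*, *A. fistulosum* and
#' their F1 diploid and triploid hybrids. These published summary counts
#' are used to build example datasets ([expand_chiasma_counts()]) and to
#' calibrate the simulator presets ([pmc_preset()]).
#'
#' @return data.frame: `sample_id`, `display_label`,
#'   `genome_composition`, `n_cells`, `n_bivalents`, `n_proximal`,
#'   `n_interstitial`, `n_distal`.
#' @examples
#' allium_chiasma_counts()
#' @export
allium_chiasma_counts <- function() {
  data.frame(
    sample_id = c("cepa", "fistulosum", "f1_diploid", "f1_triploid"),
    display_label = c("A. cepa", "A. fistulosum",
                      "F1 diploid hybrid", "F1 triploid hybrid"),
    genome_composition = c("16C", "16F", "8F+8C", "16F+8C"),
    n_cells = c(54L, 43L, 35L, 29L),
    n_bivalents = c(435L, 340L, 248L, 231L),
    n_proximal = c(18L, 643L, 48L, 167L),
    n_interstitial = c(207L, 8L, 180L, 110L),
    n_distal = c(808L, 11L, 191L, 146L),
    stringsAsFactors = FALSE)
}

#' Reference Allium MLH1/MUS81 focus totals
#'
#' Per-sample totals of MLH1 (class I crossover) and MUS81 (class II
#' crossover) immunofluorescence foci and the number of cells scored per
#' marker (markers scored on separate slides). Used to build example
#' per-cell datasets ([expand_foci_totals()]) and simulator presets.
#'
#' @return data.frame: `sample_id`, `marker`, `n_cells`, `total_signals`.
#' @examples
#' allium_foci_totals()
#' @export
allium_foci_totals <- function() {
  data.frame(
    sample_id = rep(c("cepa", "fistulosum", "f1_diploid", "f1_triploid"),
                    each = 2),
    marker = rep(c("MLH1", "MUS81"), times = 4),
    n_cells = c(37L, 39L, 40L, 41L, 38L, 37L, 36L, 38L),
    total_signals = c(409L, 158L, 257L, 272L, 320L, 136L, 311L, 214L),
    stringsAsFactors = FALSE)
}

#' Expand summary chiasma counts into per-record tables
#'
#' Reconstructs a chiasma/bivalent record dataset whose per-sample summary
#' reproduces the given counts exactly. Chiasmata are placed at the
#' midpoint of their region and distributed round-robin over the stated
#' number of bivalents, which are in turn distributed round-robin over the
#' stated number of cells. Positional detail beyond the region is
#' synthetic; region counts, bivalent counts, cell counts — and hence all
#' derived percentages, per-cell frequencies and contingency statistics —
#' are exact.
#'
#' @param counts data.frame in the format of [allium_chiasma_counts()].
#' @param boundaries a [region_boundaries()] object (region midpoints are
#'   taken from it).
#' @return list with validated `chiasmata`, `bivalents` and `samples`
#'   data.frames.
#' @export
expand_chiasma_counts <- function(counts = allium_chiasma_counts(),
                                  boundaries = region_boundaries()) {
  mid <- c(proximal = boundaries$lower / 2,
           interstitial = (boundaries$lower + boundaries$upper) / 2,
           distal = (boundaries$upper + 1) / 2)
  chi_rows <- list()
  biv_rows <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    n_biv <- row$n_bivalents
    biv_id <- sprintf("b%04d", seq_len(n_biv))
    cell_of_biv <- sprintf("c%03d", rep_len(seq_len(row$n_cells), n_biv))
    region <- rep(names(mid),
                  times = c(row$n_proximal, row$n_interstitial, row$n_distal))
    n_chi <- length(region)
    biv_of_chi <- rep_len(seq_len(n_biv), n_chi)
    chi_rows[[i]] <- data.frame(
      sample_id = row$sample_id,
      cell_id = cell_of_biv[biv_of_chi],
      bivalent_id = biv_id[biv_of_chi],
      arm_id = 1L,
      rel_pos = unname(mid[region]),
      stringsAsFactors = FALSE)
    n_per_biv <- tabulate(biv_of_chi, nbins = n_biv)
    biv_rows[[i]] <- data.frame(
      sample_id = row$sample_id,
      cell_id = cell_of_biv,
      bivalent_id = biv_id,
      is_univalent_pair = n_per_biv == 0L,
      chiasma_count = n_per_biv,
      configuration = ifelse(n_per_biv == 0L, "univalent_pair", "open"),
      subtype = ifelse(n_per_biv == 0L, "univalent", "open: synthetic"),
      stringsAsFactors = FALSE)
  }
  samples <- data.frame(sample_id = counts$sample_id,
                        display_label = counts$display_label,
                        genome_composition = counts$genome_composition,
                        expected_bivalents_per_cell = 8L,
                        stringsAsFactors = FALSE)
  list(chiasmata = validate_chiasma_records(do.call(rbind, chi_rows)),
       bivalents = validate_bivalent_records(do.call(rbind, biv_rows)),
       samples = validate_sample_records(samples))
}

#' Expand per-marker focus totals into per-cell records
#'
#' Reconstructs a per-cell focus-count dataset whose totals and cell
#' numbers match the given summary exactly, distributing each total as
#' evenly as possible over the cells (counts differ by at most one).
#' Marker means, totals and shares computed from the result equal those of
#' the summary at full precision; the per-cell dispersion is synthetic.
#'
#' @param totals data.frame in the format of [allium_foci_totals()].
#' @return a validated focus-count data.frame.
#' @export
expand_foci_totals <- function(totals = allium_foci_totals()) {
  rows <- lapply(seq_len(nrow(totals)), function(i) {
    row <- totals[i, ]
    base <- row$total_signals %/% row$n_cells
    extra <- row$total_signals %% row$n_cells
    cnt <- rep(base, row$n_cells)
    if (extra > 0) cnt[seq_len(extra)] <- cnt[seq_len(extra)] + 1L
    data.frame(sample_id = row$sample_id,
               slide_id = paste0(row$sample_id, "_slide_", row$marker),
               cell_id = sprintf("fc%03d", seq_len(row$n_cells)),
               marker = row$marker,
               count = cnt,
               stringsAsFactors = FALSE)
  })
  validate_foci_records(do.call(rbind, rows))
}
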