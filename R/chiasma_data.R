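# Record schemas: column names and the validators applied to each column.
CHIASMA_COLS <- c("sample_id", "cell_id", "bivalent_id", "arm_id", "rel_pos")
BIVALENT_COLS <- c("sample_id", "cell_id", "bivalent_id", "is_univalent_pair",
                   "chiasma_count", "configuration", "subtype")
FOCI_COLS <- c("sample_id", "slide_id", "cell_id", "marker", "count")
SAMPLE_COLS <- c("sample_id", "display_label", "genome_composition",
                 "expected_bivalents_per_cell")

FOCI_MARKERS <- c("MLH1", "MUS81")
BIVALENT_CONFIGS <- c("ring", "open", "univalent_pair")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf("%s table is missing column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  df[cols]
}

bad_rows_msg <- function(rows, what, detail) {
  sprintf("invalid %s in row(s) %s: %s",
          what, paste(rows, collapse = ", "), detail)
}

#' Validate chiasma records
#'
#' A chiasma record locates one observed chiasma: the sample, cell and
#' bivalent it belongs to, the arm (1 or 2), and its relative position
#' along the arm, measured from the centromere (0) toward the telomere (1).
#' Multiple records per bivalent are expected (multiple chiasmata);
#' univalent pairs carry no chiasma records and are represented in the
#' bivalent table instead.
#'
#' @param records data.frame with columns `sample_id`, `cell_id`,
#'   `bivalent_id`, `arm_id` (1 or 2), `rel_pos` (in \[0, 1\]).
#' @return the validated data.frame (columns in canonical order, types
#'   coerced).
#' @export
validate_chiasma_records <- function(records) {
  records <- check_columns(as.data.frame(records), CHIASMA_COLS, "chiasma")
  for (col in c("sample_id", "cell_id", "bivalent_id")) {
    records[[col]] <- as.character(records[[col]])
  }
  pos <- suppressWarnings(as.numeric(records$rel_pos))
  bad <- which(is.na(pos) | pos < 0 | pos > 1)
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(bad, "rel_pos",
                                  "must be numeric in [0, 1]"))
  }
  records$rel_pos <- pos
  arm <- suppressWarnings(as.integer(records$arm_id))
  bad <- which(is.na(arm) | !(arm %in% c(1L, 2L)))
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(bad, "arm_id", "must be 1 or 2"))
  }
  records$arm_id <- arm
  rownames(records) <- NULL
  records
}

#' Validate bivalent records
#'
#' One row per bivalent (or univalent pair). `chiasma_count` is the number
#' of chiasmata holding the pair together; a univalent pair has none, and
#' the two flags must agree. `configuration` is one of `ring` (at least one
#' chiasma on each arm), `open` (all chiasmata on one arm) or
#' `univalent_pair`; `subtype` is a free-text annotation of the regional
#' make-up (see [classify_bivalent()]).
#'
#' @param records data.frame with columns `sample_id`, `cell_id`,
#'   `bivalent_id`, `is_univalent_pair`, `chiasma_count`, `configuration`,
#'   `subtype`.
#' @return the validated data.frame.
#' @export
validate_bivalent_records <- function(records) {
  records <- check_columns(as.data.frame(records), BIVALENT_COLS, "bivalent")
  for (col in c("sample_id", "cell_id", "bivalent_id", "configuration",
                "subtype")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$is_univalent_pair <- as.logical(records$is_univalent_pair)
  cnt <- suppressWarnings(as.numeric(records$chiasma_count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(bad, "chiasma_count",
                                  "must be a non-negative integer"))
  }
  records$chiasma_count <- as.integer(cnt)
  bad <- which(is.na(records$is_univalent_pair) |
                 (records$is_univalent_pair != (records$chiasma_count == 0L)))
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(
      bad, "is_univalent_pair",
      "must be TRUE exactly when chiasma_count is 0"))
  }
  bad <- which(!(records$configuration %in% BIVALENT_CONFIGS))
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(
      bad, "configuration",
      sprintf("must be one of {%s}", paste(BIVALENT_CONFIGS, collapse = ", "))))
  }
  rownames(records) <- NULL
  records
}

#' Validate focus-count records
#'
#' One row per scored cell and marker: the number of MLH1 (class I
#' crossover) or MUS81 (class II crossover) immunofluorescence foci counted
#' in that cell. The two markers are scored on separate slide preparations,
#' so within one slide every cell carries exactly one marker.
#'
#' @param records data.frame with columns `sample_id`, `slide_id`,
#'   `cell_id`, `marker` (`MLH1` or `MUS81`), `count` (non-negative
#'   integer).
#' @return the validated data.frame.
#' @export
validate_foci_records <- function(records) {
  records <- check_columns(as.data.frame(records), FOCI_COLS, "foci")
  for (col in c("sample_id", "slide_id", "cell_id", "marker")) {
    records[[col]] <- as.character(records[[col]])
  }
  bad <- which(!(records$marker %in% FOCI_MARKERS))
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(
      bad, "marker",
      sprintf("must be one of {%s}", paste(FOCI_MARKERS, collapse = ", "))))
  }
  cnt <- suppressWarnings(as.numeric(records$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(bad, "count",
                                  "must be a non-negative integer"))
  }
  records$count <- as.integer(cnt)
  # one marker per slide
  if (nrow(records) > 0) {
    per_slide <- tapply(records$marker, records$slide_id,
                        function(m) length(unique(m)))
    mixed <- names(per_slide)[per_slide > 1]
    if (length(mixed) > 0) {
      abort_validation(sprintf(
        "slide(s) %s carry more than one marker; markers are scored on separate slides",
        paste(mixed, collapse = ", ")))
    }
  }
  rownames(records) <- NULL
  records
}

#' Validate sample metadata
#'
#' @param records data.frame with columns `sample_id`, `display_label`,
#'   `genome_composition`, `expected_bivalents_per_cell`.
#' @return the validated data.frame.
#' @export
validate_sample_records <- function(records) {
  records <- check_columns(as.data.frame(records), SAMPLE_COLS, "sample")
  for (col in c("sample_id", "display_label", "genome_composition")) {
    records[[col]] <- as.character(records[[col]])
  }
  if (anyDuplicated(records$sample_id)) {
    abort_validation("sample_id values must be unique")
  }
  n <- suppressWarnings(as.numeric(records$expected_bivalents_per_cell))
  bad <- which(is.na(n) | n < 1 | n != floor(n))
  if (length(bad) > 0) {
    abort_validation(bad_rows_msg(bad, "expected_bivalents_per_cell",
                                  "must be a positive integer"))
  }
  records$expected_bivalents_per_cell <- as.integer(n)
  rownames(records) <- NULL
  records
}

read_record_table <- function(path, validator) {
  if (!file.exists(path)) {
    abort_validation(sprintf("input file does not exist: %s", path))
  }
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = NULL, quote = "")
  validator(df)
}

#' Read observation tables
#'
#' Readers for the four tab-separated input tables: per-chiasma records,
#' per-bivalent records, per-cell marker focus counts and sample metadata.
#' Files are UTF-8, tab-separated with a fixed header row; row order is
#' preserved. Each reader applies the corresponding validator and reports
#' 1-based row numbers for offending rows.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a validated data.frame (see the `validate_*` functions for the
#'   schemas).
#' @seealso [write_table()] for the inverse operation.
#' @export
read_chiasma_table <- function(path) {
  read_record_table(path, validate_chiasma_records)
}

#' @rdname read_chiasma_table
#' @export
read_bivalent_table <- function(path) {
  read_record_table(path, validate_bivalent_records)
}

#' @rdname read_chiasma_table
#' @export
read_foci_table <- function(path) {
  read_record_table(path, validate_foci_records)
}

#' @rdname read_chiasma_table
#' @export
read_sample_table <- function(path) {
  read_record_table(path, validate_sample_records)
}

#' Write a record table to a tab-separated file
#'
#' Writes any of the package's record tables as UTF-8 TSV with a header.
#' Numeric columns are serialised with 17 significant digits so that
#' reading the file back reproduces the records exactly (round-trip
#' identity, including full `rel_pos` precision).
#'
#' @param records a validated record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  out <- as.data.frame(records)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8"),
    error = function(e) {
      abort_validation(sprintf("cannot write table to %s: %s",
                               path, conditionMessage(e)))
    })
  invisible(path)
}
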