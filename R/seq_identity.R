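STOP_CODONS <- c("TAA", "TAG", "TGA")

# codons containing N translate to X; unambiguous codons use the standard
# genetic code
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Read transcript sequences from a FASTA file
#'
#' @param path path to a (plain-text) FASTA file of nucleotide sequences.
#' @return named character vector of upper-case sequences.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("FASTA file does not exist: %s", path))
  }
  set <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}

# scan one frame of one strand; returns best ORF as list or NULL
scan_frame <- function(seq, frame) {
  n <- nchar(seq)
  n_codons <- (n - frame) %/% 3
  if (n_codons < 2) return(NULL)
  starts_nt <- frame + 3 * (seq_len(n_codons) - 1) + 1
  codons <- substring(seq, starts_nt, starts_nt + 2)
  atg <- which(codons == "ATG")
  stops <- which(codons %in% STOP_CODONS)
  if (length(atg) == 0 || length(stops) == 0) return(NULL)
  # first stop at or after each start
  idx <- findInterval(atg - 1L, stops) + 1L
  ok <- idx <= length(stops) & atg < stops[pmin(idx, length(stops))]
  if (!any(ok)) return(NULL)
  span <- stops[idx[ok]] - atg[ok]         # codons excluding the stop
  best <- which.max(span)                  # ties: earliest start wins
  s <- atg[ok][best]
  e <- stops[idx[ok][best]]
  list(frame = frame,
       start = frame + 3L * (s - 1L),      # 0-based, inclusive
       end = frame + 3L * e,               # 0-based, exclusive (incl. stop)
       protein = paste(translate_codons(codons[s:(e - 1L)]), collapse = ""))
}

#' Longest open reading frame and its translation
#'
#' Finds the longest ATG-to-stop open reading frame among the three
#' forward frames (transcripts are assumed sense-strand; set
#' `both_strands = TRUE` to also scan the reverse complement) and
#' translates it with the standard genetic code. ORFs must terminate in a
#' stop codon inside the sequence; ties are broken by the smallest start
#' coordinate. Codons containing `N` translate to `X`.
#'
#' @param sequence nucleotide sequence (character scalar over
#'   `A/C/G/T/N`, case-insensitive, length >= 6).
#' @param both_strands also scan the reverse complement (default FALSE).
#' @return list of class `orf_result`: `found` (logical), and when found
#'   `frame` (0/1/2), `start`, `end` (0-based half-open nucleotide
#'   coordinates on the reported `strand`, stop codon included),
#'   `protein` (amino acids, stop excluded), `strand` (`"+"` or `"-"`).
#' @examples
#' longest_orf("ATGAAATAG")$protein     # "MK"
#' longest_orf("CCATGGCCTAA")$protein   # "MA"
#' longest_orf("AAACCCGGG")$found       # FALSE
#' @export
longest_orf <- function(sequence, both_strands = FALSE) {
  seq <- toupper(as.character(sequence)[1])
  if (nchar(seq) < 6) {
    abort_validation("sequence must be at least 6 nucleotides")
  }
  if (grepl("[^ACGTN]", seq)) {
    abort_validation("sequence must contain only A, C, G, T or N")
  }
  strands <- list(`+` = seq)
  if (both_strands) {
    strands[["-"]] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  best <- NULL
  for (strand in names(strands)) {
    for (frame in 0:2) {
      orf <- scan_frame(strands[[strand]], frame)
      if (is.null(orf)) next
      orf$strand <- strand
      len <- orf$end - orf$start
      if (is.null(best) || len > (best$end - best$start) ||
          (len == best$end - best$start && orf$start < best$start &&
             strand == best$strand)) {
        best <- orf
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(found = FALSE), class = "orf_result"))
  }
  structure(c(list(found = TRUE), best), class = "orf_result")
}

#' Pairwise amino-acid identity of two protein sequences
#'
#' For sequences of equal length the comparison is positional:
#' `matches / length`. For unequal lengths a global alignment is computed
#' (match +1, mismatch 0, linear gap -1) and identity is
#' `matches / alignment length`.
#'
#' @param protein_a,protein_b non-empty amino-acid sequences (character
#'   scalars).
#' @return list of class `identity_result`: `matches`, `aligned_length`,
#'   `identity_fraction`, `percent` (identity rounded half-up to one
#'   decimal).
#' @examples
#' pairwise_identity("MKV", "MKL")$identity_fraction # 2/3
#' @export
pairwise_identity <- function(protein_a, protein_b) {
  a <- as.character(protein_a)[1]
  b <- as.character(protein_b)[1]
  if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    abort_validation("both protein sequences must be non-empty")
  }
  if (nchar(a) == nchar(b)) {
    matches <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    len <- nchar(a)
  } else {
    letters_ab <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
    sub_mat <- diag(1, length(letters_ab))
    dimnames(sub_mat) <- list(letters_ab, letters_ab)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::BString(a), Biostrings::BString(b), type = "global",
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 1)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    matches <- sum(pat == sub & pat != "-")
    len <- length(pat)
  }
  structure(list(matches = as.integer(matches),
                 aligned_length = as.integer(len),
                 identity_fraction = matches / len,
                 percent = round_half_up(100 * matches / len, 1)),
            class = "identity_result")
}

#' Identity over an explicit sub-range (e.g. a protein domain)
#'
#' Positional identity restricted to a 1-based inclusive residue range of
#' two equal-length sequences, for users who have domain coordinates.
#'
#' @param protein_a,protein_b equal-length amino-acid sequences.
#' @param start,end 1-based inclusive residue range.
#' @return an `identity_result` (see [pairwise_identity()]).
#' @export
range_identity <- function(protein_a, protein_b, start, end) {
  if (nchar(protein_a) != nchar(protein_b)) {
    abort_validation("range identity requires equal-length sequences")
  }
  if (start < 1 || end > nchar(protein_a) || start > end) {
    abort_validation("invalid residue range")
  }
  pairwise_identity(substr(protein_a, start, end),
                    substr(protein_b, start, end))
}
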