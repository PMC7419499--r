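# Internal helpers shared across modules.

# Normalize the many shapes a "reference" can arrive in (named character
# vector, Biostrings::DNAStringSet, or a sim_reference list) to a named
# character vector of uppercase chromosome sequences.
as_ref_seqs <- function(reference) {
  if (inherits(reference, "sim_reference")) {
    return(reference$seq)
  }
  if (inherits(reference, "DNAStringSet")) {
    return(stats::setNames(toupper(as.character(reference)), names(reference)))
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) {
      rlang::abort("reference sequences must be named by chromosome")
    }
    return(toupper(reference))
  }
  rlang::abort("unsupported reference type; use a named character vector or DNAStringSet")
}

ref_lengths <- function(reference) {
  seqs <- as_ref_seqs(reference)
  stats::setNames(nchar(seqs), names(seqs))
}

ref_base <- function(seqs, chrom, pos) {
  substr(seqs[[chrom]], pos, pos)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

# Translate a nucleotide string (length a multiple of 3) with the standard code.
translate_nt <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) rlang::abort("sequence length is not a multiple of 3")
  codons <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Interval tibbles use 1-based closed coordinates (chrom, start, end).
intervals_to_granges <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
  )
}

granges_to_intervals <- function(gr, label = NA_character_) {
  if (length(gr) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      label = character()
    ))
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    label = label
  )
}

#' Normalize an interval table
#'
#' Sorts and merges overlapping or adjacent intervals per chromosome so that
#' the result is pairwise disjoint and ordered. All mask constructors return
#' normalized tables; applying this twice is a no-op.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based closed).
#' @param label Optional label carried on the output rows.
#' @return Normalized interval tibble.
#' @export
normalize_intervals <- function(intervals, label = NA_character_) {
  if (nrow(intervals) == 0) {
    return(granges_to_intervals(GenomicRanges::GRanges(), label))
  }
  if (any(intervals$start > intervals$end)) {
    rlang::abort("interval start greater than end")
  }
  if (any(intervals$start < 1L)) {
    rlang::abort("intervals must use 1-based coordinates")
  }
  if (!is.na(label) || !"label" %in% names(intervals)) {
    lab <- label
  } else {
    lab <- if (length(unique(intervals$label)) == 1) intervals$label[1] else NA_character_
  }
  gr <- GenomicRanges::reduce(GenomicRanges::sort(intervals_to_granges(intervals)))
  granges_to_intervals(gr, lab)
}

site_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

`%notin%` <- function(x, table) !(x %in% table)
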