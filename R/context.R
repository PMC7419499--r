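# Sequence- and annotation-derived context: homopolymer runs, SSR regions,
# splice-junction flanks and bidirectional-transcription regions. All interval
# tables are 1-based closed, normalized (sorted, merged, disjoint).

#' Homopolymer run length at a variant position
#'
#' Length of the maximal single-base run containing the position after
#' substituting the alternate base into the reference. This mirrors the
#' intent of the GATK HRun annotation: an alternate allele that extends an
#' existing run of the same base is error-prone in homopolymer context.
#' A run length is always at least 1 (the substituted base itself).
#'
#' @param reference Named character vector of chromosome sequences (or
#'   `DNAStringSet` / `sim_reference`).
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param alt_base Alternate base(s), one of A/C/G/T, recycled against `pos`.
#' @return Integer vector of run lengths.
#' @export
#' @examples
#' homopolymer_run(c(chr1 = "GGTTTTAGG"), "chr1", 7, "T") # 5
homopolymer_run <- function(reference, chrom, pos, alt_base) {
  seqs <- as_ref_seqs(reference)
  n <- max(length(chrom), length(pos), length(alt_base))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  alt_base <- rep_len(toupper(alt_base), n)
  if (!all(alt_base %in% c("A", "C", "G", "T"))) {
    rlang::abort("alt_base must be one of A, C, G, T")
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- seqs[[chrom[i]]]
    if (is.null(s)) rlang::abort(paste0("unknown chromosome: ", chrom[i]))
    L <- nchar(s)
    p <- pos[i]
    if (is.na(p) || p < 1L || p > L) {
      rlang::abort(paste0("position out of bounds: ", chrom[i], ":", p))
    }
    b <- alt_base[i]
    run <- 1L
    j <- p - 1L
    while (j >= 1L && substr(s, j, j) == b) {
      run <- run + 1L
      j <- j - 1L
    }
    j <- p + 1L
    while (j <= L && substr(s, j, j) == b) {
      run <- run + 1L
      j <- j + 1L
    }
    out[i] <- run
  }
  out
}

#' Default SSR copy-number minima
#'
#' MISA-convention minimum copy counts per motif length (mono 10, di 6,
#' tri- through hexa-nucleotide 5).
#'
#' @return Named integer vector indexed by motif length "1".."6".
#' @export
ssr_default_min_copies <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

# A motif is primitive if its minimal period equals its length; this is what
# prevents an (AT)n tract from also being reported as (ATAT)n, and a
# mononucleotide run from being reported at every even motif length.
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(motif, 1L, d), k %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Detect simple sequence repeat (microsatellite) regions
#'
#' Scans each chromosome for perfect tandem repeats of 1-6 bp motifs meeting
#' per-motif-length copy minima, reports each tract extended by `flank_bp`
#' bases on each side (clipped to the chromosome), and merges overlaps.
#' Tracts are found left-to-right per motif length over full motif copies;
#' non-primitive motifs are skipped so each tract is reported once.
#'
#' @inheritParams homopolymer_run
#' @param min_copies Named vector of copy minima per motif length, as
#'   [ssr_default_min_copies()].
#' @param flank_bp Bases added on each side of a tract (default 3).
#' @return Normalized interval tibble (`chrom`, `start`, `end`, `label`).
#' @export
detect_ssr_regions <- function(reference,
                               min_copies = ssr_default_min_copies(),
                               flank_bp = 3L) {
  if (flank_bp < 0) rlang::abort("flank_bp must be >= 0")
  seqs <- as_ref_seqs(reference)
  rows <- list()
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    L <- nchar(s)
    for (k in 1:6) {
      minc <- as.integer(min_copies[[as.character(k)]])
      if (is.na(minc) || minc < 2L) {
        rlang::abort("min_copies must give a copy minimum >= 2 for motif lengths 1-6")
      }
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minc - 1L)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      for (i in seq_along(m)) {
        start <- m[i]
        motif <- substr(s, start, start + k - 1L)
        if (!is_primitive_motif(motif)) next
        end <- start + lens[i] - 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = chrom,
          start = max(1L, start - as.integer(flank_bp)),
          end = min(L, end + as.integer(flank_bp))
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(normalize_intervals(tibble::tibble(
      chrom = character(), start = integer(), end = integer()
    ), label = "ssr"))
  }
  normalize_intervals(dplyr::bind_rows(rows), label = "ssr")
}

# Exon table -> per-transcript intron tibble (1-based closed).
introns_from_annotation <- function(annotation) {
  exons <- dplyr::filter(annotation, .data$type == "exon")
  if (nrow(exons) == 0) return(tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    transcript_id = character()
  ))
  ordered <- exons |>
    dplyr::group_by(.data$transcript_id, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(.prev_end = dplyr::lag(cummax(.data$end))) |>
    dplyr::ungroup()
  overlapping <- !is.na(ordered$.prev_end) & ordered$start <= ordered$.prev_end
  if (any(overlapping)) {
    rlang::abort(paste0("malformed exon order in transcript ",
                        ordered$transcript_id[which(overlapping)[1]]))
  }
  ordered |>
    dplyr::filter(!is.na(.data$.prev_end)) |>
    dplyr::transmute(
      chrom = .data$chrom,
      intron_start = .data$.prev_end + 1L,
      intron_end = .data$start - 1L,
      transcript_id = .data$transcript_id
    ) |>
    dplyr::filter(.data$intron_end >= .data$intron_start) |>
    dplyr::rename(start = "intron_start", end = "intron_end")
}

#' Splice-junction mask
#'
#' For every intron of every multi-exon transcript, masks the first and last
#' `flank_bp` intronic bases (clipped for short introns). Single-exon
#' transcripts contribute nothing.
#'
#' @param annotation Annotation tibble with at least `type`, `chrom`, `start`,
#'   `end`, `transcript_id` (as returned by [read_gtf()]).
#' @param flank_bp Intronic flank width in bases (default 5).
#' @return Normalized interval tibble.
#' @export
splice_junction_mask <- function(annotation, flank_bp = 5L) {
  introns <- introns_from_annotation(annotation)
  if (nrow(introns) == 0) {
    return(normalize_intervals(tibble::tibble(
      chrom = character(), start = integer(), end = integer()
    ), label = "junction"))
  }
  f <- as.integer(flank_bp)
  masks <- dplyr::bind_rows(
    dplyr::transmute(introns, chrom = .data$chrom,
                     start = .data$start,
                     end = pmin(.data$start + f - 1L, .data$end)),
    dplyr::transmute(introns, chrom = .data$chrom,
                     start = pmax(.data$end - f + 1L, .data$start),
                     end = .data$end)
  )
  normalize_intervals(masks, label = "junction")
}

#' Bidirectional-transcription mask
#'
#' Regions covered by annotated gene bodies on both strands: the intersection
#' of the union of '+'-strand gene bodies with the union of '-'-strand gene
#' bodies, per chromosome. Overlapping same-strand genes do not create a mask.
#'
#' @inheritParams splice_junction_mask
#' @return Normalized interval tibble.
#' @export
bidirectional_mask <- function(annotation) {
  genes <- dplyr::filter(annotation, .data$type == "gene")
  plus <- dplyr::filter(genes, .data$strand == "+")
  minus <- dplyr::filter(genes, .data$strand == "-")
  if (nrow(plus) == 0 || nrow(minus) == 0) {
    return(normalize_intervals(tibble::tibble(
      chrom = character(), start = integer(), end = integer()
    ), label = "bidirectional"))
  }
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(intervals_to_granges(plus)),
    GenomicRanges::reduce(intervals_to_granges(minus))
  )
  out <- granges_to_intervals(gr, label = "bidirectional")
  normalize_intervals(out, label = "bidirectional")
}

#' Point-in-mask lookup
#'
#' Tests whether 1-based positions fall inside any interval of a normalized
#' mask. Backed by GenomicRanges overlap machinery (interval trees), so the
#' lookup is logarithmic in the number of intervals.
#'
#' @param intervals Normalized interval tibble.
#' @param chrom Chromosome name(s).
#' @param pos_1based Position(s), recycled against `chrom`.
#' @return Logical vector.
#' @export
point_in_mask <- function(intervals, chrom, pos_1based) {
  n <- max(length(chrom), length(pos_1based))
  chrom <- rep_len(chrom, n)
  pos_1based <- rep_len(as.integer(pos_1based), n)
  if (nrow(intervals) == 0) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos_1based, pos_1based))
  # a query chromosome with no mask intervals is a legitimate miss, not a
  # seqlevel mismatch worth warning about
  suppressWarnings(
    GenomicRanges::countOverlaps(q, intervals_to_granges(intervals)) > 0
  )
}

#' Compute all context masks for a reference + annotation
#'
#' Convenience wrapper returning the three masks used by the filter cascade.
#'
#' @inheritParams detect_ssr_regions
#' @inheritParams splice_junction_mask
#' @param ssr_min_copies Copy minima forwarded to [detect_ssr_regions()].
#' @param ssr_flank_bp SSR flank in bases (default 3).
#' @param junction_flank_bp Splice-junction intronic flank (default 5).
#' @return Named list of normalized interval tibbles:
#'   `ssr`, `junction`, `bidirectional`.
#' @export
context_masks <- function(reference, annotation,
                          ssr_min_copies = ssr_default_min_copies(),
                          ssr_flank_bp = 3L,
                          junction_flank_bp = 5L) {
  list(
    ssr = detect_ssr_regions(reference, ssr_min_copies, ssr_flank_bp),
    junction = splice_junction_mask(annotation, junction_flank_bp),
    bidirectional = bidirectional_mask(annotation)
  )
}

#' Export masks as BED
#'
#' Writes a normalized interval tibble as a BED file (0-based half-open).
#'
#' @param intervals Normalized interval tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_bed <- function(intervals, path) {
  bed <- tibble::tibble(
    chrom = intervals$chrom,
    start = intervals$start - 1L,
    end = intervals$end,
    name = intervals$label %||% "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
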