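# Variant consequence classification against a transcript model, with the
# fixed term -> impact mapping used for reporting.

#' Consequence terms in severity order
#'
#' Fixed severity order used to collapse per-transcript calls into one
#' summary consequence per variant (most severe first).
#'
#' @return Character vector of terms.
#' @export
consequence_terms <- function() {
  c("stop_gained", "stop_lost", "start_lost", "missense", "stop_retained",
    "synonymous", "five_prime_utr", "three_prime_utr", "intron",
    "upstream_gene", "downstream_gene", "other", "intergenic")
}

#' Impact class of a consequence term
#'
#' Total, fixed mapping: disruptive coding changes are HIGH, missense is
#' MODERATE, silent coding changes are LOW, and everything non-coding is
#' MODIFIER.
#'
#' @param term Character vector of consequence terms.
#' @return Character vector of impact classes.
#' @export
impact_of <- function(term) {
  map <- c(
    stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
    missense = "MODERATE",
    synonymous = "LOW", stop_retained = "LOW",
    five_prime_utr = "MODIFIER", three_prime_utr = "MODIFIER",
    intron = "MODIFIER", upstream_gene = "MODIFIER",
    downstream_gene = "MODIFIER", other = "MODIFIER",
    intergenic = "MODIFIER"
  )
  out <- unname(map[term])
  if (anyNA(out)) {
    bad <- unique(term[is.na(out)])
    rlang::abort(paste0("unknown consequence term: ", paste(bad, collapse = ", ")))
  }
  out
}

#' Build per-transcript CDS models
#'
#' For every transcript with CDS records, extracts the spliced CDS sequence
#' from the reference (reverse-complemented for '-' strand transcripts) and
#' the genomic-to-CDS coordinate map.
#'
#' @param annotation Annotation tibble (see [read_gtf()]).
#' @param reference Reference sequences.
#' @return Named list (by transcript id) of models with elements `seq`,
#'   `strand`, `chrom`, `gene_id`, `transcript_id`, `map`.
#' @export
build_cds_models <- function(annotation, reference) {
  seqs <- as_ref_seqs(reference)
  cds <- dplyr::filter(annotation, .data$type == "CDS")
  if (nrow(cds) == 0) return(list())
  models <- list()
  for (tx in unique(cds$transcript_id)) {
    rows <- cds |>
      dplyr::filter(.data$transcript_id == tx) |>
      dplyr::arrange(.data$start)
    chrom <- rows$chrom[1]
    strand <- rows$strand[1]
    pieces <- substring(seqs[[chrom]], rows$start, rows$end)
    seq <- paste(pieces, collapse = "")
    if (strand == "-") seq <- revcomp(seq)
    widths <- rows$end - rows$start + 1L
    if (strand == "+") {
      cds_start <- cumsum(c(1L, widths[-length(widths)]))
      map <- tibble::tibble(gs = rows$start, ge = rows$end,
                            cds_start = cds_start,
                            cds_end = cds_start + widths - 1L)
    } else {
      ord <- rev(seq_len(nrow(rows)))
      w <- widths[ord]
      cds_start <- cumsum(c(1L, w[-length(w)]))
      map <- tibble::tibble(gs = rows$start[ord], ge = rows$end[ord],
                            cds_start = cds_start,
                            cds_end = cds_start + w - 1L)
    }
    models[[tx]] <- list(seq = seq, strand = strand, chrom = chrom,
                         gene_id = rows$gene_id[1], transcript_id = tx,
                         map = map)
  }
  models
}

# CDS coordinate (1-based along the spliced CDS) -> genomic position.
cds_to_genomic <- function(model, cds_pos) {
  m <- model$map
  i <- which(cds_pos >= m$cds_start & cds_pos <= m$cds_end)[1]
  if (is.na(i)) rlang::abort("CDS position outside model")
  if (model$strand == "+") {
    m$gs[i] + (cds_pos - m$cds_start[i])
  } else {
    m$ge[i] - (cds_pos - m$cds_start[i])
  }
}

# Genomic position -> CDS coordinate, or NA when outside the CDS.
genomic_to_cds <- function(model, pos) {
  m <- model$map
  i <- which(pos >= m$gs & pos <= m$ge)[1]
  if (is.na(i)) return(NA_integer_)
  if (model$strand == "+") {
    m$cds_start[i] + (pos - m$gs[i])
  } else {
    m$cds_start[i] + (m$ge[i] - pos)
  }
}

classify_in_transcript <- function(pos, alt, tx, exons, model) {
  strand <- tx$strand
  # CDS?
  if (!is.null(model)) {
    cds_pos <- genomic_to_cds(model, pos)
    if (!is.na(cds_pos)) {
      tx_alt <- if (strand == "+") alt else complement_base(alt)
      ci <- (cds_pos - 1L) %/% 3L + 1L
      off <- (cds_pos - 1L) %% 3L + 1L
      codon_ref <- substr(model$seq, 3L * ci - 2L, 3L * ci)
      codon_alt <- codon_ref
      substr(codon_alt, off, off) <- tx_alt
      aa_ref <- translate_codon(codon_ref)
      aa_alt <- translate_codon(codon_alt)
      term <- if (ci == 1L && codon_ref == "ATG" && codon_alt != "ATG") {
        "start_lost"
      } else if (aa_ref != "*" && aa_alt == "*") {
        "stop_gained"
      } else if (aa_ref == "*" && aa_alt != "*") {
        "stop_lost"
      } else if (aa_ref == "*" && aa_alt == "*") {
        "stop_retained"
      } else if (aa_ref == aa_alt) {
        "synonymous"
      } else {
        "missense"
      }
      return(list(term = term,
                  codon_change = paste0(codon_ref, ">", codon_alt),
                  aa_change = paste0(aa_ref, as.character(ci), aa_alt)))
    }
  }
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  if (in_exon) {
    if (is.null(model)) return(list(term = "other", codon_change = NA, aa_change = NA))
    # exonic but outside CDS: UTR side by transcript orientation
    cds_gmin <- min(model$map$gs)
    cds_gmax <- max(model$map$ge)
    before <- pos < cds_gmin
    term <- if ((before && strand == "+") || (!before && strand == "-")) {
      "five_prime_utr"
    } else {
      "three_prime_utr"
    }
    return(list(term = term, codon_change = NA_character_, aa_change = NA_character_))
  }
  list(term = "intron", codon_change = NA_character_, aa_change = NA_character_)
}

#' Classify variant consequences
#'
#' Assigns one consequence call per overlapping transcript (coding changes
#' translated with the standard genetic code, reverse-complemented for '-'
#' strand transcripts), plus upstream/downstream calls for variants within
#' `up_down_bp` of a transcript and `intergenic` otherwise. Use
#' [most_severe_consequence()] to collapse to one call per variant.
#'
#' @param sites Site tibble with `chrom`, `pos`, `ref`, `alt`
#'   (biallelic SNPs).
#' @param annotation Annotation tibble.
#' @param reference Reference sequences.
#' @param up_down_bp Up/downstream window in bp (default 5000).
#' @return Tibble of per-transcript calls: variant key columns plus
#'   `gene_id`, `transcript_id`, `term`, `impact`, `codon_change`,
#'   `aa_change`.
#' @export
classify_consequences <- function(sites, annotation, reference,
                                  up_down_bp = 5000L) {
  seqs <- as_ref_seqs(reference)
  refb <- vapply(seq_len(nrow(sites)),
                 function(i) ref_base(seqs, sites$chrom[i], sites$pos[i]), "")
  bad <- which(refb != sites$ref)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "variant REF disagrees with the reference sequence at ",
      sites$chrom[bad[1]], ":", sites$pos[bad[1]]
    ))
  }
  txs <- dplyr::filter(annotation, .data$type == "transcript")
  exons_all <- dplyr::filter(annotation, .data$type == "exon")
  models <- build_cds_models(annotation, reference)
  tx_gr <- intervals_to_granges(txs)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    pos <- sites$pos[i]
    alt <- sites$alt[i]
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(tx_gr, q))
    base_row <- tibble::tibble(chrom = chrom, pos = pos,
                               ref = sites$ref[i], alt = alt)
    if (length(hit) > 0) {
      for (h in hit) {
        tx <- txs[h, ]
        exons <- dplyr::filter(exons_all, .data$transcript_id == tx$transcript_id)
        cls <- classify_in_transcript(pos, alt, tx, exons,
                                      models[[tx$transcript_id]])
        out[[length(out) + 1L]] <- dplyr::mutate(
          base_row, gene_id = tx$gene_id, transcript_id = tx$transcript_id,
          term = cls$term,
          codon_change = as.character(cls$codon_change),
          aa_change = as.character(cls$aa_change)
        )
      }
    } else {
      near <- txs |>
        dplyr::filter(.data$chrom == !!chrom,
                      .data$start - !!up_down_bp <= pos,
                      .data$end + !!up_down_bp >= pos)
      if (nrow(near) > 0) {
        for (h in seq_len(nrow(near))) {
          tx <- near[h, ]
          before <- pos < tx$start
          term <- if ((before && tx$strand == "+") || (!before && tx$strand == "-")) {
            "upstream_gene"
          } else {
            "downstream_gene"
          }
          out[[length(out) + 1L]] <- dplyr::mutate(
            base_row, gene_id = tx$gene_id, transcript_id = tx$transcript_id,
            term = term, codon_change = NA_character_, aa_change = NA_character_
          )
        }
      } else {
        out[[length(out) + 1L]] <- dplyr::mutate(
          base_row, gene_id = NA_character_, transcript_id = NA_character_,
          term = "intergenic", codon_change = NA_character_,
          aa_change = NA_character_
        )
      }
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(impact = impact_of(.data$term))
}

#' Collapse per-transcript calls to one summary consequence per variant
#'
#' Keeps, for each variant, the most severe term under the fixed severity
#' order of [consequence_terms()] (ties broken by transcript id).
#'
#' @param calls Per-transcript call tibble from [classify_consequences()].
#' @return One-row-per-variant tibble.
#' @export
most_severe_consequence <- function(calls) {
  sev <- match(calls$term, consequence_terms())
  calls |>
    dplyr::mutate(.sev = sev) |>
    dplyr::arrange(.data$.sev, .data$transcript_id) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(".sev")) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Tabulate consequence calls by term and by impact
#'
#' Both tables are completed with zero rows for unobserved levels, so each
#' is a partition of the input variants (term counts and impact counts both
#' sum to the number of variants).
#'
#' @param summary_calls One-call-per-variant tibble
#'   (see [most_severe_consequence()]).
#' @return List with `by_term` and `by_impact` count tibbles.
#' @export
tabulate_consequences <- function(summary_calls) {
  terms <- consequence_terms()
  by_term <- summary_calls |>
    dplyr::count(term = factor(.data$term, levels = terms), .drop = FALSE) |>
    dplyr::mutate(term = as.character(.data$term))
  impacts <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  by_impact <- summary_calls |>
    dplyr::count(impact = factor(.data$impact, levels = impacts), .drop = FALSE) |>
    dplyr::mutate(impact = as.character(.data$impact))
  list(by_term = by_term, by_impact = by_impact)
}
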