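# QTL interval colocalization: SNP positions vs trait-labelled intervals
# (1-based, inclusive ends, the AnimalQTLdb convention).

#' Load trait-labelled QTL intervals
#'
#' Reads a QTL TSV (columns `trait_name`, `chrom`, `start_1based`,
#' `end_1based`, `qtl_id`; plain `start`/`end` are also accepted), drops
#' malformed rows with a warning naming their line numbers, and optionally
#' restricts to a trait whitelist. Duplicate QTL ids are kept — overlapping
#' QTL entries are real.
#'
#' @param path QTL TSV path.
#' @param trait_whitelist Optional character vector of trait names to keep.
#' @return Tibble with `qtl_id`, `trait_name`, `chrom`, `start`, `end`.
#' @export
load_qtls <- function(path, trait_whitelist = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  nm <- names(raw)
  start_col <- if ("start_1based" %in% nm) "start_1based" else "start"
  end_col <- if ("end_1based" %in% nm) "end_1based" else "end"
  required <- c("trait_name", "chrom", start_col, end_col, "qtl_id")
  if (!all(required %in% nm)) {
    rlang::abort(paste0("QTL table missing columns: ",
                        paste(setdiff(required, nm), collapse = ", ")))
  }
  out <- tibble::tibble(
    qtl_id = raw$qtl_id,
    trait_name = raw$trait_name,
    chrom = raw$chrom,
    start = suppressWarnings(as.integer(raw[[start_col]])),
    end = suppressWarnings(as.integer(raw[[end_col]])),
    line = seq_len(nrow(raw)) + 1L
  )
  bad <- is.na(out$start) | is.na(out$end) | out$start > out$end |
    is.na(out$trait_name) | out$trait_name == "" | is.na(out$chrom)
  if (any(bad)) {
    rlang::warn(paste0("rejected malformed QTL rows at lines: ",
                       paste(out$line[bad], collapse = ", ")))
    out <- out[!bad, ]
  }
  out <- dplyr::select(out, -dplyr::all_of("line"))
  if (!is.null(trait_whitelist)) {
    out <- dplyr::filter(out, .data$trait_name %in% trait_whitelist)
  }
  out
}

#' Colocalize SNPs with QTL intervals
#'
#' Intersects SNP positions with QTL intervals (inclusive ends) and reports
#' (a) the distinct SNPs overlapping at least one QTL, (b) the total
#' SNP-by-QTL pair count, and (c) per-trait distinct-SNP counts. A SNP
#' inside several QTLs of one trait counts once for that trait's distinct
#' tally but once per QTL in the pair tally.
#'
#' @param sites Site tibble with `chrom`, `pos`.
#' @param qtls QTL tibble from [load_qtls()].
#' @return A `qtl_overlap` object: `pairs` (site x QTL rows),
#'   `n_distinct_snps`, `n_pairs`, `per_trait`, `n_sites`.
#' @export
colocalize <- function(sites, qtls) {
  sites <- dplyr::distinct(sites, .data$chrom, .data$pos)
  if (nrow(sites) == 0 || nrow(qtls) == 0) {
    pairs <- tibble::tibble(chrom = character(), pos = integer(),
                            qtl_id = character(), trait_name = character())
  } else {
    q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    s <- GenomicRanges::GRanges(qtls$chrom, IRanges::IRanges(qtls$start, qtls$end))
    hits <- GenomicRanges::findOverlaps(q, s)
    pairs <- tibble::tibble(
      chrom = sites$chrom[S4Vectors::queryHits(hits)],
      pos = sites$pos[S4Vectors::queryHits(hits)],
      qtl_id = qtls$qtl_id[S4Vectors::subjectHits(hits)],
      trait_name = qtls$trait_name[S4Vectors::subjectHits(hits)]
    ) |>
      dplyr::arrange(.data$chrom, .data$pos, .data$qtl_id)
  }
  per_trait <- pairs |>
    dplyr::distinct(.data$trait_name, .data$chrom, .data$pos) |>
    dplyr::count(.data$trait_name, name = "n_snps") |>
    dplyr::arrange(dplyr::desc(.data$n_snps))
  structure(list(
    pairs = pairs,
    n_distinct_snps = nrow(dplyr::distinct(pairs, .data$chrom, .data$pos)),
    n_pairs = nrow(pairs),
    per_trait = per_trait,
    n_sites = nrow(sites)
  ), class = "qtl_overlap")
}

#' @export
print.qtl_overlap <- function(x, ...) {
  cat("QTL colocalization:", x$n_distinct_snps, "of", x$n_sites,
      "SNPs in QTL regions (", x$n_pairs, "SNP x QTL pairs )\n")
  print(x$per_trait)
  invisible(x)
}

#' Per-trait distinct SNP counts
#'
#' @param x A `qtl_overlap`.
#' @param ... Unused.
#' @return Tibble `trait_name`, `n_snps`.
#' @export
tidy.qtl_overlap <- function(x, ...) {
  x$per_trait
}

#' One-row colocalization summary
#'
#' @param x A `qtl_overlap`.
#' @param ... Unused.
#' @return One-row tibble of totals and the QTL-region percentage.
#' @export
glance.qtl_overlap <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_sites = x$n_sites, n_distinct_snps = x$n_distinct_snps,
                   n_pairs = x$n_pairs),
    qtl_fraction(x$n_distinct_snps, x$n_sites)[, c("fraction", "percent")]
  )
}

#' Fraction of SNPs inside QTL regions
#'
#' `100 * n_overlapping / n_total`, with the percentage rounded to the
#' nearest integer for reporting and the full-precision fraction retained.
#'
#' @param n_overlapping Distinct SNPs overlapping at least one QTL (or a
#'   `qtl_overlap` object, in which case `n_total` defaults to its site
#'   count).
#' @param n_total Total SNP count.
#' @return One-row tibble: `n_overlapping`, `n_total`, `fraction`,
#'   `percent`.
#' @export
qtl_fraction <- function(n_overlapping, n_total = NULL) {
  if (inherits(n_overlapping, "qtl_overlap")) {
    ov <- n_overlapping
    n_total <- n_total %||% ov$n_sites
    n_overlapping <- ov$n_distinct_snps
  }
  if (is.null(n_total) || n_total == 0) {
    rlang::warn("zero SNPs; QTL fraction is undefined")
    return(tibble::tibble(n_overlapping = n_overlapping, n_total = n_total %||% 0,
                          fraction = NA_real_, percent = NA_real_))
  }
  frac <- n_overlapping / n_total
  tibble::tibble(n_overlapping = n_overlapping, n_total = n_total,
                 fraction = frac, percent = round(100 * frac))
}
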