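# Readers and writers for the standard formats the pipeline touches.
# FASTA via Biostrings, GTF via rtracklayer, VCF parsing via vcfR; coordinates
# in memory are 1-based closed throughout.

#' Read a reference FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_ref_seqs(x)
}

#' Write a reference FASTA (with .fai index)
#'
#' @param reference Named character vector / DNAStringSet / `sim_reference`.
#' @param path Output path.
#' @param index Also write a samtools-style .fai index (default TRUE).
#' @return The path, invisibly.
#' @export
write_fasta <- function(reference, path, index = TRUE) {
  seqs <- as_ref_seqs(reference)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  if (index) Rsamtools::indexFa(path)
  invisible(path)
}

#' Read a gene annotation GTF
#'
#' Imports a GTF (1-based closed, Ensembl dialect) into the flat annotation
#' tibble used throughout the package.
#'
#' @param path GTF path.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `type`, `gene_id`,
#'   `transcript_id`, `exon_number`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = if ("gene_id" %in% names(md)) as.character(md$gene_id) else NA_character_,
    transcript_id = if ("transcript_id" %in% names(md)) as.character(md$transcript_id) else NA_character_,
    exon_number = if ("exon_number" %in% names(md)) suppressWarnings(as.integer(md$exon_number)) else NA_integer_
  )
}

#' Write an annotation tibble as GTF
#'
#' @param annotation Annotation tibble (see [read_gtf()] for columns).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand
  )
  md <- S4Vectors::DataFrame(
    source = "tailvar",
    type = annotation$type,
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id
  )
  if ("exon_number" %in% names(annotation)) md$exon_number <- annotation$exon_number
  if ("frame" %in% names(annotation)) md$phase <- annotation$frame
  S4Vectors::mcols(gr) <- md
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

info_keys <- c("DP", "QD", "MQ", "MQRankSum", "ReadPosRankSum")
info_cols <- c("dp", "qd", "mq", "mq_rank_sum", "read_pos_rank_sum")

#' Read a multi- or single-sample VCF into a long call tibble
#'
#' Parses a VCF v4.2 file (via vcfR) into the package's long "calls" layout:
#' one row per site x sample, with site-level columns (alleles, QUAL, the
#' INFO keys DP, QD, MQ, MQRankSum, ReadPosRankSum) repeated per sample and
#' per-sample GT / AD / DP fields parsed out. Sites with no sample columns
#' yield one row with `sample_id = NA`.
#'
#' @param path VCF path (plain or bgzipped).
#' @return Long call tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `qual`, `dp`, `qd`, `mq`, `mq_rank_sum`, `read_pos_rank_sum`,
#'   `sample_id`, `gt`, `ad`, `sample_dp`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = dplyr::if_else(fix$ID %in% c(".", ""), NA_character_, fix$ID),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  for (i in seq_along(info_keys)) {
    val <- suppressWarnings(
      vcfR::extract.info(v, element = info_keys[i], as.numeric = TRUE)
    )
    sites[[info_cols[i]]] <- if (is.null(val)) NA_real_ else as.numeric(val)
  }
  n_samp <- ncol(v@gt) - 1L
  if (is.null(v@gt) || is.na(n_samp) || n_samp < 1L) {
    return(dplyr::mutate(sites, sample_id = NA_character_, gt = NA_character_,
                         ad = NA_character_, sample_dp = NA_integer_))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  sdp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  samples <- colnames(v@gt)[-1]
  long <- purrr::map_dfr(seq_along(samples), function(j) {
    ad_j <- unname(ad[, j])
    ad_j[!is.na(ad_j) & ad_j == "."] <- NA_character_
    gt_j <- unname(gt[, j])
    gt_j[is.na(gt_j) | gt_j == "."] <- "./."
    dplyr::mutate(
      sites,
      sample_id = samples[j],
      gt = gt_j,
      ad = ad_j,
      sample_dp = as.integer(unname(sdp[, j]))
    )
  })
  dplyr::arrange(long, .data$chrom, .data$pos, .data$sample_id)
}

#' Write a long call tibble as a VCF v4.2 file
#'
#' Inverse of [read_vcf()] for the package's call layout. Sample columns are
#' emitted as GT:AD:DP in sample-name order.
#'
#' @param calls Long call tibble (see [read_vcf()]).
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tailvar",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth of coverage\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
  )
  sites <- calls |>
    dplyr::distinct(.data$chrom, .data$pos, .data$id, .data$ref, .data$alt,
                    .data$qual, .data$dp, .data$qd, .data$mq,
                    .data$mq_rank_sum, .data$read_pos_rank_sum) |>
    dplyr::arrange(.data$chrom, .data$pos)
  fmt_num <- function(x) ifelse(is.na(x), NA_character_, format(x, trim = TRUE, scientific = FALSE))
  info <- purrr::pmap_chr(
    sites[, c("dp", "qd", "mq", "mq_rank_sum", "read_pos_rank_sum")],
    function(dp, qd, mq, mq_rank_sum, read_pos_rank_sum) {
      vals <- c(DP = fmt_num(dp), QD = fmt_num(qd), MQ = fmt_num(mq),
                MQRankSum = fmt_num(mq_rank_sum),
                ReadPosRankSum = fmt_num(read_pos_rank_sum))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) "." else paste(names(vals), vals, sep = "=", collapse = ";")
    }
  )
  body <- tibble::tibble(
    CHROM = sites$chrom, POS = sites$pos,
    ID = dplyr::if_else(is.na(sites$id), ".", sites$id),
    REF = sites$ref, ALT = sites$alt,
    QUAL = dplyr::if_else(is.na(sites$qual), ".", fmt_num(sites$qual)),
    FILTER = ".", INFO = info
  )
  samples <- sort(unique(calls$sample_id[!is.na(calls$sample_id)]))
  if (length(samples) > 0) {
    body$FORMAT <- "GT:AD:DP"
    keyed <- calls |>
      dplyr::filter(!is.na(.data$sample_id)) |>
      dplyr::mutate(
        key = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
        cell = paste(
          dplyr::if_else(is.na(.data$gt), "./.", .data$gt),
          dplyr::if_else(is.na(.data$ad), ".", .data$ad),
          dplyr::if_else(is.na(.data$sample_dp), ".", as.character(.data$sample_dp)),
          sep = ":"
        )
      )
    skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
    for (s in samples) {
      cells <- keyed |> dplyr::filter(.data$sample_id == s)
      body[[s]] <- cells$cell[match(skey, cells$key)]
      body[[s]][is.na(body[[s]])] <- "./.:.:."
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste0("#", paste(names(body), collapse = "\t")), con)
  lines <- do.call(paste, c(unname(as.list(body)), sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read a known-SNP database VCF
#'
#' Loads a sites-only VCF of known SNPs into the keyed lookup used by
#' [known_filter()]. Multi-allelic records are expanded so each
#' (chrom, pos, ref, alt) key appears once.
#'
#' @param path VCF path.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `rsid`.
#' @export
read_known_db <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    rsid = fix$ID
  ) |>
    tidyr::separate_longer_delim(dplyr::all_of("alt"), delim = ",") |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
}

#' Write a known-SNP database VCF
#'
#' @param db Tibble with `chrom`, `pos`, `ref`, `alt`, `rsid`.
#' @param path Output path.
#' @param contig_lengths Optional named contig lengths for the header.
#' @return The path, invisibly.
#' @export
write_known_db <- function(db, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tailvar-known-db",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  db <- dplyr::arrange(db, .data$chrom, .data$pos)
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                   db$chrom, db$pos, db$rsid, db$ref, db$alt)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a breed panel table
#'
#' @param path TSV with columns `sample_id`, `breed`.
#' @return Panel tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), breed = readr::col_character()
  ))
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  if (!all(c("sample_id", "breed") %in% names(panel))) {
    rlang::abort("panel must have columns sample_id and breed")
  }
  if (anyDuplicated(panel$sample_id)) {
    rlang::abort("sample ids must be unique across breeds")
  }
  invisible(panel)
}

#' Read a gene-set definition table
#'
#' @param path TSV with columns `term_id`, `term_name`, `gene_id`.
#' @return Gene-set tibble (one row per term-gene membership).
#' @export
read_gene_sets <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    term_id = readr::col_character(), term_name = readr::col_character(),
    gene_id = readr::col_character()
  )) |>
    dplyr::distinct(.data$term_id, .data$term_name, .data$gene_id)
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `fdr`.
#' @return DEG tibble.
#' @export
read_deg <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), log2fc = readr::col_double(),
    fdr = readr::col_double()
  ))
}

tailvar_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tailvar")
  if (path == "") rlang::abort(paste0("bundled file not found: ", file))
  path
}

#' Bundled sheep cohort alignment statistics
#'
#' Per-sample read and alignment counts for the motivating eight-animal
#' (four fat-tailed Lori-Bakhtiari, four thin-tailed Zel) sheep fat-tail
#' RNA-seq experiment, as published: raw and trimmed read counts, total
#' mapped reads, and uniquely-and-concordantly mapped reads with
#' percentages.
#'
#' @return Tibble, one row per sample.
#' @export
sheep_alignment_stats <- function() {
  readr::read_tsv(tailvar_extdata("alignment_stats.tsv"),
                  col_types = readr::cols(
                    sample = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Bundled breed-specific SNP consequence counts
#'
#' Published consequence-term and impact-class counts of the breed-specific
#' SNPs in the motivating sheep cohort (columns `lori_bakhtiari` and `zel`),
#' split into `category = "type"` (consequence terms) and
#' `category = "impact"` rows.
#'
#' @return Tibble with `category`, `level`, `lori_bakhtiari`, `zel`.
#' @export
sheep_consequence_counts <- function() {
  readr::read_tsv(tailvar_extdata("breed_specific_consequences.tsv"),
                  col_types = readr::cols(
                    category = readr::col_character(),
                    level = readr::col_character(),
                    lori_bakhtiari = readr::col_double(),
                    zel = readr::col_double()
                  ))
}

#' Bundled headline SNP counts for the sheep cohort
#'
#' Published cohort-level counts (confident, known, per-breed, common,
#' breed-specific and QTL-overlapping SNP totals) used by the worked
#' examples.
#'
#' @return Named numeric vector.
#' @export
sheep_snp_counts <- function() {
  x <- readr::read_tsv(tailvar_extdata("cohort_snp_counts.tsv"),
                       col_types = readr::cols(
                         metric = readr::col_character(),
                         value = readr::col_double()
                       ))
  stats::setNames(x$value, x$metric)
}
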