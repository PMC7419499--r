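# The stringent confidence cascade: SNP/biallelic selection, hard
# annotation cut-offs, per-sample read support, context masks, known-SNP
# intersection. Each stage reports survivors so the cascade is auditable.

CASCADE_STAGES <- c("input", "biallelic_snp", "hard_filter", "alt_support",
                    "region_mask", "known_snp")

#' Default hard-filter thresholds
#'
#' Variant-annotation cut-offs: a site is eliminated when total depth < 10,
#' homopolymer run > 5, RMS mapping quality < 40, mapping-quality rank sum
#' < -12.5, quality-by-depth < 2, or read-position rank sum < -8. All
#' inequalities are strict; a missing annotation cannot trigger its rule.
#'
#' @return Named list of thresholds.
#' @export
hard_filter_defaults <- function() {
  list(min_dp = 10, max_hrun = 5, min_mq = 40, min_mq_rank_sum = -12.5,
       min_qd = 2, min_read_pos_rank_sum = -8)
}

#' Biallelic SNP selection
#'
#' A record passes iff it has a single-base REF, exactly one ALT allele, and
#' that allele is a single base differing from REF (indels and multi-allelic
#' records fail).
#'
#' @param sites Site tibble with `ref`, `alt`.
#' @return Input with a logical `pass` column.
#' @export
biallelic_snp_filter <- function(sites) {
  bases <- c("A", "C", "G", "T")
  dplyr::mutate(
    sites,
    pass = !is.na(.data$ref) & !is.na(.data$alt) &
      nchar(.data$ref) == 1L & !grepl(",", .data$alt, fixed = TRUE) &
      nchar(.data$alt) == 1L & .data$ref %in% bases & .data$alt %in% bases &
      .data$ref != .data$alt
  )
}

#' Hard annotation filter
#'
#' Evaluates the six variant-annotation cut-offs against the site INFO
#' columns and a supplied homopolymer-run value, naming every violated rule.
#' Missing annotations pass their rule (cannot evaluate, cannot eliminate).
#'
#' @param sites Site tibble with numeric columns `dp`, `qd`, `mq`,
#'   `mq_rank_sum`, `read_pos_rank_sum`.
#' @param hrun Integer homopolymer run length per site (recycled).
#' @param thresholds Named list as [hard_filter_defaults()].
#' @return Input with logical `pass` and character `failed_rules`
#'   (comma-separated, `NA` when passing).
#' @export
hard_filter <- function(sites, hrun, thresholds = hard_filter_defaults()) {
  for (col in info_cols) {
    if (!col %in% names(sites)) sites[[col]] <- NA_real_
    if (!is.numeric(sites[[col]])) {
      rlang::abort(paste0("INFO column ", col, " is not numeric"))
    }
  }
  hrun <- rep_len(as.integer(hrun), nrow(sites))
  t <- thresholds
  fails <- list(
    depth = !is.na(sites$dp) & sites$dp < t$min_dp,
    homopolymer = !is.na(hrun) & hrun > t$max_hrun,
    mapping_quality = !is.na(sites$mq) & sites$mq < t$min_mq,
    mq_rank_sum = !is.na(sites$mq_rank_sum) & sites$mq_rank_sum < t$min_mq_rank_sum,
    quality_by_depth = !is.na(sites$qd) & sites$qd < t$min_qd,
    read_pos_rank_sum = !is.na(sites$read_pos_rank_sum) &
      sites$read_pos_rank_sum < t$min_read_pos_rank_sum
  )
  fail_mat <- do.call(cbind, fails)
  labels <- apply(fail_mat, 1L, function(row) {
    if (any(row)) paste(names(fails)[row], collapse = ",") else NA_character_
  })
  dplyr::mutate(sites, pass = !apply(fail_mat, 1L, any), failed_rules = labels)
}

gt_allele_matrix <- function(gt) {
  parts <- stringr::str_split_fixed(gt, "[/|]", 2)
  parts[parts %in% c(".", "")] <- NA
  suppressWarnings(matrix(as.integer(parts), ncol = 2))
}

gt_has_alt <- function(gt, allele = NULL) {
  m <- gt_allele_matrix(gt)
  if (is.null(allele)) {
    out <- (!is.na(m[, 1]) & m[, 1] > 0L) | (!is.na(m[, 2]) & m[, 2] > 0L)
  } else {
    out <- (!is.na(m[, 1]) & m[, 1] == allele) | (!is.na(m[, 2]) & m[, 2] == allele)
  }
  out
}

gt_is_het <- function(gt) {
  m <- gt_allele_matrix(gt)
  !is.na(m[, 1]) & !is.na(m[, 2]) & m[, 1] != m[, 2]
}

gt_is_hom_alt <- function(gt) {
  m <- gt_allele_matrix(gt)
  !is.na(m[, 1]) & !is.na(m[, 2]) & m[, 1] == m[, 2] & m[, 1] > 0L
}

ad_field <- function(ad, index) {
  purrr::map_int(stringr::str_split(ad, ","), function(x) {
    v <- suppressWarnings(as.integer(x[index]))
    if (length(v) == 0 || is.na(v)) NA_integer_ else v
  })
}

#' Per-sample alternate-read support filter
#'
#' A sample's variant call is valid iff at least `min_alt_reads` reads
#' support the alternate allele (from the AD field); calls lacking AD are
#' invalid. Non-variant calls (hom-ref or missing) are out of scope and get
#' `NA`.
#'
#' @param calls Long call tibble with `gt`, `ad`.
#' @param min_alt_reads Minimum alternate-allele reads (default 3).
#' @param pooled If `TRUE`, the rule is instead applied to the summed alt
#'   depth over all samples at the site (an alternative reading; the
#'   per-sample rule is the default).
#' @return Input with a logical `support_pass` column (`NA` for non-variant
#'   calls).
#' @export
alt_support_filter <- function(calls, min_alt_reads = 3L, pooled = FALSE) {
  has_alt <- gt_has_alt(calls$gt)
  alt_depth <- ad_field(calls$ad, 2L)
  if (pooled) {
    out <- calls |>
      dplyr::mutate(.has_alt = has_alt, .alt_depth = alt_depth) |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::mutate(
        support_pass = dplyr::if_else(
          .data$.has_alt,
          sum(.data$.alt_depth[.data$.has_alt], na.rm = TRUE) >= min_alt_reads,
          NA
        )
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-dplyr::all_of(c(".has_alt", ".alt_depth")))
    return(out)
  }
  pass <- dplyr::if_else(has_alt, !is.na(alt_depth) & alt_depth >= min_alt_reads, NA)
  dplyr::mutate(calls, support_pass = pass)
}

#' Context-mask filter
#'
#' Fails any site lying inside the SSR, splice-junction, or bidirectional
#' transcription mask, labelling every containing mask.
#'
#' @param sites Site tibble with `chrom`, `pos`.
#' @param ssr_mask,junction_mask,bidirectional_mask Normalized interval
#'   tibbles (see [context_masks()]).
#' @return Input with logical `pass` and character `failed_masks`.
#' @export
mask_filter <- function(sites, ssr_mask, junction_mask, bidirectional_mask) {
  in_ssr <- point_in_mask(ssr_mask, sites$chrom, sites$pos)
  in_junc <- point_in_mask(junction_mask, sites$chrom, sites$pos)
  in_bidi <- point_in_mask(bidirectional_mask, sites$chrom, sites$pos)
  labels <- purrr::pmap_chr(list(in_ssr, in_junc, in_bidi), function(s, j, b) {
    hit <- c("ssr", "junction", "bidirectional")[c(s, j, b)]
    if (length(hit) == 0) NA_character_ else paste(hit, collapse = ",")
  })
  dplyr::mutate(sites, pass = !(in_ssr | in_junc | in_bidi),
                failed_masks = labels)
}

#' Known-SNP database filter
#'
#' A site passes iff its (chrom, pos, ref, alt) key is present in the
#' database; on a pass the record id is set to the database rsID. Allele
#' identity is required — the same position with a different substitution
#' does not match.
#'
#' @param sites Site tibble with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `id`).
#' @param db Known-SNP tibble from [read_known_db()].
#' @return Input with `pass` and the matched `rsid` merged into `id`.
#' @export
known_filter <- function(sites, db) {
  out <- dplyr::left_join(
    sites, dplyr::select(db, dplyr::all_of(c("chrom", "pos", "ref", "alt", "rsid"))),
    by = c("chrom", "pos", "ref", "alt")
  )
  if (!"id" %in% names(out)) out$id <- NA_character_
  dplyr::mutate(out,
                pass = !is.na(.data$rsid),
                id = dplyr::coalesce(.data$rsid, .data$id)) |>
    dplyr::select(-dplyr::all_of("rsid"))
}

cascade_sites <- function(calls) {
  calls |>
    dplyr::distinct(.data$chrom, .data$pos, .data$id, .data$ref, .data$alt,
                    .data$qual, .data$dp, .data$qd, .data$mq,
                    .data$mq_rank_sum, .data$read_pos_rank_sum) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Run the full confidence cascade
#'
#' Applies, in order: SNP-only biallelic selection, the hard annotation
#' filter (with the homopolymer run recomputed from the reference — an INFO
#' HRun, if present, is ignored), the per-sample alternate-read support rule
#' (a site survives if at least one sample retains a valid supported variant
#' call; failing samples are set to missing genotype rather than dropping
#' the site), the context masks, and the known-SNP intersection.
#'
#' @param calls Long call tibble (see [read_vcf()]).
#' @param reference Reference sequences.
#' @param annotation Annotation tibble (used to derive masks when `masks`
#'   is not supplied).
#' @param known_db Known-SNP tibble from [read_known_db()].
#' @param masks Optional precomputed [context_masks()] list.
#' @param min_alt_reads Per-sample support threshold (default 3).
#' @param pooled_support Apply the support rule to pooled depth instead of
#'   per sample (default FALSE).
#' @param thresholds Hard-filter thresholds ([hard_filter_defaults()]).
#' @return A `snp_cascade` object: `calls` (surviving long calls), `sites`
#'   (surviving site tibble with rsIDs), `trace` (per input site: final
#'   status, failing stage and rule labels), `stage_counts`.
#' @export
run_cascade <- function(calls, reference, annotation = NULL, known_db,
                        masks = NULL, min_alt_reads = 3L,
                        pooled_support = FALSE,
                        thresholds = hard_filter_defaults()) {
  seqs <- as_ref_seqs(reference)
  missing_contigs <- setdiff(unique(calls$chrom), names(seqs))
  if (length(missing_contigs) > 0) {
    rlang::abort(paste0("contig absent from reference: ",
                        paste(missing_contigs, collapse = ", ")))
  }
  if (is.null(masks)) {
    if (is.null(annotation)) {
      rlang::abort("supply either masks or an annotation to derive them from")
    }
    masks <- context_masks(reference, annotation)
  }
  sites <- cascade_sites(calls)
  empty_trace <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), status = character(), failed_stage = character(),
    failed_rules = character()
  )
  if (nrow(sites) == 0) {
    counts <- tibble::tibble(stage = CASCADE_STAGES, survivors = 0L,
                             removed = 0L)
    return(structure(list(calls = calls[0, ], sites = sites, trace = empty_trace,
                          stage_counts = counts, masks = masks),
                     class = "snp_cascade"))
  }
  trace <- dplyr::mutate(sites, failed_stage = NA_character_,
                         failed_rules = NA_character_)
  alive <- rep(TRUE, nrow(sites))
  survivors <- integer(0)

  mark <- function(trace, alive, fail_idx, stage, rules = NA_character_) {
    newly <- which(alive)[fail_idx]
    trace$failed_stage[newly] <- stage
    trace$failed_rules[newly] <- rules
    alive[newly] <- FALSE
    list(trace = trace, alive = alive)
  }

  n_stage <- c(input = nrow(sites))

  # 1. biallelic SNP selection
  b <- biallelic_snp_filter(sites[alive, ])
  st <- mark(trace, alive, !b$pass, "biallelic_snp", "not_biallelic_snp")
  trace <- st$trace; alive <- st$alive
  n_stage["biallelic_snp"] <- sum(alive)

  # 2. hard annotation filter with recomputed homopolymer run
  cur <- sites[alive, ]
  hrun <- homopolymer_run(seqs, cur$chrom, cur$pos, cur$alt)
  h <- hard_filter(cur, hrun, thresholds)
  st <- mark(trace, alive, !h$pass, "hard_filter", h$failed_rules[!h$pass])
  trace <- st$trace; alive <- st$alive
  n_stage["hard_filter"] <- sum(alive)

  # 3. per-sample alternate-read support
  cur_keys <- site_key(sites[alive, ])
  sup <- calls |>
    dplyr::mutate(.key = site_key(calls)) |>
    dplyr::filter(.data$.key %in% cur_keys) |>
    alt_support_filter(min_alt_reads = min_alt_reads, pooled = pooled_support)
  site_ok <- sup |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(ok = any(.data$support_pass, na.rm = TRUE))
  failed_keys <- c(site_ok$.key[!site_ok$ok],
                   setdiff(cur_keys, site_ok$.key))
  st <- mark(trace, alive, cur_keys %in% failed_keys, "alt_support",
             "insufficient_alt_reads")
  trace <- st$trace; alive <- st$alive
  n_stage["alt_support"] <- sum(alive)

  # 4. context masks
  cur <- sites[alive, ]
  m <- mask_filter(cur, masks$ssr, masks$junction, masks$bidirectional)
  st <- mark(trace, alive, !m$pass, "region_mask", m$failed_masks[!m$pass])
  trace <- st$trace; alive <- st$alive
  n_stage["region_mask"] <- sum(alive)

  # 5. known-SNP intersection
  cur <- sites[alive, ]
  k <- known_filter(cur, known_db)
  st <- mark(trace, alive, !k$pass, "known_snp", "novel")
  trace <- st$trace; alive <- st$alive
  n_stage["known_snp"] <- sum(alive)

  out_sites <- sites[alive, ]
  ids <- known_filter(out_sites, known_db)
  out_sites$id <- ids$id

  out_keys <- site_key(out_sites)
  out_calls <- calls |>
    dplyr::mutate(.key = site_key(calls)) |>
    dplyr::filter(.data$.key %in% out_keys) |>
    alt_support_filter(min_alt_reads = min_alt_reads, pooled = pooled_support) |>
    dplyr::mutate(
      gt = dplyr::if_else(!is.na(.data$support_pass) & !.data$support_pass,
                          "./.", .data$gt),
      id = out_sites$id[match(.data$.key, out_keys)]
    ) |>
    dplyr::select(-dplyr::all_of(c(".key", "support_pass"))) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$sample_id)

  trace <- dplyr::mutate(
    trace,
    status = dplyr::if_else(is.na(.data$failed_stage), "pass", "fail")
  ) |>
    dplyr::select(dplyr::all_of(c("chrom", "pos", "ref", "alt", "status",
                                  "failed_stage", "failed_rules")))
  counts <- tibble::tibble(
    stage = CASCADE_STAGES,
    survivors = as.integer(n_stage[CASCADE_STAGES]),
    removed = c(0L, -diff(as.integer(n_stage[CASCADE_STAGES])))
  )
  structure(list(calls = out_calls, sites = out_sites, trace = trace,
                 stage_counts = counts, masks = masks),
            class = "snp_cascade")
}

#' @export
print.snp_cascade <- function(x, ...) {
  cat("SNP confidence cascade\n")
  print(x$stage_counts)
  invisible(x)
}

#' Per-site cascade outcomes
#'
#' @param x A `snp_cascade`.
#' @param ... Unused.
#' @return Tibble with one row per input site: status, failing stage and
#'   rule labels.
#' @export
tidy.snp_cascade <- function(x, ...) {
  x$trace
}

#' One-row cascade summary
#'
#' @param x A `snp_cascade`.
#' @param ... Unused.
#' @return One-row tibble of survivor counts per stage.
#' @export
glance.snp_cascade <- function(x, ...) {
  tidyr::pivot_wider(dplyr::select(x$stage_counts,
                                   dplyr::all_of(c("stage", "survivors"))),
                     names_from = dplyr::all_of("stage"),
                     values_from = dplyr::all_of("survivors"))
}

#' Write the cascade stage report
#'
#' @param x A `snp_cascade`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_stage_report <- function(x, path) {
  readr::write_tsv(x$stage_counts, path)
  invisible(path)
}
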