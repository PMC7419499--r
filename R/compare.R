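# Common-SNP and breed-specific SNP derivation, plus cohort statistics
# (Ts/Tv, het/hom ratio, windowed SNP density).

panel_samples <- function(panel, breed) {
  ids <- panel$sample_id[panel$breed == breed]
  if (length(ids) == 0) {
    rlang::abort(paste0("no samples for breed ", breed))
  }
  ids
}

#' Common SNPs within a breed
#'
#' A site is a common-SNP of a breed when at least `min_animals` of its
#' samples carry the alternate allele (het or hom-alt) with a valid
#' genotype call.
#'
#' @param calls Long call tibble (typically cascade survivors).
#' @param panel Panel tibble (`sample_id`, `breed`).
#' @param breed Breed name to evaluate.
#' @param min_animals Minimum carrier count (default 2).
#' @return Site tibble (`chrom`, `pos`, `ref`, `alt`, `id` when present,
#'   `n_carriers`).
#' @export
common_snps <- function(calls, panel, breed, min_animals = 2L) {
  validate_panel(panel)
  ids <- panel_samples(panel, breed)
  keep_cols <- intersect(c("chrom", "pos", "ref", "alt", "id"), names(calls))
  calls |>
    dplyr::filter(.data$sample_id %in% ids) |>
    dplyr::mutate(.carrier = gt_has_alt(.data$gt)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keep_cols))) |>
    dplyr::summarise(n_carriers = sum(.data$.carrier), .groups = "drop") |>
    dplyr::filter(.data$n_carriers >= min_animals) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Breed-specific SNPs
#'
#' Starting from each breed's common-SNPs, a site is specific to breed X
#' when every genotyped sample of the other breed is homozygous for the
#' allele breed X does not segregate — operationally, homozygous reference
#' at the site. Samples without a call at the site count as homozygous
#' reference; missing genotypes do not veto specificity unless
#' `strict = TRUE`. The two specific sets are disjoint by construction, and
#' relabelling the breeds swaps them exactly.
#'
#' @param calls Long call tibble (cascade survivors).
#' @param panel Panel tibble with exactly two breeds.
#' @param min_animals Carrier minimum for the common-SNP step.
#' @param strict Require every other-breed sample to have a non-missing
#'   genotype (default FALSE).
#' @return Named list of two site tibbles, one per breed.
#' @export
breed_specific_snps <- function(calls, panel, min_animals = 2L,
                                strict = FALSE) {
  validate_panel(panel)
  breeds <- unique(panel$breed)
  if (length(breeds) != 2) rlang::abort("panel must contain exactly two breeds")
  commons <- lapply(breeds, function(b) common_snps(calls, panel, b, min_animals))
  names(commons) <- breeds
  specific_one <- function(focal, other) {
    com <- commons[[focal]]
    if (nrow(com) == 0) return(com)
    other_ids <- panel_samples(panel, other)
    other_calls <- calls |>
      dplyr::filter(.data$sample_id %in% other_ids) |>
      dplyr::semi_join(com, by = c("chrom", "pos", "ref", "alt"))
    veto <- other_calls |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::summarise(
        any_alt = any(gt_has_alt(.data$gt), na.rm = TRUE),
        any_missing = any(is.na(.data$gt) | !grepl("^[0-9]", .data$gt)),
        n_called = dplyr::n(),
        .groups = "drop"
      )
    com2 <- dplyr::left_join(com, veto, by = c("chrom", "pos", "ref", "alt"))
    com2$any_alt[is.na(com2$any_alt)] <- FALSE
    if (strict) {
      com2$any_missing[is.na(com2$any_missing)] <- TRUE
      com2$n_called[is.na(com2$n_called)] <- 0L
      com2 <- dplyr::filter(com2, !.data$any_missing,
                            .data$n_called == length(other_ids))
    }
    com2 |>
      dplyr::filter(!.data$any_alt) |>
      dplyr::select(-dplyr::any_of(c("any_alt", "any_missing", "n_called")))
  }
  out <- list(specific_one(breeds[1], breeds[2]),
              specific_one(breeds[2], breeds[1]))
  names(out) <- breeds
  out
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Transition/transversion ratio of a site set
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); all others are transversions. Computed on the distinct
#' site set. Returns `NA` (with a warning) when there are no transversions
#' or no sites.
#'
#' @param sites Site tibble with `ref`, `alt` single bases.
#' @return Numeric ratio.
#' @export
ts_tv_ratio <- function(sites) {
  if (nrow(sites) == 0) {
    rlang::warn("no sites; Ts/Tv is undefined")
    return(NA_real_)
  }
  sub <- paste0(sites$ref, ">", sites$alt)
  ts <- sum(sub %in% TRANSITIONS)
  tv <- nrow(sites) - ts
  if (tv == 0) {
    rlang::warn("no transversions; Ts/Tv is undefined")
    return(NA_real_)
  }
  ts / tv
}

#' Heterozygous/homozygous ratio for one sample
#'
#' Ratio of heterozygous to homozygous-alternate calls among the sample's
#' valid variant calls. Returns `NA` (with a warning) when the sample has no
#' hom-alt call.
#'
#' @param calls Long call tibble.
#' @param sample_id Sample to evaluate.
#' @return Numeric ratio.
#' @export
het_hom_ratio <- function(calls, sample_id) {
  own <- dplyr::filter(calls, .data$sample_id == !!sample_id)
  n_het <- sum(gt_is_het(own$gt), na.rm = TRUE)
  n_hom <- sum(gt_is_hom_alt(own$gt), na.rm = TRUE)
  if (n_hom == 0) {
    rlang::warn("no homozygous-alternate calls; het/hom is undefined")
    return(NA_real_)
  }
  n_het / n_hom
}

#' Windowed SNP density
#'
#' Counts sites per non-overlapping window tiling each chromosome; window
#' counts sum to the number of sites.
#'
#' @param sites Site tibble with `chrom`, `pos`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_bp Window size in bp (> 0).
#' @return Tibble with `chrom`, `window_start`, `window_end`, `n`.
#' @export
snp_density <- function(sites, chrom_lengths, window_bp) {
  if (window_bp <= 0) rlang::abort("window_bp must be positive")
  grids <- purrr::map_dfr(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    starts <- seq(1L, L, by = as.integer(window_bp))
    tibble::tibble(chrom = chrom, window_start = starts,
                   window_end = pmin(starts + as.integer(window_bp) - 1L, L))
  })
  if (nrow(sites) > 0) {
    bad <- !(sites$chrom %in% names(chrom_lengths)) |
      sites$pos > unname(unlist(chrom_lengths)[sites$chrom]) | sites$pos < 1L
    if (any(is.na(bad)) || any(bad)) {
      rlang::abort("site outside chromosome bounds")
    }
  }
  counted <- sites |>
    dplyr::mutate(window_start = ((.data$pos - 1L) %/% as.integer(window_bp)) *
                    as.integer(window_bp) + 1L) |>
    dplyr::count(.data$chrom, .data$window_start)
  grids |>
    dplyr::left_join(counted, by = c("chrom", "window_start")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Cohort summary statistics
#'
#' Ts/Tv on the site set plus per-sample het/hom ratios.
#'
#' @param calls Long call tibble.
#' @param panel Optional panel tibble to attach breed labels.
#' @return List with `ts_tv` and a per-sample `het_hom` tibble.
#' @export
cohort_stats <- function(calls, panel = NULL) {
  sites <- dplyr::distinct(calls, .data$chrom, .data$pos, .data$ref, .data$alt)
  samples <- sort(unique(calls$sample_id[!is.na(calls$sample_id)]))
  hh <- tibble::tibble(
    sample_id = samples,
    het_hom = purrr::map_dbl(samples, function(s) {
      suppressWarnings(het_hom_ratio(calls, s))
    })
  )
  if (!is.null(panel)) hh <- dplyr::left_join(hh, panel, by = "sample_id")
  list(ts_tv = suppressWarnings(ts_tv_ratio(sites)), het_hom = hh)
}
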