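# Gene-set over-representation of SNP-bearing genes (hypergeometric upper
# tail + Benjamini-Hochberg FDR; a local stand-in for web-service
# enrichment), and intersection with a differential-expression table.

#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation test per term: `P(X >= k)` under the
#' hypergeometric law with background size `N`, term size `K` (restricted to
#' background members) and study size `n`. Evaluated with the stable
#' upper-tail implementation in `stats::phyper`. Tiers mirror common
#' reporting: FDR < 0.05 "significant", p < 0.05 and FDR < 0.3 "suggestive".
#'
#' @param study_genes Character vector of study genes (must be a subset of
#'   the background).
#' @param gene_sets Gene-set tibble (`term_id`, `term_name`, `gene_id`).
#' @param background_genes Character vector defining the test universe.
#' @param fdr_significant,fdr_suggestive,p_suggestive Tier thresholds.
#' @return Tibble with `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `tier`, sorted by p-value.
#' @export
hypergeometric_enrich <- function(study_genes, gene_sets, background_genes,
                                  fdr_significant = 0.05,
                                  fdr_suggestive = 0.3,
                                  p_suggestive = 0.05) {
  background_genes <- unique(background_genes)
  study_genes <- unique(study_genes)
  outside <- setdiff(study_genes, background_genes)
  if (length(outside) > 0) {
    rlang::abort(paste0("study gene absent from background: ",
                        paste(utils::head(outside, 5), collapse = ", ")))
  }
  N <- length(background_genes)
  n <- length(study_genes)
  res <- gene_sets |>
    dplyr::filter(.data$gene_id %in% background_genes) |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      k = sum(unique(.data$gene_id) %in% study_genes),
      K = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      p_value = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                              lower.tail = FALSE)
    )
  res |>
    dplyr::mutate(
      fdr = bh_fdr(.data$p_value),
      tier = dplyr::case_when(
        .data$fdr < fdr_significant ~ "significant",
        .data$p_value < p_suggestive & .data$fdr < fdr_suggestive ~ "suggestive",
        TRUE ~ "ns"
      )
    ) |>
    dplyr::arrange(.data$p_value, .data$term_id)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`q_i = min_{j >= i} m p_(j) / j`, clipped to
#' 1), returned in input order. Wraps `stats::p.adjust(method = "BH")` with
#' input validation.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Intersect SNP-bearing genes with a DEG table
#'
#' Returns the genes that both carry breed-specific SNPs and pass the DE
#' significance threshold, labelled up/down by log2 fold-change sign and,
#' when `snp_genes` is a tibble with a `breed` column, by breed-specific set
#' membership.
#'
#' @param snp_genes Character vector of gene ids, or a tibble with
#'   `gene_id` (and optionally `breed`).
#' @param deg_table DEG tibble (`gene_id`, `log2fc`, `fdr`); duplicate gene
#'   rows are an error.
#' @param fdr_threshold DE significance threshold (default 0.05).
#' @return Joined tibble with `gene_id`, (`breed`,) `log2fc`, `fdr`,
#'   `direction`.
#' @export
intersect_deg <- function(snp_genes, deg_table, fdr_threshold = 0.05) {
  if (anyDuplicated(deg_table$gene_id)) {
    rlang::abort("duplicate gene rows in DEG table")
  }
  genes <- if (is.data.frame(snp_genes)) {
    dplyr::distinct(snp_genes, dplyr::across(dplyr::any_of(c("gene_id", "breed"))))
  } else {
    tibble::tibble(gene_id = unique(snp_genes))
  }
  genes |>
    dplyr::inner_join(deg_table, by = "gene_id") |>
    dplyr::filter(.data$fdr <= fdr_threshold) |>
    dplyr::mutate(direction = dplyr::if_else(.data$log2fc >= 0, "up", "down")) |>
    dplyr::arrange(.data$gene_id)
}
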