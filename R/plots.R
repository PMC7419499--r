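# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA scatter of sample coordinates
#'
#' @param object A `genotype_pca`.
#' @param panel Optional panel tibble (`sample_id`, `breed`) to colour by
#'   breed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genotype_pca <- function(object, panel = NULL, ...) {
  d <- object$scores
  if (!is.null(panel)) d <- dplyr::left_join(d, panel, by = "sample_id")
  ve <- function(j) {
    if (length(object$var_explained) >= j && !is.na(object$var_explained[j])) {
      sprintf(" (%.1f%%)", 100 * object$var_explained[j])
    } else ""
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = paste0("PC1", ve(1)), y = paste0("PC2", ve(2)),
                  title = "Genotype PCA") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$breed), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' SNP density along the genome
#'
#' @param density Tibble from [snp_density()].
#' @return A ggplot of per-window counts, faceted by chromosome.
#' @export
plot_snp_density <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$window_start, y = .data$n)) +
    ggplot2::geom_col(width = density$window_end - density$window_start,
                      just = 0, fill = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "SNPs per window",
                  title = "SNP density") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' @param enrichment Tibble from [hypergeometric_enrich()].
#' @param top_n Number of top terms to show (default 20).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, top_n = 20L) {
  d <- enrichment |>
    dplyr::arrange(.data$p_value) |>
    utils::head(top_n) |>
    dplyr::mutate(term_name = factor(.data$term_name,
                                     levels = rev(unique(.data$term_name))))
  ggplot2::ggplot(d, ggplot2::aes(x = -log2(pmax(.data$fdr, 1e-300)),
                                  y = .data$term_name)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k, colour = .data$tier)) +
    ggplot2::labs(x = "-log2 FDR", y = NULL, size = "genes",
                  colour = "tier", title = "Gene-set enrichment") +
    ggplot2::theme_minimal()
}
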