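# Genotype principal components with the EIGENSTRAT/smartpca site
# normalization: dosages are centred and scaled by the binomial standard
# deviation of a shrunk allele-frequency estimate before the sample-by-sample
# covariance is eigendecomposed.

#' Build a dosage matrix from long calls
#'
#' Samples x sites matrix of alternate-allele dosage (0/1/2, `NA` for
#' missing genotypes).
#'
#' @param calls Long call tibble.
#' @return Numeric matrix with sample ids as rownames and
#'   `chrom:pos:ref:alt` site keys as colnames.
#' @export
dosage_matrix <- function(calls) {
  calls <- dplyr::filter(calls, !is.na(.data$sample_id))
  m <- gt_allele_matrix(calls$gt)
  dosage <- ifelse(is.na(m[, 1]) | is.na(m[, 2]), NA_real_,
                   (m[, 1] > 0) + (m[, 2] > 0))
  wide <- calls |>
    dplyr::mutate(key = site_key(calls), dosage = dosage) |>
    dplyr::select(dplyr::all_of(c("sample_id", "key", "dosage"))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of("key"),
                       values_from = dplyr::all_of("dosage"))
  out <- as.matrix(wide[, -1, drop = FALSE])
  rownames(out) <- wide$sample_id
  out
}

#' Genotype PCA with EIGENSTRAT normalization
#'
#' Each site column `g` is normalized as `(g - mu) / sqrt(p (1 - p))`, with
#' `mu` the observed dosage mean and `p = (1 + sum(g)) / (2 + 2 n)` the
#' shrunk allele-frequency estimate over the `n` genotyped samples; missing
#' dosages are imputed to the site mean before normalization and
#' zero-variance (monomorphic) sites are dropped. The sample-by-sample
#' covariance of the normalized matrix is then eigendecomposed.
#'
#' @param x A dosage matrix (samples x sites) or a long call tibble
#'   (converted with [dosage_matrix()]).
#' @param n_components Number of components to return (default 2).
#' @return A `genotype_pca` object: `scores` (tibble of per-sample
#'   coordinates), `eigenvalues`, `var_explained`, `n_sites_used`.
#' @export
genotype_pca <- function(x, n_components = 2L) {
  if (is.data.frame(x)) x <- dosage_matrix(x)
  if (!is.matrix(x)) rlang::abort("x must be a matrix or a call tibble")
  if (nrow(x) < 2) rlang::abort("PCA needs at least two samples")
  norm <- normalize_dosages(x)
  if (ncol(norm) < 2) {
    rlang::abort("fewer than two polymorphic sites; PCA input is degenerate")
  }
  m <- ncol(norm)
  cv <- tcrossprod(norm) / m
  eg <- eigen(cv, symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  k <- min(as.integer(n_components), nrow(x) - 1L)
  vecs <- eg$vectors[, seq_len(k), drop = FALSE]
  # fix the sign convention so results are reproducible across BLAS builds
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- tibble::as_tibble(vecs, .name_repair = ~ paste0("PC", seq_len(k)))
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), scores)
  structure(list(
    scores = scores,
    eigenvalues = eg$values[seq_len(k)],
    var_explained = if (sum(pos) > 0) pos[seq_len(k)] / sum(pos) else rep(NA_real_, k),
    n_sites_used = m,
    n_samples = nrow(x)
  ), class = "genotype_pca")
}

# EIGENSTRAT normalization of a dosage matrix; drops monomorphic columns.
normalize_dosages <- function(x) {
  n_obs <- colSums(!is.na(x))
  s <- colSums(x, na.rm = TRUE)
  mu <- s / n_obs
  p <- (1 + s) / (2 + 2 * n_obs)
  keep <- n_obs > 0 & apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    length(unique(v)) > 1
  })
  if (!any(keep)) {
    rlang::abort("all sites monomorphic; PCA input is degenerate")
  }
  x <- x[, keep, drop = FALSE]
  mu <- mu[keep]
  p <- p[keep]
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    col[is.na(col)] <- mu[j]
    x[, j] <- (col - mu[j]) / sqrt(p[j] * (1 - p[j]))
  }
  x
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("Genotype PCA:", x$n_samples, "samples,", x$n_sites_used,
      "polymorphic sites\n")
  cat("Variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  print(x$scores)
  invisible(x)
}

#' Per-sample principal-component coordinates
#'
#' @param x A `genotype_pca`.
#' @param ... Unused.
#' @return Tibble of sample coordinates.
#' @export
tidy.genotype_pca <- function(x, ...) {
  x$scores
}

#' One-row PCA summary
#'
#' @param x A `genotype_pca`.
#' @param ... Unused.
#' @return One-row tibble: sample/site counts and per-component variance
#'   fractions.
#' @export
glance.genotype_pca <- function(x, ...) {
  out <- tibble::tibble(n_samples = x$n_samples, n_sites = x$n_sites_used)
  for (j in seq_along(x$var_explained)) {
    out[[paste0("var_PC", j)]] <- x$var_explained[j]
  }
  out
}
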