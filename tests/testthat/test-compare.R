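two_breed_calls <- function(gts_a, gts_b, pos = 1L) {
  tibble::tibble(
    chrom = "chr1", pos = pos, ref = "A", alt = "G",
    sample_id = c(paste0("a", seq_along(gts_a)), paste0("b", seq_along(gts_b))),
    gt = c(gts_a, gts_b)
  )
}

two_breed_panel <- function(n_a = 4, n_b = 4) {
  tibble::tibble(sample_id = c(paste0("a", 1:n_a), paste0("b", 1:n_b)),
                 breed = rep(c("A", "B"), c(n_a, n_b)))
}

test_that("common-SNP membership needs the alt allele in two animals", {
  panel <- two_breed_panel()
  calls <- two_breed_calls(c("0/1", "1/1", "0/0", "0/0"), rep("0/0", 4))
  expect_equal(nrow(common_snps(calls, panel, "A")), 1L)
  # a single carrier is not enough
  calls1 <- two_breed_calls(c("0/1", "0/0", "0/0", "0/0"), rep("0/0", 4))
  expect_equal(nrow(common_snps(calls1, panel, "A")), 0L)
  # a carrier invalidated upstream (set to missing) no longer counts
  calls2 <- two_breed_calls(c("0/1", "./.", "0/0", "0/0"), rep("0/0", 4))
  expect_equal(nrow(common_snps(calls2, panel, "A")), 0L)
  expect_error(common_snps(calls, panel, "C"), "no samples")
})

test_that("breed-specific rule requires uniform hom-ref in the other breed", {
  panel <- two_breed_panel()
  # segregating in A, missing genotype tolerated, B uniformly 0/0
  calls <- two_breed_calls(c("0/1", "1/1", "0/0", "./."), rep("0/0", 4))
  sp <- breed_specific_snps(calls, panel)
  expect_equal(nrow(sp$A), 1L)
  expect_equal(nrow(sp$B), 0L)
  # one heterozygous sample in B vetoes specificity
  calls2 <- two_breed_calls(c("0/1", "1/1", "0/0", "0/0"),
                            c("0/1", "0/0", "0/0", "0/0"))
  sp2 <- breed_specific_snps(calls2, panel)
  expect_equal(nrow(sp2$A), 0L)
  # segregating in >= 2 samples of both breeds: in neither specific set
  calls3 <- two_breed_calls(c("0/1", "1/1", "0/0", "0/0"),
                            c("0/1", "0/1", "0/0", "0/0"))
  sp3 <- breed_specific_snps(calls3, panel)
  expect_equal(nrow(sp3$A) + nrow(sp3$B), 0L)
  # strict mode: a missing other-breed genotype withholds the site
  calls4 <- two_breed_calls(c("0/1", "1/1", "0/0", "0/0"),
                            c("0/0", "./.", "0/0", "0/0"))
  expect_equal(nrow(breed_specific_snps(calls4, panel)$A), 1L)
  expect_equal(nrow(breed_specific_snps(calls4, panel, strict = TRUE)$A), 0L)
})

test_that("relabelling the breeds swaps the two specific sets exactly", {
  co <- small_cohort()
  casc <- small_cascade()
  sp <- breed_specific_snps(casc$calls, co$panel)
  flipped_panel <- dplyr::mutate(
    co$panel,
    breed = ifelse(breed == "breedA", "breedB", "breedA")
  )
  sp_flip <- breed_specific_snps(casc$calls, flipped_panel)
  expect_setequal(key_of(sp$breedA), key_of(sp_flip$breedB))
  expect_setequal(key_of(sp$breedB), key_of(sp_flip$breedA))
})

test_that("specific sets are disjoint subsets of their common sets", {
  co <- small_cohort()
  casc <- small_cascade()
  sp <- breed_specific_snps(casc$calls, co$panel)
  com_a <- common_snps(casc$calls, co$panel, "breedA")
  com_b <- common_snps(casc$calls, co$panel, "breedB")
  expect_length(intersect(key_of(sp$breedA), key_of(sp$breedB)), 0)
  expect_true(all(key_of(sp$breedA) %in% key_of(com_a)))
  expect_true(all(key_of(sp$breedB) %in% key_of(com_b)))
})

test_that("common/specific sets match the per-site loop evaluator", {
  co <- small_cohort()
  casc <- small_cascade()
  want <- oracle_common_specific(casc$calls, co$panel)
  got_a <- common_snps(casc$calls, co$panel, "breedA")
  got_b <- common_snps(casc$calls, co$panel, "breedB")
  expect_setequal(key_of(got_a), want$common$breedA)
  expect_setequal(key_of(got_b), want$common$breedB)
  sp <- breed_specific_snps(casc$calls, co$panel)
  expect_setequal(key_of(sp$breedA), want$specific$breedA)
  expect_setequal(key_of(sp$breedB), want$specific$breedB)
})

test_that("Ts/Tv counts transitions over transversions", {
  s <- tibble::tibble(ref = c("A", "C", "G", "A"), alt = c("G", "T", "A", "C"))
  expect_equal(ts_tv_ratio(s), 3)
  all_tv <- tibble::tibble(ref = c("A", "C"), alt = c("T", "G"))
  expect_equal(ts_tv_ratio(all_tv), 0)
  expect_warning(ts_tv_ratio(s[0, ]), "undefined")
  only_ts <- tibble::tibble(ref = "A", alt = "G")
  expect_warning(out <- ts_tv_ratio(only_ts), "no transversions")
  expect_true(is.na(out))
})

test_that("het/hom ratio follows its definition", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = seq_len(77L), ref = "A", alt = "G",
    sample_id = "s1", gt = c(rep("0/1", 27), rep("1/1", 50))
  )
  expect_equal(het_hom_ratio(calls, "s1"), 0.54)
  no_het <- dplyr::mutate(calls, gt = "1/1")
  expect_equal(het_hom_ratio(no_het, "s1"), 0)
  all_het <- dplyr::mutate(calls, gt = "0/1")
  expect_warning(out <- het_hom_ratio(all_het, "s1"), "undefined")
  expect_true(is.na(out))
})

test_that("windowed density tiles chromosomes and conserves counts", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(5L, 15L, 25L))
  d <- snp_density(sites, c(chr1 = 30L), 10L)
  expect_equal(d$n, c(1L, 1L, 1L))
  expect_equal(d$window_start, c(1L, 11L, 21L))
  empty <- snp_density(sites[0, ], c(chr1 = 30L), 10L)
  expect_true(all(empty$n == 0L))
  co <- small_cohort()
  casc <- small_cascade()
  dens <- snp_density(casc$sites, co$reference$lengths, 5000L)
  expect_equal(sum(dens$n), nrow(casc$sites))
  expect_error(snp_density(tibble::tibble(chrom = "chr1", pos = 31L),
                           c(chr1 = 30L), 10L), "bounds")
})

test_that("EIGENSTRAT normalization matches the closed form", {
  x <- cbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1))
  rownames(x) <- paste0("s", 1:4)
  norm <- tailvar:::normalize_dosages(x)
  # p = (1 + 4) / (2 + 8) = 0.5, mu = 1, sd = 0.5
  expect_equal(unname(norm[, 1]), c(-2, 0, 2, 0))
  # missing dosages impute to the site mean (zero after centring)
  xm <- cbind(a = c(0, 1, 2, NA), b = c(0, 2, 2, 0))
  normm <- tailvar:::normalize_dosages(xm)
  expect_equal(unname(normm[4, 1]), 0)
})

test_that("genotype PCA is symmetric, orthogonal and degenerate-safe", {
  set.seed(21)
  x <- matrix(sample(0:2, 60, replace = TRUE), nrow = 6)
  x[5, ] <- x[1, ] # duplicated sample rows
  rownames(x) <- paste0("s", 1:6)
  p <- genotype_pca(x, n_components = 3)
  sc <- as.matrix(tidy(p)[, -1])
  expect_equal(sc[1, ], sc[5, ], tolerance = 1e-9)
  gram <- crossprod(sc)
  expect_equal(unname(gram[upper.tri(gram)]), rep(0, 3), tolerance = 1e-9)
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  mono <- matrix(1, nrow = 3, ncol = 4,
                 dimnames = list(paste0("s", 1:3), NULL))
  expect_error(genotype_pca(mono), "degenerate")
  expect_error(genotype_pca(x[1, , drop = FALSE]), "two samples")
})

test_that("PC1 separates the two breeds on the planted cohort", {
  co <- small_cohort()
  casc <- small_cascade()
  p <- genotype_pca(casc$calls)
  sc <- dplyr::left_join(tidy(p), co$panel, by = "sample_id")
  a <- sc$PC1[sc$breed == "breedA"]
  b <- sc$PC1[sc$breed == "breedB"]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("cohort statistics summarise the call set", {
  co <- small_cohort()
  casc <- small_cascade()
  st <- cohort_stats(casc$calls, co$panel)
  expect_true(st$ts_tv > 0)
  expect_equal(nrow(st$het_hom), nrow(co$panel))
  expect_true(all(is.finite(st$het_hom$het_hom)))
})
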