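test_that("term-to-impact mapping is total and fixed", {
  expect_equal(impact_of("missense"), "MODERATE")
  expect_equal(impact_of("intron"), "MODIFIER")
  expect_equal(impact_of("stop_gained"), "HIGH")
  expect_equal(impact_of(c("synonymous", "stop_retained")), c("LOW", "LOW"))
  expect_equal(impact_of(consequence_terms()),
               c("HIGH", "HIGH", "HIGH", "MODERATE", "LOW", "LOW",
                 rep("MODIFIER", 7)))
  expect_error(impact_of("frameshift"), "unknown consequence term")
})

# single-gene annotation on a hand-built chromosome; the CDS is one exon so
# codon arithmetic can be followed by eye
toy_locus <- function(strand = "+") {
  # CDS: ATG AAA TAC CAT TGA  (M K Y H *)
  cds <- "ATGAAATACCATTGA"
  left <- "GCGCGTTACG"   # 10 bases
  right <- "CGTTACGGCA"
  seq <- paste0(left, cds, right)
  if (strand == "-") {
    seq <- paste0(left, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds))), right)
  }
  ref <- c(chr1 = seq)
  ann <- tibble::tibble(
    chrom = "chr1", start = c(11L, 11L, 11L, 11L), end = c(25L, 25L, 25L, 25L),
    strand = strand, type = c("gene", "transcript", "exon", "CDS"),
    gene_id = "g1", transcript_id = c(NA, "t1", "t1", "t1"),
    exon_number = c(NA, NA, 1L, NA)
  )
  list(ref = ref, ann = ann)
}

test_that("coding substitutions are classified by codon comparison", {
  l <- toy_locus("+")
  # codon 2 AAA, third base A->G gives AAG: Lys->Lys, synonymous, LOW
  s <- tibble::tibble(chrom = "chr1", pos = 16L, ref = "A", alt = "G")
  got <- classify_consequences(s, l$ann, l$ref)
  expect_equal(got$term, "synonymous")
  expect_equal(got$impact, "LOW")
  expect_equal(got$codon_change, "AAA>AAG")
  # codon 3 TAC, C->A gives TAA: stop gained, HIGH
  s2 <- tibble::tibble(chrom = "chr1", pos = 19L, ref = "C", alt = "A")
  got2 <- classify_consequences(s2, l$ann, l$ref)
  expect_equal(got2$term, "stop_gained")
  expect_equal(got2$impact, "HIGH")
  # codon 2 first base A->C gives CAA: Lys->Gln, missense
  s3 <- tibble::tibble(chrom = "chr1", pos = 14L, ref = "A", alt = "C")
  expect_equal(classify_consequences(s3, l$ann, l$ref)$term, "missense")
  # start codon disruption
  s4 <- tibble::tibble(chrom = "chr1", pos = 11L, ref = "A", alt = "G")
  expect_equal(classify_consequences(s4, l$ann, l$ref)$term, "start_lost")
  # stop codon loss (TGA -> TGG on codon 5 third base)
  s5 <- tibble::tibble(chrom = "chr1", pos = 25L, ref = "A", alt = "G")
  expect_equal(classify_consequences(s5, l$ann, l$ref)$term, "stop_lost")
})

test_that("minus-strand variants classify on the reverse complement", {
  l <- toy_locus("-")
  # genomic end of the locus is the transcript start; CDS genomic 11..25,
  # transcript codon 2 = genomic 20..22 reverse-complemented
  # genomic base at 22 is complement of CDS base 4 (codon 2 position 1)
  cds <- "ATGAAATACCATTGA"
  g22 <- tailvar:::complement_base(substr(cds, 4, 4))
  expect_equal(substr(l$ref[["chr1"]], 22, 22), g22)
  # transcript-strand A->C (missense K->Q) is genomic T->G at position 22
  s <- tibble::tibble(chrom = "chr1", pos = 22L, ref = "T", alt = "G")
  got <- classify_consequences(s, l$ann, l$ref)
  expect_equal(got$term, "missense")
  expect_equal(got$codon_change, "AAA>CAA")
})

test_that("non-coding placements get positional terms", {
  l <- toy_locus("+")
  ann <- l$ann
  # widen the transcript to create UTRs: exon 5..30, CDS still 11..25
  ann$start[ann$type != "CDS"] <- 5L
  ann$end[ann$type != "CDS"] <- 30L
  utr5 <- tibble::tibble(chrom = "chr1", pos = 7L,
                         ref = substr(l$ref[["chr1"]], 7, 7), alt = "A")
  utr5$alt <- ifelse(utr5$ref == "A", "C", "A")
  expect_equal(classify_consequences(utr5, ann, l$ref)$term, "five_prime_utr")
  utr3 <- tibble::tibble(chrom = "chr1", pos = 28L,
                         ref = substr(l$ref[["chr1"]], 28, 28), alt = "A")
  utr3$alt <- ifelse(utr3$ref == "A", "C", "A")
  expect_equal(classify_consequences(utr3, ann, l$ref)$term, "three_prime_utr")
  # past the transcript but within the window: upstream on '+'
  up <- tibble::tibble(chrom = "chr1", pos = 2L,
                       ref = substr(l$ref[["chr1"]], 2, 2), alt = "A")
  up$alt <- ifelse(up$ref == "A", "C", "A")
  expect_equal(classify_consequences(up, ann, l$ref, up_down_bp = 10)$term,
               "upstream_gene")
  expect_equal(classify_consequences(up, ann, l$ref, up_down_bp = 1)$term,
               "intergenic")
})

test_that("REF mismatches against the reference are an error", {
  l <- toy_locus("+")
  s <- tibble::tibble(chrom = "chr1", pos = 16L, ref = "C", alt = "G")
  expect_error(classify_consequences(s, l$ann, l$ref), "disagrees")
})

test_that("engineered cohort consequences agree with a six-step oracle", {
  co <- small_cohort()
  coding <- co$truth[!is.na(co$truth$consequence), ]
  calls <- classify_consequences(
    coding[, c("chrom", "pos", "ref", "alt")], co$annotation, co$reference
  )
  summ <- most_severe_consequence(calls)
  merged <- dplyr::inner_join(
    summ, coding[, c("chrom", "pos", "consequence", "gene_id")],
    by = c("chrom", "pos")
  )
  expect_equal(nrow(merged), nrow(coding))
  expect_equal(merged$term, merged$consequence)
  expect_equal(merged$gene_id.x, merged$gene_id.y)

  # independent oracle: locate the codon in the genome, substitute,
  # translate both codons with the standard code, compare
  models <- build_cds_models(co$annotation, co$reference)
  for (i in seq_len(nrow(coding))) {
    row <- coding[i, ]
    tx_hits <- purrr::keep(models, function(m) {
      m$chrom == row$chrom && any(row$pos >= m$map$gs & row$pos <= m$map$ge)
    })
    expect_equal(length(tx_hits), 1L)
    m <- tx_hits[[1]]
    cds_pos <- tailvar:::genomic_to_cds(m, row$pos)
    ci <- (cds_pos - 1) %/% 3 + 1
    codon <- substr(m$seq, 3 * ci - 2, 3 * ci)
    tx_alt <- if (m$strand == "+") row$alt else tailvar:::complement_base(row$alt)
    codon_alt <- codon
    substr(codon_alt, (cds_pos - 1) %% 3 + 1, (cds_pos - 1) %% 3 + 1) <- tx_alt
    aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
    aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
    want <- if (aa_alt == "*" && aa_ref != "*") "stop_gained"
    else if (aa_ref == aa_alt) "synonymous" else "missense"
    expect_equal(row$consequence, want)
  }
})

test_that("term assignments are invariant under genome reverse-complement", {
  co <- small_cohort()
  casc <- small_cascade()
  set.seed(30)
  sites <- casc$sites[sample.int(nrow(casc$sites), 40), ]
  fwd <- most_severe_consequence(
    classify_consequences(sites, co$annotation, co$reference)
  )
  L <- co$reference$lengths
  flip_ref <- stats::setNames(
    vapply(names(co$reference$seq), function(ch) {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(co$reference$seq[[ch]])))
    }, ""), names(co$reference$seq))
  flip_ann <- dplyr::mutate(
    co$annotation,
    new_start = L[chrom] - end + 1L,
    new_end = L[chrom] - start + 1L,
    strand = ifelse(strand == "+", "-", "+")
  )
  flip_ann$start <- as.integer(flip_ann$new_start)
  flip_ann$end <- as.integer(flip_ann$new_end)
  flip_ann$new_start <- NULL
  flip_ann$new_end <- NULL
  flip_sites <- dplyr::mutate(
    sites,
    pos = as.integer(L[chrom] - pos + 1L),
    ref = tailvar:::complement_base(ref),
    alt = tailvar:::complement_base(alt)
  )
  rev <- most_severe_consequence(
    classify_consequences(flip_sites, flip_ann, flip_ref)
  )
  fwd_key <- paste(fwd$chrom, L[fwd$chrom] - fwd$pos + 1L)
  rev_key <- paste(rev$chrom, rev$pos)
  expect_equal(fwd$term[order(fwd_key)], rev$term[order(rev_key)])
})

test_that("tabulation is an exact partition and recovers planted counts", {
  co <- small_cohort()
  casc <- small_cascade()
  summ <- most_severe_consequence(
    classify_consequences(casc$sites, co$annotation, co$reference)
  )
  tabs <- tabulate_consequences(summ)
  expect_equal(sum(tabs$by_term$n), nrow(summ))
  expect_equal(sum(tabs$by_impact$n), nrow(summ))
  planted <- table(co$truth$consequence)
  for (term in names(planted)) {
    expect_equal(tabs$by_term$n[tabs$by_term$term == term],
                 unname(planted[term]), label = term)
  }
  empty <- tabulate_consequences(summ[0, ])
  expect_true(all(empty$by_term$n == 0L))
  expect_equal(nrow(empty$by_term), length(consequence_terms()))
})
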