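test_that("configuration is validated", {
  expect_error(sim_config(n_specific_a = -1), "non-negative")
  expect_error(sim_config(chrom_length_bp = 5000), "10,000")
  expect_error(sim_config(known_db_fraction = 0), "known_db_fraction")
  expect_error(sim_config(known_db_fraction = 1.2), "known_db_fraction")
  expect_error(sim_config(n_specific_a = 2, n_specific_b = 2, n_shared = 2,
                          n_missense = 10), "coding sites")
  # default novel count tracks the known-db fraction target
  cfg <- sim_config()
  expect_equal(cfg$n_novel, round(200 * 0.06 / 0.94))
})

test_that("reference generation honours the generator contract", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length_bp = 100000L)
  ref <- generate_reference(cfg)
  expect_equal(nchar(ref$seq[["chr1"]]), 100000L)
  gc <- sum(strsplit(ref$seq[["chr1"]], "")[[1]] %in% c("G", "C")) / 100000
  expect_gt(gc, 0.3)
  expect_lt(gc, 0.7)
  # same config twice: identical sequences
  ref2 <- generate_reference(cfg)
  expect_identical(ref$seq, ref2$seq)
})

test_that("planted context features read back from their coordinates", {
  ref <- generate_reference(sim_config(seed = 5))
  for (i in seq_len(nrow(ref$planted))) {
    f <- ref$planted[i, ]
    tract <- substr(ref$seq[[f$chrom]], f$start, f$end)
    width <- f$end - f$start + 1L
    if (f$type == "homopolymer") {
      expect_equal(tract, strrep(f$motif, width))
    } else {
      expect_equal(width %% nchar(f$motif), 0L)
      expect_equal(tract, strrep(f$motif, width / nchar(f$motif)))
    }
  }
})

test_that("annotation has antisense overlap and valid reading frames", {
  cfg <- sim_config(seed = 9)
  ann <- generate_annotation(generate_reference(cfg), cfg)
  genes <- ann$genes[ann$genes$type == "gene", ]
  # at least one +/- overlapping pair per chromosome
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    plus <- g[g$strand == "+", ]
    minus <- g[g$strand == "-", ]
    overlap <- FALSE
    for (i in seq_len(nrow(plus))) {
      if (any(minus$start <= plus$end[i] & minus$end >= plus$start[i])) {
        overlap <- TRUE
      }
    }
    expect_true(overlap)
  }
  # every CDS translates cleanly: starts with M, single terminal stop
  models <- build_cds_models(ann$genes, ann$reference)
  expect_gt(length(models), 0)
  for (m in models) {
    expect_equal(nchar(m$seq) %% 3L, 0L)
    aa <- tailvar:::translate_nt(m$seq)
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
})

test_that("annotation placement fails cleanly on a too-small genome", {
  cfg <- sim_config(seed = 2, chrom_length_bp = 10000L, n_genes = 40L,
                    n_chromosomes = 1L)
  expect_error(generate_annotation(generate_reference(cfg), cfg),
               "too small|too crowded")
})

test_that("truth-table accounting matches the configured class counts", {
  co <- small_cohort()
  cfg <- co$config
  counts <- table(co$truth$class)
  expect_equal(unname(counts["specific_A"]), cfg$n_specific_a)
  expect_equal(unname(counts["specific_B"]), cfg$n_specific_b)
  # a handful of near-gene shared sites are planted on top of n_shared
  expect_gte(unname(counts["shared"]), cfg$n_shared)
  for (cl in c("low_depth", "low_support", "multiallelic", "in_ssr",
               "in_junction_flank", "in_bidirectional", "high_hrun")) {
    expect_equal(unname(counts[cl]), cfg$n_artifacts_per_class)
  }
  expect_equal(unname(counts["novel"]), cfg$n_novel)
  # each planted site appears exactly once
  expect_equal(anyDuplicated(paste(co$truth$chrom, co$truth$pos)), 0L)
})

test_that("breed-specific truth rows leave the other breed homozygous reference", {
  co <- small_cohort()
  gt_cols_b <- paste0("gt_", co$panel$sample_id[co$panel$breed == "breedB"])
  gt_cols_a <- paste0("gt_", co$panel$sample_id[co$panel$breed == "breedA"])
  spec_a <- truth_sites(co, "specific_A")
  expect_true(all(as.matrix(spec_a[, gt_cols_b]) == "0/0"))
  spec_b <- truth_sites(co, "specific_B")
  expect_true(all(as.matrix(spec_b[, gt_cols_a]) == "0/0"))
  # shared sites segregate in >= 2 samples of both breeds
  shared <- truth_sites(co, "shared")
  carriers <- function(m) rowSums(matrix(grepl("[12]", as.matrix(m)), nrow = nrow(m)))
  expect_true(all(carriers(shared[, gt_cols_a]) >= 2))
  expect_true(all(carriers(shared[, gt_cols_b]) >= 2))
})

test_that("realized known-database fraction is close to its target", {
  co <- small_cohort()
  non_artifact <- truth_sites(co, c("specific_A", "specific_B", "shared", "novel"))
  db_keys <- paste(co$known_db$chrom, co$known_db$pos, co$known_db$ref,
                   co$known_db$alt, sep = ":")
  realized <- mean(key_of(non_artifact) %in% db_keys)
  expect_lt(abs(realized - co$config$known_db_fraction), 0.02)
  # every clean planted site is known, every novel site is not
  clean <- truth_sites(co, c("specific_A", "specific_B", "shared"))
  expect_true(all(key_of(clean) %in% db_keys))
  expect_false(any(key_of(truth_sites(co, "novel")) %in% db_keys))
})

test_that("mask-class sites lie inside their recomputed masks", {
  co <- small_cohort()
  masks <- context_masks(co$reference, co$annotation)
  for (pair in list(c("in_ssr", "ssr"), c("in_junction_flank", "junction"),
                    c("in_bidirectional", "bidirectional"))) {
    s <- truth_sites(co, pair[1])
    expect_true(all(point_in_mask(masks[[pair[2]]], s$chrom, s$pos)))
  }
  hh <- truth_sites(co, "high_hrun")
  expect_true(all(homopolymer_run(co$reference, hh$chrom, hh$pos, hh$alt) > 5))
})

test_that("identical configurations produce byte-identical output files", {
  cfg <- sim_config(seed = 77, chrom_length_bp = 30000L, n_chromosomes = 1L,
                    n_genes = 5L, n_specific_a = 5, n_specific_b = 5,
                    n_shared = 10, n_artifacts_per_class = 2, n_missense = 1,
                    n_synonymous = 1, n_stop_gained = 1, n_deg_overlap = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = paste("file", f))
  }
})

test_that("emitted VCFs round-trip the planted genotypes exactly", {
  co <- small_cohort()
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_vcf(file.path(d, "cohort.vcf"))
  merged <- dplyr::inner_join(
    back, co$calls,
    by = c("chrom", "pos", "ref", "alt", "sample_id"),
    suffix = c(".file", ".mem")
  )
  expect_equal(nrow(merged), nrow(co$calls))
  expect_equal(merged$gt.file, merged$gt.mem)
  expect_equal(merged$ad.file, merged$ad.mem)
  expect_equal(merged$dp.file, merged$dp.mem)

  # every truth coordinate appears in at least one per-sample VCF
  per_sample <- lapply(co$panel$sample_id, function(s) {
    read_vcf(file.path(d, paste0(s, ".vcf")))
  })
  seen <- unique(dplyr::bind_rows(lapply(per_sample, function(x) {
    x[, c("chrom", "pos")]
  })))
  truth_keys <- paste(co$truth$chrom, co$truth$pos)
  expect_true(all(truth_keys %in% paste(seen$chrom, seen$pos)))

  # annotation and reference round-trip through their standard formats
  ann_back <- read_gtf(file.path(d, "annotation.gtf"))
  expect_setequal(unique(ann_back$type), unique(co$annotation$type))
  expect_equal(nrow(ann_back), nrow(co$annotation))
  ref_back <- read_fasta(file.path(d, "reference.fa"))
  expect_identical(ref_back, co$reference$seq)
})
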