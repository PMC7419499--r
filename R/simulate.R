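# Synthetic two-breed cohort generator. Emulates the study design the
# pipeline targets: a 4 + 4 animal, two-breed RNA-seq cohort with
# breed-divergent SNPs, shared SNPs, and one planted artifact family per
# filter rule, so that every downstream stage has a planted-answer surface.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ARTIFACT_CLASSES <- c("low_depth", "low_support", "multiallelic", "in_ssr",
                      "in_junction_flank", "in_bidirectional", "high_hrun")
CLEAN_CLASSES <- c("specific_A", "specific_B", "shared")

#' Simulation configuration
#'
#' Builds and validates the configuration object that fully determines a
#' synthetic cohort: with a fixed seed the generated files are byte-identical
#' across runs.
#'
#' @param seed Integer RNG seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome (>= 10,000).
#' @param n_genes Total number of genes, distributed evenly over chromosomes.
#' @param n_breed_a_samples,n_breed_b_samples Animals per breed (default 4+4,
#'   the design of the motivating cohort).
#' @param n_specific_a,n_specific_b Planted breed-specific SNP counts.
#' @param n_shared Planted SNPs segregating in both breeds.
#' @param n_artifacts_per_class Planted sites per filter-violating artifact
#'   class (`low_depth`, `low_support`, `multiallelic`, `in_ssr`,
#'   `in_junction_flank`, `in_bidirectional`, `high_hrun`).
#' @param known_db_fraction Target fraction of planted non-artifact sites
#'   present in the known-SNP database (default 0.94); determines the default
#'   number of planted `novel` sites.
#' @param n_novel Planted true SNPs absent from the known database; default
#'   derived from `known_db_fraction`.
#' @param up_downstream_bp Up/downstream annotation window in bp.
#' @param n_missense,n_synonymous,n_stop_gained Of the planted clean sites,
#'   how many are engineered into CDS with the given coding consequence.
#' @param n_deg_overlap Number of breed-specific-SNP-bearing genes planted as
#'   significant in the simulated DEG table.
#' @param breed_a,breed_b Breed labels used for sample naming.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 100000L,
                       n_genes = 16L,
                       n_breed_a_samples = 4L,
                       n_breed_b_samples = 4L,
                       n_specific_a = 50L,
                       n_specific_b = 50L,
                       n_shared = 100L,
                       n_artifacts_per_class = 10L,
                       known_db_fraction = 0.94,
                       n_novel = NULL,
                       up_downstream_bp = 5000L,
                       n_missense = 10L,
                       n_synonymous = 5L,
                       n_stop_gained = 3L,
                       n_deg_overlap = 7L,
                       breed_a = "breedA",
                       breed_b = "breedB") {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_genes = as.integer(n_genes),
    n_breed_a_samples = as.integer(n_breed_a_samples),
    n_breed_b_samples = as.integer(n_breed_b_samples),
    n_specific_a = as.integer(n_specific_a),
    n_specific_b = as.integer(n_specific_b),
    n_shared = as.integer(n_shared),
    n_artifacts_per_class = as.integer(n_artifacts_per_class),
    known_db_fraction = known_db_fraction,
    up_downstream_bp = as.integer(up_downstream_bp),
    n_missense = as.integer(n_missense),
    n_synonymous = as.integer(n_synonymous),
    n_stop_gained = as.integer(n_stop_gained),
    n_deg_overlap = as.integer(n_deg_overlap),
    breed_a = breed_a,
    breed_b = breed_b
  )
  counts <- unlist(cfg[c("n_chromosomes", "n_genes", "n_breed_a_samples",
                         "n_breed_b_samples", "n_specific_a", "n_specific_b",
                         "n_shared", "n_artifacts_per_class", "n_missense",
                         "n_synonymous", "n_stop_gained", "n_deg_overlap")])
  if (any(is.na(counts)) || any(counts < 0)) {
    rlang::abort("all counts must be non-negative integers")
  }
  if (cfg$chrom_length_bp < 10000L) {
    rlang::abort("chrom_length_bp must be at least 10,000")
  }
  if (!is.numeric(known_db_fraction) ||
      known_db_fraction <= 0 || known_db_fraction > 1) {
    rlang::abort("known_db_fraction must lie in (0, 1]")
  }
  n_clean <- cfg$n_specific_a + cfg$n_specific_b + cfg$n_shared
  cfg$n_novel <- if (is.null(n_novel)) {
    as.integer(round(n_clean * (1 - known_db_fraction) / known_db_fraction))
  } else {
    as.integer(n_novel)
  }
  if (cfg$n_missense + cfg$n_synonymous + cfg$n_stop_gained > n_clean) {
    rlang::abort("engineered coding sites exceed the planted clean-site count")
  }
  structure(cfg, class = "sim_config")
}

sim_samples <- function(config) {
  list(
    a = paste0(config$breed_a, "_", seq_len(config$n_breed_a_samples)),
    b = paste0(config$breed_b, "_", seq_len(config$n_breed_b_samples))
  )
}

sim_panel <- function(config) {
  s <- sim_samples(config)
  tibble::tibble(
    sample_id = c(s$a, s$b),
    breed = c(rep(config$breed_a, length(s$a)), rep(config$breed_b, length(s$b)))
  )
}

#' Generate the synthetic reference genome
#'
#' Uniform-random chromosomes with deliberately planted homopolymer runs
#' (length 6-8, guarded on both sides so the run length is exact) and
#' perfect SSR tracts, all at recorded coordinates.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_reference` list: `seq` (named character vector), `planted`
#'   (tibble of planted context features), `lengths`.
#' @export
generate_reference <- function(config) {
  if (config$chrom_length_bp <= 0) rlang::abort("non-positive chromosome length")
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  n_feat_each <- max(2L, ceiling(max(1L, config$n_artifacts_per_class) /
                                   config$n_chromosomes))
  seqs <- character(0)
  planted <- list()
  for (chrom in chroms) {
    L <- config$chrom_length_bp
    chars <- sample(bases, L, replace = TRUE)
    occupied <- tibble::tibble(start = integer(), end = integer())
    place <- function(width) {
      for (try in 1:200) {
        s <- sample.int(L - width - 10L, 1) + 5L
        e <- s + width - 1L
        if (!any(pmax(occupied$start, s - 25L) <= pmin(occupied$end, e + 25L))) {
          return(c(s, e))
        }
      }
      rlang::abort("could not place planted feature; chromosome too crowded")
    }
    for (i in seq_len(n_feat_each)) {
      b <- sample(bases, 1)
      len <- sample(6:8, 1)
      se <- place(len)
      chars[se[1]:se[2]] <- b
      guard <- sample(setdiff(bases, b), 2, replace = TRUE)
      chars[se[1] - 1L] <- guard[1]
      chars[se[2] + 1L] <- guard[2]
      occupied <- dplyr::bind_rows(occupied,
                                   tibble::tibble(start = se[1], end = se[2]))
      planted[[length(planted) + 1L]] <- tibble::tibble(
        chrom = chrom, start = se[1], end = se[2],
        type = "homopolymer", motif = b
      )
    }
    for (i in seq_len(n_feat_each)) {
      k <- sample(1:6, 1)
      repeat {
        motif <- paste(sample(bases, k, replace = TRUE), collapse = "")
        if (is_primitive_motif(motif)) break
      }
      copies <- if (k == 1L) sample(10:12, 1) else if (k == 2L) sample(6:8, 1) else sample(5:6, 1)
      tract <- strrep(motif, copies)
      len <- nchar(tract)
      se <- place(len)
      chars[se[1]:se[2]] <- strsplit(tract, "")[[1]]
      g1 <- sample(setdiff(bases, c(substr(motif, 1, 1), substr(motif, k, k))), 1)
      g2 <- sample(setdiff(bases, c(substr(motif, 1, 1), substr(motif, k, k))), 1)
      chars[se[1] - 1L] <- g1
      chars[se[2] + 1L] <- g2
      occupied <- dplyr::bind_rows(occupied,
                                   tibble::tibble(start = se[1], end = se[2]))
      planted[[length(planted) + 1L]] <- tibble::tibble(
        chrom = chrom, start = se[1], end = se[2],
        type = "ssr", motif = motif
      )
    }
    seqs[chrom] <- paste(chars, collapse = "")
  }
  structure(list(
    seq = seqs,
    planted = dplyr::bind_rows(planted),
    lengths = stats::setNames(rep(config$chrom_length_bp, length(chroms)), chroms)
  ), class = "sim_reference")
}

# Build one gene's exon/CDS structure starting at `start` on `strand`.
# Returns annotation rows plus the CDS sequence to patch in.
build_gene <- function(chrom, start, strand, gene_id) {
  n_ex <- sample(2:5, 1)
  exon_lens <- sample(180:400, n_ex, replace = TRUE)
  intron_lens <- if (n_ex > 1) sample(120:400, n_ex - 1, replace = TRUE) else integer(0)
  exon_starts <- start + cumsum(c(0L, exon_lens[-n_ex] + intron_lens))
  exon_ends <- exon_starts + exon_lens - 1L
  gene_end <- exon_ends[n_ex]
  exonic_total <- sum(exon_lens)
  utr5 <- sample(30:80, 1)
  utr3 <- sample(80:160, 1)
  cds_len <- exonic_total - utr5 - utr3
  cds_len <- cds_len - (cds_len %% 3L)
  utr3 <- exonic_total - utr5 - cds_len
  stopifnot(cds_len >= 60L)

  # transcript-order exons; transcript coordinate 1 is the 5' end
  ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  tx_len <- cumsum(exon_lens[ord])
  tx_starts <- c(1L, tx_len[-n_ex] + 1L)
  cds_tx <- c(utr5 + 1L, utr5 + cds_len)
  cds_rows <- list()
  for (i in seq_len(n_ex)) {
    e <- ord[i]
    lo <- max(cds_tx[1], tx_starts[i])
    hi <- min(cds_tx[2], tx_starts[i] + exon_lens[e] - 1L)
    if (lo > hi) next
    if (strand == "+") {
      gs <- exon_starts[e] + (lo - tx_starts[i])
      ge <- exon_starts[e] + (hi - tx_starts[i])
    } else {
      ge <- exon_ends[e] - (lo - tx_starts[i])
      gs <- exon_ends[e] - (hi - tx_starts[i])
    }
    cds_rows[[length(cds_rows) + 1L]] <- tibble::tibble(
      gs = gs, ge = ge, cds_start = lo - utr5, cds_end = hi - utr5
    )
  }
  cds_map <- dplyr::bind_rows(cds_rows)
  n_codons <- cds_len %/% 3L
  interior <- sample(setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS),
                     n_codons - 2L, replace = TRUE)
  cds_seq <- paste0("ATG", paste(interior, collapse = ""),
                    sample(STOP_CODONS, 1))
  tx_id <- paste0(gene_id, ".t1")
  ann <- dplyr::bind_rows(
    tibble::tibble(chrom = chrom, start = start, end = gene_end,
                   strand = strand, type = "gene", gene_id = gene_id,
                   transcript_id = NA_character_, exon_number = NA_integer_,
                   frame = NA_integer_),
    tibble::tibble(chrom = chrom, start = start, end = gene_end,
                   strand = strand, type = "transcript", gene_id = gene_id,
                   transcript_id = tx_id, exon_number = NA_integer_,
                   frame = NA_integer_),
    tibble::tibble(chrom = chrom, start = exon_starts, end = exon_ends,
                   strand = strand, type = "exon", gene_id = gene_id,
                   transcript_id = tx_id,
                   exon_number = order(ord), frame = NA_integer_)
  )
  cds_map_tx <- dplyr::arrange(cds_map, .data$cds_start)
  phase <- (3L - (cds_map_tx$cds_start - 1L) %% 3L) %% 3L
  ann <- dplyr::bind_rows(ann, tibble::tibble(
    chrom = chrom, start = cds_map_tx$gs, end = cds_map_tx$ge,
    strand = strand, type = "CDS", gene_id = gene_id,
    transcript_id = tx_id, exon_number = NA_integer_, frame = phase
  ))
  list(ann = ann, cds_seq = cds_seq, cds_map = cds_map_tx,
       gene_start = start, gene_end = gene_end, strand = strand,
       cds_gmin = min(cds_map_tx$gs), cds_gmax = max(cds_map_tx$ge))
}

patch_cds <- function(seq, gene) {
  genomic <- if (gene$strand == "+") gene$cds_seq else revcomp(gene$cds_seq)
  m <- dplyr::arrange(gene$cds_map, .data$gs)
  offset <- 0L
  for (i in seq_len(nrow(m))) {
    w <- m$ge[i] - m$gs[i] + 1L
    substr(seq, m$gs[i], m$ge[i]) <- substr(genomic, offset + 1L, offset + w)
    offset <- offset + w
  }
  seq
}

#' Generate the synthetic gene annotation
#'
#' Places non-nested genes with 2-5 exons each on alternating strands, with
#' at least one overlapping antisense gene pair per chromosome (exercising
#' the bidirectional-transcription mask), and writes valid open reading
#' frames (start codon, no internal stops, terminal stop codon) into the CDS
#' regions of the reference. Because the reference sequence is patched, the
#' updated reference is returned alongside the gene model.
#'
#' @param reference A `sim_reference` from [generate_reference()].
#' @param config A [sim_config()] object.
#' @return A `sim_annotation` list: `genes` (annotation tibble), `reference`
#'   (patched `sim_reference`).
#' @export
generate_annotation <- function(reference, config) {
  set.seed(config$seed + 1L)
  chroms <- names(reference$seq)
  quota <- diff(round(seq(0, config$n_genes, length.out = length(chroms) + 1)))
  seqs <- reference$seq
  ann <- list()
  gene_counter <- 0L
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    L <- nchar(seqs[[chrom]])
    avoid <- dplyr::filter(reference$planted, .data$chrom == !!chrom)
    clear_of_features <- function(s, e) {
      nrow(avoid) == 0 ||
        !any(pmax(avoid$start - 30L, s) <= pmin(avoid$end + 30L, e))
    }
    n_here <- quota[ci]
    if (n_here == 0) next
    cursor <- sample(1200:2200, 1)
    commit <- function(g) {
      seqs[[chrom]] <<- patch_cds(seqs[[chrom]], g)
      ann[[length(ann) + 1L]] <<- g$ann
      cursor <<- max(cursor, g$gene_end) + sample(900:2200, 1)
    }
    n_remaining <- n_here
    # the antisense pair is placed first, as a unit: gene 2 ('-') starts just
    # past gene 1's CDS end so the gene bodies overlap (exercising the
    # bidirectional mask) while the two open reading frames stay disjoint
    if (n_here >= 2L) {
      id1 <- sprintf("G%03d", gene_counter + 1L)
      id2 <- sprintf("G%03d", gene_counter + 2L)
      pair <- NULL
      for (try in 1:300) {
        g1 <- build_gene(chrom, cursor, "+", id1)
        if (g1$gene_end + 600L <= L &&
            clear_of_features(g1$gene_start - 5L, g1$gene_end + 5L)) {
          for (k in 1:40) {
            g2 <- build_gene(chrom, g1$cds_gmax + 10L, "-", id2)
            if (g2$gene_end + 600L <= L &&
                clear_of_features(g2$gene_start - 5L, g2$gene_end + 5L) &&
                g2$gene_start <= g1$gene_end &&
                g2$cds_gmin > g1$cds_gmax) {
              pair <- list(g1, g2)
              break
            }
          }
        }
        if (!is.null(pair)) break
        cursor <- cursor + sample(300:800, 1)
        if (cursor + 8000L > L) cursor <- sample(1200:2200, 1)
      }
      if (is.null(pair)) {
        rlang::abort("genome too small for the requested number of genes")
      }
      commit(pair[[1]])
      commit(pair[[2]])
      cursor <- max(pair[[1]]$gene_end, pair[[2]]$gene_end) + sample(900:2200, 1)
      gene_counter <- gene_counter + 2L
      n_remaining <- n_here - 2L
    }
    for (gi in seq_len(n_remaining)) {
      gene_counter <- gene_counter + 1L
      gene_id <- sprintf("G%03d", gene_counter)
      strand <- if (gi %% 2L == 1L) "+" else "-"
      placed <- FALSE
      for (try in 1:120) {
        g <- build_gene(chrom, cursor, strand, gene_id)
        if (g$gene_end + 600L > L) {
          rlang::abort("genome too small for the requested number of genes")
        }
        if (clear_of_features(g$gene_start - 5L, g$gene_end + 5L)) {
          commit(g)
          placed <- TRUE
          break
        }
        cursor <- cursor + sample(200:600, 1)
        if (cursor + 2500L > L) {
          rlang::abort("genome too small for the requested number of genes")
        }
      }
      if (!placed) rlang::abort("failed to place gene; genome too crowded")
    }
  }
  genes <- dplyr::bind_rows(ann)
  patched <- structure(list(
    seq = seqs, planted = reference$planted, lengths = reference$lengths
  ), class = "sim_reference")
  structure(list(genes = genes, reference = patched), class = "sim_annotation")
}

# --- genotype block builders ----------------------------------------------

carrier_call <- function() {
  gt <- sample(c("0/1", "1/1"), 1, prob = c(0.7, 0.3))
  dp <- sample(20:40, 1)
  if (gt == "0/1") {
    alt <- min(dp - 1L, max(3L, stats::rbinom(1, dp, 0.5)))
    ref <- dp - alt
  } else {
    ref <- sample(0:2, 1)
    alt <- dp - ref
  }
  tibble::tibble(gt = gt, ad = paste(ref, alt, sep = ","), sample_dp = dp)
}

homref_call <- function() {
  dp <- sample(15:40, 1)
  tibble::tibble(gt = "0/0", ad = paste0(dp, ",0"), sample_dp = dp)
}

missing_call <- function() {
  tibble::tibble(gt = "./.", ad = NA_character_, sample_dp = NA_integer_)
}

breed_block <- function(ids, n_carriers, carrier_fun = carrier_call,
                        allow_missing = TRUE) {
  carriers <- sample(ids, n_carriers)
  purrr::map_dfr(ids, function(s) {
    if (s %in% carriers) {
      dplyr::mutate(carrier_fun(), sample_id = s)
    } else if (allow_missing && stats::runif(1) < 0.08) {
      dplyr::mutate(missing_call(), sample_id = s)
    } else {
      dplyr::mutate(homref_call(), sample_id = s)
    }
  })
}

genotypes_for_class <- function(class, samples) {
  a <- samples$a
  b <- samples$b
  seg_a <- function(...) sample(2:length(a), 1)
  seg_b <- function(...) sample(2:length(b), 1)
  if (class == "specific_A") {
    ga <- breed_block(a, seg_a())
    gb <- purrr::map_dfr(b, function(s) dplyr::mutate(homref_call(), sample_id = s))
  } else if (class == "specific_B") {
    ga <- purrr::map_dfr(a, function(s) dplyr::mutate(homref_call(), sample_id = s))
    gb <- breed_block(b, seg_b())
  } else if (class == "low_support") {
    weak <- function() {
      dp <- sample(20:40, 1)
      tibble::tibble(gt = "0/1", ad = paste(dp - 2L, 2L, sep = ","), sample_dp = dp)
    }
    ga <- breed_block(a, seg_a(), carrier_fun = weak, allow_missing = FALSE)
    gb <- breed_block(b, seg_b(), carrier_fun = weak, allow_missing = FALSE)
  } else if (class == "multiallelic") {
    tri <- function() {
      dp <- sample(24:40, 1)
      which_alt <- sample(1:2, 1)
      alt_d <- max(4L, stats::rbinom(1, dp, 0.4))
      ref_d <- dp - alt_d
      ad <- if (which_alt == 1L) c(ref_d, alt_d, 0L) else c(ref_d, 0L, alt_d)
      tibble::tibble(gt = paste0("0/", which_alt),
                     ad = paste(ad, collapse = ","), sample_dp = dp)
    }
    ga <- breed_block(a, seg_a(), carrier_fun = tri, allow_missing = FALSE)
    gb <- breed_block(b, seg_b(), carrier_fun = tri, allow_missing = FALSE)
  } else {
    # shared, novel and remaining artifact classes segregate in both breeds
    ga <- breed_block(a, seg_a(), allow_missing = class == "shared")
    gb <- breed_block(b, seg_b(), allow_missing = class == "shared")
  }
  dplyr::bind_rows(ga, gb)[, c("sample_id", "gt", "ad", "sample_dp")]
}

site_info <- function(class) {
  tibble::tibble(
    qual = round(stats::runif(1, 100, 2000), 1),
    dp = if (class == "low_depth") 9 else sample(15:60, 1),
    qd = round(stats::runif(1, 5, 30), 2),
    mq = round(stats::runif(1, 50, 60), 2),
    mq_rank_sum = round(stats::runif(1, -2, 2), 2),
    read_pos_rank_sum = round(stats::runif(1, -2, 2), 2)
  )
}

# --- position sampling -----------------------------------------------------

new_position_pool <- function() new.env(parent = emptyenv())

pos_used <- function(pool, chrom, pos) {
  exists(paste0(chrom, ":", pos), envir = pool, inherits = FALSE)
}

pos_mark <- function(pool, chrom, pos) {
  assign(paste0(chrom, ":", pos), TRUE, envir = pool)
}

# Per-chromosome logical lookup vectors over every mask / region class, so
# the rejection sampling below runs in O(1) per candidate.
make_region_lookup <- function(masks, genes, seqs) {
  lens <- stats::setNames(nchar(seqs), names(seqs))
  blank <- lapply(lens, function(L) logical(L))
  fill <- function(vecs, intervals) {
    for (i in seq_len(nrow(intervals))) {
      ch <- intervals$chrom[i]
      vecs[[ch]][intervals$start[i]:intervals$end[i]] <- TRUE
    }
    vecs
  }
  cds <- dplyr::filter(genes, .data$type == "CDS")
  gene_rows <- dplyr::filter(genes, .data$type == "gene")
  list(
    ssr = fill(blank, masks$ssr),
    junction = fill(blank, masks$junction),
    bidirectional = fill(blank, masks$bidirectional),
    cds = fill(blank, cds),
    gene = fill(blank, gene_rows)
  )
}

lookup_hit <- function(lookup, layer, chrom, pos) {
  lookup[[layer]][[chrom]][pos]
}

position_ok <- function(seqs, lookup, pool, chrom, pos, alt,
                        require_unmasked = TRUE, forbid_cds = TRUE) {
  if (pos < 2L || pos > nchar(seqs[[chrom]]) - 1L) return(FALSE)
  if (pos_used(pool, chrom, pos)) return(FALSE)
  refb <- ref_base(seqs, chrom, pos)
  if (!refb %in% c("A", "C", "G", "T") || refb == alt) return(FALSE)
  if (require_unmasked &&
      (lookup_hit(lookup, "ssr", chrom, pos) ||
       lookup_hit(lookup, "junction", chrom, pos) ||
       lookup_hit(lookup, "bidirectional", chrom, pos))) {
    return(FALSE)
  }
  if (forbid_cds && lookup_hit(lookup, "cds", chrom, pos)) return(FALSE)
  if (homopolymer_run(seqs, chrom, pos, alt) > 5L) return(FALSE)
  TRUE
}

sample_genic_position <- function(seqs, gene_rows, lookup, pool) {
  bases <- c("A", "C", "G", "T")
  for (try in 1:500) {
    g <- gene_rows[sample.int(nrow(gene_rows), 1), ]
    pos <- sample(g$start:g$end, 1)
    refb <- ref_base(seqs, g$chrom, pos)
    if (!refb %in% bases) next
    alt <- sample(setdiff(bases, refb), 1)
    if (position_ok(seqs, lookup, pool, g$chrom, pos, alt)) {
      return(list(chrom = g$chrom, pos = pos, ref = refb, alt = alt,
                  gene_id = g$gene_id))
    }
  }
  rlang::abort("could not place a genic site; class counts exceed available positions")
}

sample_flank_position <- function(seqs, gene_rows, lookup, pool, window) {
  bases <- c("A", "C", "G", "T")
  for (try in 1:500) {
    g <- gene_rows[sample.int(nrow(gene_rows), 1), ]
    side <- sample(c(-1L, 1L), 1)
    off <- sample(seq_len(window), 1)
    pos <- if (side < 0) g$start - off else g$end + off
    if (pos < 2L || pos > nchar(seqs[[g$chrom]]) - 1L) next
    if (lookup_hit(lookup, "gene", g$chrom, pos)) next
    refb <- ref_base(seqs, g$chrom, pos)
    if (!refb %in% bases) next
    alt <- sample(setdiff(bases, refb), 1)
    if (position_ok(seqs, lookup, pool, g$chrom, pos, alt,
                    forbid_cds = FALSE)) {
      return(list(chrom = g$chrom, pos = pos, ref = refb, alt = alt,
                  gene_id = NA_character_))
    }
  }
  rlang::abort("could not place a flanking site")
}

sample_in_mask_position <- function(seqs, mask, other_layers, lookup, pool) {
  bases <- c("A", "C", "G", "T")
  for (try in 1:500) {
    iv <- mask[sample.int(nrow(mask), 1), ]
    pos <- sample(iv$start:iv$end, 1)
    if (pos_used(pool, iv$chrom, pos)) next
    if (pos < 2L || pos > nchar(seqs[[iv$chrom]]) - 1L) next
    refb <- ref_base(seqs, iv$chrom, pos)
    if (!refb %in% bases) next
    in_other <- any(vapply(other_layers, function(layer) {
      lookup_hit(lookup, layer, iv$chrom, pos)
    }, logical(1)))
    if (in_other) next
    ok_alt <- NULL
    for (alt in sample(setdiff(bases, refb))) {
      if (homopolymer_run(seqs, iv$chrom, pos, alt) <= 5L) {
        ok_alt <- alt
        break
      }
    }
    if (is.null(ok_alt)) next
    return(list(chrom = iv$chrom, pos = pos, ref = refb, alt = ok_alt,
                gene_id = NA_character_))
  }
  rlang::abort("could not place an in-mask site")
}

engineer_coding_site <- function(models, lookup, seqs, pool, target_term) {
  tx_ids <- names(models)
  bases <- c("A", "C", "G", "T")
  for (try in 1:500) {
    model <- models[[sample(tx_ids, 1)]]
    n_cod <- nchar(model$seq) %/% 3L
    if (n_cod < 4L) next
    ci <- sample(2:(n_cod - 1L), 1)
    codon <- substr(model$seq, 3L * ci - 2L, 3L * ci)
    cands <- list()
    for (p in 1:3) {
      cur <- substr(codon, p, p)
      for (alt in setdiff(bases, cur)) {
        newc <- codon
        substr(newc, p, p) <- alt
        aa_ref <- translate_codon(codon)
        aa_alt <- translate_codon(newc)
        term <- if (aa_alt == "*") "stop_gained"
        else if (aa_alt == aa_ref) "synonymous"
        else "missense"
        if (term == target_term) {
          cands[[length(cands) + 1L]] <- list(p = p, alt = alt)
        }
      }
    }
    if (length(cands) == 0) next
    pick <- cands[[sample.int(length(cands), 1)]]
    cds_pos <- 3L * (ci - 1L) + pick$p
    gpos <- cds_to_genomic(model, cds_pos)
    galt <- if (model$strand == "+") pick$alt else complement_base(pick$alt)
    refb <- ref_base(seqs, model$chrom, gpos)
    if (refb == galt) next
    if (pos_used(pool, model$chrom, gpos)) next
    if (lookup_hit(lookup, "ssr", model$chrom, gpos) ||
        lookup_hit(lookup, "junction", model$chrom, gpos) ||
        lookup_hit(lookup, "bidirectional", model$chrom, gpos)) next
    if (homopolymer_run(seqs, model$chrom, gpos, galt) > 5L) next
    return(list(chrom = model$chrom, pos = gpos, ref = refb, alt = galt,
                gene_id = model$gene_id, transcript_id = model$transcript_id,
                term = target_term))
  }
  rlang::abort(paste0("could not engineer a ", target_term, " site"))
}

# --- cohort assembly -------------------------------------------------------

#' Simulate the cohort call set and companion resources
#'
#' Plants every site class (breed-specific, shared, one class per filter
#' rule, novel), realizes per-sample genotypes with read support, and builds
#' the known-SNP database, QTL table, gene sets and DEG table, together with
#' the truth table that records every planted site and its intended fate.
#'
#' @param reference The patched `sim_reference` from [generate_annotation()].
#' @param annotation A `sim_annotation` (or its `genes` tibble).
#' @param config A [sim_config()] object.
#' @return A `sim_cohort` list: `calls` (long call tibble over all samples),
#'   `truth`, `known_db`, `qtls`, `gene_sets`, `deg`, `panel`, `masks`,
#'   `annotation`, `reference`, `deg_overlap_genes`, `config`.
#' @export
simulate_cohort <- function(reference, annotation, config) {
  genes <- if (inherits(annotation, "sim_annotation")) annotation$genes else annotation
  if (inherits(annotation, "sim_annotation")) reference <- annotation$reference
  set.seed(config$seed + 2L)
  seqs <- as_ref_seqs(reference)
  samples <- sim_samples(config)
  masks <- context_masks(reference, genes)
  lookup <- make_region_lookup(masks, genes, seqs)
  gene_rows <- dplyr::filter(genes, .data$type == "gene")
  models <- build_cds_models(genes, reference)
  pool <- new_position_pool()

  plan <- list()
  add_site <- function(loc, class, consequence = NA_character_,
                       transcript_id = NA_character_, alt_override = NULL) {
    pos_mark(pool, loc$chrom, loc$pos)
    plan[[length(plan) + 1L]] <<- tibble::tibble(
      chrom = loc$chrom, pos = loc$pos, ref = loc$ref,
      alt = alt_override %||% loc$alt, class = class,
      consequence = consequence,
      gene_id = loc$gene_id %||% NA_character_,
      transcript_id = transcript_id
    )
  }

  # engineered coding sites are drawn from the clean pools round-robin
  coding_terms <- c(rep("missense", config$n_missense),
                    rep("synonymous", config$n_synonymous),
                    rep("stop_gained", config$n_stop_gained))
  clean_quota <- c(specific_A = config$n_specific_a,
                   specific_B = config$n_specific_b,
                   shared = config$n_shared)
  coding_class <- character(0)
  if (length(coding_terms) > 0) {
    avail <- names(clean_quota)[clean_quota > 0]
    coding_class <- rep_len(avail, length(coding_terms))
  }
  for (i in seq_along(coding_terms)) {
    site <- engineer_coding_site(models, lookup, seqs, pool, coding_terms[i])
    add_site(site, coding_class[i], consequence = coding_terms[i],
             transcript_id = site$transcript_id)
    clean_quota[coding_class[i]] <- clean_quota[coding_class[i]] - 1L
  }
  for (class in names(clean_quota)) {
    for (i in seq_len(clean_quota[[class]])) {
      add_site(sample_genic_position(seqs, gene_rows, lookup, pool), class)
    }
  }
  # a slice of near-gene sites so up/downstream terms are represented
  n_flank <- min(8L, config$n_shared)
  for (i in seq_len(n_flank)) {
    add_site(sample_flank_position(seqs, gene_rows, lookup, pool,
                                   config$up_downstream_bp), "shared")
  }
  for (i in seq_len(config$n_novel)) {
    add_site(sample_genic_position(seqs, gene_rows, lookup, pool), "novel")
  }

  n_art <- config$n_artifacts_per_class
  for (i in seq_len(n_art)) {
    add_site(sample_genic_position(seqs, gene_rows, lookup, pool), "low_depth")
    add_site(sample_genic_position(seqs, gene_rows, lookup, pool), "low_support")
    loc <- sample_genic_position(seqs, gene_rows, lookup, pool)
    alt2 <- sample(setdiff(c("A", "C", "G", "T"), c(loc$ref, loc$alt)), 1)
    add_site(loc, "multiallelic",
             alt_override = paste(sort(c(loc$alt, alt2)), collapse = ","))
  }
  if (n_art > 0) {
    runs <- dplyr::filter(reference$planted, .data$type == "homopolymer")
    if (nrow(runs) < n_art) rlang::abort("not enough planted homopolymer runs")
    for (i in seq_len(n_art)) {
      r <- runs[i, ]
      pos <- r$start - 1L
      refb <- ref_base(seqs, r$chrom, pos)
      stopifnot(refb != r$motif)
      add_site(list(chrom = r$chrom, pos = pos, ref = refb, alt = r$motif,
                    gene_id = NA_character_), "high_hrun")
    }
    for (i in seq_len(n_art)) {
      add_site(sample_in_mask_position(
        seqs, masks$ssr, c("junction", "bidirectional"), lookup, pool
      ), "in_ssr")
      add_site(sample_in_mask_position(
        seqs, masks$junction, c("ssr", "bidirectional"), lookup, pool
      ), "in_junction_flank")
      add_site(sample_in_mask_position(
        seqs, masks$bidirectional, c("ssr", "junction"), lookup, pool
      ), "in_bidirectional")
    }
  }

  sites <- dplyr::bind_rows(plan) |>
    dplyr::arrange(.data$chrom, .data$pos)

  geno <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    dplyr::mutate(genotypes_for_class(sites$class[i], samples),
                  chrom = sites$chrom[i], pos = sites$pos[i])
  })
  info <- purrr::map_dfr(sites$class, site_info)
  sites <- dplyr::bind_cols(sites, info)

  truth <- sites |>
    dplyr::select(dplyr::all_of(c("chrom", "pos", "ref", "alt", "class",
                                  "consequence", "gene_id"))) |>
    dplyr::left_join(
      geno |>
        dplyr::mutate(sample_id = paste0("gt_", .data$sample_id)) |>
        tidyr::pivot_wider(id_cols = dplyr::all_of(c("chrom", "pos")),
                           names_from = dplyr::all_of("sample_id"),
                           values_from = dplyr::all_of("gt")),
      by = c("chrom", "pos")
    )

  calls <- sites |>
    dplyr::mutate(id = NA_character_) |>
    dplyr::inner_join(geno, by = c("chrom", "pos")) |>
    dplyr::select(dplyr::all_of(c(
      "chrom", "pos", "id", "ref", "alt", "qual", "dp", "qd", "mq",
      "mq_rank_sum", "read_pos_rank_sum", "sample_id", "gt", "ad", "sample_dp"
    ))) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$sample_id)

  # known-SNP DB: every clean (specific/shared) planted site, plus decoys;
  # novel and artifact sites are left out
  known_sites <- dplyr::filter(sites, .data$class %in% CLEAN_CLASSES)
  decoys <- list()
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(40L)) {
    chrom <- sample(names(seqs), 1)
    pos <- sample.int(nchar(seqs[[chrom]]) - 2L, 1) + 1L
    if (pos_used(pool, chrom, pos)) next
    refb <- ref_base(seqs, chrom, pos)
    if (!refb %in% bases) next
    pos_mark(pool, chrom, pos)
    decoys[[length(decoys) + 1L]] <- tibble::tibble(
      chrom = chrom, pos = pos, ref = refb,
      alt = sample(setdiff(bases, refb), 1)
    )
  }
  known_db <- dplyr::bind_rows(
    dplyr::select(known_sites,
                  dplyr::all_of(c("chrom", "pos", "ref", "alt"))),
    dplyr::bind_rows(decoys)
  ) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(rsid = sprintf("rs9%08d", dplyr::row_number()))

  # QTL intervals: most anchored on breed-specific sites so colocalization
  # has signal; a few placed independently
  traits <- c("Tail fat deposition", "Total fat area",
              "Carcass fat percentage", "Subcutaneous fat thickness",
              "Abdominal fat weight", "Fat density")
  spec_sites <- dplyr::filter(sites, .data$class %in% c("specific_A", "specific_B"))
  qtl_rows <- list()
  n_anchored <- min(8L, nrow(spec_sites))
  anchors <- if (n_anchored > 0) spec_sites[sample.int(nrow(spec_sites), n_anchored), ] else spec_sites
  for (i in seq_len(n_anchored)) {
    half <- sample(1500:5000, 1)
    qtl_rows[[length(qtl_rows) + 1L]] <- tibble::tibble(
      qtl_id = sprintf("QTL%03d", i),
      trait_name = sample(traits, 1),
      chrom = anchors$chrom[i],
      start = max(1L, anchors$pos[i] - half),
      end = min(nchar(seqs[[anchors$chrom[i]]]), anchors$pos[i] + half)
    )
  }
  for (i in seq_len(4L)) {
    chrom <- sample(names(seqs), 1)
    s <- sample.int(nchar(seqs[[chrom]]) - 8000L, 1)
    qtl_rows[[length(qtl_rows) + 1L]] <- tibble::tibble(
      qtl_id = sprintf("QTL%03d", n_anchored + i),
      trait_name = sample(traits, 1),
      chrom = chrom, start = s, end = s + sample(3000:8000, 1)
    )
  }
  qtls <- dplyr::bind_rows(qtl_rows)

  gene_ids <- unique(dplyr::filter(genes, .data$type == "gene")$gene_id)
  spec_genes <- sort(unique(stats::na.omit(spec_sites$gene_id)))
  term_names <- c("fatty acid oxidation", "lipid biosynthetic process",
                  "fatty acid transport", "MAP kinase activity",
                  "membrane organization", "RNA processing")
  gene_set_rows <- list()
  for (t in seq_along(term_names)) {
    members <- if (t == 1L && length(spec_genes) >= 4L) {
      unique(c(sample(spec_genes, min(6L, length(spec_genes))),
               sample(gene_ids, 2L)))
    } else {
      sample(gene_ids, min(length(gene_ids), sample(3:6, 1)))
    }
    gene_set_rows[[t]] <- tibble::tibble(
      term_id = sprintf("T%04d", t), term_name = term_names[t],
      gene_id = sort(members)
    )
  }
  gene_sets <- dplyr::bind_rows(gene_set_rows)

  if (config$n_deg_overlap > length(spec_genes)) {
    rlang::abort("n_deg_overlap exceeds the number of genes carrying breed-specific SNPs")
  }
  overlap_genes <- sort(sample(spec_genes, config$n_deg_overlap))
  non_spec <- setdiff(gene_ids, spec_genes)
  decoy_deg <- if (length(non_spec) > 0) {
    sample(non_spec, min(3L, length(non_spec)))
  } else {
    character(0)
  }
  deg <- tibble::tibble(
    gene_id = gene_ids,
    log2fc = round(stats::rnorm(length(gene_ids), 0, 1.2), 3),
    fdr = round(stats::runif(length(gene_ids), 0.06, 0.9), 4)
  ) |>
    dplyr::mutate(
      fdr = dplyr::if_else(.data$gene_id %in% c(overlap_genes, decoy_deg),
                           round(stats::runif(dplyr::n(), 0.001, 0.049), 4),
                           .data$fdr),
      log2fc = dplyr::if_else(.data$gene_id %in% c(overlap_genes, decoy_deg),
                              round(sample(c(-1, 1), dplyr::n(), replace = TRUE) *
                                      stats::runif(dplyr::n(), 1, 3), 3),
                              .data$log2fc)
    )

  structure(list(
    calls = calls, truth = truth, known_db = known_db, qtls = qtls,
    gene_sets = gene_sets, deg = deg, panel = sim_panel(config),
    masks = masks, annotation = genes, reference = reference,
    deg_overlap_genes = overlap_genes, config = config
  ), class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits every companion file: reference FASTA (+ .fai), GTF, merged
#' multi-sample VCF, one VCF per sample (sites where the sample carries a
#' non-reference allele), known-SNP DB VCF, QTL / gene-set / DEG / panel /
#' truth-table TSVs.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  lens <- ref_lengths(cohort$reference)
  write_fasta(cohort$reference, p("reference.fa"))
  write_gtf(cohort$annotation, p("annotation.gtf"))
  write_vcf(cohort$calls, p("cohort.vcf"), contig_lengths = lens)
  sample_paths <- character(0)
  for (s in unique(cohort$panel$sample_id)) {
    own <- cohort$calls |>
      dplyr::filter(.data$sample_id == s,
                    !is.na(.data$gt), grepl("[12]", .data$gt))
    f <- p(paste0(s, ".vcf"))
    write_vcf(own, f, contig_lengths = lens)
    sample_paths[s] <- f
  }
  write_known_db(cohort$known_db, p("known_snps.vcf"), contig_lengths = lens)
  readr::write_tsv(
    dplyr::transmute(cohort$qtls, trait_name = .data$trait_name,
                     chrom = .data$chrom, start_1based = .data$start,
                     end_1based = .data$end, qtl_id = .data$qtl_id),
    p("qtls.tsv")
  )
  readr::write_tsv(cohort$gene_sets, p("gene_sets.tsv"))
  readr::write_tsv(cohort$deg, p("deg.tsv"))
  readr::write_tsv(cohort$panel, p("panel.tsv"))
  readr::write_tsv(cohort$truth, p("truth_table.tsv"))
  invisible(c(
    list(reference = p("reference.fa"), annotation = p("annotation.gtf"),
         vcf = p("cohort.vcf"), known_db = p("known_snps.vcf"),
         qtls = p("qtls.tsv"), gene_sets = p("gene_sets.tsv"),
         deg = p("deg.tsv"), panel = p("panel.tsv"),
         truth = p("truth_table.tsv")),
    sample_vcfs = list(sample_paths)
  ))
}

#' Generate a complete synthetic cohort
#'
#' One-shot wrapper: reference, annotation (with ORF patching), cohort, and
#' optionally all files on disk.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional output directory for [write_cohort()].
#' @return A `sim_cohort`; if `out_dir` is given, with a `paths` attribute.
#' @export
generate_cohort <- function(config = sim_config(), out_dir = NULL) {
  ref <- generate_reference(config)
  ann <- generate_annotation(ref, config)
  cohort <- simulate_cohort(ann$reference, ann, config)
  if (!is.null(out_dir)) {
    attr(cohort, "paths") <- write_cohort(cohort, out_dir)
  }
  cohort
}
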