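# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no GenomicRanges, no regex repeat scan, no phyper) so they
# can serve as cross-checks.

oracle_point_in_mask <- function(intervals, chrom, pos) {
  any(intervals$chrom == chrom & intervals$start <= pos & intervals$end >= pos)
}

oracle_hrun <- function(seq, pos, alt) {
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- alt
  run <- 1L
  i <- pos - 1L
  while (i >= 1 && chars[i] == alt) {
    run <- run + 1L
    i <- i - 1L
  }
  i <- pos + 1L
  while (i <= length(chars) && chars[i] == alt) {
    run <- run + 1L
    i <- i + 1L
  }
  run
}

# Left-to-right scan per motif length over full motif copies, mirroring the
# documented SSR tract definition without regular expressions.
oracle_ssr_intervals <- function(seq, min_copies = c(`1` = 10, `2` = 6, `3` = 5,
                                                     `4` = 5, `5` = 5, `6` = 5),
                                 flank = 3L) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  prim <- function(motif) {
    k <- length(motif)
    if (k == 1) return(TRUE)
    for (d in seq_len(k - 1)) {
      if (k %% d == 0 && all(motif == rep(motif[seq_len(d)], k / d))) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (k in 1:6) {
    minc <- min_copies[[as.character(k)]]
    i <- 1L
    while (i + k * minc - 1L <= n) {
      motif <- chars[i:(i + k - 1L)]
      copies <- 1L
      while (i + (copies + 1L) * k - 1L <= n &&
             all(chars[(i + copies * k):(i + (copies + 1L) * k - 1L)] == motif)) {
        copies <- copies + 1L
      }
      if (copies >= minc && prim(motif)) {
        out[[length(out) + 1L]] <- c(max(1L, i - flank),
                                     min(n, i + copies * k - 1L + flank))
        i <- i + copies * k
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge
  merged <- list(m[1, ])
  for (r in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[r, 1] <= last[2] + 1) {
      merged[[length(merged)]] <- c(last[1], max(last[2], m[r, 2]))
    } else {
      merged[[length(merged) + 1L]] <- m[r, ]
    }
  }
  do.call(rbind, merged)
}

# Full per-site re-evaluation of the cascade predicates with plain loops.
oracle_cascade_survivors <- function(calls, seqs, masks, db, min_alt_reads = 3) {
  sites <- unique(calls[, c("chrom", "pos", "ref", "alt", "dp", "qd", "mq",
                            "mq_rank_sum", "read_pos_rank_sum")])
  bases <- c("A", "C", "G", "T")
  keys <- character(0)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (!(nchar(s$ref) == 1 && s$ref %in% bases && !grepl(",", s$alt) &&
          nchar(s$alt) == 1 && s$alt %in% bases && s$alt != s$ref)) next
    hrun <- oracle_hrun(seqs[[s$chrom]], s$pos, s$alt)
    if (!is.na(s$dp) && s$dp < 10) next
    if (hrun > 5) next
    if (!is.na(s$mq) && s$mq < 40) next
    if (!is.na(s$mq_rank_sum) && s$mq_rank_sum < -12.5) next
    if (!is.na(s$qd) && s$qd < 2) next
    if (!is.na(s$read_pos_rank_sum) && s$read_pos_rank_sum < -8) next
    own <- calls[calls$chrom == s$chrom & calls$pos == s$pos &
                   calls$ref == s$ref & calls$alt == s$alt &
                   !is.na(calls$sample_id), ]
    supported <- FALSE
    for (j in seq_len(nrow(own))) {
      gt <- own$gt[j]
      if (is.na(gt) || !grepl("[1-9]", gt)) next
      ad <- suppressWarnings(as.integer(strsplit(own$ad[j], ",")[[1]]))
      if (length(ad) >= 2 && !is.na(ad[2]) && ad[2] >= min_alt_reads) {
        supported <- TRUE
        break
      }
    }
    if (!supported) next
    in_any_mask <- FALSE
    for (m in masks) {
      if (oracle_point_in_mask(m, s$chrom, s$pos)) in_any_mask <- TRUE
    }
    if (in_any_mask) next
    hit <- db[db$chrom == s$chrom & db$pos == s$pos &
                db$ref == s$ref & db$alt == s$alt, ]
    if (nrow(hit) == 0) next
    keys <- c(keys, paste(s$chrom, s$pos, s$ref, s$alt, sep = ":"))
  }
  sort(keys)
}

oracle_qtl_pairs <- function(sites, qtls) {
  n <- 0L
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(qtls))) {
      if (sites$chrom[i] == qtls$chrom[j] &&
          sites$pos[i] >= qtls$start[j] && sites$pos[i] <= qtls$end[j]) {
        n <- n + 1L
      }
    }
  }
  n
}

# Exact hypergeometric upper tail via log-space combinatorics.
oracle_hyper_p <- function(N, K, n, k) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

gt_carries_alt <- function(gt) {
  !is.na(gt) & grepl("[1-9]", gt)
}

# Per-site loop evaluation of the common / breed-specific rules.
oracle_common_specific <- function(calls, panel, min_animals = 2) {
  breeds <- unique(panel$breed)
  sites <- unique(calls[, c("chrom", "pos", "ref", "alt")])
  commons <- list()
  for (b in breeds) {
    ids <- panel$sample_id[panel$breed == b]
    keys <- character(0)
    for (i in seq_len(nrow(sites))) {
      own <- calls[calls$chrom == sites$chrom[i] & calls$pos == sites$pos[i] &
                     calls$sample_id %in% ids, ]
      if (sum(gt_carries_alt(own$gt)) >= min_animals) {
        keys <- c(keys, paste(sites$chrom[i], sites$pos[i],
                              sites$ref[i], sites$alt[i], sep = ":"))
      }
    }
    commons[[b]] <- keys
  }
  specifics <- list()
  for (b in breeds) {
    other <- setdiff(breeds, b)
    other_ids <- panel$sample_id[panel$breed == other]
    keys <- character(0)
    for (key in commons[[b]]) {
      parts <- strsplit(key, ":")[[1]]
      own <- calls[calls$chrom == parts[1] & calls$pos == as.integer(parts[2]) &
                     calls$sample_id %in% other_ids, ]
      if (!any(gt_carries_alt(own$gt))) keys <- c(keys, key)
    }
    specifics[[b]] <- keys
  }
  list(common = commons, specific = specifics)
}
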