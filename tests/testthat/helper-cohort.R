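# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Moderate cohort for module tests: smaller than the acceptance cohort but
# exercising every planted class.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(
      seed = 42, n_specific_a = 20, n_specific_b = 20, n_shared = 40,
      n_artifacts_per_class = 5, n_missense = 5, n_synonymous = 3,
      n_stop_gained = 2, n_deg_overlap = 5
    )
    .fixtures$small <- generate_cohort(cfg)
  }
  .fixtures$small
}

small_cascade <- function() {
  if (is.null(.fixtures$small_cascade)) {
    co <- small_cohort()
    .fixtures$small_cascade <- run_cascade(
      co$calls, co$reference, co$annotation, co$known_db, masks = co$masks
    )
  }
  .fixtures$small_cascade
}

# The full-size cohort under the documented study-like conditions
# (2 x 100 kb, 4 + 4 samples, 50 + 50 specific, 100 shared, 10 artifacts per
# class), used by the end-to-end acceptance checks.
study_cohort <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- generate_cohort(sim_config(seed = 20260101 %% 10000))
  }
  .fixtures$study
}

study_cascade <- function() {
  if (is.null(.fixtures$study_cascade)) {
    co <- study_cohort()
    .fixtures$study_cascade <- run_cascade(
      co$calls, co$reference, co$annotation, co$known_db, masks = co$masks
    )
  }
  .fixtures$study_cascade
}

truth_sites <- function(cohort, classes) {
  cohort$truth[cohort$truth$class %in% classes, ]
}

key_of <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
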