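---
title: "Methods: stringent SNP filtering and breed-specific variant discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stringent SNP filtering and breed-specific variant discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailvar)
library(dplyr)
```

## The problem

SNPs called from RNA-seq alignments are contaminated by several error
modes that DNA-seq pipelines do not face at the same rate: spliced
alignment artifacts near exon–intron boundaries, apparent variants created
by overlapping antisense transcription, RNA editing, and polymerase
slippage in homopolymers and microsatellites. When the scientific question
is which variants *distinguish two diverged populations* — here fat-tailed
versus thin-tailed sheep breeds, four animals each — false positives are
especially damaging, because a site miscalled in only one breed
masquerades as a breed-specific variant. `tailvar` implements the
post-calling half of such a study: everything downstream of a per-sample
VCF.

## The filter cascade

`run_cascade()` applies five stages in a fixed order, and reports
per-stage survivor counts so the cascade is auditable:

1. *Biallelic SNP selection.* Multi-allelic records and indels are
   removed. Indels are out of scope throughout the package.
2. *Hard annotation filter.* A site is eliminated when total depth < 10,
   homopolymer run > 5, RMS mapping quality < 40, mapping-quality rank sum
   < −12.5, quality-by-depth < 2, or read-position rank sum < −8. All
   comparisons are strict, so boundary values (DP = 10, QD = 2.0, …)
   survive. A missing annotation cannot trigger its rule: "cannot
   evaluate" never becomes "eliminate", which keeps the cascade total over
   arbitrary VCFs and mirrors common hard-filter practice.
3. *Per-sample alternate-read support.* A sample's variant call is valid
   only with ≥ 3 alternate reads in its AD field; calls without AD are
   invalid. A site survives when at least one valid supported call
   remains; failing samples are set to missing genotype rather than
   removing the site for everyone, so one bad sample does not erase a
   variant that is well supported elsewhere. Whether the support rule
   should instead pool reads across samples is a genuinely open reading;
   the per-sample rule is the default and a `pooled` switch exposes the
   alternative without claiming equivalence.
4. *Context masks.* Three masks are recomputed from the reference and
   annotation (never trusted from INFO fields, so the cascade is
   reproducible on any VCF):
   - **SSR mask** — perfect tandem repeats of 1–6 bp motifs, extended by
     3 bp each side. The copy-number minima are the MISA community
     defaults (mono ≥ 10, di ≥ 6, tri–hexa ≥ 5) and are configurable,
     since the upstream convention only fixes the ± 3 flank. Motif
     primitivity (an (AT)n tract is not re-reported as (ATAT)n) prevents
     double counting; tracts are found left-to-right over full motif
     copies.
   - **Splice-junction mask** — the first and last 5 intronic bases of
     every intron, clipped for introns shorter than 10 bp.
   - **Bidirectional-transcription mask** — the intersection of the
     union of '+'-strand gene bodies with the union of '−'-strand gene
     bodies. How such regions were derived upstream (annotation overlap
     versus observed antisense expression) is not specified by the
     convention this follows; annotation overlap is implemented because it
     is deterministic and reference-only, and the alternative would
     require expression data this package does not consume. Same-strand
     overlap deliberately contributes nothing.
5. *Known-SNP intersection.* Restricting to database-known SNPs removes
   residual RNA-editing sites and other novelties at the cost of
   discarding genuinely novel variants; that trade-off is inherited from
   the study design this package supports. Matching requires allele
   identity, not just position — position-only matching would admit a
   different substitution as "known".

The homopolymer run of stage 2 is defined as the length of the maximal
single-base run containing the variant position *after substituting the
alternate base*: an alternate allele that extends an existing run is
exactly the error mode the annotation exists to flag. This definition is
deterministic, reference-only, and always ≥ 1.

## Breed comparison

A **common-SNP** of a breed is a surviving site whose alternate allele is
carried (het or hom-alt, with a valid genotype) by at least two animals of
that breed. Carrying the allele — rather than sharing the same genotype
class — is used for "common to at least two animals", the more natural
reading for four-animal panels.

A **breed-specific SNP** of breed X is a common-SNP of X at which every
genotyped animal of the other breed is homozygous for the allele X does
not segregate; operationally, homozygous reference at X's alternate
site. Two interpretive choices are made explicit:

- An animal of the other breed with no call at the site counts as
  homozygous reference (per-sample callers do not emit hom-ref records).
- A missing genotype does not veto specificity; `strict = TRUE` requires
  all other-breed animals to be positively genotyped.

These choices reproduce "segregating only in one breed" and make the two
specific sets provably disjoint and symmetric under breed relabelling
(both properties are tested).

Cohort statistics follow their usual definitions: Ts/Tv on distinct sites
(transitions A↔G, C↔T), het/hom-alt per sample, and windowed SNP density.
Undefined ratios (no transversions, no hom-alt calls) warn and return
`NA` rather than erroring, since they occur on legitimate small inputs.

## Genotype PCA

`genotype_pca()` uses the EIGENSTRAT/smartpca normalization: for a site
with dosages `g` over `n` genotyped samples,
`g' = (g − mu) / sqrt(p(1 − p))` with `mu` the observed mean and
`p = (1 + Σg)/(2 + 2n)` the shrunk allele-frequency estimate. Missing
dosages are imputed to the site mean *before* normalization (they then
contribute exactly zero), monomorphic sites are dropped, and the
sample-by-sample covariance is eigendecomposed. Mean imputation was chosen
for determinism; no missingness thresholds are applied because
cascade-filtered data is near-complete. Eigenvector signs are fixed by
making the largest-magnitude loading positive, so coordinates are
reproducible across linear-algebra backends; separation tests are written
sign-invariantly regardless.

## Consequence annotation

`classify_consequences()` emits one call per overlapping transcript and
`most_severe_consequence()` collapses them by a fixed severity order
(stop_gained > stop_lost > start_lost > missense > stop_retained >
synonymous > UTRs > intron > up/downstream > intergenic). Coding changes
are evaluated by locating the variant in spliced CDS coordinates
(reverse-complemented for '−'-strand transcripts), substituting the
transcript-strand allele into its codon, and translating both codons with
the standard genetic code. The up/downstream window defaults to 5,000 bp,
the convention of the widely-used effect predictors; it is configurable.
CDS records are assumed in-frame from their first base (phase handling for
partial CDS is out of scope). The term → impact mapping is total and
fixed: disruptive coding terms are HIGH, missense MODERATE, silent coding
LOW, everything non-coding MODIFIER; an `other` bucket keeps tabulation a
partition for terms outside the core set. Homology-based deleteriousness
(SIFT-style) is deliberately not reimplemented — it requires cross-species
protein alignments — and can be supplied as an external column.

## QTL colocalization

QTL intervals are 1-based with inclusive ends (the AnimalQTLdb
convention), converted once at load; duplicate QTL identifiers are kept
because overlapping QTL entries are real. A SNP inside several QTLs of one
trait counts once in that trait's distinct tally but once per QTL in the
pair tally — this dual counting is what reconciles "SNPs in QTL regions"
with "QTL positions" style reporting. `qtl_fraction()` reports a rounded
percentage while retaining full precision.

## Enrichment

Over-representation of SNP-bearing genes is the hypergeometric upper tail
`P(X ≥ k)` (equivalently one-sided Fisher), computed with `stats::phyper`,
with Benjamini–Hochberg FDR via `stats::p.adjust`. This is a local,
deterministic stand-in for web-service enrichment tools, which blend
several rank statistics; only adjusted p-value thresholds are mirrored
(FDR < 0.05 "significant"; p < 0.05 and FDR < 0.3 "suggestive"). The
background defaults to whatever universe the caller provides; for
SNP-gene enrichment the natural choices are "all annotated genes" or "all
genes carrying a tested SNP", and the choice is left explicit in the API
because it materially changes p-values.

## The synthetic cohort

The generator emulates the *design* of the motivating experiment — two
breeds, four animals each — at desk scale: by default two 100 kb
chromosomes, 16 genes with valid ORFs (2–5 exons, patched start/stop
codons, one antisense overlapping gene pair per chromosome), 50 + 50
breed-specific sites, 100 shared sites, 10 sites per filter-violating
artifact class, and a known-SNP database covering ≈ 94% of the non-artifact
sites (the novel-site count is derived from `known_db_fraction`). Site
INFO values are drawn from envelopes that clear the hard-filter cut-offs
with margin (DP 15–60, QD 5–30, MQ 50–60, rank sums ± 2) so that artifact
classes are the only filter casualties; each artifact class violates
exactly one rule (DP = 9 for low depth, alternate AD = 2 for low support,
two ALT alleles, residence in exactly one mask, or adjacency to a planted
homopolymer run so the substituted run exceeds 5). A configurable slice of
the clean sites is engineered into CDS codons with chosen consequences
(10 missense, 5 synonymous, 3 stop-gained by default) so consequence
tabulation has a planted answer; remaining clean sites are placed in
non-CDS gene space plus a few up/downstream positions. Everything is
driven by one seed and regenerating with the same configuration is
byte-identical.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: read-level noise (alignment and
duplicate structure, base-quality miscalibration), linkage disequilibrium
and realistic allele-frequency spectra, RNA editing, expression-dependent
coverage, indels, and partially-overlapping error modes (each planted
artifact violates exactly one rule, whereas real artifacts violate
several at once). The planted-truth results certify the *logic* of the
cascade and comparison rules, not their field sensitivity/specificity.

## Numerical and coordinate choices

- All in-memory intervals are 1-based closed, the R/Bioconductor
  convention, implemented on GenomicRanges/IRanges; BED export converts
  to 0-based half-open at the boundary. VCF/GTF I/O is 1-based by format.
- Point-in-mask lookups go through interval trees (logarithmic), and are
  tested for exact agreement with a linear scan.
- The hypergeometric tail is computed in log space by `phyper`; tests
  require 1e-12 relative agreement with an exact `lchoose` summation.
- Ties in most-severe consequence collapse are broken by transcript id;
  input order never affects any result (permutation-invariance is
  tested for the cascade, BH adjustment and QTL counts).
- Degenerate inputs (no transversions, no hom-alt calls, zero SNPs,
  all-monomorphic dosage matrices) signal with a warning or a typed error
  rather than producing misleading numbers.

## Problem sizes

The bundled test suite and the acceptance script use the default
generator conditions (2 × 100 kb, 4 + 4 samples, ~290 planted sites) and
a smaller variant for module tests; these sizes exercise every code path,
keep the whole suite under a couple of minutes on one CPU, and were chosen
as the package's standing validation conditions. Oracle-equivalence
checks run on fixtures up to ~1,000 elements, where brute force is
feasible and exact.

## Known limitations

- Consequence annotation assumes one in-frame CDS per transcript and does
  not model splice-donor/acceptor disruption, multi-nucleotide effects or
  selenocysteine recoding.
- The breed-specific rule is defined for exactly two panels; multi-breed
  generalisations would need a different divergence criterion.
- No selection statistics (FST, XP-EHH), phasing or kinship — the package
  reports divergent segregation, not evidence of selection.
- The enrichment stand-in is the plain hypergeometric tail; results are
  not numerically comparable to web services that combine rank statistics.
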