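# tailvar

Post-calling analysis of RNA-seq derived SNPs in two-breed designs, built
around the question that motivated it: which genetic variants distinguish
fat-tailed from thin-tailed sheep? Given per-sample variant calls from an
RNA-seq cohort (e.g. four Lori-Bakhtiari and four Zel animals), `tailvar`
applies a stringent confidence cascade, derives common and breed-specific
SNPs, annotates their functional consequences, colocalizes them with
fatness QTL intervals, and summarises the cohort (Ts/Tv, het/hom, SNP
density, genotype PCA) — plus hypergeometric gene-set enrichment of the
affected genes. It is aimed at researchers reproducing or extending
RNA-seq-based variant discovery between diverged livestock populations.

Because RNA-seq variant calls are error-prone (splicing artifacts,
antisense transcription, RNA editing, homopolymer slippage), the package
centres on a five-stage filter cascade applied to called sites:

1. **Biallelic SNP selection** — keep sites with exactly one single-base
   non-reference allele (indels and multi-allelic records are dropped).
2. **Hard annotation filter** — eliminate sites with
   `DP < 10`, `HRun > 5`, `MQ < 40`, `MQRankSum < -12.5`, `QD < 2` or
   `ReadPosRankSum < -8` (strict inequalities; missing annotations cannot
   eliminate). The homopolymer run is recomputed from the reference as the
   run of the alternate base through the substituted position.
3. **Per-sample read support** — a sample's variant call is valid only with
   ≥ 3 alternate-allele reads (AD field); a site survives if at least one
   valid supported call remains.
4. **Context masks** — remove sites inside (a) bidirectional-transcription
   regions (opposite-strand gene-body overlap), (b) simple sequence repeats
   ± 3 bases (MISA-style minima: mono ≥ 10, di ≥ 6, tri–hexa ≥ 5 copies),
   and (c) splice-junction flanks (first/last 5 intronic bases).
5. **Known-SNP intersection** — keep sites whose (chrom, pos, ref, alt) key
   is present in a known-SNP database; matching requires allele identity.

Downstream, a *common-SNP* of a breed is a site whose alternate allele is
carried by ≥ 2 animals of that breed, and a *breed-specific SNP* is a
common-SNP where every genotyped animal of the other breed is homozygous
for the allele the focal breed does not segregate. Genotype PCA uses the
EIGENSTRAT/smartpca normalization `g' = (g - mu) / sqrt(p(1-p))` with the
shrunk frequency `p = (1 + sum g) / (2 + 2n)`. Enrichment is the
hypergeometric upper tail `P(X >= k)` with Benjamini–Hochberg FDR.

A fully seeded synthetic-cohort generator (`sim_config()`,
`generate_cohort()`) builds a two-breed toy cohort — reference, gene
models with valid ORFs, per-sample VCFs, known-SNP DB, QTLs, gene sets,
DEG table — with a truth table that plants breed-specific, shared and
one artifact class per filter rule, so every stage can be validated
against a planted answer.

## Worked example

```r
library(tailvar)
library(dplyr)

cohort  <- generate_cohort(sim_config(seed = 1))
cascade <- run_cascade(cohort$calls, cohort$reference, cohort$annotation,
                       cohort$known_db, masks = cohort$masks)
cascade
#> SNP confidence cascade
#> # A tibble: 6 × 3
#>   stage         survivors removed
#>   <chr>             <int>   <int>
#> 1 input               291       0
#> 2 biallelic_snp       281      10
#> 3 hard_filter         261      20
#> 4 alt_support         251      10
#> 5 region_mask         221      30
#> 6 known_snp           208      13

specific <- breed_specific_snps(cascade$calls, cohort$panel)
sapply(specific, nrow)
#> breedA breedB
#>     50     50

glance(genotype_pca(cascade$calls))
#> # A tibble: 1 × 4
#>   n_samples n_sites var_PC1 var_PC2
#>       <int>   <int>   <dbl>   <dbl>
#> 1         8     207   0.387   0.128

glance(colocalize(bind_rows(specific), cohort$qtls))
#> # A tibble: 1 × 5
#>   n_sites n_distinct_snps n_pairs fraction percent
#>     <int>           <int>   <int>    <dbl>   <dbl>
#> 1     100              80     131      0.8      80
```

The cascade table reads top to bottom: 291 planted sites enter; the 10
multi-allelic records fall at stage 1; 20 sites violating the annotation
cut-offs (low depth, long homopolymer run) fall at stage 2; 10
weakly-supported sites at stage 3; 30 mask-resident sites at stage 4; and
the 13 sites absent from the known-SNP database at stage 5, leaving the
208 planted clean sites. The two 50-SNP breed-specific sets are recovered
exactly, PC1 of the genotype PCA separates the two breeds, and 80 of the
100 breed-specific SNPs fall inside the planted QTL intervals.

Result objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` / `plot_*()` views. `inst/scripts/tailvar.R` wraps the same
functions as a small CLI (`simulate`, `masks`, `filter`, `compare`,
`annotate`, `qtl`, `enrich`) for file-based use.

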