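# micropopgen

Within-species population genetics from metagenomic read mappings.

Abundant environmental bacteria — the dominant taxa of soils, sediments
and freshwater — are mostly uncultivated, so their evolution cannot be
studied from isolate collections. Shotgun metagenomes offer a way in:
once reads from many samples are mapped against one representative genome
per species, each mapped read pair is a short genomic sequence from
(almost certainly) a distinct cell of the population. `micropopgen`
turns those mappings into population-genetic inference for ecologists and
microbial population geneticists: how diverse is each population, how
structured is it in space, how much does it recombine, and which genes
show evidence of recent gene-specific selective sweeps.

## What it computes

Starting from per-sample SAM/BAM alignments, a reference FASTA, gene
coordinates (GFF3) and a sample metadata table:

- **Read-pair filtering** — a pair is kept iff both mates map to the same
  contig within a 1500 bp end-to-end span, the combined pair identity
  `1 − (NM₁+NM₂)/(L₁+L₂)` is ≥ 0.96, and at least one mate has MAPQ > 1.
  Genome–sample combinations require ≥ 50% breadth at ≥ 5× coverage.
- **Nucleotide diversity** — per site, `π = 1 − (f_A² + f_C² + f_G² + f_T²)`
  from Q ≥ 30 bases; per gene, the mean over positions covered ≥ 5×;
  pooled across nested spatial scales (sample → replicate → plot → block
  → meadow) by summing counts and recomputing, never averaging π.
- **SNP calling** — a position is a SNP iff its leading minor allele
  count exceeds the sequencing-error null threshold (smallest k with
  `P(Binom(cov, ε/3) ≥ k) ≤ 10⁻⁶`, ε = 10⁻⁴) and its frequency is
  ≥ 5%; effects (synonymous / nonsynonymous / intergenic) by codon
  substitution and translation.
- **Linkage disequilibrium** — r² and D′ from 2×2 allele co-observation
  tables over read pairs physically spanning two SNPs (≥ 30 pairs, Q ≥ 30
  bases), decay with distance, N/S stratification, and the fraction of
  site pairs showing all four haplotypes (D′ < 1 — direct evidence of
  recombination).
- **Differentiation scan** — per-gene Hudson F_ST between blocks as a
  ratio of averaged numerators `(p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)`
  to averaged denominators `p₁(1−p₂) + p₂(1−p₁)` (sites ≥ 20× per block;
  genes with aberrant coverage excluded); a moving 5-gene window flags
  loci above mean + 2.5 SD; candidate sweeps are confirmed only with a
  significant increase in linkage (one-sided Wilcoxon) *and* a
  significant change in per-block diversity (Welch t), both BH-corrected.
- **Synthetic data** — a generator producing aligned paired reads
  (SAM/FASTA/GFF3/TSV) from a two-founder crossover haplotype model with
  Balding–Nichols block structure, implantable sweeps, F_ST-only decoy
  loci, and complete truth tables.

See `vignettes/methods.Rmd` for the full model description, parameter
semantics and design choices.

## Worked example

Simulate a two-block population, run the full pipeline, and summarize:

```r
library(micropopgen)

cfg <- run_config("demo_out", seed = 7,
                  simulate = list(n_samples = 6L, coverage_per_sample = 15))
res <- run_all(cfg)
#> run_all: 6618/6693 pairs passed filters; 299 SNPs; 446 linkage records;
#>          0 candidate loci; 0 confirmed sweeps

res$snps[1:3, c("contig", "pos", "major", "minor", "minor_count",
                "coverage", "freq", "effect")]
#>      contig   pos  major  minor minor_count coverage      freq        effect
#> 1: contig_1    84      C      T           7       21 0.3333333 nonsynonymous
#> 2: contig_1    85      G      T           7       22 0.3181818 nonsynonymous
#> 3: contig_1   123      C      G           6       28 0.2142857 nonsynonymous

s <- population_summaries(res$snps, sum(nchar(res$ref$contigs)))
sprintf("SNPs/Mb: %.0f   N:S = %.2f", s$snps_per_mb, s$ns_ratio)
#> "SNPs/Mb: 9967   N:S = 3.73"
four_haplotype_fraction(res$linkage)
#> 0.061
mean(res$gene_fst$fst, na.rm = TRUE)
#> 0.0731
```

Reading the numbers: 6618 of 6693 simulated pairs pass the filters (the
remainder are injected decoys violating one filter each). 299 of the 300
simulated segregating sites are recovered as SNPs at the meadow-wide
pooled coverage. The four-haplotype fraction of 6% says that at this
simulated recombination rate only a small minority of co-observed SNP
pairs show direct evidence of recombination, and the mean per-gene F_ST
of 0.07 reflects the simulated block differentiation (target 0.1, eroded
slightly by within-block sampling at modest coverage). No sweep was
implanted, and none is confirmed.

Everything is also available stage-by-stage (`filter_pairs()`,
`build_pileup()`, `pool_by_level()`, `gene_diversity()`, `call_snps()`,
`extract_pair_haplotypes()`, `linkage_stats()`, `gene_fst()`,
`window_scan()`, `confirm_sweeps()`), and a thin command-line wrapper is
shipped at `inst/scripts/micropopgen.R` (`simulate`, `run-all`).

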