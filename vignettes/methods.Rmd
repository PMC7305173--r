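---
title: "Methods: within-species population genetics from metagenomic read mappings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-species population genetics from metagenomic read mappings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropopgen)
```

# Overview

`micropopgen` measures genetic variation *within* microbial species from
shotgun metagenomes. The unit of observation is a mapped read pair: because
environmental populations contain orders of magnitude more cells than are
ever sequenced, each read pair can be treated as a short genomic sequence
from a distinct cell. From per-sample alignments against one representative
genome per species, the package derives:

1. filtered read pairs (span, combined identity, MAPQ rules);
2. base-count pileups and per-site / per-gene nucleotide diversity at
   nested pooling scales (sample, replicate, plot, block, meadow);
3. SNPs called against a sequencing-error null model with a minor allele
   frequency cutoff;
4. linkage disequilibrium (r², D′) between SNP pairs physically
   co-observed on read pairs;
5. per-gene Hudson F_ST between geographic blocks, a moving-window scan
   for highly differentiated loci, and confirmation tests for
   gene-specific selective sweeps.

A synthetic-data generator produces aligned paired reads with complete
truth tables, so every stage is validated against known population
parameters without any external data.

# Statistical model and estimators

## Nucleotide diversity

At a genome position with Q30-masked base counts $(A, C, G, T)$ and
coverage $n = A+C+G+T$, nucleotide diversity is

$$\pi = 1 - (f_A^2 + f_C^2 + f_G^2 + f_T^2),$$

the probability that two reads drawn at the position differ. Per-gene
$\pi$ is the unweighted mean over positions inside the gene with coverage
$\ge$ 5, monomorphic positions included as zeros; positions below the
depth threshold are excluded from both numerator and denominator. Whether
the per-gene average should weight sites by coverage is a genuinely open
choice; equal weighting was selected because it keeps the per-gene value
insensitive to coverage ripples within the gene.

Pooling across samples always sums base counts first and recomputes $\pi$
on the pooled counts — never averages per-sample $\pi$. The distinction
matters: two samples fixed for different alleles each have $\pi = 0$ but
a pooled $\pi$ of 0.5. By Jensen's inequality pooled $\pi$ is always at
least the coverage-weighted mean of the per-sample values, a property the
test suite checks on random fixtures.

The plug-in estimator is biased downward at finite coverage:
$E[\hat\pi] = \frac{n-1}{n}\pi$ under multinomial (with-replacement)
sampling at depth $n$. `subsample_coverage()` quantifies this on real
pileups, by default drawing without replacement (a hypergeometric
subsample of the observed bases, matching what subsampling actual reads
would do); the with-replacement mode exists so the exact
$\tfrac{n-1}{n}$ identity can be verified against enumeration, which the
acceptance suite does at $n \in \{2, 5\}$. The bias is negligible above
roughly 50× and is one reason diversity statistics are computed on pooled
(hundreds-fold) coverage.

## Read-pair filters

A pair passes iff (i) both mates map to the same contig with an
end-to-end span (leftmost to rightmost aligned base) of at most 1500 bp,
(ii) the combined identity $1 - (\mathrm{NM}_1 + \mathrm{NM}_2) /
(L_1 + L_2) \ge 0.96$ (edit distance over aligned length summed across
mates; soft-clipped bases excluded from the denominator), and (iii) at
least one mate has MAPQ strictly greater than 1. Failures are attributed
to the first failed rule in that order. Only primary alignments are
considered. The MAPQ rule's meaning depends on the mapping index: against
a multi-genome competitive index it selects uniquely-best pairs, which a
single-genome synthetic index cannot fully reproduce; the filter is
implemented as stated and index construction is out of scope.

A genome–sample combination enters the analysis only if at least 50% of
the genome is covered at $\ge$ 5× by passing pairs.

## SNP calling

SNPs are called once on the meadow-wide pooled pileup. The null model
asks how many counts of a *specific* alternate base could arise from
sequencing error alone: at coverage $c$ the threshold is the smallest
$k$ with $P(X \ge k) \le \alpha$, $X \sim \mathrm{Binomial}(c,
\varepsilon/3)$, with $\varepsilon = 10^{-4}$ and $\alpha = 10^{-6}$ by
default. The division by 3 reflects that the total error rate spreads
uniformly over the three alternative bases; a `split_alt = FALSE` switch
tests against the undivided rate for a more conservative threshold. The
default mode evaluates the exact binomial tail; a `simulated` mode
reproduces the threshold by resampling and is validated against the
analytic tail. A position is a SNP iff its leading non-major allele meets
the count threshold *and* has frequency $\ge$ 0.05 (inclusive). At the
pooled coverages this pipeline targets (hundreds-fold), the MAF cutoff
alone is already far more stringent than the error model.

Two ambiguities in the stated error-model are resolved as configuration:
the quoted error rate of 0.01% does not equal the Phred-30 error
probability (0.1%); $10^{-4}$ is the default and $\varepsilon$ is a
parameter. Similarly "frequency above 5%" versus "minimum allele
frequency of 5%" is resolved as inclusive $\ge 0.05$.

Each SNP's coding effect is found by substituting the minor allele into
its reference codon (reverse-complemented for minus-strand genes) and
translating with the standard code; the test suite cross-checks every
classification against translation of the whole mutated gene.

## Linkage disequilibrium

Haplotypes come only from physical co-observation: two SNP sites
contribute a 2×2 count table over the read pairs that cover both with
Q ≥ 30 bases, using the meadow-wide major/minor alleles (other bases are
discarded rather than lumped). Site pairs with fewer than 30 spanning
pairs are dropped. With $p_{AB} = n_{AB}/n$, $p_A$, $p_B$ the marginal
major-allele frequencies:

$$D = p_{AB} - p_A p_B, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad
  D' = \frac{|D|}{D_{\max}},$$

where $D_{\max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D > 0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ for $D < 0$; $D = 0$ yields $D' = 0$ by
convention. On every 2×2 table, $r^2 \le D'^2$ and $D' < 1$ exactly when
all four haplotype combinations are observed — the property that makes
the four-haplotype fraction a recombination detector; the acceptance
suite verifies both identities exhaustively over all tables with
$n \le 12$. Distances are between site coordinates, so the assessable
range is bounded by read geometry (about 0.8–1 kb for 200 bp mates with
a ~380 bp gap). Per-genome linkage summaries are unweighted means over
retained site pairs; decay curves weight distance bins by spanning-pair
counts. Where a single per-gene "linkage" number is needed (sweep
confirmation), mean $r^2$ is the default statistic and D′ is also
computed, since the choice between them is not determined by the method's
definition.

## Hudson F_ST and the sweep scan

For two blocks with allele frequencies $p_1, p_2$ and read coverages
$n_1, n_2$ at a site:

$$\text{num} = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1}
  - \frac{p_2(1-p_2)}{n_2 - 1}, \qquad
  \text{den} = p_1(1-p_2) + p_2(1-p_1).$$

Read coverage serves as the sample size in the finite-sample correction
because pooled read pairs stand in for cells. Sites need $\ge$ 20×
coverage in both blocks and must segregate across the pooled block pair.
Per-gene F_ST is the *ratio of averages* — summed numerators over summed
denominators — which is robust to low-information sites in a way the
average of per-site ratios is not. Genes whose mean coverage in either
block falls outside mean ± 2 SD (across genes, per block) are excluded
as likely copy-number or mapping artifacts.

The scan slides a 5-gene window (step one gene, ordered by coordinate,
missing genes skipped, windows never spanning contigs). A candidate
locus is a maximal run of genes covered by at least one window whose
mean exceeds the genomic mean + 2.5 SD of per-gene F_ST: successful
windows extend the locus for as long as the moving mean stays above the
cutoff, and overlapping windows merge. Extension was deliberately tied
to the moving window rather than to the cumulative locus mean — under a
cumulative rule the number of background genes a strong core can drag
into its locus grows linearly with the core's F_ST, which both inflates
locus lengths and dilutes the confirmation tests. Even so, a locus can
carry up to window − 1 unswept flank genes on each side, which is the
main cost in power for the per-gene diversity test on short partial
sweeps.

Candidate loci are then confirmed with two tests: a one-sided two-sample
Wilcoxon rank-sum test that per-site-pair linkage inside the locus
exceeds the genomic background (a sweep drags a haplotype up in
frequency, so linkage must *increase*), and a two-sided Welch t-test of
per-gene $\pi$ inside versus outside the locus, run per block (the
diversity change may go either way a priori; the direction is reported).
Linkage p-values are Benjamini–Hochberg corrected across loci, diversity
p-values across loci × blocks — the two test families are corrected
separately, mirroring how the two kinds of evidence are interpreted. A
locus is confirmed iff both corrected tests pass at $\alpha = 0.05$
(diversity in at least one block). High-F_ST loci produced by coverage
or reference artifacts carry neither signal and are rejected — the
package's own negative controls (below) exercise exactly this case.

# The synthetic-data generator

The generator works backwards from the statistics: it must produce data
whose truth values are computable exactly, not a realistic coalescent.

**Population model.** Segregating sites are biallelic with target minor
allele frequencies drawn from Uniform(0.05, 0.5) by default (the MAF
regime the SNP caller operates in). Haplotypes descend from two founder
lineages mixed by crossovers: each haplotype is a Markov walk along the
ordered sites whose lineage state persists between adjacent sites and is
resampled with probability $\rho_{\mathrm{sim}}/(m-1)$ per interval, so
$\rho_{\mathrm{sim}}$ is the expected number of crossovers per haplotype.
$\rho_{\mathrm{sim}} = 0$ gives a strictly two-clone population (all
pairs fully linked, $r^2 = 1$); very large values give independent
per-site draws (linkage equilibrium). In the clonal limit all sites
share the founder mixture frequency — as in a real two-clone population —
while in the recombining limit every site attains its own target
frequency. This is deliberately simpler than a coalescent: it dials
linkage from clonal to free with one parameter and keeps every truth
value computable from the realized haplotype matrix.

**Blocks.** Geographic differentiation uses the Balding–Nichols model:
block frequencies are Beta-distributed around each site's global
frequency with parameter $F$ equal to the target F_ST, so the expected
Hudson estimate across many sites equals the target. The acceptance
suite verifies calibration to ±0.03 at targets 0, 0.1 and 0.3 (5000
sites, 100× per block, 10 seeds).

**Sweeps and decoys.** `implant_sweep()` converts each haplotype of one
block, with probability equal to the sweep strength, to the block-major
allele at every site of a contiguous gene run — diversity collapses,
F_ST rises, within-locus linkage rises, exactly the triple signature the
scan confirms. `implant_fst_decoy()` swaps the allele labels of one
block at a locus: F_ST inflates but per-block diversity is exactly
unchanged ($p(1-p)$ is symmetric) and linkage statistics are invariant
under relabeling, so confirmation must reject it. One caveat discovered
during validation: pooling two blocks whose frequencies differ creates
mixture LD, so decoys *can* show elevated pooled linkage; their rejection
rests on the diversity test, which is precisely why confirmation demands
both signals.

**Reads.** Pairs are emitted pre-aligned (coordinates known by
construction); running an aligner would add nondeterminism without
exercising any of the statistics. Defaults mirror the sequencing design
the pipeline targets: 200 bp mates (2 × 250 bp libraries quality-trimmed
to ≤ 200 bp), mate gaps from a truncated normal with median 383 bp capped
so the template span stays within the 1500 bp filter, ~10–25× per-sample
coverage pooled to hundreds-fold, substitution errors at $10^{-4}$ per
base uniformly over the three alternatives, and two-level qualities
(Q37 with 2% of bases at Q20) so the Phred-30 mask has something to
remove. A small decoy fraction (0.5–1%) of pairs violates one filter
each (low identity, low MAPQ, oversized span) so the filters are
exercised. Alignments round-trip through coordinate-sorted SAM with NM
tags via standard htslib-based readers.

**What the generator does not emulate:** coalescent genealogies, indels
and structural variation, cross-species read mixtures beyond the decoy
pairs, GC or positional error profiles, and full base-quality
distributions. Passing tests therefore demonstrate estimator
correctness and calibration under a controlled population model — not
robustness to every artifact of real soil metagenomes.

# Numerical and design choices

- **Coordinates** are 0-based half-open internally; every emitted
  TSV/GFF/SAM uses its standard's 1-based convention.
- **Q30 masking** is applied to the pileups used for *all* statistics.
  Restricting the mask to SNP and linkage analyses only (leaving raw
  counts for diversity) would require two parallel pileups that can
  disagree; a single masked pileup was chosen, controlled by
  `min_baseq`.
- **Boundary conventions:** identity ≥ 0.96 (inclusive), MAPQ > 1
  (strict), breadth ≥ 0.5 (inclusive), MAF ≥ 0.05 (inclusive), at least
  30 spanning pairs (inclusive), diversity outliers strictly greater
  than mean + 2.5 SD.
- **Degenerate inputs:** zero-coverage positions are undefined for
  $\pi$ and skipped; genes with no qualifying position are flagged
  missing rather than zero-filled (zero-filling would bias the scan's
  genomic SD); monomorphic 2×2 tables are dropped; zero-variance t-tests
  report p = 1 with a flag; loci without linkage records are
  unconfirmable and reported with the reason.
- **Determinism:** every stochastic step takes a seed; identical
  configuration and seed produce byte-identical artifacts, which the
  test suite asserts via file checksums.

# Problem sizes used in the packaged checks

The packaged test and acceptance fixtures run at sizes chosen so each
statistical guarantee is measurable with margin: the SNP null model on
$10^6$ monomorphic sites at 300×; linkage identities exhaustively over
all 2×2 tables with $n \le 12$; F_ST calibration on 5000 sites × 100×
per block × 10 seeds per target; the sweep scan on a 500-gene genome
with two implanted sweeps (strengths 1.0 and 0.9), two allele-swap
decoys, and 20 null tracks; and the end-to-end pipeline on a 30–110 kb
genome with 6–10 samples at 15–30× each. These were fixed from the
statistical requirements before results were inspected and are the
package's reference conditions.

# Known limitations

- The two-founder crossover model cannot represent deep population
  structure (more than two clades) or gene-specific recombination rate
  variation.
- With a single-genome index, MAPQ semantics differ from competitive
  multi-genome mapping; the MAPQ filter is exercised by decoys rather
  than by genuine multi-mapping.
- The per-gene linkage statistic used in sweep confirmation (mean r²)
  is one of several defensible choices; D′ is computed alongside.
- The recombination-to-mutation rate (γ/μ) estimation that complements
  these analyses in the field is intentionally out of scope, as are
  assembly, binning, gene prediction and annotation: gene coordinates
  and category labels are inputs.
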