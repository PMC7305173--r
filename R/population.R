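#' Generate a segregating-site haplotype pool on a reference
#'
#' Creates biallelic segregating sites along the genome and a pool of
#' haplotypes built from two founder lineages mixed by random crossovers.
#' Each haplotype is a Markov walk along the ordered sites: the lineage
#' state persists between adjacent sites and is resampled (a crossover) with
#' probability `rho_sim / (n_sites - 1)` per interval, so `rho_sim` is the
#' expected number of crossovers per haplotype. `rho_sim = 0` yields a
#' strictly two-clone, fully linked population; very large `rho_sim` yields
#' independent per-site draws (linkage equilibrium). When a crossover occurs
#' at site i the state is redrawn Bernoulli(p_i), so in the freely
#' recombining limit every site attains its own target minor-allele
#' frequency, while in the clonal limit all sites share the founder mixture
#' frequency -- as in a real two-clone population.
#'
#' @param ref A `ref_genome`.
#' @param n_sites Number of segregating sites to place (uniformly at random
#'   over genome positions, without replacement).
#' @param maf_distribution A function `n -> numeric` drawing target derived
#'   allele frequencies in (0, 1); default Uniform(0.05, 0.5), mirroring a
#'   5\% minimum allele frequency regime.
#' @param rho_sim Expected crossovers per haplotype draw (>= 0).
#' @param n_haplotypes Haplotypes per population block (>= 2).
#' @param seed Integer seed.
#'
#' @return An object of class `haplotype_pool`: list with `sites`
#'   (data.table: site_id, contig, pos 0-based, ref_base, alt_base, freq),
#'   `blocks` (character vector, initially `"meadow"`), `block_freq`
#'   (blocks x sites matrix of derived-allele frequencies used for
#'   generation), `haplotypes` (per-block binary matrix, haplotype x site;
#'   1 = derived), `rho_sim`, `n_haplotypes`, and `sweeps` (truth table of
#'   implanted sweeps, initially empty).
#' @export
make_population <- function(ref, n_sites,
                            maf_distribution = function(n) runif(n, 0.05, 0.5),
                            rho_sim = 5, n_haplotypes = 100, seed = 1) {
  stopifnot(inherits(ref, "ref_genome"), n_haplotypes >= 2, rho_sim >= 0)
  set.seed(seed)
  clen <- nchar(ref$contigs)
  total <- sum(clen)
  if (n_sites > total) {
    stop(sprintf("n_sites (%d) exceeds genome length (%d)", n_sites, total))
  }
  # sample global positions, map to (contig, pos)
  gpos <- sort(sample.int(total, n_sites))
  offsets <- cumsum(c(0L, clen[-length(clen)]))
  ci <- findInterval(gpos - 1L, offsets)
  pos <- gpos - 1L - offsets[ci]
  contig <- names(clen)[ci]
  ref_base <- substring(ref$contigs[contig], pos + 1L, pos + 1L)
  bases <- c("A", "C", "G", "T")
  alt_base <- vapply(ref_base, function(b) sample(setdiff(bases, b), 1L),
                     character(1), USE.NAMES = FALSE)
  freq <- maf_distribution(n_sites)
  stopifnot(all(freq > 0 & freq < 1))
  sites <- data.table(site_id = seq_len(n_sites), contig = contig,
                      pos = as.integer(pos), ref_base = ref_base,
                      alt_base = alt_base, freq = freq)

  haps <- gen_haplotypes(n_haplotypes, freq, rho_sim)
  structure(list(
    sites = sites,
    blocks = "meadow",
    block_freq = matrix(freq, nrow = 1,
                        dimnames = list("meadow", NULL)),
    haplotypes = list(meadow = haps),
    rho_sim = rho_sim,
    n_haplotypes = n_haplotypes,
    sweeps = data.table(block = character(), gene_ids = character(),
                        strength = numeric(), n_sites = integer())
  ), class = "haplotype_pool")
}

# Markov two-lineage haplotype draws: n haplotypes over sites with target
# derived frequencies `freq`; crossover probability per interval derived
# from rho (expected crossovers per haplotype).
gen_haplotypes <- function(n, freq, rho) {
  m <- length(freq)
  out <- matrix(0L, nrow = n, ncol = m)
  if (m == 0L) return(out)
  state <- as.integer(runif(n) < freq[1])
  out[, 1] <- state
  if (m == 1L) return(out)
  cx_p <- min(1, rho / (m - 1))
  for (j in 2:m) {
    cx <- runif(n) < cx_p
    if (any(cx)) state[cx] <- as.integer(runif(sum(cx)) < freq[j])
    out[, j] <- state
  }
  out
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf(
    "haplotype_pool: %d sites, %d block(s) [%s], %d haplotypes/block, rho_sim=%g, %d sweep(s)\n",
    nrow(x$sites), length(x$blocks), paste(x$blocks, collapse = ","),
    x$n_haplotypes, x$rho_sim, nrow(x$sweeps)))
  invisible(x)
}

#' Differentiate a population into geographic blocks
#'
#' Splits the pool into `n_blocks` subpopulations whose per-site allele
#' frequencies are drawn from a Balding-Nichols distribution around each
#' site's global frequency: p_b ~ Beta(p (1-F)/F, (1-p)(1-F)/F) with
#' F = `fst_target`. Haplotypes are regenerated per block with the same
#' crossover process, so the expected Hudson F_ST between blocks across many
#' sites approximates `fst_target`. `fst_target = 0` copies the global
#' frequencies into every block.
#'
#' @param pool A `haplotype_pool` (any prior block structure is replaced).
#' @param n_blocks Number of blocks (>= 2).
#' @param fst_target Target differentiation, in [0, 1).
#' @param seed Integer seed.
#' @param block_ids Optional block names; default `B1..Bn`.
#' @return A new `haplotype_pool` with per-block frequencies and haplotypes.
#' @export
apply_block_structure <- function(pool, n_blocks, fst_target, seed,
                                  block_ids = sprintf("B%d", seq_len(n_blocks))) {
  stopifnot(inherits(pool, "haplotype_pool"),
            n_blocks >= 2, fst_target >= 0, fst_target < 1)
  set.seed(seed)
  p <- pool$sites$freq
  m <- length(p)
  bf <- matrix(NA_real_, nrow = n_blocks, ncol = m,
               dimnames = list(block_ids, NULL))
  for (b in seq_len(n_blocks)) {
    if (fst_target == 0) {
      bf[b, ] <- p
    } else {
      k <- (1 - fst_target) / fst_target
      bf[b, ] <- rbeta(m, p * k, (1 - p) * k)
    }
  }
  haps <- lapply(seq_len(n_blocks), function(b) {
    gen_haplotypes(pool$n_haplotypes, bf[b, ], pool$rho_sim)
  })
  names(haps) <- block_ids
  pool$blocks <- block_ids
  pool$block_freq <- bf
  pool$haplotypes <- haps
  pool
}

# sites (row indices into pool$sites) falling inside a set of genes
sites_in_genes <- function(pool, ref, gene_ids) {
  g <- ref$genes[ref$genes$gene_id %in% gene_ids, ]
  s <- pool$sites
  idx <- integer(0)
  for (i in seq_len(nrow(g))) {
    idx <- c(idx, which(s$contig == g$contig[i] &
                          s$pos >= g$start[i] & s$pos < g$end[i]))
  }
  sort(unique(idx))
}

#' Implant a gene-specific selective sweep into one block
#'
#' Within a contiguous run of genes, each haplotype of the designated block
#' is converted, with probability `sweep_strength`, to carry the block-major
#' allele at every segregating site of the locus. This emulates a local
#' haplotype rising toward fixation: nucleotide diversity drops in the swept
#' block, allele frequencies diverge from the other blocks (raising F_ST),
#' and within-locus linkage rises because the swept fraction is clonal.
#' `sweep_strength = 1` leaves the locus monomorphic in the swept block;
#' `sweep_strength = 0` is the identity.
#'
#' @param pool A `haplotype_pool` with block structure.
#' @param ref The `ref_genome` the pool was built on.
#' @param gene_ids Contiguous run of at least 5 gene ids (the sweep-scan
#'   window size) on one contig, in genome order.
#' @param block_id Block receiving the sweep.
#' @param sweep_strength Fraction of the block's haplotypes converted, in
#'   [0, 1].
#' @return The modified pool; the sweep is recorded in `pool$sweeps`.
#' @export
implant_sweep <- function(pool, ref, gene_ids, block_id, sweep_strength) {
  stopifnot(inherits(pool, "haplotype_pool"),
            block_id %in% pool$blocks,
            sweep_strength >= 0, sweep_strength <= 1)
  check_contiguous_genes(ref, gene_ids, min_run = 5L)
  if (sweep_strength == 0) return(pool)
  idx <- sites_in_genes(pool, ref, gene_ids)
  if (length(idx)) {
    H <- pool$haplotypes[[block_id]]
    target <- as.integer(colMeans(H[, idx, drop = FALSE]) > 0.5)
    swept <- runif(nrow(H)) < sweep_strength
    if (any(swept)) {
      H[swept, idx] <- matrix(target, nrow = sum(swept),
                              ncol = length(idx), byrow = TRUE)
    }
    pool$haplotypes[[block_id]] <- H
    pool$block_freq[block_id, idx] <- colMeans(H[, idx, drop = FALSE])
  }
  pool$sweeps <- rbind(pool$sweeps, data.table(
    block = block_id, gene_ids = paste(gene_ids, collapse = ","),
    strength = sweep_strength, n_sites = length(idx)))
  pool
}

#' Implant an F_ST-only decoy locus (allele swap between blocks)
#'
#' Negative control for the sweep scan: at every segregating site of a
#' contiguous gene run, the allele labels of one block are swapped
#' (haplotype column complemented; frequency p becomes 1-p). This inflates
#' between-block F_ST at the locus while leaving per-block nucleotide
#' diversity exactly unchanged (p(1-p) is symmetric) and leaving linkage
#' unchanged (r-squared and D-prime are invariant under allele relabeling).
#' A scan should flag the locus; sweep confirmation should reject it.
#'
#' @param pool A `haplotype_pool` with block structure.
#' @param ref The `ref_genome`.
#' @param gene_ids Contiguous run of at least 5 gene ids.
#' @param block_id Block whose alleles are swapped at the locus.
#' @return The modified pool.
#' @export
implant_fst_decoy <- function(pool, ref, gene_ids, block_id) {
  stopifnot(inherits(pool, "haplotype_pool"), block_id %in% pool$blocks)
  check_contiguous_genes(ref, gene_ids, min_run = 5L)
  idx <- sites_in_genes(pool, ref, gene_ids)
  if (length(idx)) {
    H <- pool$haplotypes[[block_id]]
    H[, idx] <- 1L - H[, idx]
    pool$haplotypes[[block_id]] <- H
    pool$block_freq[block_id, idx] <- 1 - pool$block_freq[block_id, idx]
  }
  pool
}

check_contiguous_genes <- function(ref, gene_ids, min_run = 5L) {
  g <- ref$genes
  rows <- match(gene_ids, g$gene_id)
  if (anyNA(rows)) stop("unknown gene_id(s): ",
                        paste(gene_ids[is.na(rows)], collapse = ", "))
  if (length(rows) < min_run) {
    stop(sprintf("sweep locus needs a run of >= %d genes, got %d",
                 min_run, length(rows)))
  }
  ord <- g[order(g$contig, g$start), ]
  pos <- match(gene_ids, ord$gene_id)
  if (any(diff(sort(pos)) != 1L) ||
      length(unique(ord$contig[pos])) != 1L) {
    stop("gene_ids must form a contiguous run on one contig")
  }
  invisible(TRUE)
}

#' Truth tables for a haplotype pool
#'
#' Computes, from the realized haplotype matrices, the quantities a perfect
#' estimator should recover: per-site per-block derived-allele frequencies,
#' per-gene expected nucleotide diversity per block and pooled over all
#' blocks (sum over segregating sites in the gene of 2p(1-p), divided by
#' gene length), and per-gene Hudson F_ST between every block pair
#' (ratio of averages, with the finite-sample correction at
#' n = number of haplotypes).
#'
#' @param pool A `haplotype_pool`.
#' @param ref The `ref_genome`.
#' @return List with `site_freq` (data.table: site_id, block, freq),
#'   `gene_pi` (gene_id, block [including "pooled"], pi),
#'   `gene_fst` (gene_id, block_pair, fst), and `sweeps`.
#' @export
truth_tables <- function(pool, ref) {
  s <- pool$sites
  blocks <- pool$blocks
  fr <- lapply(blocks, function(b) {
    data.table(site_id = s$site_id, block = b,
               freq = colMeans(pool$haplotypes[[b]]))
  })
  site_freq <- rbindlist(fr)
  fmat <- do.call(rbind, lapply(blocks, function(b)
    colMeans(pool$haplotypes[[b]])))
  rownames(fmat) <- blocks
  pooled <- colMeans(fmat)

  g <- ref$genes
  gene_pi <- vector("list", 0)
  gene_fst <- vector("list", 0)
  n <- pool$n_haplotypes
  for (i in seq_len(nrow(g))) {
    idx <- which(s$contig == g$contig[i] & s$pos >= g$start[i] &
                   s$pos < g$end[i])
    glen <- g$end[i] - g$start[i]
    for (b in blocks) {
      p <- fmat[b, idx]
      gene_pi[[length(gene_pi) + 1L]] <- data.table(
        gene_id = g$gene_id[i], block = b,
        pi = sum(2 * p * (1 - p)) / glen)
    }
    p <- pooled[idx]
    gene_pi[[length(gene_pi) + 1L]] <- data.table(
      gene_id = g$gene_id[i], block = "pooled",
      pi = sum(2 * p * (1 - p)) / glen)
    if (length(blocks) >= 2) {
      for (bi in seq_len(length(blocks) - 1L)) {
        for (bj in (bi + 1L):length(blocks)) {
          p1 <- fmat[bi, idx]; p2 <- fmat[bj, idx]
          num <- (p1 - p2)^2 - p1 * (1 - p1) / (n - 1) -
            p2 * (1 - p2) / (n - 1)
          den <- p1 * (1 - p2) + p2 * (1 - p1)
          keep <- den > 0
          gene_fst[[length(gene_fst) + 1L]] <- data.table(
            gene_id = g$gene_id[i],
            block_pair = paste(blocks[bi], blocks[bj], sep = "-"),
            fst = if (any(keep)) sum(num[keep]) / sum(den[keep]) else NA_real_)
        }
      }
    }
  }
  list(site_freq = site_freq,
       gene_pi = rbindlist(gene_pi),
       gene_fst = if (length(gene_fst)) rbindlist(gene_fst) else
         data.table(gene_id = character(), block_pair = character(),
                    fst = numeric()),
       sweeps = pool$sweeps)
}
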