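#' Sample per-block base-count pileups directly from a haplotype pool
#'
#' Count-level companion to [simulate_reads()]: at every genome position a
#' fixed sequencing depth of bases is drawn, and at each segregating site
#' the derived-allele count is Binomial(depth, realized block frequency) --
#' equivalent to sampling reads (cells) from the block's haplotype pool with
#' replacement at that site, without the cost of generating reads. Used for
#' estimator-calibration work (F_ST recovery, sweep-scan fixtures) where
#' read geometry is irrelevant.
#'
#' @param pool A `haplotype_pool`.
#' @param ref The `ref_genome`.
#' @param depth Per-position depth (per block).
#' @param seed Integer seed.
#' @return Named list of per-block `pileup`s.
#' @export
sample_block_counts <- function(pool, ref, depth = 100L, seed = 1) {
  set.seed(seed)
  s <- pool$sites
  lapply(setNames(pool$blocks, pool$blocks), function(b) {
    freq <- colMeans(pool$haplotypes[[b]])
    counts <- lapply(names(ref$contigs), function(cid) {
      L <- nchar(ref$contigs[[cid]])
      m <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
      rb <- match(strsplit(ref$contigs[[cid]], "", fixed = TRUE)[[1]],
                  BASES)
      m[cbind(seq_len(L), rb)] <- as.integer(depth)
      i <- which(s$contig == cid)
      if (length(i)) {
        alt_n <- rbinom(length(i), depth, freq[i])
        rows <- s$pos[i] + 1L
        m[cbind(rows, match(s$ref_base[i], BASES))] <-
          as.integer(depth) - alt_n
        m[cbind(rows, match(s$alt_base[i], BASES))] <- alt_n
      }
      m
    })
    names(counts) <- names(ref$contigs)
    pileup_from_counts(counts, samples = paste0("counts_", b))
  })
}

#' Sample two-site haplotype co-observations from a pool
#'
#' Count-level companion to [extract_pair_haplotypes()]: for every pair of
#' segregating sites within each gene, draws `n_obs` haplotypes from the
#' pool (blocks pooled with equal weight) and tabulates the 2x2 allele
#' co-observation counts, emulating read pairs that physically span the two
#' sites. Alleles A/B are the ancestral (reference) alleles.
#'
#' @param pool A `haplotype_pool`.
#' @param ref The `ref_genome`.
#' @param n_obs Haplotype draws per site pair (default 50).
#' @param seed Integer seed.
#' @param max_pairs_per_gene Cap on site pairs sampled per gene (default
#'   Inf).
#' @return `data.table` in the [extract_pair_haplotypes()] layout
#'   (contig, pos1, pos2, distance, n, n_AB, n_Ab, n_aB, n_ab, gene_id1,
#'   gene_id2).
#' @export
sample_pair_haplotypes <- function(pool, ref, n_obs = 50L, seed = 1,
                                   max_pairs_per_gene = Inf) {
  set.seed(seed)
  s <- pool$sites
  H <- do.call(rbind, pool$haplotypes)  # blocks pooled equally
  g <- ref$genes
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    idx <- which(s$contig == g$contig[i] & s$pos >= g$start[i] &
                   s$pos < g$end[i])
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    if (ncol(cmb) > max_pairs_per_gene) {
      cmb <- cmb[, sample.int(ncol(cmb), max_pairs_per_gene), drop = FALSE]
    }
    rows <- matrix(sample.int(nrow(H), n_obs * ncol(cmb), replace = TRUE),
                   nrow = n_obs)
    res <- matrix(0L, ncol(cmb), 4L)
    for (k in seq_len(ncol(cmb))) {
      a1 <- H[rows[, k], cmb[1, k]]
      a2 <- H[rows[, k], cmb[2, k]]
      res[k, ] <- c(sum(a1 == 0L & a2 == 0L), sum(a1 == 0L & a2 == 1L),
                    sum(a1 == 1L & a2 == 0L), sum(a1 == 1L & a2 == 1L))
    }
    out[[i]] <- data.table(
      contig = g$contig[i], pos1 = s$pos[cmb[1, ]], pos2 = s$pos[cmb[2, ]],
      distance = s$pos[cmb[2, ]] - s$pos[cmb[1, ]],
      n = as.integer(n_obs),
      n_AB = res[, 1], n_Ab = res[, 2], n_aB = res[, 3], n_ab = res[, 4],
      gene_id1 = g$gene_id[i], gene_id2 = g$gene_id[i])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_phc())
  rbindlist(out)
}

#' Per-gene nucleotide diversity per block from count-level samples
#'
#' Convenience wrapper: [gene_diversity()] applied to each block's sampled
#' pileup, returned in the long format [confirm_sweeps()] expects.
#'
#' @param block_pileups Named list of per-block `pileup`s.
#' @param genes Gene annotation table.
#' @param min_depth Minimum per-site coverage (default 5).
#' @return `data.table`: gene_id, block, pi.
#' @export
gene_pi_by_block <- function(block_pileups, genes, min_depth = 5L) {
  rbindlist(lapply(names(block_pileups), function(b) {
    gd <- gene_diversity(block_pileups[[b]], genes, min_depth)
    data.table(gene_id = gd$gene_id, block = b, pi = gd$pi)
  }))
}
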