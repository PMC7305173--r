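#' Hudson per-site F_ST components
#'
#' numerator = (p1 - p2)^2 - p1 (1 - p1)/(n1 - 1) - p2 (1 - p2)/(n2 - 1);
#' denominator = p1 (1 - p2) + p2 (1 - p1). The finite-sample correction
#' uses the per-block read coverage as the sample size (pooled reads, each
#' read pair approximately one cell). Per-site estimates can legitimately be
#' negative; sites with n <= 1 in either block are undefined.
#'
#' @param p1,p2 Allele frequencies of the same allele in the two blocks.
#' @param n1,n2 Sample sizes (read coverages) in the two blocks.
#' @return `data.table` with `num` and `den` (NA where undefined).
#' @export
hudson_site_fst <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  bad <- n1 <= 1 | n2 <= 1
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  data.table(num = num, den = den)
}

# per-block frequency of each SNP's minor allele + coverage at SNP sites
snp_block_freq <- function(snps, block_pileup) {
  s <- as.data.table(snps)
  freq <- numeric(nrow(s))
  cov <- numeric(nrow(s))
  cnt <- numeric(nrow(s))
  for (cid in unique(s$contig)) {
    m <- block_pileup$counts[[cid]]
    i <- which(s$contig == cid)
    rows <- s$pos[i] + 1L
    cv <- rowSums(m[rows, , drop = FALSE])
    mc <- m[cbind(rows, match(s$minor[i], BASES))]
    cov[i] <- cv
    cnt[i] <- mc
    freq[i] <- ifelse(cv > 0, mc / cv, NA_real_)
  }
  data.table(freq = freq, cov = cov, count = cnt)
}

#' Per-gene Hudson F_ST between two blocks (ratio of averages)
#'
#' Sites must be segregating across the pooled pair of blocks and covered at
#' `min_cov` or more in each block. Genes whose mean coverage in either
#' block falls outside mean +/- `coverage_sd_k` standard deviations (over
#' genes, per block) are excluded. Per gene, F_ST is the ratio of the summed
#' Hudson numerators to the summed denominators over qualifying sites --
#' never the mean of per-site ratios.
#'
#' @param snps A `snp_table` (called on the pooled pileup).
#' @param pileup1,pileup2 Block-level pooled `pileup`s.
#' @param genes Gene annotation table.
#' @param min_cov Minimum per-site coverage in each block (default 20).
#' @param coverage_sd_k Gene coverage exclusion width (default 2 SD).
#' @return `data.table`: gene_id, n_sites, fst (`NA` when missing),
#'   mean_cov_b1, mean_cov_b2, excluded (TRUE if dropped by the coverage
#'   rule).
#' @export
gene_fst <- function(snps, pileup1, pileup2, genes, min_cov = 20L,
                     coverage_sd_k = 2) {
  s <- as.data.table(snps)
  g <- as.data.table(genes)
  f1 <- snp_block_freq(s, pileup1)
  f2 <- snp_block_freq(s, pileup2)
  # segregating across the pooled pair of blocks
  seg <- (f1$count + f2$count) > 0 &
    (f1$count + f2$count) < (f1$cov + f2$cov)
  usable <- seg & f1$cov >= min_cov & f2$cov >= min_cov
  hf <- hudson_site_fst(f1$freq, f1$cov, f2$freq, f2$cov)

  # mean gene coverage per block (all positions)
  gcov <- function(pileup) {
    vapply(seq_len(nrow(g)), function(i) {
      m <- pileup$counts[[g$contig[i]]]
      mean(rowSums(m[(g$start[i] + 1L):g$end[i], , drop = FALSE]))
    }, numeric(1))
  }
  cov1 <- gcov(pileup1)
  cov2 <- gcov(pileup2)
  excl <- rep(FALSE, nrow(g))
  for (cv in list(cov1, cov2)) {
    mu <- mean(cv); sdv <- sd(cv)
    if (!is.na(sdv) && sdv > 0) {
      excl <- excl | cv > mu + coverage_sd_k * sdv |
        cv < mu - coverage_sd_k * sdv
    }
  }

  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    si <- which(s$contig == g$contig[i] & s$pos >= g$start[i] &
                  s$pos < g$end[i] & usable)
    fst <- NA_real_
    if (!excl[i] && length(si)) {
      sn <- sum(hf$num[si]); sdn <- sum(hf$den[si])
      if (!is.na(sdn) && sdn > 0) fst <- sn / sdn
    }
    out[[i]] <- data.table(gene_id = g$gene_id[i], contig = g$contig[i],
                           start = g$start[i],
                           n_sites = length(si), fst = fst,
                           mean_cov_b1 = cov1[i], mean_cov_b2 = cov2[i],
                           excluded = excl[i])
  }
  rbindlist(out)
}

#' Moving-window scan for highly differentiated loci
#'
#' Orders genes by genome coordinate within each contig, skips genes without
#' an F_ST value, and slides a `window`-gene window (step one gene). The
#' genomic threshold is mean + `k_sd` SD of all per-gene F_ST values. A
#' candidate locus is a maximal run of genes covered by at least one window
#' whose mean exceeds the threshold -- i.e. successful windows extend a
#' locus for as long as the moving window mean stays above the cutoff, and
#' overlapping windows merge. (Extending on the cumulative locus mean
#' instead would make locus length grow without bound in the core's F_ST,
#' swallowing arbitrarily many background genes around a strong core.)
#' Windows never span contigs.
#'
#' @param gene_fst_table Output of [gene_fst()] (needs gene_id, contig,
#'   start, fst).
#' @param window Window size in genes (default 5).
#' @param k_sd Threshold in genomic SDs (default 2.5).
#' @return `data.table` of candidate loci: locus_id, contig, gene_ids
#'   (comma-joined, in order), n_genes, mean_fst, threshold. Empty when no
#'   window exceeds the threshold.
#' @export
window_scan <- function(gene_fst_table, window = 5L, k_sd = 2.5) {
  gf <- as.data.table(gene_fst_table)
  vals <- gf$fst[!is.na(gf$fst)]
  if (length(vals) < 2) stop("need >= 2 genes with F_ST values")
  thr <- mean(vals) + k_sd * sd(vals)
  loci <- list()
  for (cid in unique(gf$contig)) {
    sub <- gf[gf$contig == cid & !is.na(gf$fst)]
    setorder(sub, start)
    ng <- nrow(sub)
    if (ng < window) {
      warning("contig ", cid, " has fewer than ", window,
              " genes with F_ST values; skipped")
      next
    }
    f <- sub$fst
    cs <- cumsum(c(0, f))
    wmean <- (cs[(window + 1):(ng + 1)] - cs[seq_len(ng - window + 1)]) /
      window
    seeds <- which(wmean > thr)
    if (!length(seeds)) next
    # genes covered by any significant window; maximal covered runs merge
    runs <- lapply(seeds, function(sdx) c(sdx, sdx + window - 1L))
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], r[2]))
      } else merged[[length(merged) + 1L]] <- r
    }
    for (r in merged) {
      ids <- sub$gene_id[r[1]:r[2]]
      loci[[length(loci) + 1L]] <- data.table(
        contig = cid, gene_ids = paste(ids, collapse = ","),
        n_genes = length(ids), mean_fst = mean(f[r[1]:r[2]]),
        threshold = thr)
    }
  }
  if (!length(loci)) {
    return(data.table(locus_id = character(), contig = character(),
                      gene_ids = character(), n_genes = integer(),
                      mean_fst = numeric(), threshold = numeric()))
  }
  out <- rbindlist(loci)
  out <- cbind(data.table(locus_id = sprintf("locus_%02d",
                                             seq_len(nrow(out)))), out)
  out
}

#' Confirm candidate sweep loci with linkage and diversity tests
#'
#' For each candidate locus: (a) a one-sided two-sample Wilcoxon rank-sum
#' test that per-site-pair linkage (r^2 by default) inside the locus exceeds
#' the genomic background; (b) per block, a two-sided Welch t-test of
#' per-gene nucleotide diversity inside the locus versus the rest of the
#' genome. Linkage p-values are Benjamini-Hochberg corrected across loci;
#' diversity p-values across loci x blocks. A locus is confirmed iff
#' q_linkage < alpha and q_pi < alpha in at least one block. The direction
#' of the diversity change per block is reported.
#'
#' @param candidates Output of [window_scan()].
#' @param linkage_records Output of [linkage_stats()] with `gene_id1`
#'   (records are assigned to loci via the gene of their first site).
#' @param gene_pi_by_block Data frame: gene_id, block, pi (per-gene
#'   diversity per block).
#' @param alpha Significance level after correction (default 0.05).
#' @param linkage_stat Column of `linkage_records` used as the linkage
#'   measure (default "r2").
#' @return `data.table`: locus_id, gene_ids, mean_fst, n_linkage_in,
#'   p_linkage, q_linkage, per-block p/q/direction for pi (long format in
#'   `pi_tests` attribute is avoided; columns are per block), confirmed,
#'   reason (for unconfirmable loci).
#' @export
confirm_sweeps <- function(candidates, linkage_records, gene_pi_by_block,
                           alpha = 0.05, linkage_stat = "r2") {
  cand <- as.data.table(candidates)
  lr <- as.data.table(linkage_records)
  gp <- as.data.table(gene_pi_by_block)
  blocks <- sort(unique(gp$block))
  if (!nrow(cand)) {
    out <- data.table(locus_id = character(), gene_ids = character(),
                      mean_fst = numeric(), n_linkage_in = integer(),
                      p_linkage = numeric(), q_linkage = numeric(),
                      confirmed = logical(), reason = character())
    return(out)
  }
  gene_sets <- strsplit(cand$gene_ids, ",", fixed = TRUE)
  lstat <- lr[[linkage_stat]]

  p_link <- rep(NA_real_, nrow(cand))
  n_in <- integer(nrow(cand))
  reason <- rep("", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    inside <- lr$gene_id1 %in% gene_sets[[i]]
    n_in[i] <- sum(inside)
    if (n_in[i] == 0 || sum(!inside) == 0) {
      reason[i] <- "no linkage records in locus"
      next
    }
    p_link[i] <- suppressWarnings(
      wilcox.test(lstat[inside], lstat[!inside],
                  alternative = "greater")$p.value)
  }

  p_pi <- matrix(NA_real_, nrow(cand), length(blocks),
                 dimnames = list(NULL, blocks))
  dir_pi <- matrix(NA_character_, nrow(cand), length(blocks),
                   dimnames = list(NULL, blocks))
  for (b in blocks) {
    gb <- gp[gp$block == b & !is.na(gp$pi)]
    for (i in seq_len(nrow(cand))) {
      a <- gb$pi[gb$gene_id %in% gene_sets[[i]]]
      r <- gb$pi[!(gb$gene_id %in% gene_sets[[i]])]
      if (length(a) >= 2 && length(r) >= 2 &&
          (sd(a) > 0 || sd(r) > 0)) {
        p_pi[i, b] <- t.test(a, r)$p.value
        dir_pi[i, b] <- if (mean(a) < mean(r)) "decrease" else "increase"
      }
    }
  }

  q_link <- p.adjust(p_link, method = "BH")
  q_pi <- matrix(p.adjust(p_pi, method = "BH"), nrow(cand),
                 length(blocks), dimnames = list(NULL, blocks))
  any_pi <- apply(q_pi, 1, function(r) any(!is.na(r) & r < alpha))
  confirmed <- !is.na(q_link) & q_link < alpha & any_pi
  out <- data.table(locus_id = cand$locus_id, gene_ids = cand$gene_ids,
                    mean_fst = cand$mean_fst, n_linkage_in = n_in,
                    p_linkage = p_link, q_linkage = q_link,
                    confirmed = confirmed, reason = reason)
  for (b in blocks) {
    out[[paste0("p_pi_", b)]] <- p_pi[, b]
    out[[paste0("q_pi_", b)]] <- q_pi[, b]
    out[[paste0("dir_pi_", b)]] <- dir_pi[, b]
  }
  out
}
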