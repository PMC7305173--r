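#' Minimum alternate-allele count under the sequencing-error null model
#'
#' For a position at a given coverage, the smallest alternate-allele count k
#' such that P(X >= k) <= alpha where X ~ Binomial(coverage, eps_alt), the
#' null distribution of counts of one specific alternate base arising purely
#' from sequencing error. By default the total per-base error rate `eps` is
#' split uniformly over the three alternative bases (`eps_alt = eps / 3`);
#' set `split_alt = FALSE` to test against the total error rate (more
#' conservative). The analytic mode evaluates the exact binomial tail; the
#' simulated mode reproduces the null by resampling (simple sampling with
#' replacement) and is validated against the analytic tail.
#'
#' @param coverage Integer coverage(s) (>= 1).
#' @param eps Per-base error rate (default 1e-4, i.e. 0.01\%).
#' @param alpha Target per-site false positive rate (default 1e-6).
#' @param mode "analytic" (exact tail) or "simulated".
#' @param split_alt Split eps over the 3 alternate bases (default TRUE).
#' @param n_draws Monte-Carlo draws for simulated mode (default 1e8; tail
#'   estimates below ~10/alpha draws are noisy).
#' @param seed Seed for simulated mode.
#' @return Integer vector of thresholds; `NA` where alpha is unreachable at
#'   that coverage (k would exceed coverage: position uncallable).
#' @export
error_count_threshold <- function(coverage, eps = 1e-4, alpha = 1e-6,
                                  mode = c("analytic", "simulated"),
                                  split_alt = TRUE, n_draws = 1e8,
                                  seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(coverage >= 1), eps > 0, eps < 1, alpha > 0, alpha <= 1)
  p <- if (split_alt) eps / 3 else eps
  if (mode == "analytic") {
    # smallest k with P(X >= k) <= alpha:
    # qbinom(alpha, ..., lower.tail = FALSE) is the smallest x with
    # P(X > x) <= alpha, hence k = x + 1
    k <- qbinom(alpha, coverage, p, lower.tail = FALSE) + 1L
  } else {
    set.seed(seed)
    k <- vapply(unique(coverage), function(cv) {
      tail_counts <- integer(cv + 1L)  # tail_counts[j+1] = #draws == j
      chunk <- 1e7
      done <- 0
      while (done < n_draws) {
        nn <- min(chunk, n_draws - done)
        x <- rbinom(nn, cv, p)
        tail_counts <- tail_counts + tabulate(x + 1L, nbins = cv + 1L)
        done <- done + nn
      }
      tail_p <- rev(cumsum(rev(tail_counts))) / n_draws
      hit <- which(tail_p <= alpha)  # index j+1 -> count j
      if (length(hit)) as.integer(min(hit) - 1L) else NA_integer_
    }, integer(1))[match(coverage, unique(coverage))]
  }
  k[!is.na(k) & k > coverage] <- NA_integer_
  # an observation requires at least one read
  k[!is.na(k)] <- pmax(k[!is.na(k)], 1L)
  as.integer(k)
}

#' Call SNPs from a pooled pileup with an error null model and MAF cutoff
#'
#' A position is called a SNP iff its most common non-major allele has
#' (1) a count at or above the null-model threshold for the position's
#' coverage and (2) a frequency of at least `maf` (5\% by default,
#' inclusive). SNPs are intended to be called once on the meadow-wide pooled
#' pileup and then profiled per block or sample. Multi-allelic positions
#' keep the top two alleles for downstream biallelic analyses, with all four
#' counts retained in the pileup.
#'
#' @param pileup Pooled `pileup`.
#' @param ref Optional `ref_genome`; adds reference base and coding effect
#'   per SNP (see [classify_effect()]).
#' @param eps,alpha,mode,split_alt,seed Passed to
#'   [error_count_threshold()].
#' @param maf Minimum minor allele frequency (default 0.05, inclusive).
#' @return `data.table` (class also `snp_table`): contig, pos (0-based),
#'   ref_base, major, minor, major_count, minor_count, coverage, freq,
#'   gene_id, effect.
#' @export
call_snps <- function(pileup, ref = NULL, eps = 1e-4, alpha = 1e-6,
                      maf = 0.05, mode = "analytic", split_alt = TRUE,
                      seed = 1) {
  rows <- vector("list", length(pileup$counts))
  names(rows) <- names(pileup$counts)
  for (cid in names(pileup$counts)) {
    m <- pileup$counts[[cid]]
    cov <- rowSums(m)
    # major = argmax count; minor = runner-up
    maj_i <- max.col(m, ties.method = "first")
    maj_c <- m[cbind(seq_len(nrow(m)), maj_i)]
    m2 <- m
    m2[cbind(seq_len(nrow(m)), maj_i)] <- -1L
    min_i <- max.col(m2, ties.method = "first")
    min_c <- m2[cbind(seq_len(nrow(m2)), min_i)]
    cand <- which(cov > 0 & min_c > 0 & min_c / cov >= maf)
    if (!length(cand)) next
    thr <- error_count_threshold(cov[cand], eps = eps, alpha = alpha,
                                 mode = mode, split_alt = split_alt,
                                 seed = seed)
    called <- cand[!is.na(thr) & min_c[cand] >= thr]
    if (!length(called)) next
    rows[[cid]] <- data.table(
      contig = cid, pos = called - 1L,
      major = BASES[maj_i[called]], minor = BASES[min_i[called]],
      major_count = maj_c[called], minor_count = min_c[called],
      coverage = as.integer(cov[called]),
      freq = min_c[called] / cov[called])
  }
  snps <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(snps)) {
    snps <- data.table(contig = character(), pos = integer(),
                       major = character(), minor = character(),
                       major_count = integer(), minor_count = integer(),
                       coverage = integer(), freq = numeric())
  }
  if (!is.null(ref) && nrow(snps)) {
    snps$ref_base <- substring(ref$contigs[snps$contig], snps$pos + 1L,
                               snps$pos + 1L)
    eff <- classify_effect(snps, ref)
    snps$gene_id <- eff$gene_id
    snps$effect <- eff$effect
  } else if (nrow(snps)) {
    snps$ref_base <- NA_character_
    snps$gene_id <- NA_character_
    snps$effect <- NA_character_
  }
  class(snps) <- c("snp_table", class(snps))
  snps
}

#' Classify the coding effect of SNPs
#'
#' For each variant position, substitutes the minor allele into the
#' reference codon of the containing gene (reverse-complemented for minus
#' strand genes), translates with the standard genetic code, and labels the
#' change synonymous or nonsynonymous. Positions outside genes are
#' intergenic; positions in an incomplete terminal codon are `unknown` and
#' excluded from N:S. When genes overlap, the first containing gene in
#' coordinate order is used.
#'
#' @param snps Table with `contig`, `pos` (0-based), `minor` columns.
#' @param ref The `ref_genome` (with genes).
#' @return `data.table`: gene_id, effect in
#'   {synonymous, nonsynonymous, intergenic, unknown}.
#' @export
classify_effect <- function(snps, ref) {
  s <- as.data.table(snps)
  g <- ref$genes
  n <- nrow(s)
  gene_id <- rep(NA_character_, n)
  effect <- rep("intergenic", n)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(n)) {
    hit <- which(g$contig == s$contig[i] & g$start <= s$pos[i] &
                   g$end > s$pos[i])
    if (!length(hit)) next
    hit <- hit[1]
    gene_id[i] <- g$gene_id[hit]
    glen <- g$end[hit] - g$start[hit]
    # offset within the transcribed frame
    off <- if (g$strand[hit] == "+") s$pos[i] - g$start[hit] else
      g$end[hit] - 1L - s$pos[i]
    codon_i <- off %/% 3L
    if ((codon_i + 1L) * 3L > glen) {  # incomplete terminal codon
      effect[i] <- "unknown"
      next
    }
    # genome-forward coordinates of the codon
    if (g$strand[hit] == "+") {
      c0 <- g$start[hit] + codon_i * 3L
      codon <- substring(ref$contigs[[s$contig[i]]], c0 + 1L, c0 + 3L)
      within <- s$pos[i] - c0 + 1L
      mut <- codon
      substr(mut, within, within) <- s$minor[i]
    } else {
      c0 <- g$end[hit] - (codon_i + 1L) * 3L
      fwd <- substring(ref$contigs[[s$contig[i]]], c0 + 1L, c0 + 3L)
      mfwd <- fwd
      within <- s$pos[i] - c0 + 1L
      substr(mfwd, within, within) <- s$minor[i]
      codon <- revcomp(fwd)
      mut <- revcomp(mfwd)
    }
    aa0 <- code[[codon]]
    aa1 <- code[[mut]]
    effect[i] <- if (identical(aa0, aa1)) "synonymous" else "nonsynonymous"
  }
  data.table(gene_id = gene_id, effect = effect)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Population-level SNP summaries
#'
#' @param snps A `snp_table` with effects.
#' @param genome_length Total genome length in bp.
#' @return List with `n_snps`, `snps_per_mb`, `n_nonsyn`, `n_syn`,
#'   `ns_ratio` (`NA` with a flag if no synonymous SNPs).
#' @export
population_summaries <- function(snps, genome_length) {
  stopifnot(genome_length > 0)
  nN <- sum(snps$effect == "nonsynonymous", na.rm = TRUE)
  nS <- sum(snps$effect == "synonymous", na.rm = TRUE)
  list(n_snps = nrow(snps),
       snps_per_mb = nrow(snps) * 1e6 / genome_length,
       n_nonsyn = nN, n_syn = nS,
       ns_ratio = if (nS > 0) nN / nS else NA_real_,
       ns_undefined = nS == 0)
}

#' Write a SNP table as TSV (1-based positions)
#'
#' @param snps A `snp_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps_tsv <- function(snps, path) {
  out <- as.data.table(snps)
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
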