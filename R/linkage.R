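#' Extract two-site haplotype counts from read pairs
#'
#' For every pair of called SNP sites co-observed within a single read pair
#' (on the same mate or across mates), tabulates the 2x2 counts of allele
#' co-observations. Only bases with quality at or above `min_base_quality`
#' are used; bases matching neither the site's called major nor minor allele
#' are discarded. Site pairs spanned by fewer than `min_pairs` read pairs
#' are dropped. Allele A/B denote the (meadow-wide) major allele at site 1
#' and site 2; a/b the minors.
#'
#' @param pairs Filtered pair table.
#' @param snps A `snp_table` (called on the pooled pileup).
#' @param min_base_quality Minimum base quality (default 30).
#' @param min_pairs Minimum spanning read pairs per site pair (default 30,
#'   strict "at least").
#' @return `data.table`: contig, pos1 < pos2 (0-based), distance, n,
#'   n_AB, n_Ab, n_aB, n_ab, plus per-site effects (effect1, effect2) when
#'   present in the SNP table.
#' @export
extract_pair_haplotypes <- function(pairs, snps, min_base_quality = 30L,
                                    min_pairs = 30L) {
  p <- as.data.table(pairs)
  s <- as.data.table(snps)
  if (!nrow(s) || !nrow(p)) return(empty_phc())
  s <- s[order(s$contig, s$pos)]
  s$sidx <- seq_len(nrow(s))
  qmin <- min_base_quality + 33L
  obs <- vector("list", 2L * length(unique(s$contig)))
  oi <- 0L
  for (cid in unique(s$contig)) {
    sc <- s[s$contig == cid]
    sp <- sc$pos
    for (mate in 1:2) {
      ccol <- if (mate == 2 && "contig2" %in% names(p)) p$contig2 else
        p$contig
      sel <- which(ccol == cid)
      if (!length(sel)) next
      starts <- if (mate == 1) p$start1[sel] else p$start2[sel]
      lens <- if (mate == 1) p$len1[sel] else p$len2[sel]
      i1 <- findInterval(starts - 0.5, sp) + 1L
      i2 <- findInterval(starts + lens - 0.5, sp)
      hit <- which(i2 >= i1)
      if (!length(hit)) next
      reads <- rep.int(hit, i2[hit] - i1[hit] + 1L)
      sr <- sequence(i2[hit] - i1[hit] + 1L, from = i1[hit])
      off <- sp[sr] - starts[reads] + 1L
      seqs <- if (mate == 1) p$seq1[sel][reads] else p$seq2[sel][reads]
      quals <- if (mate == 1) p$qual1[sel][reads] else p$qual2[sel][reads]
      base <- substr(seqs, off, off)
      q <- utf8ToInt(paste(substr(quals, off, off), collapse = ""))
      keep <- length(q) > 0 & q >= qmin
      allele <- rep(NA_integer_, length(base))
      allele[base == sc$major[sr]] <- 0L
      allele[base == sc$minor[sr]] <- 1L
      keep <- keep & !is.na(allele)
      if (!any(keep)) next
      oi <- oi + 1L
      obs[[oi]] <- data.table(read = p$read_id[sel][reads[keep]],
                              sidx = sc$sidx[sr[keep]],
                              allele = allele[keep])
    }
  }
  if (oi == 0L) return(empty_phc())
  obs <- rbindlist(obs[seq_len(oi)])
  # one observation per (read pair, site): drop conflicting duplicates
  obs <- obs[, if (.N == 1L || length(unique(allele)) == 1L)
    .SD[1L], by = .(read, sidx)]
  # all unordered site pairs co-observed within a read pair
  j <- merge(obs, obs, by = "read", allow.cartesian = TRUE,
             suffixes = c("1", "2"))
  j <- j[j$sidx1 < j$sidx2]
  if (!nrow(j)) return(empty_phc())
  tab <- j[, .(n_AB = sum(allele1 == 0L & allele2 == 0L),
               n_Ab = sum(allele1 == 0L & allele2 == 1L),
               n_aB = sum(allele1 == 1L & allele2 == 0L),
               n_ab = sum(allele1 == 1L & allele2 == 1L)),
           by = .(sidx1, sidx2)]
  tab$n <- tab$n_AB + tab$n_Ab + tab$n_aB + tab$n_ab
  tab <- tab[tab$n >= min_pairs]
  if (!nrow(tab)) return(empty_phc())
  out <- data.table(
    contig = s$contig[tab$sidx1],
    pos1 = s$pos[tab$sidx1], pos2 = s$pos[tab$sidx2],
    distance = s$pos[tab$sidx2] - s$pos[tab$sidx1],
    n = tab$n, n_AB = tab$n_AB, n_Ab = tab$n_Ab, n_aB = tab$n_aB,
    n_ab = tab$n_ab)
  if ("effect" %in% names(s)) {
    out$effect1 <- s$effect[tab$sidx1]
    out$effect2 <- s$effect[tab$sidx2]
  }
  if ("gene_id" %in% names(s)) {
    out$gene_id1 <- s$gene_id[tab$sidx1]
    out$gene_id2 <- s$gene_id[tab$sidx2]
  }
  out
}

empty_phc <- function() {
  data.table(contig = character(), pos1 = integer(), pos2 = integer(),
             distance = integer(), n = integer(), n_AB = integer(),
             n_Ab = integer(), n_aB = integer(), n_ab = integer())
}

#' Linkage disequilibrium statistics from 2x2 haplotype counts
#'
#' With n = total pairs, p_AB = n_AB/n, p_A = (n_AB + n_Ab)/n and
#' p_B = (n_AB + n_aB)/n: D = p_AB - p_A p_B;
#' r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B));
#' D' = |D| / D_max with D_max = min(p_A (1 - p_B), (1 - p_A) p_B) when
#' D > 0 and min(p_A p_B, (1 - p_A)(1 - p_B)) when D < 0; D = 0 gives
#' D' = 0 by convention. Tables monomorphic at either site are dropped
#' (denominators vanish). `four_haplotypes` records whether all four allele
#' combinations were observed, which is equivalent to D' < 1.
#'
#' @param counts Table with columns n_AB, n_Ab, n_aB, n_ab (and any
#'   passthrough columns, e.g. from [extract_pair_haplotypes()]).
#' @return Input rows that are polymorphic at both sites, with added
#'   columns n, p_A, p_B, D, r2, Dprime, four_haplotypes.
#' @export
linkage_stats <- function(counts) {
  x <- as.data.table(counts)
  n <- x$n_AB + x$n_Ab + x$n_aB + x$n_ab
  p_AB <- x$n_AB / n
  p_A <- (x$n_AB + x$n_Ab) / n
  p_B <- (x$n_AB + x$n_aB) / n
  D <- p_AB - p_A * p_B
  denom <- p_A * (1 - p_A) * p_B * (1 - p_B)
  keep <- n > 0 & denom > 0
  r2 <- D^2 / denom
  dmax <- ifelse(D > 0,
                 pmin(p_A * (1 - p_B), (1 - p_A) * p_B),
                 pmin(p_A * p_B, (1 - p_A) * (1 - p_B)))
  dprime <- ifelse(D == 0, 0, abs(D) / dmax)
  x$n <- n
  x$p_A <- p_A
  x$p_B <- p_B
  x$D <- D
  x$r2 <- r2
  x$Dprime <- dprime
  x$four_haplotypes <- x$n_AB > 0 & x$n_Ab > 0 & x$n_aB > 0 & x$n_ab > 0
  x[keep]
}

#' Linkage decay with genomic distance
#'
#' Bins site pairs by distance and reports the per-bin mean r^2 and D',
#' weighted by the number of spanning read pairs, plus per-bin totals.
#'
#' @param records Output of [linkage_stats()] with a `distance` column.
#' @param bin_width Bin width in bp (default 50).
#' @return `data.table`: bin (left edge), mid, n_pairs (site pairs),
#'   total_obs, mean_r2, mean_Dprime.
#' @export
linkage_decay <- function(records, bin_width = 50L) {
  r <- as.data.table(records)
  if (!nrow(r)) stop("no linkage records")
  r$bin <- (r$distance %/% bin_width) * bin_width
  out <- r[, .(n_pairs = .N, total_obs = sum(n),
               mean_r2 = sum(r2 * n) / sum(n),
               mean_Dprime = sum(Dprime * n) / sum(n)),
           by = bin]
  out$mid <- out$bin + bin_width / 2
  setorder(out, bin)
  out
}

#' Stratify linkage by the coding effect of the paired SNPs
#'
#' Computes unweighted mean r^2 and D' for site pairs whose both sites are
#' nonsynonymous (NN), both synonymous (SS), or mixed (NS), and the
#' N/S ratios of the class means. Ratios are `NA` when a class is empty.
#'
#' @param records Output of [linkage_stats()] with `effect1`, `effect2`.
#' @return List with `by_class` (data.table: class, n, mean_r2,
#'   mean_Dprime) and `ratios` (r2_NN_over_SS, Dprime_NN_over_SS).
#' @export
stratify_by_effect <- function(records) {
  r <- as.data.table(records)
  stopifnot(all(c("effect1", "effect2") %in% names(r)))
  cls <- rep(NA_character_, nrow(r))
  nn <- r$effect1 == "nonsynonymous" & r$effect2 == "nonsynonymous"
  ss <- r$effect1 == "synonymous" & r$effect2 == "synonymous"
  ns <- (r$effect1 == "nonsynonymous" & r$effect2 == "synonymous") |
    (r$effect1 == "synonymous" & r$effect2 == "nonsynonymous")
  cls[nn] <- "NN"; cls[ss] <- "SS"; cls[ns] <- "NS"
  by_class <- rbindlist(lapply(c("NN", "SS", "NS"), function(k) {
    i <- which(cls == k)
    data.table(class = k, n = length(i),
               mean_r2 = if (length(i)) mean(r$r2[i]) else NA_real_,
               mean_Dprime = if (length(i)) mean(r$Dprime[i]) else NA_real_)
  }))
  m <- function(k, col) by_class[[col]][by_class$class == k]
  list(by_class = by_class,
       ratios = list(
         r2_NN_over_SS = if (m("NN", "n") > 0 && m("SS", "n") > 0)
           m("NN", "mean_r2") / m("SS", "mean_r2") else NA_real_,
         Dprime_NN_over_SS = if (m("NN", "n") > 0 && m("SS", "n") > 0)
           m("NN", "mean_Dprime") / m("SS", "mean_Dprime") else NA_real_))
}

#' Fraction of site pairs with all four haplotype combinations
#'
#' All four combinations observed is equivalent to D' < 1 and is evidence of
#' recombination (or recurrent mutation) between the sites.
#'
#' @param records Output of [linkage_stats()].
#' @return Fraction in [0, 1].
#' @export
four_haplotype_fraction <- function(records) {
  r <- as.data.table(records)
  if (!nrow(r)) stop("no linkage records")
  mean(r$four_haplotypes)
}

#' Write linkage records as TSV (1-based positions)
#'
#' @param records Linkage records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_tsv <- function(records, path) {
  out <- as.data.table(records)
  if (nrow(out)) {
    out$pos1 <- out$pos1 + 1L
    out$pos2 <- out$pos2 + 1L
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
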