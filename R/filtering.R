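#' Combined percent identity of a read pair
#'
#' Identity of the combined pair against the reference:
#' `1 - (nm1 + nm2) / (len1 + len2)`, i.e. summed edit distance over summed
#' aligned length across both mates (indel columns count through the edit
#' distance; soft-clipped bases are excluded from the denominator because
#' they are not aligned).
#'
#' @param pairs Pair table (internal aligned-pair format) with `nm1`, `nm2`,
#'   `len1`, `len2`.
#' @return Numeric vector of identities in [0, 1].
#' @export
pair_identity <- function(pairs) {
  p <- as.data.table(pairs)
  if (anyNA(p$nm1) || anyNA(p$nm2)) {
    stop("pair with missing edit distance (unaligned mate or absent NM tag)")
  }
  1 - (p$nm1 + p$nm2) / (p$len1 + p$len2)
}

#' Pair span: end-to-end template length
#'
#' Distance from the leftmost aligned base to the rightmost aligned base of
#' the two mates. Pairs on different contigs get `NA`.
#'
#' @param pairs Pair table.
#' @return Integer vector of spans in bp.
#' @export
pair_span <- function(pairs) {
  p <- as.data.table(pairs)
  c2 <- if ("contig2" %in% names(p)) p$contig2 else p$contig
  span <- pmax(p$start1 + p$len1, p$start2 + p$len2) -
    pmin(p$start1, p$start2)
  span[p$contig != c2] <- NA_integer_
  as.integer(span)
}

#' Filter read pairs by span, identity and MAPQ
#'
#' A pair passes iff (1) both mates map to the same contig with an
#' end-to-end span of at most `max_span` bp, (2) the combined pair identity
#' is at least `min_identity`, and (3) at least one mate has MAPQ strictly
#' greater than `min_mapq`. Failure is attributed to the first failed rule
#' in that order.
#'
#' @param pairs Pair table.
#' @param max_span Maximum template span in bp (default 1500).
#' @param min_identity Minimum combined identity (default 0.96, inclusive).
#' @param min_mapq Pairs need `max(mapq1, mapq2) > min_mapq` (default 1,
#'   strict).
#' @return List with `pairs` (passing subset) and `report` (a one-row
#'   `data.table`: total, fail_span, fail_identity, fail_mapq, pass).
#' @export
filter_pairs <- function(pairs, max_span = 1500L, min_identity = 0.96,
                         min_mapq = 1L) {
  p <- as.data.table(pairs)
  n <- nrow(p)
  if (n == 0L) {
    return(list(pairs = p, report = data.table(
      total = 0L, fail_span = 0L, fail_identity = 0L, fail_mapq = 0L,
      pass = 0L)))
  }
  span <- pair_span(p)
  ok_span <- !is.na(span) & span <= max_span
  ident <- pair_identity(p)
  ok_ident <- ident >= min_identity
  ok_mapq <- pmax(p$mapq1, p$mapq2) > min_mapq
  first_fail <- rep("pass", n)
  first_fail[!ok_mapq] <- "mapq"
  first_fail[!ok_ident] <- "identity"
  first_fail[!ok_span] <- "span"
  report <- data.table(
    total = n,
    fail_span = sum(first_fail == "span"),
    fail_identity = sum(first_fail == "identity"),
    fail_mapq = sum(first_fail == "mapq"),
    pass = sum(first_fail == "pass"))
  list(pairs = p[first_fail == "pass"], report = report)
}

# per-position read coverage (no base-quality mask) from passing pairs
coverage_vector <- function(pairs, contig_lengths) {
  p <- as.data.table(pairs)
  cov <- lapply(contig_lengths, function(L) integer(L))
  for (cid in names(contig_lengths)) {
    for (mate in 1:2) {
      s <- if (mate == 1) p$start1[p$contig == cid] else
        p$start2[p[[if ("contig2" %in% names(p)) "contig2" else
          "contig"]] == cid]
      l <- if (mate == 1) p$len1[p$contig == cid] else
        p$len2[p[[if ("contig2" %in% names(p)) "contig2" else
          "contig"]] == cid]
      if (!length(s)) next
      L <- contig_lengths[[cid]]
      # clip to contig and accumulate via difference array
      a <- pmax(pmin(s + 1L, L), 1L)
      b <- pmin(s + l, L)
      keep <- b >= a
      ta <- tabulate(a[keep], nbins = L)
      tb <- tabulate(b[keep] + 1L, nbins = L + 1L)
      cov[[cid]] <- cov[[cid]] + cumsum(ta - tb[seq_len(L)])
    }
  }
  cov
}

#' Breadth of genome covered at or above a depth
#'
#' Fraction of genome positions with read coverage of at least `min_depth`,
#' computed from filtered pairs.
#'
#' @param pairs Filtered pair table.
#' @param ref The `ref_genome`.
#' @param min_depth Depth threshold (default 5).
#' @return Fraction in [0, 1].
#' @export
breadth_at_depth <- function(pairs, ref, min_depth = 5L) {
  clen <- as.list(nchar(ref$contigs))
  total <- sum(unlist(clen))
  if (total == 0) stop("empty genome")
  cov <- coverage_vector(pairs, clen)
  sum(vapply(cov, function(v) sum(v >= min_depth), numeric(1))) / total
}

#' Select genome-sample combinations passing the breadth cutoff
#'
#' Every (genome, sample) combination in the breadth table is a candidate;
#' those with breadth at or above `min_breadth` are included.
#'
#' @param breadth_table Data frame with columns `genome`, `sample_id`,
#'   `breadth`.
#' @param min_breadth Inclusion threshold (default 0.5, inclusive).
#' @return List with `included` (data.table of passing combinations),
#'   `n_candidates` and `n_included`.
#' @export
select_genome_samples <- function(breadth_table, min_breadth = 0.5) {
  bt <- as.data.table(breadth_table)
  stopifnot(all(c("genome", "sample_id", "breadth") %in% names(bt)))
  inc <- bt[bt$breadth >= min_breadth]
  list(included = inc, n_candidates = nrow(bt), n_included = nrow(inc))
}

#' Relative DNA abundance of genomes per sample
#'
#' Total reads mapped to each genome in each sample divided by the total
#' number of reads in that sample.
#'
#' @param mapped_counts Data frame with columns `genome`, `sample_id`,
#'   `mapped_reads`.
#' @param sample_totals Data frame with columns `sample_id`, `total_reads`.
#' @return `data.table` with an added `rel_abundance` column.
#' @export
relative_abundance <- function(mapped_counts, sample_totals) {
  mc <- as.data.table(mapped_counts)
  st <- as.data.table(sample_totals)
  if (any(st$total_reads <= 0)) stop("sample with zero total reads")
  out <- merge(mc, st, by = "sample_id")
  out$rel_abundance <- out$mapped_reads / out$total_reads
  if (any(out$rel_abundance < 0 | out$rel_abundance > 1)) {
    stop("mapped read count exceeds sample total")
  }
  out
}
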