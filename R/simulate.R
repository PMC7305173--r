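#' Build a sample plan mapping samples to blocks, plots and depths
#'
#' Convenience constructor for the metadata table the simulator and the
#' pooling machinery consume. Samples are spread evenly over blocks; within
#' each block, over plots; depths cycle; the replicate group is the
#' (plot, depth) combination.
#'
#' @param n_samples Total number of samples.
#' @param blocks Character vector of block ids.
#' @param plots_per_block Number of plots per block.
#' @param depths Depth labels cycled across samples.
#' @return A `data.table` with columns `sample_id`, `block`, `plot`,
#'   `depth`, `replicate`.
#' @export
make_sample_plan <- function(n_samples, blocks = c("B1", "B2"),
                             plots_per_block = 2,
                             depths = c("10-20", "20-30", "30-40")) {
  i <- seq_len(n_samples) - 1L
  block <- blocks[(i %/% (n_samples / length(blocks))) %% length(blocks) + 1L]
  plot <- paste0(block, "_p", (i %% plots_per_block) + 1L)
  depth <- depths[(i %% length(depths)) + 1L]
  data.table(sample_id = sprintf("S%02d", i + 1L),
             block = block, plot = plot, depth = depth,
             replicate = paste(plot, depth, sep = "_"))
}

#' Simulate aligned paired reads from a haplotype pool
#'
#' Emits per-sample sets of already-aligned proper read pairs (alignment
#' coordinates are known by construction, so no aligner is involved). Each
#' pair draws one haplotype from its sample's block, copies the reference,
#' applies the haplotype's derived alleles, and injects independent
#' substitution errors per base (uniform over the three alternative bases).
#' Mate gaps follow a truncated normal so the template span stays below the
#' read-pair filter's maximum. Per-base qualities are two-level (Q37 with a
#' configurable fraction of Q20 bases) so a Phred-30 mask is exercisable.
#' A small fraction of decoy pairs (low identity, low MAPQ, or oversized
#' span) is injected so the read-pair filters have something to remove.
#'
#' @param pool A `haplotype_pool`.
#' @param ref The `ref_genome`.
#' @param sample_plan Data frame from [make_sample_plan()]; its `block`
#'   values must exist in `pool$blocks`.
#' @param coverage_per_sample Mean per-sample coverage (x-fold).
#' @param read_length Read length in bp after trimming (default 200, as for
#'   2 x 250 bp libraries quality-trimmed to at most 200 bp).
#' @param insert_median Median gap between mates in bp (default 383).
#' @param insert_sd SD of the mate gap.
#' @param max_span Maximum end-to-end template span (default 1500).
#' @param error_rate Per-base substitution error rate (default 1e-4).
#' @param low_q_fraction Fraction of bases emitted at Q20 (< Q30 mask).
#' @param decoy_fraction Fraction of pairs converted to filter decoys.
#' @param seed Integer seed; output is fully reproducible.
#'
#' @return Object of class `sim_reads`: list with `samples` (named list of
#'   per-sample pair tables in the internal aligned-pair format), `plan`,
#'   `truth` (see [truth_tables()]) and `params`.
#' @export
simulate_reads <- function(pool, ref, sample_plan,
                           coverage_per_sample = 10,
                           read_length = 200L,
                           insert_median = 383, insert_sd = 100,
                           max_span = 1500L,
                           error_rate = 1e-4,
                           low_q_fraction = 0.02,
                           decoy_fraction = 0.005,
                           seed = 1) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(ref, "ref_genome"),
            coverage_per_sample > 0)
  plan <- as.data.table(sample_plan)
  if (!all(plan$block %in% pool$blocks)) {
    stop("sample_plan references blocks absent from the pool: ",
         paste(setdiff(plan$block, pool$blocks), collapse = ", "))
  }
  clen <- nchar(ref$contigs)
  if (any(clen < 2L * read_length)) {
    stop(sprintf(
      "contig(s) shorter than one read pair (2 x %d bp): no pair fits",
      read_length))
  }
  set.seed(seed)
  samples <- vector("list", nrow(plan))
  names(samples) <- plan$sample_id
  for (si in seq_len(nrow(plan))) {
    samples[[si]] <- sim_sample_pairs(
      pool, ref, plan$sample_id[si], plan$block[si],
      coverage_per_sample, read_length, insert_median, insert_sd,
      max_span, error_rate, low_q_fraction, decoy_fraction)
  }
  structure(list(
    samples = samples, plan = plan, truth = truth_tables(pool, ref),
    params = list(coverage_per_sample = coverage_per_sample,
                  read_length = read_length, insert_median = insert_median,
                  insert_sd = insert_sd, max_span = max_span,
                  error_rate = error_rate, low_q_fraction = low_q_fraction,
                  decoy_fraction = decoy_fraction, seed = seed)
  ), class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  n <- sum(vapply(x$samples, nrow, integer(1)))
  cat(sprintf("sim_reads: %d sample(s), %s read pairs, read length %d bp\n",
              length(x$samples), format(n, big.mark = ","),
              x$params$read_length))
  invisible(x)
}

sim_sample_pairs <- function(pool, ref, sample_id, block, coverage,
                             read_length, insert_median, insert_sd,
                             max_span, error_rate, low_q_fraction,
                             decoy_fraction) {
  rl <- as.integer(read_length)
  H <- pool$haplotypes[[block]]
  out <- vector("list", length(ref$contigs))
  for (ci in seq_along(ref$contigs)) {
    cid <- names(ref$contigs)[ci]
    cseq <- ref$contigs[[ci]]
    L <- nchar(cseq)
    n <- rpois(1, coverage * L / (2 * rl))
    if (n == 0) next
    span_cap <- min(max_span, L)
    gap <- pmax(0, round(rnorm(n, insert_median, insert_sd)))
    span <- pmin(2L * rl + as.integer(gap), span_cap)
    start1 <- vapply(span, function(s) sample.int(L - s + 1L, 1L) - 1L,
                     integer(1))
    start2 <- start1 + span - rl
    hap <- sample.int(nrow(H), n, replace = TRUE)

    seq1 <- substring(cseq, start1 + 1L, start1 + rl)
    seq2 <- substring(cseq, start2 + 1L, start2 + rl)

    # apply derived alleles of the drawn haplotypes
    s <- pool$sites[pool$sites$contig == cid, ]
    if (nrow(s)) {
      sp <- s$pos
      for (mate in 1:2) {
        starts <- if (mate == 1) start1 else start2
        i1 <- findInterval(starts - 0.5, sp) + 1L
        i2 <- findInterval(starts + rl - 0.5, sp)
        hit <- which(i2 >= i1)
        if (!length(hit)) next
        reads <- rep.int(hit, i2[hit] - i1[hit] + 1L)
        sidx <- sequence(i2[hit] - i1[hit] + 1L, from = i1[hit])
        carr <- H[cbind(hap[reads], s$site_id[sidx])] == 1L
        reads <- reads[carr]; sidx <- sidx[carr]
        if (!length(reads)) next
        off <- sp[sidx] - starts[reads] + 1L
        nb <- s$alt_base[sidx]
        if (mate == 1) {
          for (k in seq_along(reads))
            substr(seq1[reads[k]], off[k], off[k]) <- nb[k]
        } else {
          for (k in seq_along(reads))
            substr(seq2[reads[k]], off[k], off[k]) <- nb[k]
        }
      }
    }

    # per-base sequencing errors, uniform over the 3 alternative bases
    if (error_rate > 0) {
      for (mate in 1:2) {
        ne <- rbinom(1, n * rl, error_rate)
        if (ne > 0) {
          flat <- sample.int(n * rl, ne)
          rd <- (flat - 1L) %/% rl + 1L
          off <- (flat - 1L) %% rl + 1L
          for (k in seq_len(ne)) {
            tgt <- if (mate == 1) seq1[rd[k]] else seq2[rd[k]]
            cur <- substr(tgt, off[k], off[k])
            nb <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
            if (mate == 1) substr(seq1[rd[k]], off[k], off[k]) <- nb
            else substr(seq2[rd[k]], off[k], off[k]) <- nb
          }
        }
      }
    }

    qual1 <- make_quals(n, rl, low_q_fraction)
    qual2 <- make_quals(n, rl, low_q_fraction)
    dt <- data.table(
      read_id = sprintf("%s_%s_p%06d", sample_id, cid, seq_len(n)),
      sample_id = sample_id, contig = cid,
      start1 = as.integer(start1), len1 = rl, seq1 = seq1, qual1 = qual1,
      mapq1 = 42L,
      start2 = as.integer(start2), len2 = rl, seq2 = seq2, qual2 = qual2,
      mapq2 = 42L, contig2 = cid, decoy = "")

    # decoy pairs exercising each filter rule
    nd <- rbinom(1, n, decoy_fraction)
    if (nd > 0) {
      di <- sample.int(n, nd)
      type <- rep_len(c("identity", "mapq", "span"), nd)
      for (k in seq_len(nd)) {
        i <- di[k]
        if (type[k] == "identity") {
          noff <- max(1L, round(0.10 * rl))
          for (m in 1:2) {
            offs <- sample.int(rl, noff)
            for (o in offs) {
              cur <- if (m == 1) substr(dt$seq1[i], o, o) else
                substr(dt$seq2[i], o, o)
              nb <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
              if (m == 1) substr(dt$seq1[i], o, o) <- nb
              else substr(dt$seq2[i], o, o) <- nb
            }
          }
        } else if (type[k] == "mapq") {
          dt$mapq1[i] <- 1L; dt$mapq2[i] <- 0L
        } else if (L > max_span + 2L * rl + 10L) {
          dt$start2[i] <- min(L - rl,
                              dt$start1[i] + max_span + sample.int(100L, 1L))
        } else {
          dt$mapq1[i] <- 0L; dt$mapq2[i] <- 1L
        }
        dt$decoy[i] <- type[k]
      }
    }

    # NM = mismatches of the final read vs the reference window
    dt$nm1 <- count_mismatches(dt$seq1,
                               substring(cseq, dt$start1 + 1L, dt$start1 + rl))
    dt$nm2 <- count_mismatches(dt$seq2,
                               substring(cseq, dt$start2 + 1L, dt$start2 + rl))
    out[[ci]] <- dt
  }
  res <- rbindlist(out)
  if (!nrow(res)) stop("no read pairs generated for sample ", sample_id,
                       ": coverage too low")
  res
}

make_quals <- function(n, rl, low_q_fraction) {
  ch <- ifelse(runif(n * rl) < low_q_fraction, "5", "F")  # Q20 / Q37
  big <- paste(ch, collapse = "")
  substring(big, seq(1L, n * rl, rl), seq(rl, n * rl * 1L, rl))
}

count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

#' Write aligned pairs as a coordinate-sorted SAM file
#'
#' Emits one SAM record per mate with proper-pair flags, MAPQ, full-match
#' CIGAR, per-base qualities and NM tags, sorted by coordinate.
#'
#' @param pairs A pair table in the internal aligned-pair format.
#' @param ref The `ref_genome` (for the header).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, ref, path) {
  p <- as.data.table(pairs)
  if (!"contig2" %in% names(p)) p$contig2 <- p$contig
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$contigs),
                   nchar(ref$contigs)))
  same <- p$contig == p$contig2
  flag1 <- 1L + 64L + 32L + ifelse(same, 2L, 0L)
  flag2 <- 1L + 128L + 16L + ifelse(same, 2L, 0L)
  left <- pmin(p$start1, p$start2)
  right <- pmax(p$start1 + p$len1, p$start2 + p$len2)
  tlen <- ifelse(same, right - left, 0L)
  rec1 <- data.table(
    qname = p$read_id, flag = flag1, rname = p$contig, pos = p$start1 + 1L,
    mapq = p$mapq1, cigar = sprintf("%dM", p$len1),
    rnext = ifelse(same, "=", p$contig2), pnext = p$start2 + 1L,
    tlen = ifelse(p$start1 <= p$start2, tlen, -tlen),
    seq = p$seq1, qual = p$qual1, nm = sprintf("NM:i:%d", p$nm1))
  rec2 <- data.table(
    qname = p$read_id, flag = flag2, rname = p$contig2, pos = p$start2 + 1L,
    mapq = p$mapq2, cigar = sprintf("%dM", p$len2),
    rnext = ifelse(same, "=", p$contig), pnext = p$start1 + 1L,
    tlen = ifelse(p$start1 <= p$start2, -tlen, tlen),
    seq = p$seq2, qual = p$qual2, nm = sprintf("NM:i:%d", p$nm2))
  rec <- rbind(rec1, rec2)
  setorder(rec, rname, pos, qname, flag)
  lines <- do.call(paste, c(as.list(rec), sep = "\t"))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read aligned read pairs from SAM/BAM
#'
#' Loads primary alignments, pairs mates by read name, and returns the
#' internal aligned-pair format used by the filters and pileup builders.
#' Requires NM tags for the identity filter. SAM input is converted to BAM
#' internally via Rsamtools.
#'
#' @param path SAM or BAM path.
#' @param sample_id Sample label attached to every pair.
#' @return A pair `data.table` (one row per pair; mates ordered so that
#'   mate 1 is the SAM first-of-pair).
#' @export
read_pairs_sam <- function(path, sample_id = NA_character_) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path,
                     destination = tempfile(fileext = ""),
                     overwrite = TRUE, indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  aln_len <- cigar_ref_width(x$cigar)
  dt <- data.table(
    qname = x$qname, flag = x$flag, contig = as.character(x$rname),
    start = x$pos - 1L, len = aln_len, mapq = as.integer(x$mapq),
    seq = as.character(x$seq), qual = as.character(x$qual),
    nm = as.integer(x$tag$NM))
  # primary records only
  dt <- dt[bitwAnd(dt$flag, 256L) == 0L & bitwAnd(dt$flag, 2048L) == 0L]
  dt$first <- bitwAnd(dt$flag, 64L) > 0L
  m1 <- dt[dt$first]
  m2 <- dt[!dt$first]
  setkey(m1, qname); setkey(m2, qname)
  j <- merge(m1, m2, by = "qname", suffixes = c("1", "2"))
  data.table(
    read_id = j$qname, sample_id = sample_id, contig = j$contig1,
    start1 = j$start1, len1 = j$len1, seq1 = j$seq1, qual1 = j$qual1,
    mapq1 = j$mapq1, start2 = j$start2, len2 = j$len2, seq2 = j$seq2,
    qual2 = j$qual2, mapq2 = j$mapq2, contig2 = j$contig2,
    nm1 = j$nm1, nm2 = j$nm2)
}

# reference-consumed width of simple CIGARs (M/D/N/=/X consume reference)
cigar_ref_width <- function(cig) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cig)
  vapply(regmatches(cig, ops), function(parts) {
    w <- 0L
    for (p in parts) {
      op <- substr(p, nchar(p), nchar(p))
      if (op %in% c("M", "D", "N", "=", "X"))
        w <- w + as.integer(substr(p, 1, nchar(p) - 1L))
    }
    w
  }, integer(1))
}

#' Write sample metadata TSV
#'
#' @param plan Sample plan table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(plan, path) {
  write.table(plan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write truth tables to TSV files
#'
#' @param truth List from [truth_tables()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("site_freq", "gene_pi", "gene_fst", "sweeps")) {
    write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
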