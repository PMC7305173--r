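BASES <- c("A", "C", "G", "T")

#' Build a base-count pileup from filtered read pairs
#'
#' Tabulates A/C/G/T counts per genome position from the aligned bases of
#' both mates, masking bases with quality below `min_baseq` (Phred 30 by
#' default). The pileup is the substrate for nucleotide diversity, SNP
#' calling and F_ST.
#'
#' @param pairs Filtered pair table.
#' @param ref The `ref_genome`.
#' @param min_baseq Minimum base quality for a base to be counted
#'   (default 30).
#' @return Object of class `pileup`: list with `counts` (named list per
#'   contig of L x 4 integer matrices, columns A,C,G,T; rows are 0-based
#'   positions + 1), `min_baseq`, and `samples` (provenance labels).
#' @export
build_pileup <- function(pairs, ref, min_baseq = 30L) {
  p <- as.data.table(pairs)
  counts <- lapply(ref$contigs, function(s)
    matrix(0L, nrow = nchar(s), ncol = 4L,
           dimnames = list(NULL, BASES)))
  qmin <- min_baseq + 33L
  for (cid in names(ref$contigs)) {
    L <- nchar(ref$contigs[[cid]])
    for (mate in 1:2) {
      ccol <- if (mate == 2 && "contig2" %in% names(p)) p$contig2 else
        p$contig
      sel <- which(ccol == cid)
      if (!length(sel)) next
      starts <- if (mate == 1) p$start1[sel] else p$start2[sel]
      lens <- if (mate == 1) p$len1[sel] else p$len2[sel]
      seqs <- if (mate == 1) p$seq1[sel] else p$seq2[sel]
      quals <- if (mate == 1) p$qual1[sel] else p$qual2[sel]
      pos <- sequence(lens, from = starts + 1L)  # 1-based positions
      base <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
      q <- utf8ToInt(paste(quals, collapse = ""))
      bi <- match(base, BASES)
      keep <- !is.na(bi) & q >= qmin & pos >= 1L & pos <= L
      idx <- (pos[keep] - 1L) * 4L + bi[keep]
      tab <- tabulate(idx, nbins = 4L * L)
      counts[[cid]] <- counts[[cid]] +
        matrix(tab, ncol = 4L, byrow = TRUE, dimnames = list(NULL, BASES))
    }
  }
  smp <- unique(p$sample_id)
  structure(list(counts = counts, min_baseq = min_baseq,
                 samples = smp[!is.na(smp)]),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  total <- sum(vapply(x$counts, sum, numeric(1)))
  npos <- sum(vapply(x$counts, nrow, numeric(1)))
  cat(sprintf(
    "pileup: %d contig(s), %s positions, %s bases (Q>=%d), samples: %s\n",
    length(x$counts), format(npos, big.mark = ","),
    format(total, big.mark = ","), x$min_baseq,
    paste(utils::head(x$samples, 5), collapse = ",")))
  invisible(x)
}

#' Construct a pileup directly from count matrices
#'
#' Used by simulations that work at the count level (no reads), and by
#' tests.
#'
#' @param counts Named list per contig of L x 4 integer matrices with
#'   columns A,C,G,T.
#' @param min_baseq Quality mask recorded as provenance.
#' @param samples Provenance labels.
#' @return A `pileup`.
#' @export
pileup_from_counts <- function(counts, min_baseq = 30L,
                               samples = character()) {
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    colnames(m) <- BASES
    storage.mode(m) <- "integer"
    m
  })
  structure(list(counts = counts, min_baseq = min_baseq, samples = samples),
            class = "pileup")
}

#' Pool pileups by summing counts
#'
#' Sums base counts position-wise across samples of a group. Diversity must
#' then be recomputed on the pooled counts (never averaged from per-sample
#' values): two samples fixed for different alleles have per-sample pi = 0
#' but pooled pi = 0.5.
#'
#' @param pileups List of `pileup` objects on the same reference.
#' @return A pooled `pileup`.
#' @export
pool_counts <- function(pileups) {
  stopifnot(length(pileups) >= 1)
  ref_names <- names(pileups[[1]]$counts)
  dims <- vapply(pileups[[1]]$counts, nrow, integer(1))
  for (p in pileups) {
    if (!identical(names(p$counts), ref_names) ||
        !identical(vapply(p$counts, nrow, integer(1)), dims)) {
      stop("pileups built on different references cannot be pooled")
    }
  }
  counts <- lapply(ref_names, function(cid) {
    Reduce(`+`, lapply(pileups, function(p) p$counts[[cid]]))
  })
  names(counts) <- ref_names
  structure(list(counts = counts,
                 min_baseq = pileups[[1]]$min_baseq,
                 samples = unlist(lapply(pileups, `[[`, "samples"))),
            class = "pileup")
}

#' Pool per-sample pileups at a spatial scale
#'
#' Groups samples by the requested pooling level (`sample`, `replicate`,
#' `plot`, `block`, or `meadow`) and sums counts within each group.
#'
#' @param pileups Named list of per-sample `pileup`s (names = sample ids).
#' @param plan Sample metadata with columns `sample_id`, `replicate`,
#'   `plot`, `block`.
#' @param level Pooling level.
#' @return Named list of pooled `pileup`s (one per group).
#' @export
pool_by_level <- function(pileups, plan,
                          level = c("sample", "replicate", "plot", "block",
                                    "meadow")) {
  level <- match.arg(level)
  plan <- as.data.table(plan)
  stopifnot(all(names(pileups) %in% plan$sample_id))
  key <- switch(level,
                sample = plan$sample_id,
                replicate = plan$replicate,
                plot = plan$plot,
                block = plan$block,
                meadow = rep("meadow", nrow(plan)))
  names(key) <- plan$sample_id
  groups <- split(names(pileups), key[names(pileups)])
  lapply(groups, function(ids) pool_counts(pileups[ids]))
}

#' Subsample pileup coverage at each position
#'
#' At each position with coverage at least `target_depth`, draws
#' `target_depth` bases from the observed counts -- without replacement
#' (hypergeometric) by default, matching a subsampling of actual reads; a
#' with-replacement (multinomial) mode is provided for exact bias analysis,
#' where E[pi_hat] = ((n-1)/n) pi. Positions below the target depth are
#' zeroed (dropped from downstream statistics).
#'
#' @param pileup A `pileup`.
#' @param target_depth Target coverage (>= 1).
#' @param seed Integer seed; deterministic output for a fixed seed.
#' @param replace Draw with replacement (default FALSE).
#' @return A subsampled `pileup`.
#' @export
subsample_coverage <- function(pileup, target_depth, seed, replace = FALSE) {
  stopifnot(target_depth >= 1)
  set.seed(seed)
  counts <- lapply(pileup$counts, function(m) {
    cov <- rowSums(m)
    out <- matrix(0L, nrow = nrow(m), ncol = 4L,
                  dimnames = list(NULL, BASES))
    idx <- which(cov >= target_depth)
    if (!length(idx)) return(out)
    eq <- idx[cov[idx] == target_depth]
    out[eq, ] <- m[eq, ]
    todo <- idx[cov[idx] > target_depth]
    if (length(todo)) {
      sub <- matrix(0L, nrow = length(todo), ncol = 4L)
      remaining_n <- rep(as.integer(target_depth), length(todo))
      remaining_cov <- as.integer(cov[todo])
      for (b in 1:3) {
        cb <- m[todo, b]
        if (replace) {
          draw <- rbinom(length(todo), remaining_n,
                         ifelse(remaining_cov > 0, cb / remaining_cov, 0))
        } else {
          draw <- rhyper(length(todo), cb, remaining_cov - cb, remaining_n)
        }
        sub[, b] <- draw
        remaining_n <- remaining_n - draw
        remaining_cov <- remaining_cov - cb
      }
      sub[, 4] <- remaining_n
      out[todo, ] <- sub
    }
    out
  })
  structure(list(counts = counts, min_baseq = pileup$min_baseq,
                 samples = pileup$samples),
            class = "pileup")
}
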