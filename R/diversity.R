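#' Per-site nucleotide diversity
#'
#' pi = 1 - (fA^2 + fC^2 + fG^2 + fT^2), the expected frequency of a
#' difference between two sequencing reads drawn at the position. Zero
#' coverage yields `NA` (position undefined, skipped downstream).
#'
#' @param counts Numeric vector of 4 counts (A,C,G,T) or an n x 4 matrix.
#' @return pi value(s) in [0, 0.75], `NA` where coverage is 0.
#' @export
site_diversity <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  cov <- rowSums(counts)
  pi <- 1 - rowSums((counts / cov)^2)
  pi[cov == 0] <- NA_real_
  pi
}

#' Per-gene nucleotide diversity from a pileup
#'
#' For every gene, averages per-site pi over positions inside the gene with
#' coverage of at least `min_depth` (positions are weighted equally;
#' monomorphic covered positions contribute 0). Genes with no qualifying
#' position are reported with `pi = NA` and flagged missing.
#'
#' @param pileup A `pileup` (typically Q30-masked counts from passing
#'   pairs).
#' @param genes Gene annotation table (`gene_id`, `contig`, `start`, `end`
#'   0-based half-open).
#' @param min_depth Minimum per-site coverage (default 5).
#' @return `data.table`: gene_id, pi, n_pos (positions used), mean_cov
#'   (over used positions), missing.
#' @export
gene_diversity <- function(pileup, genes, min_depth = 5L) {
  g <- as.data.table(genes)
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    m <- pileup$counts[[g$contig[i]]]
    if (is.null(m)) stop("gene on unknown contig: ", g$contig[i])
    if (g$end[i] > nrow(m) || g$start[i] < 0) {
      stop("gene outside contig bounds: ", g$gene_id[i])
    }
    rows <- (g$start[i] + 1L):g$end[i]
    sub <- m[rows, , drop = FALSE]
    cov <- rowSums(sub)
    use <- cov >= min_depth
    if (!any(use)) {
      out[[i]] <- data.table(gene_id = g$gene_id[i], pi = NA_real_,
                             n_pos = 0L, mean_cov = NA_real_,
                             missing = TRUE)
    } else {
      pis <- site_diversity(sub[use, , drop = FALSE])
      out[[i]] <- data.table(gene_id = g$gene_id[i], pi = mean(pis),
                             n_pos = sum(use), mean_cov = mean(cov[use]),
                             missing = FALSE)
    }
  }
  rbindlist(out)
}

#' Flag genes with outlier diversity
#'
#' Flags genes whose value is strictly greater than
#' `mean + k_sd * SD`, with mean and SD computed over all genes with a
#' defined value (no trimming).
#'
#' @param values Numeric per-gene values (e.g. pi).
#' @param k_sd Number of standard deviations (default 2.5).
#' @return Logical vector (`NA` values are never flagged).
#' @export
flag_outlier_genes <- function(values, k_sd = 2.5) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 genes with defined values")
  thr <- mean(v) + k_sd * sd(v)
  out <- !is.na(values) & values > thr
  out
}

#' Hypergeometric enrichment of gene families among flagged genes
#'
#' Upper-tail hypergeometric test per family: given `sum(flags)` genes drawn
#' from the genome, the p-value of observing at least the realized number of
#' flagged family members.
#'
#' @param flags Logical vector over genes.
#' @param families Character vector of family labels, parallel to `flags`
#'   (`NA` = unannotated).
#' @return `data.table`: family, n_family, n_flagged_in_family, p.
#' @export
category_enrichment <- function(flags, families) {
  stopifnot(length(flags) == length(families))
  keep <- !is.na(families)
  fams <- unique(families[keep])
  N <- length(flags)
  K <- sum(flags)
  out <- lapply(fams, function(f) {
    inf <- families == f & !is.na(families)
    m <- sum(inf)
    x <- sum(flags & inf)
    # P(X >= x) with X ~ Hypergeometric(m successes, N - m, K draws)
    p <- phyper(x - 1L, m, N - m, K, lower.tail = FALSE)
    data.table(family = f, n_family = m, n_flagged_in_family = x, p = p)
  })
  rbindlist(out)
}

#' Compare per-gene diversity between a gene category and the rest
#'
#' Welch unequal-variance two-sample t-test of per-gene values between genes
#' of a category and all other genes, with Benjamini-Hochberg correction
#' across the tests of one call.
#'
#' @param gene_stats Data frame with per-gene values and a `category`
#'   column.
#' @param value_col Name of the value column (default "pi").
#' @param categories Categories to test (default: all non-"other" labels).
#' @return `data.table`: category, n_in, n_out, mean_in, mean_out, t, p, q,
#'   degenerate (TRUE when a group variance is zero and p is reported as 1).
#' @export
compare_categories <- function(gene_stats, value_col = "pi",
                               categories = NULL) {
  gs <- as.data.table(gene_stats)
  v <- gs[[value_col]]
  if (is.null(categories)) {
    categories <- setdiff(unique(gs$category), c("other", NA))
  }
  out <- lapply(categories, function(cat) {
    a <- v[gs$category == cat & !is.na(v)]
    b <- v[gs$category != cat & !is.na(v)]
    if (length(a) < 2 || length(b) < 2) {
      stop("each group needs >= 2 genes for category ", cat)
    }
    degenerate <- (sd(a) == 0 && sd(b) == 0)
    if (degenerate || (sd(a) == 0 && sd(b) == 0)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(a, b)  # Welch by default
    }
    data.table(category = cat, n_in = length(a), n_out = length(b),
               mean_in = mean(a), mean_out = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               degenerate = degenerate)
  })
  res <- rbindlist(out)
  res$q <- p.adjust(res$p, method = "BH")
  res
}
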