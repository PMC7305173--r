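#' Generate a random reference genome with gene annotations
#'
#' Builds a synthetic "representative genome": one or more contigs of random
#' sequence and a set of non-overlapping protein-coding genes tiled along the
#' contigs with intergenic gaps. The genome stands in for a dereplicated
#' species-representative assembly that metagenomic reads are mapped against.
#'
#' Genes are placed left to right with random intergenic gaps; gene lengths
#' are multiples of 3 so coding effects of variants are well defined, and
#' strands are assigned at random so both orientations are exercised.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (scalar or vector of
#'   length `n_contigs`).
#' @param n_genes Total number of genes to place across all contigs
#'   (allocated proportionally to contig length).
#' @param seed Integer seed; the genome is fully reproducible given the seed.
#' @param gene_length_range Range of gene lengths in codons (each gene length
#'   is `3 * sample(gene_length_range)` bp).
#' @param gap_range Range of intergenic gap lengths in bp.
#' @param category_probs Named probability vector used to draw a functional
#'   category label per gene (e.g. ribosomal, biosynthetic, other).
#'
#' @return An object of class `ref_genome`: a list with `contigs` (named
#'   character vector of sequences) and `genes` (a `data.table` with columns
#'   `gene_id`, `contig`, `start`, `end` (0-based half-open), `strand`,
#'   `category`, ordered by genome coordinate).
#' @export
make_reference <- function(n_contigs, contig_length, n_genes, seed,
                           gene_length_range = c(80L, 250L),
                           gap_range = c(20L, 150L),
                           category_probs = c(other = 0.90,
                                              ribosomal = 0.05,
                                              biosynthetic = 0.05)) {
  stopifnot(n_contigs >= 1, all(contig_length > 0), n_genes >= 0)
  set.seed(seed)
  contig_length <- rep_len(as.integer(contig_length), n_contigs)
  contig_ids <- sprintf("contig_%d", seq_len(n_contigs))

  contigs <- vapply(contig_length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(contigs) <- contig_ids

  # allocate genes to contigs proportionally to length
  alloc <- if (n_genes > 0) {
    a <- floor(n_genes * contig_length / sum(contig_length))
    rem <- n_genes - sum(a)
    if (rem > 0) {
      extra <- order(contig_length, decreasing = TRUE)[seq_len(rem)]
      a[extra] <- a[extra] + 1L
    }
    a
  } else rep(0L, n_contigs)

  genes <- vector("list", n_contigs)
  gi <- 0L
  for (ci in seq_len(n_contigs)) {
    k <- alloc[ci]
    if (k == 0L) next
    L <- contig_length[ci]
    # feasibility: smallest possible footprint of k genes with minimal gaps
    min_len <- 3L * gene_length_range[1]
    min_need <- k * (min_len + gap_range[1])
    if (min_need > L) {
      stop(sprintf(paste0(
        "cannot place %d genes on a %d bp contig: minimum footprint ",
        "(%d genes x (%d bp gene + %d bp gap) = %d bp) exceeds contig length"),
        k, L, k, min_len, gap_range[1], min_need))
    }
    starts <- integer(k); ends <- integer(k)
    cursor <- sample(gap_range[1]:gap_range[2], 1L)
    for (j in seq_len(k)) {
      len <- 3L * sample(gene_length_range[1]:gene_length_range[2], 1L)
      # shrink if remaining genes would not fit
      remaining <- (k - j) * (min_len + gap_range[1])
      if (cursor + len + remaining > L) {
        len <- max(min_len, 3L * ((L - cursor - remaining) %/% 3L))
        if (cursor + len + remaining > L) len <- min_len
      }
      starts[j] <- cursor
      ends[j] <- cursor + len
      gap <- sample(gap_range[1]:gap_range[2], 1L)
      cursor <- ends[j] + gap
      if (cursor > L && j < k) {
        stop(sprintf("gene placement overflow on contig %s (gene %d of %d)",
                     contig_ids[ci], j + 1L, k))
      }
    }
    genes[[ci]] <- data.table(
      gene_id = sprintf("gene_%04d", gi + seq_len(k)),
      contig = contig_ids[ci],
      start = starts, end = ends,
      strand = sample(c("+", "-"), k, replace = TRUE),
      category = sample(names(category_probs), k, replace = TRUE,
                        prob = category_probs)
    )
    gi <- gi + k
  }
  genes <- if (gi > 0) rbindlist(genes) else
    data.table(gene_id = character(), contig = character(),
               start = integer(), end = integer(),
               strand = character(), category = character())
  ref <- structure(list(contigs = contigs, genes = genes),
                   class = "ref_genome")
  validate_reference(ref)
  ref
}

#' Validate a reference genome object
#'
#' Checks that contigs are non-empty, gene intervals lie within their contig
#' and coding genes have lengths divisible by 3.
#'
#' @param ref A `ref_genome` object.
#' @return `ref`, invisibly; errors on violation.
#' @export
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "ref_genome"))
  if (any(nchar(ref$contigs) == 0)) stop("empty contig sequence")
  g <- ref$genes
  if (nrow(g)) {
    if (any(g$start >= g$end)) stop("gene with start >= end")
    clen <- nchar(ref$contigs)[g$contig]
    if (any(is.na(clen)) || any(g$end > clen))
      stop("gene interval outside contig bounds")
    if (any((g$end - g$start) %% 3L != 0L))
      stop("coding gene length not divisible by 3")
  }
  invisible(ref)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("ref_genome: %d contig(s), %s bp total, %d gene(s)\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Write a reference genome to FASTA
#'
#' @param ref A `ref_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_ref_fasta <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Write gene annotations to GFF3
#'
#' Emits CDS features with 1-based inclusive coordinates per the GFF3
#' standard.
#'
#' @param ref A `ref_genome`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(ref, path) {
  g <- ref$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  gr$type <- "CDS"
  gr$source <- "micropopgen"
  gr$phase <- 0L
  gr$ID <- g$gene_id
  gr$category <- g$category
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Converts to the 0-based half-open convention used internally.
#'
#' @param path GFF3 path.
#' @return A `data.table` of gene annotations.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  data.table(
    gene_id = as.character(meta$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = if ("category" %in% names(meta))
      as.character(meta$category) else NA_character_
  )
}

#' Write gene calls as a Prodigal-style TSV
#'
#' Columns: gene_id, contig, begin (1-based), end (inclusive), strand (1/-1),
#' category.
#'
#' @param ref A `ref_genome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genes_tsv <- function(ref, path) {
  g <- ref$genes
  out <- data.table(gene_id = g$gene_id, contig = g$contig,
                    begin = g$start + 1L, end = g$end,
                    strand = ifelse(g$strand == "+", 1L, -1L),
                    category = g$category)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference genome from FASTA plus gene annotations
#'
#' @param fasta_path FASTA path.
#' @param gff_path Optional GFF3 path with gene calls.
#' @return A `ref_genome`.
#' @export
read_reference <- function(fasta_path, gff_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- as.character(seqs)
  names(contigs) <- sub("\\s.*$", "", names(seqs))
  genes <- if (is.null(gff_path)) {
    data.table(gene_id = character(), contig = character(),
               start = integer(), end = integer(),
               strand = character(), category = character())
  } else read_genes_gff3(gff_path)
  structure(list(contigs = contigs, genes = genes), class = "ref_genome")
}
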