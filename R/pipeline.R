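#' Build a pipeline run configuration
#'
#' Collects every threshold of the analysis with defaults equal to the
#' study's printed values: read-pair span 1500 bp, combined identity 0.96,
#' MAPQ > 1, inclusion breadth 0.5 at 5x, per-site depth 5, base quality 30,
#' error rate 1e-4, null-model FPR 1e-6, MAF 0.05, 30 spanning read pairs,
#' F_ST site coverage 20x per block, gene coverage exclusion 2 SD, 5-gene
#' scan window at 2.5 SD, alpha 0.05.
#'
#' @param outdir Output directory.
#' @param seed Integer seed for every stochastic step.
#' @param paths Optional named list of input paths (`reference` FASTA,
#'   `genes` GFF3, `alignments` directory of per-sample SAM/BAM named
#'   `<sample_id>.sam`, `metadata` TSV). Ignored when `simulate` is set.
#' @param simulate Optional named list of simulation parameters
#'   (`n_contigs`, `contig_length`, `n_genes`, `n_sites`, `rho_sim`,
#'   `n_haplotypes`, `n_blocks`, `fst_target`, `n_samples`,
#'   `coverage_per_sample`, ...); when non-NULL the pipeline generates its
#'   own inputs.
#' @param ... Threshold overrides (see Details).
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(outdir, seed = 1, paths = NULL, simulate = NULL,
                       ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    paths = paths, simulate = simulate,
    max_span = 1500L, min_identity = 0.96, min_mapq = 1L,
    min_breadth = 0.5, breadth_depth = 5L,
    min_depth = 5L, min_baseq = 30L,
    error_rate = 1e-4, fpr = 1e-6, maf = 0.05,
    min_pairs = 30L, fst_min_cov = 20L, coverage_sd_k = 2,
    window = 5L, k_sd = 2.5, alpha = 0.05)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$max_span > 0, cfg$min_identity >= 0, cfg$min_identity <= 1,
            cfg$min_breadth >= 0, cfg$min_breadth <= 1,
            cfg$min_depth >= 1, cfg$min_baseq >= 0,
            cfg$error_rate > 0, cfg$error_rate < 1,
            cfg$fpr > 0, cfg$fpr <= 1, cfg$maf >= 0, cfg$maf <= 1,
            cfg$min_pairs >= 1, cfg$fst_min_cov >= 2,
            cfg$window >= 2, cfg$k_sd > 0, cfg$alpha > 0, cfg$alpha < 1)
  invisible(cfg)
}

#' Write / read a run configuration as YAML
#'
#' The configuration round-trips unchanged.
#'
#' @param cfg A `run_config`.
#' @param path YAML path.
#' @return `path` / a `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  int_fields <- c("seed", "max_span", "min_mapq", "breadth_depth",
                  "min_depth", "min_baseq", "min_pairs", "fst_min_cov",
                  "window")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  structure(cfg, class = "run_config")
}

default_sim_params <- function() {
  list(n_contigs = 1L, contig_length = 30000L, n_genes = 25L,
       n_sites = 300L, rho_sim = 5, n_haplotypes = 60L,
       n_blocks = 2L, fst_target = 0.1, n_samples = 8L,
       coverage_per_sample = 15, read_length = 200L,
       error_rate = 1e-4, low_q_fraction = 0.02, decoy_fraction = 0.01,
       sweeps = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> filter -> profile -> call-snps ->
#' linkage -> fst-scan, writing stage outputs as TSV under
#' `config$outdir` and returning the in-memory results plus a run report
#' whose record counts reconcile across stages. Identical config and seed
#' produce byte-identical outputs.
#'
#' @param config A `run_config`.
#' @return Invisible list with elements `ref`, `plan`, `filtered`,
#'   `filter_report`, `pileups`, `gene_stats`, `snps`, `linkage`,
#'   `gene_fst`, `candidates`, `sweeps`, `report`.
#' @export
run_all <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  # ---- stage 0: inputs ----
  if (!is.null(cfg$simulate)) {
    sp <- default_sim_params()
    sp[names(cfg$simulate)] <- cfg$simulate
    ref <- make_reference(sp$n_contigs, sp$contig_length, sp$n_genes,
                          seed = cfg$seed)
    pool <- make_population(ref, sp$n_sites, rho_sim = sp$rho_sim,
                            n_haplotypes = sp$n_haplotypes,
                            seed = cfg$seed + 1L)
    pool <- apply_block_structure(pool, sp$n_blocks, sp$fst_target,
                                  seed = cfg$seed + 2L)
    if (!is.null(sp$sweeps)) {
      for (sw in sp$sweeps) {
        pool <- implant_sweep(pool, ref, sw$gene_ids, sw$block,
                              sw$strength)
      }
    }
    plan <- make_sample_plan(sp$n_samples, blocks = pool$blocks)
    sim <- simulate_reads(pool, ref, plan,
                          coverage_per_sample = sp$coverage_per_sample,
                          read_length = sp$read_length,
                          error_rate = sp$error_rate,
                          low_q_fraction = sp$low_q_fraction,
                          decoy_fraction = sp$decoy_fraction,
                          max_span = cfg$max_span,
                          seed = cfg$seed + 3L)
    indir <- file.path(cfg$outdir, "inputs")
    dir.create(indir, showWarnings = FALSE)
    write_ref_fasta(ref, file.path(indir, "reference.fasta"))
    write_genes_gff3(ref, file.path(indir, "genes.gff3"))
    write_metadata(plan, file.path(indir, "metadata.tsv"))
    for (sid in names(sim$samples)) {
      write_sam(sim$samples[[sid]], ref,
                file.path(indir, paste0(sid, ".sam")))
    }
    write_truth(sim$truth, file.path(cfg$outdir, "truth"))
    raw <- sim$samples
  } else {
    if (is.null(cfg$paths)) stop("config needs either $simulate or $paths")
    need <- c("reference", "genes", "alignments", "metadata")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "))
    ref <- read_reference(cfg$paths$reference, cfg$paths$genes)
    plan <- as.data.table(read.table(cfg$paths$metadata, header = TRUE,
                                     sep = "\t",
                                     stringsAsFactors = FALSE))
    need_cols <- c("sample_id", "plot", "block", "depth", "replicate")
    miss <- setdiff(need_cols, names(plan))
    if (length(miss)) stop("metadata is missing column(s): ",
                           paste(miss, collapse = ", "))
    raw <- lapply(plan$sample_id, function(sid) {
      f <- file.path(cfg$paths$alignments, paste0(sid, ".sam"))
      if (!file.exists(f)) {
        f <- file.path(cfg$paths$alignments, paste0(sid, ".bam"))
      }
      if (!file.exists(f)) stop("no alignment file for sample ", sid)
      read_pairs_sam(f, sample_id = sid)
    })
    names(raw) <- plan$sample_id
  }

  # ---- stage 1: filter ----
  filtered <- list()
  reports <- list()
  for (sid in names(raw)) {
    fr <- filter_pairs(raw[[sid]], max_span = cfg$max_span,
                       min_identity = cfg$min_identity,
                       min_mapq = cfg$min_mapq)
    filtered[[sid]] <- fr$pairs
    reports[[sid]] <- cbind(data.table(sample_id = sid), fr$report)
  }
  filter_report <- rbindlist(reports)
  write.table(filter_report, file.path(cfg$outdir, "filter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  breadth <- data.table(
    genome = "reference",
    sample_id = names(filtered),
    breadth = vapply(filtered, function(p)
      breadth_at_depth(p, ref, cfg$breadth_depth), numeric(1)))
  keep <- select_genome_samples(breadth, cfg$min_breadth)
  filtered <- filtered[names(filtered) %in% keep$included$sample_id]
  write.table(breadth, file.path(cfg$outdir, "breadth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- stage 2: profile ----
  pileups <- lapply(filtered, build_pileup, ref = ref,
                    min_baseq = cfg$min_baseq)
  plan_used <- plan[plan$sample_id %in% names(pileups)]
  by_block <- pool_by_level(pileups, plan_used, "block")
  meadow <- pool_by_level(pileups, plan_used, "meadow")[["meadow"]]

  gene_stats <- rbindlist(c(
    lapply(names(pileups), function(sid)
      cbind(scale = "sample", group = sid,
            gene_diversity(pileups[[sid]], ref$genes, cfg$min_depth))),
    lapply(names(by_block), function(b)
      cbind(scale = "block", group = b,
            gene_diversity(by_block[[b]], ref$genes, cfg$min_depth))),
    list(cbind(scale = "meadow", group = "meadow",
               gene_diversity(meadow, ref$genes, cfg$min_depth)))))
  write.table(gene_stats, file.path(cfg$outdir, "gene_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_pileup_tsv(meadow, file.path(cfg$outdir, "pileup_meadow.tsv"))

  # ---- stage 3: SNPs ----
  snps <- call_snps(meadow, ref, eps = cfg$error_rate, alpha = cfg$fpr,
                    maf = cfg$maf)
  write_snps_tsv(snps, file.path(cfg$outdir, "snps.tsv"))

  # ---- stage 4: linkage ----
  all_pairs <- rbindlist(filtered)
  phc <- extract_pair_haplotypes(all_pairs, snps,
                                 min_base_quality = cfg$min_baseq,
                                 min_pairs = cfg$min_pairs)
  lrec <- linkage_stats(phc)
  write_linkage_tsv(lrec, file.path(cfg$outdir, "linkage.tsv"))

  # ---- stage 5: F_ST scan + sweep confirmation ----
  blocks <- sort(names(by_block))
  gene_fst_all <- list()
  sweeps <- list()
  candidates <- list()
  gene_pi_by_block <- rbindlist(lapply(names(by_block), function(b) {
    gd <- gene_diversity(by_block[[b]], ref$genes, cfg$min_depth)
    data.table(gene_id = gd$gene_id, block = b, pi = gd$pi)
  }))
  if (length(blocks) >= 2) {
    for (i in seq_len(length(blocks) - 1L)) {
      for (j in (i + 1L):length(blocks)) {
        bp <- paste(blocks[i], blocks[j], sep = "-")
        gf <- gene_fst(snps, by_block[[blocks[i]]], by_block[[blocks[j]]],
                       ref$genes, min_cov = cfg$fst_min_cov,
                       coverage_sd_k = cfg$coverage_sd_k)
        gf$block_pair <- bp
        gene_fst_all[[bp]] <- gf
        cand <- tryCatch(
          window_scan(gf, window = cfg$window, k_sd = cfg$k_sd),
          error = function(e) NULL)
        if (is.null(cand) || !nrow(cand)) next
        cand$block_pair <- bp
        candidates[[bp]] <- cand
        sw <- confirm_sweeps(cand, lrec, gene_pi_by_block,
                             alpha = cfg$alpha)
        sw$block_pair <- bp
        sweeps[[bp]] <- sw
      }
    }
  }
  gene_fst_all <- if (length(gene_fst_all)) rbindlist(gene_fst_all) else
    data.table()
  candidates <- if (length(candidates)) rbindlist(candidates) else
    data.table()
  sweeps <- if (length(sweeps)) rbindlist(sweeps, fill = TRUE) else
    data.table()
  write.table(gene_fst_all, file.path(cfg$outdir, "gene_fst.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sweeps, file.path(cfg$outdir, "sweep_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- report ----
  cfg_file <- file.path(cfg$outdir, "config.yaml")
  write_config(cfg, cfg_file)
  # canonical hash: configuration content without machine-specific paths
  canon <- unclass(cfg)
  canon$outdir <- NULL
  canon$paths <- NULL
  canon_file <- tempfile()
  yaml::write_yaml(canon, canon_file)
  report <- list(
    version = as.character(utils::packageVersion("micropopgen")),
    config_md5 = unname(tools::md5sum(canon_file)),
    n_samples = length(raw),
    n_pairs_total = sum(filter_report$total),
    n_pairs_pass = sum(filter_report$pass),
    n_samples_included = keep$n_included,
    n_candidates_evaluated = keep$n_candidates,
    n_snps = nrow(snps),
    n_linkage_records = nrow(lrec),
    n_candidate_loci = if (nrow(candidates)) nrow(candidates) else 0L,
    n_confirmed_sweeps = if (nrow(sweeps)) sum(sweeps$confirmed) else 0L,
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0,
                                            units = "secs")), 2))
  yaml::write_yaml(report[names(report) != "elapsed_sec"],
                   file.path(cfg$outdir, "run_report.yaml"))
  message(sprintf(
    "run_all: %d/%d pairs passed filters; %d SNPs; %d linkage records; %d candidate loci; %d confirmed sweeps",
    report$n_pairs_pass, report$n_pairs_total, report$n_snps,
    report$n_linkage_records, report$n_candidate_loci,
    report$n_confirmed_sweeps))
  invisible(list(ref = ref, plan = plan, filtered = filtered,
                 filter_report = filter_report, breadth = breadth,
                 pileups = pileups, by_block = by_block, meadow = meadow,
                 gene_stats = gene_stats, snps = snps, linkage = lrec,
                 gene_fst = gene_fst_all, candidates = candidates,
                 sweeps = sweeps, report = report))
}

#' Write a per-site pileup TSV (1-based positions)
#'
#' @param pileup A `pileup`.
#' @param path Output path.
#' @param drop_zero Skip zero-coverage positions (default TRUE).
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path, drop_zero = TRUE) {
  rows <- lapply(names(pileup$counts), function(cid) {
    m <- pileup$counts[[cid]]
    dt <- data.table(contig = cid, pos = seq_len(nrow(m)),
                     A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4])
    if (drop_zero) dt <- dt[dt$A + dt$C + dt$G + dt$T > 0]
    dt
  })
  write.table(rbindlist(rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
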