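test_that("Hudson per-site components match their closed forms", {
  # fixed difference: F_ST = 1 regardless of n
  h <- hudson_site_fst(1, 100, 0, 50)
  expect_equal(h$num, 1)
  expect_equal(h$den, 1)

  # identical intermediate frequencies: small negative numerator
  h <- hudson_site_fst(0.5, 100, 0.5, 100)
  expect_equal(h$num, -2 * 0.25 / 99)
  expect_equal(h$den, 0.5)

  # strong differentiation example
  h <- hudson_site_fst(0.8, 100, 0.2, 100)
  expect_equal(h$num, 0.36 - 2 * 0.16 / 99)
  expect_equal(h$den, 0.8 * 0.8 + 0.2 * 0.2)
  expect_equal(h$num / h$den, 0.5247, tolerance = 1e-4)

  # n <= 1 is undefined
  h <- hudson_site_fst(0.5, 1, 0.5, 100)
  expect_true(is.na(h$num))
})

test_that("per-gene F_ST is a ratio of averages, not an average of ratios", {
  # sites with numerators (0.3, -0.1), denominators (0.5, 0.5):
  # ratio of averages = 0.2; mean of ratios would be 0.2 vs 0.25 average
  expect_equal(sum(c(0.3, -0.1)) / sum(c(0.5, 0.5)), 0.2)

  # construct a two-gene pileup pair where the arithmetic is checkable
  ref <- structure(list(
    contigs = c(c1 = strrep("A", 60)),
    genes = data.table::data.table(
      gene_id = c("g1", "g2"), contig = "c1", start = c(0L, 30L),
      end = c(30L, 60L), strand = "+", category = "other")),
    class = "ref_genome")
  mkp <- function(freqs, depth = 100L) {
    m <- matrix(0L, 60, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    m[, 1] <- depth
    for (i in seq_along(freqs)) {
      alt <- as.integer(round(freqs[i] * depth))
      m[i * 10, ] <- c(depth - alt, alt, 0L, 0L)
    }
    pileup_from_counts(list(c1 = m))
  }
  # two segregating sites in g1 (pos 10, 20), one in g2 (pos 30 is in g1;
  # use 40): frequencies differ between blocks
  p1 <- mkp(c(0.5, 0.8, 0.1, 0.9))
  p2 <- mkp(c(0.5, 0.2, 0.1, 0.1))
  snps <- data.frame(contig = "c1", pos = c(9L, 19L, 29L, 39L),
                     major = "A", minor = "C")
  gf <- gene_fst(snps, p1, p2, ref$genes, min_cov = 20)
  h <- hudson_site_fst(c(0.5, 0.8, 0.1), 100, c(0.5, 0.2, 0.1), 100)
  expect_equal(gf$fst[gf$gene_id == "g1"],
               sum(h$num) / sum(h$den))
  # g2's single site (pos 39): fst = per-site ratio
  h2 <- hudson_site_fst(0.9, 100, 0.1, 100)
  expect_equal(gf$fst[gf$gene_id == "g2"], h2$num / h2$den)

  # low coverage in one block excludes sites -> gene missing
  p2low <- mkp(c(0.5, 0.2, 0.1, 0.1), depth = 10L)
  gflow <- gene_fst(snps, p1, p2low, ref$genes, min_cov = 20,
                    coverage_sd_k = 100)
  expect_true(all(is.na(gflow$fst)))
  expect_equal(gflow$n_sites, c(0L, 0L))
})

test_that("genes with aberrant coverage are excluded from the scan", {
  ref <- structure(list(
    contigs = c(c1 = strrep("A", 400)),
    genes = data.table::data.table(
      gene_id = sprintf("g%02d", 1:10), contig = "c1",
      start = seq(0L, 360L, 40L), end = seq(40L, 400L, 40L),
      strand = "+", category = "other")), class = "ref_genome")
  m <- matrix(0L, 400, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[, 1] <- 100L
  m[1:40, 1] <- 1000L  # g1 at 10x the coverage of the rest
  pu <- pileup_from_counts(list(c1 = m))
  snps <- data.frame(contig = "c1", pos = seq(5L, 395L, 40L),
                     major = "A", minor = "C")
  gf <- gene_fst(snps, pu, pu, ref$genes)
  expect_true(gf$excluded[1])
  expect_false(any(gf$excluded[-1]))
  expect_true(is.na(gf$fst[1]))
})

test_that("window scan seeds, extends and merges loci", {
  mk_track <- function(fst) data.frame(
    gene_id = sprintf("g%03d", seq_along(fst)), contig = "c1",
    start = seq_along(fst) * 100L, fst = fst)

  # flat track: no candidates
  set.seed(60)
  flat <- mk_track(rnorm(200, 0.02, 0.01))
  expect_equal(nrow(window_scan(flat)), 0L)

  # 6-gene block at 0.5 over a low background: one locus spanning >= 6
  tr <- mk_track(c(rnorm(100, 0.02, 0.01), rep(0.5, 6),
                   rnorm(94, 0.02, 0.01)))
  cand <- window_scan(tr)
  expect_equal(nrow(cand), 1L)
  expect_gte(cand$n_genes, 6L)
  expect_true(all(sprintf("g%03d", 101:106) %in%
                    strsplit(cand$gene_ids, ",")[[1]]))

  # two implanted loci 50 genes apart: two loci, not merged
  tr2 <- mk_track(c(rnorm(60, 0.02, 0.01), rep(0.6, 6),
                    rnorm(50, 0.02, 0.01), rep(0.6, 6),
                    rnorm(78, 0.02, 0.01)))
  cand2 <- window_scan(tr2)
  expect_equal(nrow(cand2), 2L)

  # genes without F_ST are skipped in window composition
  tr3 <- mk_track(c(rnorm(100, 0.02, 0.01), rep(0.5, 6),
                    rnorm(94, 0.02, 0.01)))
  tr3$fst[103] <- NA
  cand3 <- window_scan(tr3)
  expect_equal(nrow(cand3), 1L)
  expect_false("g103" %in% strsplit(cand3$gene_ids, ",")[[1]])

  # fewer genes than the window on a contig: warning, no crash
  expect_warning(window_scan(mk_track(c(0.1, 0.2, 0.9))), "fewer than")
})

test_that("sweep confirmation requires both linkage and diversity signals", {
  set.seed(61)
  n_genes <- 120
  genes <- sprintf("g%03d", 1:n_genes)
  locus <- genes[51:56]
  cand <- data.frame(locus_id = "locus_01",
                     gene_ids = paste(locus, collapse = ","),
                     mean_fst = 0.5, threshold = 0.1)
  # linkage records: elevated r2 inside the locus
  lr_in <- data.frame(n_AB = 28L, n_Ab = 1L, n_aB = 1L, n_ab = 20L,
                      gene_id1 = rep(locus, each = 10))
  bg_tabs <- data.frame(n_AB = rbinom(400, 15, 0.5) + 5L,
                        n_Ab = rbinom(400, 10, 0.5) + 2L,
                        n_aB = rbinom(400, 10, 0.5) + 2L,
                        n_ab = rbinom(400, 15, 0.5) + 5L,
                        gene_id1 = sample(setdiff(genes, locus), 400,
                                          TRUE))
  lrec <- linkage_stats(rbind(lr_in, bg_tabs))
  # diversity: pi collapses in block B1 inside the locus
  gpb <- rbind(
    data.frame(gene_id = genes, block = "B1",
               pi = ifelse(genes %in% locus, 0.0005,
                           rnorm(n_genes, 0.02, 0.004))),
    data.frame(gene_id = genes, block = "B2",
               pi = rnorm(n_genes, 0.02, 0.004)))
  sw <- confirm_sweeps(cand, lrec, gpb)
  expect_true(sw$confirmed)
  expect_equal(sw[["dir_pi_B1"]], "decrease")

  # coverage-artifact decoy: high F_ST but background linkage and pi
  lrec_null <- linkage_stats(bg_tabs)
  lrec_null$gene_id1 <- sample(genes, nrow(lrec_null), TRUE)
  gpb_null <- rbind(
    data.frame(gene_id = genes, block = "B1",
               pi = rnorm(n_genes, 0.02, 0.004)),
    data.frame(gene_id = genes, block = "B2",
               pi = rnorm(n_genes, 0.02, 0.004)))
  sw2 <- confirm_sweeps(cand, lrec_null, gpb_null)
  expect_false(sw2$confirmed)

  # locus without linkage records is unconfirmable with a reason
  lrec_out <- lrec[!(lrec$gene_id1 %in% locus), ]
  sw3 <- confirm_sweeps(cand, lrec_out, gpb)
  expect_false(sw3$confirmed)
  expect_match(sw3$reason, "no linkage records")
})

test_that("per-gene ratio-of-averages F_ST recovers the simulated target", {
  ref <- make_reference(1, 80000, 100, seed = 62, gap_range = c(20L, 60L))
  vals <- vapply(1:3, function(sd) {
    pool <- make_population(ref, 1500, rho_sim = 1500, n_haplotypes = 200,
                            seed = 70 + sd)
    pool <- apply_block_structure(pool, 2, 0.2, seed = 80 + sd)
    bc <- sample_block_counts(pool, ref, depth = 100, seed = 90 + sd)
    snps <- call_snps(pool_counts(bc), maf = 0)
    gf <- gene_fst(snps, bc$B1, bc$B2, ref$genes)
    mean(gf$fst, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.2), 0.03)
})
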