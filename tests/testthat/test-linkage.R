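test_that("linkage statistics match their closed forms", {
  r <- linkage_stats(data.frame(n_AB = 25, n_Ab = 0, n_aB = 0, n_ab = 25))
  expect_equal(r$D, 0.25)
  expect_equal(r$r2, 1)
  expect_equal(r$Dprime, 1)
  expect_false(r$four_haplotypes)

  r <- linkage_stats(data.frame(n_AB = 25, n_Ab = 25, n_aB = 25,
                                n_ab = 25))
  expect_equal(r$D, 0)
  expect_equal(r$r2, 0)
  expect_equal(r$Dprime, 0)
  expect_true(r$four_haplotypes)

  r <- linkage_stats(data.frame(n_AB = 40, n_Ab = 10, n_aB = 10,
                                n_ab = 40))
  expect_equal(r$p_A, 0.5)
  expect_equal(r$p_B, 0.5)
  expect_equal(r$D, 0.15)
  expect_equal(r$r2, 0.36)
  expect_equal(r$Dprime, 0.6)
  expect_true(r$four_haplotypes)

  # monomorphic tables are dropped
  expect_equal(nrow(linkage_stats(
    data.frame(n_AB = 30, n_Ab = 0, n_aB = 30, n_ab = 0))), 0L)
})

test_that("r2 and Dprime are invariant under allele relabeling", {
  set.seed(12)
  for (i in 1:200) {
    x <- as.integer(rmultinom(1, 40, runif(4, 0.05, 1)))
    t0 <- data.frame(n_AB = x[1], n_Ab = x[2], n_aB = x[3], n_ab = x[4])
    # swap alleles at site 1: rows exchange; at site 2: columns exchange
    t1 <- data.frame(n_AB = x[3], n_Ab = x[4], n_aB = x[1], n_ab = x[2])
    t2 <- data.frame(n_AB = x[2], n_Ab = x[1], n_aB = x[4], n_ab = x[3])
    r0 <- linkage_stats(t0); r1 <- linkage_stats(t1)
    r2_ <- linkage_stats(t2)
    if (nrow(r0)) {
      expect_equal(r0$r2, r1$r2)
      expect_equal(r0$Dprime, r1$Dprime)
      expect_equal(r0$r2, r2_$r2)
      expect_equal(r0$Dprime, r2_$Dprime)
    }
  }
})

test_that("read-pair haplotype extraction enforces quality and pair rules", {
  # two SNP sites 100 bp apart; construct reads covering both
  ref <- make_reference(1, 1000, 0, seed = 1)
  base1 <- substr(ref$contigs[[1]], 101, 101)
  base2 <- substr(ref$contigs[[1]], 201, 201)
  alt <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  snps <- data.frame(contig = "contig_1", pos = c(100L, 200L),
                     major = c(base1, base2),
                     minor = c(alt(base1), alt(base2)))
  mk_read <- function(id, b1, b2, lowq = FALSE) {
    seq <- substr(ref$contigs[[1]], 51, 250)
    substr(seq, 51, 51) <- b1
    substr(seq, 151, 151) <- b2
    q <- strrep("F", 200)
    if (lowq) substr(q, 51, 51) <- "5"  # Q20 at site 1
    mk_pair(id, contig = "contig_1", start1 = 50L, len1 = 200L,
            start2 = 700L, len2 = 200L, seq1 = seq, qual1 = q,
            seq2 = substr(ref$contigs[[1]], 701, 900),
            qual2 = strrep("F", 200))
  }
  # 35 informative pairs: mixture of coupling haplotypes
  pairs <- data.table::rbindlist(c(
    lapply(1:20, function(i) mk_read(paste0("a", i), base1, base2)),
    lapply(1:15, function(i) mk_read(paste0("b", i), alt(base1),
                                     alt(base2)))))
  phc <- extract_pair_haplotypes(pairs, snps, min_pairs = 30)
  expect_equal(nrow(phc), 1L)
  expect_equal(phc$n, 35L)
  expect_equal(phc$n_AB, 20L)
  expect_equal(phc$n_ab, 15L)
  expect_equal(phc$distance, 100L)

  # 29 spanning pairs -> dropped (strict "at least 30")
  phc29 <- extract_pair_haplotypes(pairs[1:29], snps, min_pairs = 30)
  expect_equal(nrow(phc29), 0L)

  # low-quality base at one site excludes that observation
  pairs_q <- data.table::rbindlist(c(
    lapply(1:30, function(i) mk_read(paste0("a", i), base1, base2)),
    lapply(1:5, function(i) mk_read(paste0("q", i), base1, base2,
                                    lowq = TRUE))))
  phc_q <- extract_pair_haplotypes(pairs_q, snps, min_pairs = 30)
  expect_equal(phc_q$n, 30L)

  # a third allele at a site excludes the read from the 2x2 table
  third <- setdiff(c("A", "C", "G", "T"), c(base1, alt(base1)))[1]
  pairs_t <- data.table::rbindlist(c(
    lapply(1:30, function(i) mk_read(paste0("a", i), base1, base2)),
    lapply(1:5, function(i) mk_read(paste0("t", i), third, base2))))
  phc_t <- extract_pair_haplotypes(pairs_t, snps, min_pairs = 30)
  expect_equal(phc_t$n, 30L)
})

test_that("linkage decay is flat for clones and decreases with rho", {
  ref <- make_reference(1, 20000, 15, seed = 50)
  # clonal: r2 = 1 at all distances, no four-haplotype pairs
  pool0 <- make_population(ref, 100,
                           maf_distribution = function(n) rep(0.4, n),
                           rho_sim = 0, n_haplotypes = 50, seed = 51)
  lr0 <- linkage_stats(sample_pair_haplotypes(pool0, ref, n_obs = 40,
                                              seed = 52))
  dec0 <- linkage_decay(lr0, bin_width = 100)
  expect_true(all(abs(dec0$mean_r2 - 1) < 1e-12))
  expect_equal(four_haplotype_fraction(lr0), 0)

  # genome-mean r2 decreases monotonically across a rho gradient
  means <- vapply(c(0, 2, 10, 50, 1e5), function(rho) {
    pool <- make_population(ref, 100,
                            maf_distribution = function(n) rep(0.4, n),
                            rho_sim = rho, n_haplotypes = 80, seed = 53)
    lr <- linkage_stats(sample_pair_haplotypes(pool, ref, n_obs = 60,
                                               seed = 54))
    mean(lr$r2)
  }, numeric(1))
  expect_true(all(diff(means) < 0))

  # free recombination at balanced frequencies: nearly all site pairs
  # show all four haplotypes at n >= 30
  poolF <- make_population(ref, 100,
                           maf_distribution = function(n) rep(0.5, n),
                           rho_sim = 1e6, n_haplotypes = 200, seed = 55)
  lrF <- linkage_stats(sample_pair_haplotypes(poolF, ref, n_obs = 60,
                                              seed = 56))
  expect_gt(four_haplotype_fraction(lrF), 0.95)
})

test_that("effect stratification computes class means and ratios", {
  rec <- data.frame(
    n_AB = c(30, 30, 30), n_Ab = c(0, 10, 5), n_aB = c(0, 10, 5),
    n_ab = c(30, 30, 30),
    effect1 = c("nonsynonymous", "synonymous", "nonsynonymous"),
    effect2 = c("nonsynonymous", "synonymous", "synonymous"))
  lr <- linkage_stats(rec)
  st <- stratify_by_effect(lr)
  expect_equal(st$by_class$n, c(1L, 1L, 1L))
  expect_equal(st$ratios$r2_NN_over_SS,
               lr$r2[1] / lr$r2[2])
  # all-synonymous input: NN class empty, ratio flagged NA
  st2 <- stratify_by_effect(lr[2, ])
  expect_true(is.na(st2$ratios$r2_NN_over_SS))

  # permuting labels on identically-distributed records gives ratio ~ 1
  set.seed(57)
  n <- 400
  tabs <- data.frame(n_AB = rbinom(n, 20, 0.5) + 5L,
                     n_Ab = rbinom(n, 10, 0.5),
                     n_aB = rbinom(n, 10, 0.5),
                     n_ab = rbinom(n, 20, 0.5) + 5L)
  tabs$effect1 <- sample(c("synonymous", "nonsynonymous"), n, TRUE)
  tabs$effect2 <- sample(c("synonymous", "nonsynonymous"), n, TRUE)
  st3 <- stratify_by_effect(linkage_stats(tabs))
  expect_lt(abs(st3$ratios$r2_NN_over_SS - 1), 0.25)
})
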