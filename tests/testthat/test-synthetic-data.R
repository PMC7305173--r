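test_that("reference generation is deterministic and respects invariants", {
  r1 <- make_reference(1, 30000, 25, seed = 1)
  r2 <- make_reference(1, 30000, 25, seed = 1)
  expect_identical(r1$contigs, r2$contigs)
  expect_identical(as.data.frame(r1$genes), as.data.frame(r2$genes))
  expect_equal(nrow(r1$genes), 25)

  # gene-free contig
  r0 <- make_reference(1, 300, 0, seed = 0)
  expect_equal(nrow(r0$genes), 0)
  expect_equal(nchar(r0$contigs), c(contig_1 = 300L))

  # two contigs: genes on both, all intervals within bounds, no overlap
  r <- make_reference(2, 15000, 12, seed = 7)
  expect_setequal(unique(r$genes$contig), c("contig_1", "contig_2"))
  expect_true(all(r$genes$start < r$genes$end))
  expect_true(all(r$genes$end <= nchar(r$contigs)[r$genes$contig]))
  expect_true(all((r$genes$end - r$genes$start) %% 3 == 0))
  expect_setequal(unique(r$genes$strand), c("+", "-"))
  g <- r$genes[order(r$genes$contig, r$genes$start), ]
  same <- g$contig[-1] == g$contig[-nrow(g)]
  expect_true(all(g$start[-1][same] >= g$end[-nrow(g)][same]))

  # impossible placement names the constraint
  expect_error(make_reference(1, 1000, 50, seed = 1), "cannot place")
})

test_that("clonal populations are two-clone and fully linked", {
  ref <- make_reference(1, 5000, 4, seed = 2)
  pool <- make_population(ref, 40,
                          maf_distribution = function(n) rep(0.5, n),
                          rho_sim = 0, n_haplotypes = 50, seed = 3)
  H <- pool$haplotypes$meadow
  # every haplotype is entirely founder 0 or founder 1
  expect_true(all(rowSums(H) %in% c(0L, ncol(H))))
  # every site pair: at most 2 observed classes, r^2 = 1 where polymorphic
  phc <- sample_pair_haplotypes(pool, ref, n_obs = 50, seed = 4)
  lr <- linkage_stats(phc)
  expect_true(all(!lr$four_haplotypes))
  expect_true(all(abs(lr$r2 - 1) < 1e-12))
})

test_that("free recombination matches independent-draw oracle", {
  ref <- make_reference(1, 5000, 4, seed = 2)
  pool <- make_population(ref, 50,
                          maf_distribution = function(n) rep(0.3, n),
                          rho_sim = 1e6, n_haplotypes = 400, seed = 5)
  H <- pool$haplotypes$meadow
  # realized per-site frequency ~ Binomial(n_haplotypes, 0.3)
  f <- colMeans(H)
  se <- sqrt(0.3 * 0.7 / 400)
  expect_true(all(abs(f - 0.3) < 4 * se))
  # mean r^2 across pairs approaches the finite-sample floor of truly
  # independent draws (brute-force oracle with the same geometry)
  lr <- linkage_stats(sample_pair_haplotypes(pool, ref, n_obs = 100,
                                             seed = 6))
  set.seed(7)
  oracle <- replicate(2000, {
    a <- rbinom(100, 1, 0.3); b <- rbinom(100, 1, 0.3)
    n11 <- sum(a & b); pA <- mean(a); pB <- mean(b)
    D <- n11 / 100 - pA * pB
    den <- pA * (1 - pA) * pB * (1 - pB)
    if (den > 0) D^2 / den else NA_real_
  })
  expect_lt(abs(mean(lr$r2) - mean(oracle, na.rm = TRUE)), 0.01)
})

test_that("block structure calibrates Hudson F_ST to its target", {
  ref <- make_reference(1, 60000, 10, seed = 8, gap_range = c(20L, 40L),
                        gene_length_range = c(400L, 600L))
  # fst_target = 0: identical block frequencies; reads drawn from the
  # shared frequencies give a Hudson numerator with mean ~ 0 (the
  # correction removes read-sampling noise exactly)
  pool0 <- make_population(ref, 5000, rho_sim = 5000, n_haplotypes = 100,
                           seed = 9)
  pool0 <- apply_block_structure(pool0, 2, 0, seed = 10)
  expect_identical(pool0$block_freq[1, ], pool0$block_freq[2, ])
  set.seed(11)
  p <- pool0$block_freq[1, ]
  p1 <- rbinom(length(p), 100, p) / 100
  p2 <- rbinom(length(p), 100, p) / 100
  hf <- hudson_site_fst(p1, 100, p2, 100)
  se <- sd(hf$num) / sqrt(length(p))
  expect_lte(mean(hf$num), 3 * se)

  # fst_target = 0.99: many near-fixed opposite sites
  pool9 <- make_population(ref, 500, rho_sim = 500, n_haplotypes = 100,
                           seed = 12)
  pool9 <- apply_block_structure(pool9, 2, 0.99, seed = 13)
  d <- abs(pool9$block_freq[1, ] - pool9$block_freq[2, ])
  expect_gt(mean(d > 0.95), 0.3)
})

test_that("sweep implantation hits diversity, F_ST and identity limits", {
  ref <- make_reference(1, 30000, 20, seed = 14)
  g <- ref$genes[order(ref$genes$start)]
  run <- g$gene_id[6:11]
  pool <- make_population(ref, 300, rho_sim = 300, n_haplotypes = 80,
                          seed = 15)
  pool <- apply_block_structure(pool, 2, 0.05, seed = 16)

  # strength 0: identity
  p0 <- implant_sweep(pool, ref, run, "B1", 0)
  expect_identical(p0$haplotypes, pool$haplotypes)

  # strength 1: locus monomorphic in the swept block, pi = 0 there
  p1 <- implant_sweep(pool, ref, run, "B1", 1)
  tt <- truth_tables(p1, ref)
  swept_pi <- tt$gene_pi[tt$gene_pi$block == "B1" &
                           tt$gene_pi$gene_id %in% run, ]
  expect_true(all(swept_pi$pi == 0))
  expect_equal(nrow(p1$sweeps), 1L)

  # strength 0.9: locus F_ST exceeds genome mean by > 2.5 genome SD
  p9 <- implant_sweep(pool, ref, run, "B1", 0.9)
  tt9 <- truth_tables(p9, ref)
  gf <- tt9$gene_fst
  bg <- gf$fst[!(gf$gene_id %in% run)]
  locus <- mean(gf$fst[gf$gene_id %in% run], na.rm = TRUE)
  expect_gt(locus, mean(bg, na.rm = TRUE) + 2.5 * sd(bg, na.rm = TRUE))

  # non-contiguous runs are rejected
  expect_error(implant_sweep(pool, ref, g$gene_id[c(1:5, 9)], "B1", 1),
               "contiguous")
})

test_that("read simulation is deterministic and recovers truth", {
  fx <- small_sim()
  sim2 <- simulate_reads(fx$pool, fx$ref, fx$plan,
                         coverage_per_sample = 20, seed = 45,
                         decoy_fraction = 0.01)
  expect_identical(lapply(fx$sim$samples, as.data.frame),
                   lapply(sim2$samples, as.data.frame))

  # emitted bases ~ coverage * genome length (counting check)
  total_bases <- sum(vapply(fx$sim$samples, function(p)
    sum(p$len1 + p$len2), numeric(1)))
  expected <- 6 * 20 * 20000
  expect_lt(abs(total_bases - expected) / expected, 0.05)
})

test_that("error-free single-haplotype reads match reference off-site", {
  ref <- make_reference(1, 6000, 5, seed = 17)
  pool <- make_population(ref, 50, rho_sim = 0, n_haplotypes = 2,
                          maf_distribution = function(n) rep(0.5, n),
                          seed = 18)
  # collapse to one haplotype: frequencies in {0,1} afterwards
  pool$haplotypes$meadow <- pool$haplotypes$meadow[c(1, 1), ]
  plan <- make_sample_plan(1, blocks = "meadow")
  sim <- simulate_reads(pool, ref, plan, coverage_per_sample = 30,
                        error_rate = 0, low_q_fraction = 0,
                        decoy_fraction = 0, seed = 19)
  pu <- build_pileup(sim$samples[[1]], ref, min_baseq = 30)
  m <- pu$counts$contig_1
  cov <- rowSums(m)
  frac_major <- apply(m, 1, max) / cov
  expect_true(all(frac_major[cov > 0] == 1))
})

test_that("pooled observed frequencies converge to truth at high coverage", {
  ref <- make_reference(1, 5000, 4, seed = 20)
  pool <- make_population(ref, 60, rho_sim = 60, n_haplotypes = 200,
                          seed = 21)
  plan <- make_sample_plan(1, blocks = "meadow")
  sim <- simulate_reads(pool, ref, plan, coverage_per_sample = 500,
                        error_rate = 0, decoy_fraction = 0, seed = 22)
  pu <- build_pileup(sim$samples[[1]], ref)
  s <- pool$sites
  truth <- colMeans(pool$haplotypes$meadow)
  m <- pu$counts$contig_1
  cov <- rowSums(m[s$pos + 1L, , drop = FALSE])
  alt <- m[cbind(s$pos + 1L, match(s$alt_base, BASES_for_test()))]
  obs <- alt / cov
  tol <- 3 * sqrt(pmax(truth * (1 - truth), 1e-4) / cov)
  expect_true(all(abs(obs - truth) <= pmax(tol, 0.02)))
})

test_that("simulation fails loudly on impossible geometry", {
  ref <- make_reference(1, 300, 0, seed = 0)
  pool <- make_population(ref, 5, rho_sim = 0, n_haplotypes = 4, seed = 1)
  plan <- make_sample_plan(1, blocks = "meadow")
  expect_error(simulate_reads(pool, ref, plan, coverage_per_sample = 5,
                              read_length = 200, seed = 1),
               "no pair fits")
  pool2 <- make_population(ref, 5, rho_sim = 0, n_haplotypes = 4, seed = 1)
  expect_error(make_population(ref, 500, seed = 1), "exceeds genome length")
})
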