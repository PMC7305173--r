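# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# small two-block simulation exercised by several modules
small_sim <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  ref <- make_reference(1, 20000, 18, seed = 42)
  pool <- make_population(ref, 200, rho_sim = 5, n_haplotypes = 60,
                          seed = 43)
  pool <- apply_block_structure(pool, 2, 0.1, seed = 44)
  plan <- make_sample_plan(6, blocks = c("B1", "B2"))
  sim <- simulate_reads(pool, ref, plan, coverage_per_sample = 20,
                        seed = 45, decoy_fraction = 0.01)
  filtered <- lapply(sim$samples, function(p) filter_pairs(p)$pairs)
  pileups <- lapply(filtered, build_pileup, ref = ref)
  meadow <- pool_by_level(pileups, plan, "meadow")[["meadow"]]
  by_block <- pool_by_level(pileups, plan, "block")
  snps <- call_snps(meadow, ref)
  .fixture_cache$small <- list(ref = ref, pool = pool, plan = plan,
                               sim = sim, filtered = filtered,
                               pileups = pileups, meadow = meadow,
                               by_block = by_block, snps = snps)
  .fixture_cache$small
}

# hand-built aligned pair rows for filter unit tests
mk_pair <- function(read_id = "r1", contig = "c1", start1 = 0L,
                    len1 = 200L, start2 = 500L, len2 = 200L,
                    nm1 = 0L, nm2 = 0L, mapq1 = 42L, mapq2 = 42L,
                    contig2 = contig, seq1 = strrep("A", len1),
                    seq2 = strrep("A", len2),
                    qual1 = strrep("F", len1), qual2 = strrep("F", len2)) {
  data.table::data.table(
    read_id = read_id, sample_id = "s", contig = contig,
    start1 = start1, len1 = len1, seq1 = seq1, qual1 = qual1,
    mapq1 = mapq1, start2 = start2, len2 = len2, seq2 = seq2,
    qual2 = qual2, mapq2 = mapq2, contig2 = contig2, nm1 = nm1, nm2 = nm2)
}

BASES_for_test <- function() c("A", "C", "G", "T")

# derived-allele frequency at the pool's sites from a pileup
snp_freq_for_test <- function(pileup, sites) {
  vapply(seq_len(nrow(sites)), function(i) {
    m <- pileup$counts[[sites$contig[i]]]
    row <- m[sites$pos[i] + 1L, ]
    row[sites$alt_base[i]] / sum(row)
  }, numeric(1))
}

# enumerate all 2x2 haplotype tables with total n in 1..n_max
all_2x2_tables <- function(n_max) {
  g <- expand.grid(n_AB = 0:n_max, n_Ab = 0:n_max, n_aB = 0:n_max,
                   n_ab = 0:n_max)
  tot <- rowSums(g)
  g[tot >= 1 & tot <= n_max, ]
}
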