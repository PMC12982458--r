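test_that("reference generation honours the length contract and seed", {
  cfg <- sim_config(n_contigs = 2L, contig_length_bp = 5000L,
                    planted_locus_count = 2L, rng_seed = 1L)
  ref <- simulate_reference(cfg)
  expect_length(ref, 2L)
  expect_equal(unname(Biostrings::width(ref)), c(5000L, 5000L))
  expect_true(all(strsplit(as.character(ref[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))

  ref2 <- simulate_reference(cfg)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(ref, f1); write_fasta(ref2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a contig too short for one window is a configuration error", {
  expect_error(sim_config(contig_length_bp = 100L),
               class = "mnp_config_error")
})

test_that("invalid rates and counts are configuration errors", {
  expect_error(sim_config(dropout_rate = 1.5), class = "mnp_config_error")
  expect_error(sim_config(n_accessions = 0L), class = "mnp_config_error")
  cfg <- sim_config(planted_locus_count = 10000L, n_contigs = 5L)
  ref <- simulate_reference(cfg)
  expect_error(simulate_population_variants(ref, cfg),
               class = "mnp_config_error")
})

test_that("planted loci meet the construction contract", {
  cfg <- tiny_sim()
  pv <- simulate_population_variants(simulate_reference(cfg), cfg)
  loci <- pv$truth$loci
  expect_equal(nrow(loci), 10L)
  expect_true(all(loci$n_snps >= 4L))
  for (i in seq_len(nrow(loci))) {
    pos <- as.integer(strsplit(loci$snp_pos[i], ",")[[1]])
    expect_lte(max(pos) - min(pos) + 1L, 300L)
    expect_true(all(pos >= loci$amplicon_start[i] & pos <= loci$amplicon_end[i]))
    len <- loci$amplicon_end[i] - loci$amplicon_start[i] + 1L
    expect_gte(len, 200L); expect_lte(len, 300L)
    expect_lte(loci$amplicon_end[i], cfg$contig_length_bp)
  }
  # every true allele appears in at least one accession
  seen <- unique(unlist(strsplit(pv$truth$fingerprints$alleles, ";")))
  for (l in loci$locus_id) {
    per_acc <- pv$truth$fingerprints$alleles[
      pv$truth$fingerprints$locus_id == l]
    expect_true(all(unlist(strsplit(per_acc, ";")) %in% seen))
  }
})

test_that("one founder and one cluster yields monomorphic planted loci", {
  cfg <- tiny_sim(n_founder_haplotypes = 1L, cluster_count = 1L,
                  snp_rate = 0)
  pv <- simulate_population_variants(simulate_reference(cfg), cfg)
  expect_true(all(pv$truth$loci$dp == 0))
  # and each accession carries the single founder sequence
  expect_equal(length(unique(pv$truth$fingerprints$alleles[
    pv$truth$fingerprints$locus_id == pv$truth$loci$locus_id[1]])), 1L)
})

test_that("variant generation is deterministic for a fixed seed", {
  cfg <- tiny_sim(seed = 42)
  pv1 <- simulate_population_variants(simulate_reference(cfg), cfg)
  pv2 <- simulate_population_variants(simulate_reference(cfg), cfg)
  expect_identical(pv1$variants$sites, pv2$variants$sites)
  expect_identical(pv1$variants$geno, pv2$variants$geno)
  expect_identical(pv1$truth$fingerprints, pv2$truth$fingerprints)
  f1 <- tempfile(fileext = ".vcf.gz"); f2 <- tempfile(fileext = ".vcf.gz")
  write_variants_vcf(pv1$variants, f1)
  write_variants_vcf(pv2$variants, f2)
  v1 <- read_variants_vcf(f1); v2 <- read_variants_vcf(f2)
  expect_identical(v1$sites, v2$sites)
  expect_identical(v1$geno, v2$geno)
})

test_that("planted-locus DP matches the brute-force pairwise oracle", {
  cfg <- tiny_sim(seed = 3)
  pv <- simulate_population_variants(simulate_reference(cfg), cfg)
  v <- pv$variants
  for (i in seq_len(nrow(pv$truth$loci))) {
    pos <- as.integer(strsplit(pv$truth$loci$snp_pos[i], ",")[[1]])
    idx <- which(v$sites$contig == pv$truth$loci$contig[i] &
                   v$sites$pos %in% pos)
    labs <- apply(v$geno[idx, , drop = FALSE], 2, function(g)
      haplotype_of(g, v$sites$ref[idx], v$sites$alt[idx]))
    expect_equal(pv$truth$loci$dp[i], oracle_dp(labs), tolerance = 1e-12)
  }
})

test_that("read generation honours dropout and error settings", {
  cfg <- tiny_sim(seed = 5)
  pv <- simulate_population_variants(simulate_reference(cfg), cfg)
  reads <- simulate_amplicon_reads(pv$truth, cfg)
  # dropout_rate = 0: every accession x locus cell has reads
  cells <- unique(paste(reads$accession, reads$locus_id))
  expect_equal(length(cells), 12L * 10L)
  # seq_error_rate = 0: every read is exactly a true allele sequence
  truth_key <- paste(pv$truth$fingerprints$accession,
                     pv$truth$fingerprints$locus_id)
  al <- strsplit(pv$truth$fingerprints$alleles, ";")
  ok <- mapply(function(a, l, s) {
    s %in% al[[match(paste(a, l), truth_key)]]
  }, reads$accession, reads$locus_id, reads$seq)
  expect_true(all(ok))
})

test_that("designated high-dropout accessions lose about the stated locus fraction", {
  cfg <- tiny_sim(seed = 9, n_contigs = 60L, planted_locus_count = 60L,
                  highdrop_accessions = 3L, highdrop_rate = 0.35)
  pv <- simulate_population_variants(simulate_reference(cfg), cfg)
  reads <- simulate_amplicon_reads(pv$truth, cfg)
  tp <- truth_panel(pv$truth)
  fp <- genotype_cohort(assign_reads_to_loci(reads, tp, "tagged")$assigned, tp)
  dr <- detection_rate(fp, nrow(tp))
  hi <- tail(sort(names(dr)), 3L)        # last accessions carry the high rate
  expect_true(all(abs(dr[hi] - 0.65) < 0.15))
  expect_true(all(dr[setdiff(names(dr), hi)] > 0.9))
})
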