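test_that("haplotype labels concatenate genotype symbols with IUPAC hets", {
  expect_equal(haplotype_of(c(0L, 0L, 0L, 0L),
                            c("A", "C", "G", "T"), c("G", "T", "A", "C")),
               "ACGT")
  expect_equal(haplotype_of(c(1L, 0L, 0L, 0L),
                            c("A", "C", "G", "T"), c("G", "A", "C", "A")),
               "RCGT")
  expect_true(is.na(haplotype_of(c(0L, NA, 0L, 0L),
                                 c("A", "C", "G", "T"),
                                 c("G", "T", "A", "C"))))
})

test_that("discriminative power equals the pair-enumeration oracle", {
  expect_equal(discriminative_power(rep("g", 30L)), 0.0)
  expect_equal(discriminative_power(as.character(1:30)), 1.0)
  expect_equal(discriminative_power(c("g1", "g1", "g2", "g2")), 4 / 6)
  expect_error(discriminative_power(c("g1", NA)), class = "mnp_data_error")

  set.seed(1)
  for (rep in 1:20) {
    labs <- sample(letters[1:4], 15, replace = TRUE)
    labs[sample(15, 2)] <- NA
    expect_equal(discriminative_power(labs), oracle_dp(labs),
                 tolerance = 1e-12)
  }
})

test_that("windows covering a 4-SNP cluster qualify at exactly the expected starts", {
  # SNPs at 1-based 101, 151, 201, 251 with fully distinct haplotypes
  geno <- matrix(c(0L, 0L, 0L, 0L,
                   2L, 0L, 0L, 0L,
                   0L, 2L, 0L, 0L,
                   0L, 0L, 2L, 0L,
                   0L, 0L, 0L, 2L,
                   2L, 2L, 0L, 0L), nrow = 4L)
  colnames(geno) <- sprintf("S%d", 1:6)
  v <- make_variants(pos = c(101L, 151L, 201L, 251L), geno = geno,
                     contig_len = 1000L)
  w <- scan_windows(v, screening_config())
  # window [s, s+299] holds all 4 SNPs iff s <= 101 (and s >= 1)
  expect_equal(w$window_start, 1:101)
  expect_true(all(w$n_snps == 4L))
})

test_that("exactly three SNPs in a window is not more than three", {
  geno <- matrix(rep(c(0L, 2L), each = 3L), nrow = 3L)
  geno <- cbind(geno, 1L - 0L * geno)  # 4 samples, polymorphic
  colnames(geno) <- sprintf("S%d", seq_len(ncol(geno)))
  v <- make_variants(pos = c(101L, 151L, 201L), geno = geno,
                     contig_len = 1000L)
  expect_equal(nrow(scan_windows(v, screening_config())), 0L)
})

test_that("contigs with no SNPs or shorter than the window produce nothing", {
  g <- matrix(c(0L, 2L, 0L, 2L), nrow = 1L,
              dimnames = list(NULL, sprintf("S%d", 1:4)))
  v <- make_variants(pos = 150L, geno = g, contig_len = 200L)
  expect_warning(w <- scan_windows(v, screening_config()), "shorter")
  expect_equal(nrow(w), 0L)
})

test_that("event sweep equals the brute-force all-starts oracle", {
  set.seed(42)
  for (rep in 1:4) {
    n_snp <- sample(6:14, 1)
    pos <- sort(sample(2000L, n_snp))
    geno <- matrix(sample(c(0L, 1L, 2L, NA), n_snp * 8, replace = TRUE,
                          prob = c(0.4, 0.3, 0.25, 0.05)), nrow = n_snp)
    colnames(geno) <- sprintf("S%d", 1:8)
    v <- make_variants(pos = pos, geno = geno, contig_len = 2300L)
    cfg <- screening_config(min_snps_exclusive = 2L, dp_min = 0.1)
    got <- scan_windows(v, cfg)
    want <- oracle_scan(v, cfg)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("overlapping qualifying runs merge into single candidates", {
  # two 4-SNP clusters far apart on one contig -> two candidates
  geno <- matrix(c(rep(c(0L, 2L), 4L), rep(c(2L, 0L), 4L)), nrow = 8L,
                 byrow = FALSE)
  geno <- cbind(geno, matrix(c(rep(0L, 4), rep(2L, 4)), nrow = 8L),
                matrix(c(rep(2L, 4), rep(1L, 4)), nrow = 8L))
  colnames(geno) <- sprintf("S%d", seq_len(ncol(geno)))
  v <- make_variants(pos = c(1101L, 1131L, 1161L, 1191L,
                             5101L, 5131L, 5161L, 5191L),
                     geno = geno, contig_len = 10000L)
  w <- scan_windows(v, screening_config())
  cand <- merge_to_candidates(w, v, screening_config())
  expect_equal(nrow(cand), 2L)
  expect_true(all(cand$n_snps == 4L))
  lens <- cand$amplicon_end - cand$amplicon_start + 1L
  expect_true(all(lens >= 200L & lens <= 300L))
  # SNP-free flanks, rechecked post hoc
  for (i in 1:2) {
    pos <- as.integer(strsplit(cand$snp_pos[i], ",")[[1]])
    expect_true(all(pos >= cand$amplicon_start[i] + 20L &
                      pos <= cand$amplicon_end[i] - 20L))
  }
})

test_that("a run whose SNP span cannot fit the amplicon limit is dropped", {
  # 5 SNPs spanning 290 bp: amplicon needs 290 + 40 = 330 > 300
  pos <- c(1001L, 1051L, 1101L, 1201L, 1290L)
  # sample j carries the binary expansion of j: all labels distinct, DP = 1
  geno <- vapply(1:8, function(j)
    2L * as.integer(bitwAnd(j, 2L^(0:4)) > 0L), integer(5))
  colnames(geno) <- sprintf("S%d", 1:8)
  v <- make_variants(pos = pos, geno = geno, contig_len = 5000L)
  cfg <- screening_config(min_snps_exclusive = 4L)
  w <- scan_windows(v, cfg)
  expect_gt(nrow(w), 0L)  # windows qualify on count and DP...
  expect_message(cand <- merge_to_candidates(w, v, cfg), "dropped")
  expect_equal(nrow(cand), 0L)  # ...but no feasible amplicon exists
})

test_that("panel spacing keeps one locus per crowded neighbourhood", {
  cand <- structure(data.frame(
    locus_id = c("L1", "L2", "L3"),
    contig = c("c1", "c1", "c2"),
    amplicon_start = c(1000L, 6000L, 1000L),
    amplicon_end = c(1250L, 6250L, 1250L),
    window_start = c(990L, 5990L, 990L),
    window_end = c(1289L, 6289L, 1289L),
    dp = c(0.9, 0.7, 0.5), n_snps = c(6L, 5L, 4L),
    snp_pos = "", stringsAsFactors = FALSE),
    class = c("mnp_panel", "data.frame"))
  sel <- space_panel(cand, screening_config(min_spacing_bp = 10000L))
  # c1 loci are 5 kb apart: only the higher-DP one survives; c2 unaffected
  expect_setequal(sel$locus_id, c("L1", "L3"))
  sel2 <- space_panel(cand, screening_config(min_spacing_bp = 1000L))
  expect_equal(nrow(sel2), 3L)
  sel3 <- space_panel(cand, screening_config(min_spacing_bp = 1000L,
                                             target_panel_size = 2L))
  expect_equal(nrow(sel3), 2L)
})

test_that("screened panels satisfy every admission rule post hoc", {
  cfg <- tiny_sim(seed = 31, n_contigs = 30L, planted_locus_count = 25L)
  pv <- simulate_population_variants(simulate_reference(cfg), cfg)
  panel <- screen_panel(filter_variants(pv$variants)$variants)
  expect_gt(nrow(panel), 0L)
  expect_true(all(panel$n_snps > 3L))
  expect_true(all(panel$dp >= 0.2))
  lens <- panel$amplicon_end - panel$amplicon_start + 1L
  expect_true(all(lens >= 200L & lens <= 300L))
  # spacing within contigs
  for (ctg in unique(panel$contig)) {
    st <- sort(panel$amplicon_start[panel$contig == ctg])
    if (length(st) > 1L) expect_true(all(diff(st) >= 10000L))
  }
})
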