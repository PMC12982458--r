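test_that("genetic similarity counts identical allele sets per locus", {
  m <- matrix(c("A;B", "C", "D",
                "A;B", "C", "E"), nrow = 3L,
              dimnames = list(c("L1", "L2", "L3"), c("x", "y")))
  fpx <- make_fingerprints(m[, "x", drop = FALSE])
  fpy <- make_fingerprints(m[, "y", drop = FALSE])
  r <- genetic_similarity(fpx, fpy)
  expect_equal(r$n_compared, 3L)
  expect_equal(r$n_identical, 2L)
  expect_equal(r$n_differential, 1L)
  expect_equal(r$gs, 2 / 3)
  expect_equal(r$differentiation_ratio, 1 / 3)

  # identical fingerprints: gs 1 in both modes when all loci are called
  r2 <- genetic_similarity(fpx, fpx)
  expect_equal(r2$gs, 1.0)
  # disjoint fingerprints: gs 0
  m2 <- m; m2[, "y"] <- c("Z", "Z", "Z")
  r3 <- genetic_similarity(fpx, make_fingerprints(m2[, "y", drop = FALSE]))
  expect_equal(r3$gs, 0.0)

  # panel-mode denominator is the panel size, not the shared-call count
  m3 <- m; m3[3, "y"] <- NA
  r4 <- genetic_similarity(fpx, make_fingerprints(m3[, "y", drop = FALSE]),
                           denominator = "panel")
  expect_equal(r4$gs, 2 / 3)
  r5 <- genetic_similarity(fpx, make_fingerprints(m3[, "y", drop = FALSE]),
                           denominator = "shared_called")
  expect_equal(r5$gs, 2 / 2)
})

test_that("324 identical loci of a 505-locus panel give GS 64.16%", {
  m <- matrix("H1", nrow = 505L, ncol = 2L,
              dimnames = list(sprintf("L%03d", 1:505), c("a", "b")))
  m[1:181, 2] <- "H2"            # 181 differential loci
  fp <- make_fingerprints(m)
  cmp <- pairwise_compare(fp, denominator = "panel")
  expect_equal(cmp$n_identical, 324L)
  expect_equal(cmp$gs, 324 / 505)
  expect_equal(round(100 * cmp$gs, 2), 64.16)
})

test_that("pairwise comparison yields exactly choose(n, 2) ordered rows", {
  mk <- function(n) {
    m <- matrix(rep(c("A", "B"), length.out = 2L * n), nrow = 2L,
                dimnames = list(c("L1", "L2"), sprintf("a%03d", seq_len(n))))
    make_fingerprints(m)
  }
  expect_equal(nrow(pairwise_compare(mk(2))), 1L)
  expect_equal(nrow(pairwise_compare(mk(30))), 435L)
  cmp <- pairwise_compare(mk(10))
  expect_true(all(cmp$accession_a < cmp$accession_b))
  dup <- mk(3); dup$accession[dup$accession == "a002"] <- "a001"
  expect_error(pairwise_compare(dup), class = "mnp_data_error")
})

test_that("reproducibility compares cells called in both runs", {
  m <- matrix(c("A", "B", "C", "D"), nrow = 4L,
              dimnames = list(sprintf("L%d", 1:4), "x"))
  run1 <- make_fingerprints(m)
  expect_equal(reproducibility(run1, run1)$fraction, 1.0)

  m2 <- m; m2[1, 1] <- "Z"; m2[2, 1] <- NA
  run2 <- make_fingerprints(m2)
  r <- reproducibility(run1, run2)
  expect_equal(r$n_compared, 3L)
  expect_equal(r$n_reproducible, 2L)
  expect_equal(r$fraction, 2 / 3)

  m3 <- m; m3[, 1] <- NA
  expect_error(reproducibility(run1, make_fingerprints(m3)),
               class = "mnp_data_error")
})

test_that("accuracy maps reproducibility through 1 - (1 - r)/2", {
  expect_equal(accuracy_from_reproducibility(0.9980), 0.9990)
  expect_equal(accuracy_from_reproducibility(0.9978), 0.9989)
  expect_equal(accuracy_from_reproducibility(1.0), 1.0)
  expect_equal(accuracy_from_reproducibility(0.0), 0.5)
  # affine and monotone increasing
  r <- seq(0, 1, by = 0.1)
  a <- accuracy_from_reproducibility(r)
  expect_true(all(diff(a) > 0))
  expect_equal(diff(a), rep(0.05, 10))
  expect_error(accuracy_from_reproducibility(1.2), class = "mnp_data_error")
})

test_that("PIC follows the Botstein form and its bounds", {
  expect_equal(pic(1.0), 0.0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_gt(pic(rep(1 / 100, 100)), 0.97)   # many equifrequent alleles -> 1
  expect_error(pic(numeric(0)), class = "mnp_data_error")
  expect_error(pic(c(0.5, 0.4)), class = "mnp_data_error")

  # PIC <= expected heterozygosity for every frequency vector
  set.seed(11)
  for (rep in 1:50) {
    k <- sample(2:10, 1)
    p <- runif(k); p <- p / sum(p)
    expect_lte(pic(p), 1 - sum(p^2) + 1e-12)
  }
})

test_that("allele statistics count distinct alleles across the cohort", {
  m <- matrix(c("A", "B",
                "X;Y", "X;Z",
                NA, "Q"), nrow = 3L, byrow = TRUE,
              dimnames = list(c("L1", "L2", "L3"), c("s1", "s2")))
  st <- allele_stats(make_fingerprints(m))
  per <- st$per_locus
  expect_equal(per$allele_count[per$locus_id == "L1"], 2L)
  expect_equal(per$allele_count[per$locus_id == "L2"], 3L)
  expect_equal(per$allele_count[per$locus_id == "L3"], 1L)
  expect_equal(per$detection_rate, c(1, 1, 0.5))
  # allele frequencies: L2 has X twice, Y and Z once each
  expect_equal(per$pic[per$locus_id == "L2"], pic(c(0.5, 0.25, 0.25)))
  expect_equal(st$summary$mean_alleles, 2)
  expect_equal(st$summary$sd_alleles, 1)

  # single accession, one allele per locus
  m1 <- matrix("H", 3L, 1L, dimnames = list(c("L1", "L2", "L3"), "s"))
  st1 <- allele_stats(make_fingerprints(m1))
  expect_true(all(st1$per_locus$allele_count == 1L))
  expect_equal(st1$summary$mean_alleles, 1)
  expect_equal(st1$summary$sd_alleles, 0)
})

test_that("cohort allele inventories match the simulation truth", {
  cfg <- tiny_sim(seed = 37)
  pv <- simulate_population_variants(simulate_reference(cfg), cfg)
  st <- allele_stats(make_truth_fp(pv$truth))
  truth_counts <- vapply(split(pv$truth$fingerprints$alleles,
                               pv$truth$fingerprints$locus_id),
                         function(a) length(unique(unlist(strsplit(a, ";")))),
                         integer(1))
  m <- match(st$per_locus$locus_id, names(truth_counts))
  expect_equal(st$per_locus$allele_count, unname(truth_counts[m]))
})

test_that("molecular IDs are deterministic, injective and registry-stable", {
  m <- matrix(c("A;B", "C", "A", "C", "A;B", "D"), nrow = 2L,
              dimnames = list(c("L1", "L2"), c("x", "y", "z")))
  fp <- make_fingerprints(m)
  id1 <- molecular_id(fp)
  id2 <- molecular_id(fp)
  expect_identical(id1$ids, id2$ids)
  expect_equal(length(unique(id1$ids$digest)), 3L)
  expect_equal(length(unique(id1$ids$canonical)), 3L)

  # same fingerprint -> same ID even via an external registry
  id3 <- molecular_id(fp, registry = id1$registry)
  expect_identical(id3$ids, id1$ids)

  # a new allele extends the registry deterministically with a warning
  m2 <- m; m2[1, "x"] <- "A;Q"
  expect_warning(id4 <- molecular_id(make_fingerprints(m2),
                                     registry = id1$registry),
                 "extended")
  expect_true("Q" %in% id4$registry$L1)

  # no-call cells appear as "." in the canonical string
  m3 <- m; m3[2, "x"] <- NA
  id5 <- molecular_id(make_fingerprints(m3))
  expect_match(id5$ids$canonical[id5$ids$accession == "x"], "\\.")
})
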