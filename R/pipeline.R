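#' End-to-end demonstration pipeline
#'
#' Runs simulate -> filter -> screen -> genotype -> compare -> cluster on
#' synthetic data with a fixed seed and writes every intermediate artifact
#' plus a manifest. A second, independently seeded read set is genotyped
#' for the same cohort so the reproducibility/accuracy statistics of a
#' two-run replicate design are also produced.
#'
#' Outputs written under `out_dir`: `reference.fasta`,
#' `population.vcf.gz`, `filter_tally.tsv`, `panel.tsv`, `reads.fastq`,
#' `fingerprints.tsv`, `fingerprints_run2.tsv`, `sample_summary.tsv`,
#' `comparisons.tsv`, `panel_stats.tsv`, `molecular_ids.tsv`,
#' `reproducibility.json`, `tree.nwk`, `pcoa.tsv`, `manifest.json`.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving every stage.
#' @param sim An [sim_config()]; its `rng_seed` is overridden by `seed`.
#' @param filt An [filter_config()].
#' @param screen An [screening_config()].
#' @param geno An [genotyping_config()].
#' @param denominator GS denominator mode, see [genetic_similarity()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(out_dir,
                         seed = 1L,
                         sim = sim_config(),
                         filt = filter_config(),
                         screen = screening_config(),
                         geno = genotyping_config(),
                         denominator = "panel") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim$rng_seed <- as.integer(seed)
  t0 <- Sys.time()
  paths <- list()
  stage_info <- list()

  note <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  ref <- simulate_reference(sim)
  paths$reference <- file.path(out_dir, "reference.fasta")
  write_fasta(ref, paths$reference)
  note("simulate", "%d contigs of %d bp", length(ref), sim$contig_length_bp)

  pv <- simulate_population_variants(ref, sim)
  paths$vcf <- file.path(out_dir, "population.vcf.gz")
  write_variants_vcf(pv$variants, paths$vcf)
  note("simulate", "%d SNPs across %d accessions; %d planted loci",
       nrow(pv$variants$sites), sim$n_accessions, nrow(pv$truth$loci))

  fl <- filter_variants(pv$variants, filt)
  paths$tally <- file.path(out_dir, "filter_tally.tsv")
  write.table(data.frame(rule = names(fl$tally), rejected = fl$tally),
              paths$tally, sep = "\t", quote = FALSE, row.names = FALSE)
  note("filter", "%d of %d SNPs retained", nrow(fl$variants$sites),
       nrow(pv$variants$sites))

  panel <- screen_panel(fl$variants, screen)
  paths$panel <- file.path(out_dir, "panel.tsv")
  write_panel(panel, paths$panel)
  note("screen", "panel of %d loci (target %d)", nrow(panel),
       screen$target_panel_size)

  reads <- simulate_amplicon_reads(pv$truth, sim)
  paths$reads <- file.path(out_dir, "reads.fastq")
  write_fastq(reads, paths$reads)
  note("simulate", "%d amplicon reads", nrow(reads))

  # Reads are tagged with truth locus ids; relabel them with the matching
  # screened panel locus (same contig, overlapping amplicons).
  map <- match_loci(truth_panel(pv$truth), panel)
  reads$locus_id <- unname(map[reads$locus_id])
  reads <- reads[!is.na(reads$locus_id), , drop = FALSE]

  asg <- assign_reads_to_loci(reads, panel, mode = "tagged")
  fp <- genotype_cohort(asg$assigned, panel, geno,
                        accessions = accession_ids(sim$n_accessions))
  paths$fingerprints <- file.path(out_dir, "fingerprints.tsv")
  write_fingerprints(fp, paths$fingerprints)

  summ <- sample_summary(fp, nrow(panel))
  paths$summary <- file.path(out_dir, "sample_summary.tsv")
  write.table(summ, paths$summary, sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("genotype", "mean detection rate %.2f%%",
       100 * mean(summ$detection_rate))

  # Replicate run: fresh reads (independent errors, dropouts unchanged).
  sim2 <- sim
  sim2$rng_seed <- as.integer(seed) + 100000L
  reads2 <- simulate_amplicon_reads(pv$truth, sim2)
  reads2$locus_id <- unname(map[reads2$locus_id])
  reads2 <- reads2[!is.na(reads2$locus_id), , drop = FALSE]
  fp2 <- genotype_cohort(
    assign_reads_to_loci(reads2, panel, mode = "tagged")$assigned,
    panel, geno, accessions = accession_ids(sim$n_accessions))
  paths$fingerprints2 <- file.path(out_dir, "fingerprints_run2.tsv")
  write_fingerprints(fp2, paths$fingerprints2)
  rep2 <- reproducibility(fp, fp2)
  rep_report <- list(
    n_compared = rep2$n_compared,
    n_reproducible = rep2$n_reproducible,
    reproducibility = rep2$fraction,
    accuracy = accuracy_from_reproducibility(rep2$fraction))
  paths$reproducibility <- file.path(out_dir, "reproducibility.json")
  jsonlite::write_json(rep_report, paths$reproducibility, auto_unbox = TRUE,
                       digits = NA)
  note("reproducibility", "%d/%d cells reproducible (%.2f%%), accuracy %.2f%%",
       rep2$n_reproducible, rep2$n_compared, 100 * rep2$fraction,
       100 * rep_report$accuracy)

  cmp <- pairwise_compare(fp, denominator = denominator,
                          panel_size = nrow(panel))
  paths$comparisons <- file.path(out_dir, "comparisons.tsv")
  write.table(cmp, paths$comparisons, sep = "\t", quote = FALSE,
              row.names = FALSE)

  st <- allele_stats(fp)
  paths$panel_stats <- file.path(out_dir, "panel_stats.tsv")
  write.table(st$per_locus, paths$panel_stats, sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("panel-stats", "%.2f +/- %.2f alleles per locus, PIC %.2f +/- %.2f",
       st$summary$mean_alleles, st$summary$sd_alleles,
       st$summary$mean_pic, st$summary$sd_pic)

  mid <- molecular_id(fp)
  paths$molecular_ids <- file.path(out_dir, "molecular_ids.tsv")
  write.table(mid$ids[, c("accession", "digest")], paths$molecular_ids,
              sep = "\t", quote = FALSE, row.names = FALSE)

  d <- gs_distance(cmp)
  tree <- upgma(d)
  paths$tree <- file.path(out_dir, "tree.nwk")
  to_newick(tree, paths$tree)
  ord <- pcoa(d, n_axes = 2L)
  paths$pcoa <- file.path(out_dir, "pcoa.tsv")
  write.table(
    data.frame(accession = rownames(ord$coordinates), ord$coordinates),
    paths$pcoa, sep = "\t", quote = FALSE, row.names = FALSE)
  note("cluster", "tree and 2-axis ordination written")

  manifest <- list(
    seed = as.integer(seed),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    parameters = list(simulation = unclass(sim), filtering = unclass(filt),
                      screening = unclass(screen), genotyping = unclass(geno),
                      gs_denominator = denominator),
    counts = list(
      n_snps_simulated = nrow(pv$variants$sites),
      n_snps_retained = nrow(fl$variants$sites),
      n_candidate_loci = nrow(panel),
      panel_size = nrow(panel),
      n_reads = nrow(reads),
      mean_detection_rate = mean(summ$detection_rate),
      reproducibility = rep_report$reproducibility,
      accuracy = rep_report$accuracy),
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = digest_file(p))))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Map locus ids of panel `from` to overlapping locus ids of panel `to`
# (same contig, overlapping amplicon spans). Unmatched loci map to NA.
match_loci <- function(from, to) {
  map <- setNames(rep(NA_character_, nrow(from)), from$locus_id)
  for (i in seq_len(nrow(from))) {
    j <- which(to$contig == from$contig[i] &
               to$amplicon_start <= from$amplicon_end[i] &
               to$amplicon_end >= from$amplicon_start[i])
    if (length(j)) map[i] <- to$locus_id[j[1L]]
  }
  map
}
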