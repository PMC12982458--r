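#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The generator emulates the
#' data a marker-panel study collects: a fragmented reference assembly of
#' short contigs, reduced-representation SNP genotypes for a screening
#' cohort, and per-locus amplicon reads for fingerprinting. Defaults
#' describe a 30-accession screening cohort genotyped over ~505 planted
#' MNP loci with 4 population sub-clusters.
#'
#' Accessions are assigned to `cluster_count` sub-populations; founder
#' haplotypes are partitioned among clusters, so accessions of one cluster
#' share allele pools while different clusters are (at planted loci)
#' disjoint. Each accession carries `alleles_per_accession` founder copies
#' per locus -- ploidy is deliberately not modelled as strictly diploid,
#' only the screening-stage SNP matrix is diploid-coded.
#'
#' @param n_contigs Number of reference contigs.
#' @param contig_length_bp Length of each contig; must be at least 301 bp so
#'   a 300-bp screening window fits.
#' @param n_accessions Cohort size.
#' @param n_founder_haplotypes Founder haplotypes per locus, partitioned
#'   among clusters.
#' @param snp_rate Background (unlinked) SNP rate per bp outside planted
#'   loci.
#' @param cluster_count Number of population sub-clusters.
#' @param planted_locus_count Number of high-linkage MNP loci planted in the
#'   genome.
#' @param read_depth_mean Mean amplicon read depth per locus and accession.
#' @param seq_error_rate Per-base substitution error rate of simulated reads.
#' @param dropout_rate Probability that a locus fails (no reads) in a
#'   sample; independent Bernoulli per locus x sample.
#' @param rng_seed Integer seed fixing every output byte.
#' @param alleles_per_accession Founder copies carried per accession per
#'   locus.
#' @param min_snps_per_locus,mean_snps_per_locus,max_snps_per_locus Planted
#'   SNPs per locus: `min + Poisson(mean - min)`, capped at the maximum.
#' @param highdrop_accessions Number of accessions (the last ones in the
#'   cohort) subjected to `highdrop_rate` instead of `dropout_rate`,
#'   emulating poorly amplifying samples.
#' @param highdrop_rate Dropout rate for those accessions.
#' @param depth_model `"poisson"` or `"nbinom"` per-cell depth; the
#'   negative-binomial option adds overdispersion `depth_dispersion` (size
#'   parameter).
#' @param depth_dispersion Negative-binomial size when
#'   `depth_model = "nbinom"`.
#' @param window_bp,flank_clear_bp,amplicon_min_bp,amplicon_max_bp Geometry
#'   the planted loci must satisfy so that the screening stage can recover
#'   them: SNPs confined to a window core leaving `flank_clear_bp` SNP-free
#'   bases at each amplicon end, amplicon length within
#'   `[amplicon_min_bp, amplicon_max_bp]`.
#' @return A list of class `mnp_sim_config`.
#' @export
sim_config <- function(n_contigs = 550L,
                       contig_length_bp = 2000L,
                       n_accessions = 30L,
                       n_founder_haplotypes = 16L,
                       snp_rate = 0.001,
                       cluster_count = 4L,
                       planted_locus_count = 505L,
                       read_depth_mean = 100L,
                       seq_error_rate = 0.001,
                       dropout_rate = 0.01,
                       rng_seed = 1L,
                       alleles_per_accession = 2L,
                       min_snps_per_locus = 4L,
                       mean_snps_per_locus = 9.4,
                       max_snps_per_locus = 44L,
                       highdrop_accessions = 0L,
                       highdrop_rate = 0.35,
                       depth_model = c("poisson", "nbinom"),
                       depth_dispersion = 5,
                       window_bp = 300L,
                       flank_clear_bp = 20L,
                       amplicon_min_bp = 200L,
                       amplicon_max_bp = 300L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length_bp = as.integer(contig_length_bp),
    n_accessions = as.integer(n_accessions),
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    snp_rate = snp_rate,
    cluster_count = as.integer(cluster_count),
    planted_locus_count = as.integer(planted_locus_count),
    read_depth_mean = as.numeric(read_depth_mean),
    seq_error_rate = seq_error_rate,
    dropout_rate = dropout_rate,
    rng_seed = as.integer(rng_seed),
    alleles_per_accession = as.integer(alleles_per_accession),
    min_snps_per_locus = as.integer(min_snps_per_locus),
    mean_snps_per_locus = as.numeric(mean_snps_per_locus),
    max_snps_per_locus = as.integer(max_snps_per_locus),
    highdrop_accessions = as.integer(highdrop_accessions),
    highdrop_rate = highdrop_rate,
    depth_model = match.arg(depth_model),
    depth_dispersion = as.numeric(depth_dispersion),
    window_bp = as.integer(window_bp),
    flank_clear_bp = as.integer(flank_clear_bp),
    amplicon_min_bp = as.integer(amplicon_min_bp),
    amplicon_max_bp = as.integer(amplicon_max_bp)
  )
  counts <- c("n_contigs", "contig_length_bp", "n_accessions",
              "n_founder_haplotypes", "cluster_count", "planted_locus_count",
              "alleles_per_accession", "min_snps_per_locus",
              "max_snps_per_locus", "window_bp")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_config("sim_config: '%s' must be a count >= 1", f)
  }
  probs <- c("snp_rate", "seq_error_rate", "dropout_rate", "highdrop_rate")
  for (f in probs) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config("sim_config: '%s' must be a probability in [0, 1]", f)
  }
  if (cfg$contig_length_bp < cfg$window_bp + 1L)
    stop_config("sim_config: contig_length_bp must be >= %d (one %d-bp window plus 1)",
                cfg$window_bp + 1L, cfg$window_bp)
  if (cfg$highdrop_accessions > cfg$n_accessions)
    stop_config("sim_config: highdrop_accessions exceeds n_accessions")
  if (cfg$read_depth_mean < 1)
    stop_config("sim_config: read_depth_mean must be >= 1")
  class(cfg) <- "mnp_sim_config"
  cfg
}

# Shared amplicon geometry: tightest span covering [snp_min, snp_max] with
# `flank` SNP-free bases each side, extended symmetrically to amplicon_min
# and clamped to the contig. 1-based inclusive coordinates. NULL if the
# length constraint cannot be met.
amplicon_span <- function(snp_min, snp_max, contig_len,
                          amplicon_min, amplicon_max, flank) {
  a <- snp_min - flank
  b <- snp_max + flank
  len <- b - a + 1L
  if (len > amplicon_max) return(NULL)
  if (len < amplicon_min) {
    d <- amplicon_min - len
    a <- a - d %/% 2L
    b <- b + (d - d %/% 2L)
  }
  if (a < 1L) { b <- b + (1L - a); a <- 1L }
  if (b > contig_len) { a <- a - (b - contig_len); b <- contig_len }
  if (a < 1L) return(NULL)
  len <- b - a + 1L
  if (len < amplicon_min || len > amplicon_max) return(NULL)
  c(start = as.integer(a), end = as.integer(b))
}

#' Simulate a fragmented reference assembly
#'
#' Generates `n_contigs` random contigs of `contig_length_bp` uniform
#' A/C/G/T bases. Deterministic for a fixed `rng_seed`.
#'
#' @param config An [sim_config()] object.
#' @return A [Biostrings::DNAStringSet] named `ctg_0001`, `ctg_0002`, ...
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "mnp_sim_config"))
  set.seed(stage_seed(config$rng_seed, "reference"))
  seqs <- vapply(seq_len(config$n_contigs), function(i) {
    paste(sample(DNA_BASES, config$contig_length_bp, replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("ctg_%04d", seq_len(config$n_contigs))
  Biostrings::DNAStringSet(seqs)
}

accession_ids <- function(n) sprintf("ACC_%03d", seq_len(n))

#' Simulate population SNP genotypes with planted MNP loci
#'
#' Places `planted_locus_count` windows of tightly linked SNPs (founder
#' haplotypes drawn per population cluster, so linkage within a window is
#' complete) plus unlinked background SNPs at `snp_rate`, and draws a
#' diploid-coded genotype matrix for the cohort. Returns the genotype
#' matrix together with the truth set (planted loci, founder amplicon
#' sequences, true fingerprints, dropout events) that downstream stages are
#' validated against.
#'
#' @param reference A `DNAStringSet` from [simulate_reference()].
#' @param config An [sim_config()] object.
#' @return A list with elements `variants` (an `mnp_variants` object, see
#'   [mnp_variants()]) and `truth` (class `mnp_truth`).
#' @export
simulate_population_variants <- function(reference, config) {
  stopifnot(inherits(config, "mnp_sim_config"))
  set.seed(stage_seed(config$rng_seed, "variants"))
  contig_len <- setNames(Biostrings::width(reference), names(reference))
  contigs <- names(reference)
  n_acc <- config$n_accessions
  acc <- accession_ids(n_acc)
  k <- config$alleles_per_accession
  flank <- config$flank_clear_bp
  win <- config$window_bp

  # Placement capacity: loci on one contig keep >= 10 kb + window start
  # spacing so panel spacing rules never exclude a planted locus.
  slot_bp <- 10000L + win
  cap <- 1L + pmax(0L, (contig_len - win - 60L) %/% slot_bp)
  if (config$planted_locus_count > sum(cap))
    stop_config(
      "planted loci cannot fit: capacity %d < requested %d (lengthen or add contigs)",
      sum(cap), config$planted_locus_count)

  # Round-robin assignment of loci to contigs, then slots within contig.
  placement <- data.frame(contig = character(0), slot = integer(0))
  ki <- 0L
  slot_of <- integer(length(contigs))
  order_c <- seq_along(contigs)
  while (ki < config$planted_locus_count) {
    for (ci in order_c) {
      if (ki >= config$planted_locus_count) break
      if (slot_of[ci] < cap[ci]) {
        placement <- rbind(placement,
                           data.frame(contig = contigs[ci], slot = slot_of[ci]))
        slot_of[ci] <- slot_of[ci] + 1L
        ki <- ki + 1L
      }
    }
    if (all(slot_of >= cap)) break
  }

  cluster_of_acc <- ((seq_len(n_acc) - 1L) %% config$cluster_count) + 1L
  names(cluster_of_acc) <- acc
  cluster_of_founder <-
    ((seq_len(config$n_founder_haplotypes) - 1L) %% config$cluster_count) + 1L

  core_width <- min(win, config$amplicon_max_bp) - 2L * flank
  if (core_width < 1L)
    stop_config("flank_clear_bp too large for the amplicon length limits")

  loci <- vector("list", nrow(placement))
  founder_seqs <- list()
  fp_rows <- vector("list", nrow(placement))
  site_rows <- vector("list", nrow(placement))
  geno_blocks <- vector("list", nrow(placement))

  for (i in seq_len(nrow(placement))) {
    ctg <- placement$contig[i]
    L <- contig_len[[ctg]]
    lo <- 31L + placement$slot[i] * slot_bp
    hi <- min(L - win + 1L - 30L, lo + 400L)
    ws <- if (hi > lo) sample(lo:hi, 1L) else lo
    n_snp <- min(config$max_snps_per_locus,
                 config$min_snps_per_locus +
                   rpois(1L, max(0, config$mean_snps_per_locus -
                                      config$min_snps_per_locus)))
    core <- seq.int(ws + flank, ws + flank + core_width - 1L)
    pos <- sort(sample(core, min(n_snp, length(core))))
    n_snp <- length(pos)

    # Founder haplotypes: 0 = ref, 1 = alt; each SNP column kept polymorphic
    # when more than one founder exists.
    nf <- config$n_founder_haplotypes
    H <- matrix(rbinom(nf * n_snp, 1L, 0.5), nrow = nf)
    if (nf >= 2L) {
      for (j in seq_len(n_snp)) {
        if (length(unique(H[, j])) == 1L)
          H[sample.int(nf, 1L), j] <- 1L - H[1L, j]
      }
    }

    ref_bases <- strsplit(as.character(
      Biostrings::subseq(reference[[ctg]], min(pos), max(pos))), "")[[1]]
    ref_snp <- ref_bases[pos - min(pos) + 1L]
    alt_snp <- vapply(ref_snp, function(r)
      sample(setdiff(DNA_BASES, r), 1L), character(1))

    span <- amplicon_span(min(pos), max(pos), L,
                          config$amplicon_min_bp, config$amplicon_max_bp,
                          flank)
    if (is.null(span))
      stop_config("internal: planted locus %d has no feasible amplicon", i)
    locus_id <- sprintf("MNP_%s_%06d", ctg, span[["start"]])

    amp_chars <- strsplit(as.character(
      Biostrings::subseq(reference[[ctg]], span[["start"]], span[["end"]])),
      "")[[1]]
    off <- pos - span[["start"]] + 1L
    fseq <- vapply(seq_len(nf), function(h) {
      ch <- amp_chars
      mut <- H[h, ] == 1L
      ch[off[mut]] <- alt_snp[mut]
      paste(ch, collapse = "")
    }, character(1))
    founder_seqs[[locus_id]] <- fseq

    # Accessions draw k founder copies from their cluster's founder pool.
    copies <- matrix(0L, nrow = n_acc, ncol = k)
    for (a in seq_len(n_acc)) {
      pool <- which(cluster_of_founder == cluster_of_acc[a])
      if (length(pool) == 0L) pool <- seq_len(nf)
      copies[a, ] <- sample(pool, k, replace = TRUE)
    }

    # Diploid-coded screening genotypes: 0 all-ref, 2 all-alt, 1 mixed.
    g <- matrix(0L, nrow = n_snp, ncol = n_acc)
    for (a in seq_len(n_acc)) {
      al <- H[copies[a, ], , drop = FALSE]
      cs <- colSums(al)
      g[, a] <- ifelse(cs == 0L, 0L, ifelse(cs == k, 2L, 1L))
    }

    allele_sets <- vapply(seq_len(n_acc), function(a) {
      paste(sort(unique(fseq[copies[a, ]])), collapse = ";")
    }, character(1))

    hap_labels <- hap_labels_from_codes(g, ref_snp, alt_snp)
    dp <- discriminative_power(hap_labels)

    loci[[i]] <- data.frame(
      locus_id = locus_id, contig = ctg,
      window_start = ws, window_end = ws + win - 1L,
      amplicon_start = span[["start"]], amplicon_end = span[["end"]],
      n_snps = n_snp, snp_pos = paste(pos, collapse = ","),
      dp = dp, stringsAsFactors = FALSE)
    fp_rows[[i]] <- data.frame(accession = acc, locus_id = locus_id,
                               alleles = allele_sets, stringsAsFactors = FALSE)
    site_rows[[i]] <- data.frame(contig = ctg, pos = pos, ref = ref_snp,
                                 alt = alt_snp, stringsAsFactors = FALSE)
    geno_blocks[[i]] <- g
  }

  loci <- do.call(rbind, loci)
  truth_fp <- do.call(rbind, fp_rows)
  sites <- do.call(rbind, site_rows)
  geno <- do.call(rbind, geno_blocks)

  # Background SNPs: unlinked, kept out of planted amplicons and flanks.
  forbidden <- vector("list", length(contigs))
  names(forbidden) <- contigs
  for (i in seq_len(nrow(loci))) {
    ctg <- loci$contig[i]
    forbidden[[ctg]] <- c(forbidden[[ctg]],
                          seq.int(max(1L, loci$amplicon_start[i] - flank),
                                  min(contig_len[[ctg]],
                                      loci$amplicon_end[i] + flank)))
  }
  bg_sites <- list(); bg_geno <- list()
  if (config$snp_rate > 0) {
    for (ctg in contigs) {
      allowed <- setdiff(seq_len(contig_len[[ctg]]), forbidden[[ctg]])
      if (length(allowed) == 0L) next
      n_bg <- rbinom(1L, length(allowed), config$snp_rate)
      if (n_bg == 0L) next
      pos <- sort(sample(allowed, n_bg))
      refs <- strsplit(as.character(reference[[ctg]]), "")[[1]][pos]
      alts <- vapply(refs, function(r)
        sample(setdiff(DNA_BASES, r), 1L), character(1))
      p <- runif(n_bg, 0.05, 0.5)
      g <- t(vapply(p, function(pp) rbinom(n_acc, 2L, pp), integer(n_acc)))
      bg_sites[[ctg]] <- data.frame(contig = ctg, pos = pos, ref = refs,
                                    alt = alts, stringsAsFactors = FALSE)
      bg_geno[[ctg]] <- g
    }
  }
  if (length(bg_sites)) {
    sites <- rbind(sites, do.call(rbind, bg_sites))
    geno <- rbind(geno, do.call(rbind, bg_geno))
  }
  ord <- order(match(sites$contig, contigs), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL
  colnames(geno) <- acc

  # Dropout events: independent Bernoulli; designated accessions at the
  # elevated rate (poorly amplifying samples).
  rate_of_acc <- rep(config$dropout_rate, n_acc)
  if (config$highdrop_accessions > 0L) {
    idx <- seq.int(n_acc - config$highdrop_accessions + 1L, n_acc)
    rate_of_acc[idx] <- config$highdrop_rate
  }
  drop_mask <- runif(nrow(truth_fp)) <
    rate_of_acc[match(truth_fp$accession, acc)]
  dropouts <- truth_fp[drop_mask, c("accession", "locus_id")]
  rownames(dropouts) <- NULL

  variants <- mnp_variants(sites, geno, contig_lengths = contig_len)
  truth <- structure(list(
    loci = loci,
    founder_seqs = founder_seqs,
    fingerprints = truth_fp,
    dropouts = dropouts,
    clusters = cluster_of_acc,
    config = config
  ), class = "mnp_truth")
  list(variants = variants, truth = truth)
}

#' Panel definition implied by a truth set
#'
#' Recasts the planted loci of a simulation truth set as an `mnp_panel`, so
#' genotyping can be exercised against known loci independently of the
#' screening stage.
#'
#' @param truth An `mnp_truth` object.
#' @return An `mnp_panel` data frame (see [write_panel()]).
#' @export
truth_panel <- function(truth) {
  stopifnot(inherits(truth, "mnp_truth"))
  p <- truth$loci[, c("locus_id", "contig", "amplicon_start", "amplicon_end",
                      "window_start", "window_end", "dp", "n_snps", "snp_pos")]
  p <- p[order(p$contig, p$amplicon_start), ]
  rownames(p) <- NULL
  class(p) <- c("mnp_panel", "data.frame")
  p
}

#' Simulate amplicon sequencing reads
#'
#' For every accession x locus cell not listed as a dropout, draws a read
#' depth (Poisson or negative-binomial around `read_depth_mean`), samples
#' each read uniformly from the accession's true allele sequences, and
#' applies per-base substitution errors at `seq_error_rate`. Read names
#' carry accession and locus identity as `accession|locus|serial`, the
#' tagged-assignment contract of [assign_reads_to_loci()].
#'
#' @param truth An `mnp_truth` object.
#' @param config The [sim_config()] used to generate it.
#' @return An `mnp_reads` data frame: `read_id`, `accession`, `locus_id`,
#'   `seq`.
#' @export
simulate_amplicon_reads <- function(truth, config) {
  stopifnot(inherits(truth, "mnp_truth"), inherits(config, "mnp_sim_config"))
  set.seed(stage_seed(config$rng_seed, "reads"))
  fp <- truth$fingerprints
  if (nrow(truth$dropouts)) {
    key <- paste(fp$accession, fp$locus_id)
    fp <- fp[!key %in% paste(truth$dropouts$accession,
                             truth$dropouts$locus_id), ]
  }
  al_list <- strsplit(fp$alleles, ";", fixed = TRUE)
  n_all <- lengths(al_list)
  d <- switch(config$depth_model,
    poisson = rpois(nrow(fp), config$read_depth_mean),
    nbinom = rnbinom(nrow(fp), mu = config$read_depth_mean,
                     size = config$depth_dispersion))
  keep <- d > 0L
  fp <- fp[keep, ]; al_list <- al_list[keep]
  n_all <- n_all[keep]; d <- d[keep]

  rep_cell <- rep(seq_len(nrow(fp)), d)
  pick <- pmin(floor(runif(length(rep_cell)) * n_all[rep_cell]) + 1L,
               n_all[rep_cell])
  offsets <- cumsum(c(0L, n_all))
  seqs <- unlist(al_list, use.names = FALSE)[offsets[rep_cell] + pick]

  if (config$seq_error_rate > 0 && length(seqs)) {
    len <- nchar(seqs)
    nerr <- rbinom(length(seqs), len, config$seq_error_rate)
    for (i in which(nerr > 0L)) {
      s <- seqs[i]
      for (p in sample.int(len[i], nerr[i])) {
        substr(s, p, p) <- sample(setdiff(DNA_BASES, substr(s, p, p)), 1L)
      }
      seqs[i] <- s
    }
  }

  serial <- sequence(d)
  reads <- data.frame(
    read_id = paste(fp$accession[rep_cell], fp$locus_id[rep_cell], serial,
                    sep = "|"),
    accession = fp$accession[rep_cell],
    locus_id = fp$locus_id[rep_cell],
    seq = seqs,
    stringsAsFactors = FALSE)
  class(reads) <- c("mnp_reads", "data.frame")
  reads
}
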