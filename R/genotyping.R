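#' Genotyping configuration
#'
#' Thresholds of the haplotype-sequence allele caller. A locus needs
#' `min_locus_depth` assigned reads to be called; a sequence is an allele
#' when its read fraction reaches `min_allele_fraction`; at most
#' `max_alleles_per_locus` alleles are kept (more trigger a warning, since
#' ploidy may be uncharacterized). Before calling, rare sequences (fraction
#' below `error_collapse_fraction`) lying within
#' `error_collapse_max_mismatch` substitutions of a sequence at least 10x
#' more abundant are folded into it -- the sequencing-error collapse.
#'
#' @param min_locus_depth Minimum reads per locus for a call.
#' @param min_allele_fraction Minimum read fraction per called allele; in
#'   (0, 0.5].
#' @param max_alleles_per_locus Allele cap per call.
#' @param error_collapse_max_mismatch Maximum substitutions for collapsing.
#' @param error_collapse_fraction Fraction below which a sequence is
#'   considered error-derived.
#' @return A list of class `mnp_genotyping_config`.
#' @export
genotyping_config <- function(min_locus_depth = 20L,
                              min_allele_fraction = 0.2,
                              max_alleles_per_locus = 2L,
                              error_collapse_max_mismatch = 1L,
                              error_collapse_fraction = 0.05) {
  cfg <- list(min_locus_depth = as.integer(min_locus_depth),
              min_allele_fraction = min_allele_fraction,
              max_alleles_per_locus = as.integer(max_alleles_per_locus),
              error_collapse_max_mismatch = as.integer(error_collapse_max_mismatch),
              error_collapse_fraction = error_collapse_fraction)
  if (min_allele_fraction <= 0 || min_allele_fraction > 0.5)
    stop_config("min_allele_fraction must be in (0, 0.5]")
  if (cfg$max_alleles_per_locus < 1L)
    stop_config("max_alleles_per_locus must be >= 1")
  class(cfg) <- "mnp_genotyping_config"
  cfg
}

#' Assign amplicon reads to panel loci
#'
#' `"tagged"` mode trusts the `locus_id` embedded in read names by the
#' simulator (or an upstream demultiplexer); reads tagged with unknown
#' loci are counted unassigned. `"flank"` mode matches each read's first
#' and last `flank_bp` bases against every locus's amplicon flanks, both
#' orientations; a read must match both flanks of exactly one locus, and a
#' reverse-complement match stores the reoriented sequence.
#'
#' @param reads An `mnp_reads` data frame.
#' @param panel An `mnp_panel`.
#' @param mode `"tagged"` or `"flank"`.
#' @param reference `DNAStringSet`; required in flank mode to extract
#'   amplicon flank sequences.
#' @param flank_bp Flank length used for matching (default 20).
#' @return A list: `assigned` (`mnp_reads` with a validated `locus_id`),
#'   `n_unassigned`, `unassigned` (read ids). Assigned plus unassigned
#'   always equals the input read count.
#' @export
assign_reads_to_loci <- function(reads, panel, mode = c("tagged", "flank"),
                                 reference = NULL, flank_bp = 20L) {
  mode <- match.arg(mode)
  if (mode == "tagged") {
    known <- reads$locus_id %in% panel$locus_id
    if (any(!known))
      message(sum(!known), " reads with unknown or missing locus tags left unassigned")
    assigned <- reads[known, , drop = FALSE]
  } else {
    if (is.null(reference))
      stop_data("flank mode requires the reference sequences")
    amp <- vapply(seq_len(nrow(panel)), function(i) {
      as.character(Biostrings::subseq(reference[[panel$contig[i]]],
                                      panel$amplicon_start[i],
                                      panel$amplicon_end[i]))
    }, character(1))
    key_fwd <- paste(substr(amp, 1L, flank_bp),
                     substring(amp, nchar(amp) - flank_bp + 1L))
    lookup <- setNames(panel$locus_id, key_fwd)
    probe <- function(s) paste(substr(s, 1L, flank_bp),
                               substring(s, nchar(s) - flank_bp + 1L))
    hit_f <- lookup[probe(reads$seq)]
    rc <- revcomp(reads$seq)
    hit_r <- lookup[probe(rc)]
    use_rc <- is.na(hit_f) & !is.na(hit_r)
    locus <- ifelse(is.na(hit_f), hit_r, hit_f)
    seqs <- ifelse(use_rc, rc, reads$seq)
    known <- !is.na(locus)
    assigned <- reads[known, , drop = FALSE]
    assigned$locus_id <- unname(locus[known])
    assigned$seq <- seqs[known]
  }
  class(assigned) <- c("mnp_reads", "data.frame")
  list(assigned = assigned,
       n_unassigned = nrow(reads) - nrow(assigned),
       unassigned = reads$read_id[!reads$read_id %in% assigned$read_id])
}

#' Collapse sequencing-error sequences within one locus read group
#'
#' Tallies exact sequences, then processes rare sequences (initial fraction
#' below `error_collapse_fraction`) in descending count (ties broken
#' lexicographically): each is folded into the most abundant sequence of
#' equal length within `error_collapse_max_mismatch` substitutions that is
#' at least 10x more abundant.
#'
#' @param seqs Character vector of reads from one locus, or a named
#'   integer vector of pre-tallied counts.
#' @param config An [genotyping_config()].
#' @return Named integer vector of counts, descending (ties
#'   lexicographic).
#' @export
collapse_errors <- function(seqs, config = genotyping_config()) {
  counts <- if (is.numeric(seqs)) {
    stopifnot(!is.null(names(seqs)))
    seqs
  } else {
    tab <- table(seqs)
    setNames(as.integer(tab), names(tab))
  }
  counts <- counts[order(-counts, names(counts))]
  total <- sum(counts)
  if (total == 0L || length(counts) < 2L) return(counts)
  init_frac <- counts / total
  rare <- names(counts)[init_frac < config$error_collapse_fraction]
  rare <- rare[order(-counts[rare], rare)]
  for (s in rare) {
    cs <- counts[[s]]
    if (cs == 0L) next
    others <- setdiff(names(counts)[counts >= 10L * cs], s)
    if (!length(others)) next
    dists <- vapply(others, function(o) {
      d <- hamming(s, o)
      if (is.na(d)) Inf else d
    }, numeric(1))
    ok <- others[dists <= config$error_collapse_max_mismatch]
    if (!length(ok)) next
    parent <- ok[order(-counts[ok], ok)][1L]
    counts[[parent]] <- counts[[parent]] + cs
    counts <- counts[names(counts) != s]
  }
  counts[order(-counts, names(counts))]
}

#' Call the MNP genotype of one locus from collapsed counts
#'
#' With total depth below `min_locus_depth` the locus is a no-call.
#' Otherwise alleles are the sequences whose read fraction reaches
#' `min_allele_fraction`, capped at `max_alleles_per_locus` by descending
#' count (ties lexicographic); exceeding the cap logs a warning. If no
#' sequence reaches the fraction threshold the locus is reported as
#' `no_call_ambiguous`.
#'
#' @param counts Named integer vector from [collapse_errors()].
#' @param config An [genotyping_config()].
#' @return A list: `alleles` (sorted character vector), `depth`,
#'   `fractions` (named, for the called alleles), `status`.
#' @export
call_genotype <- function(counts, config = genotyping_config()) {
  depth <- sum(counts)
  if (depth < config$min_locus_depth) {
    return(list(alleles = character(0), depth = depth,
                fractions = numeric(0), status = "no_call_low_depth"))
  }
  frac <- counts / depth
  cand <- names(counts)[frac >= config$min_allele_fraction]
  if (!length(cand)) {
    return(list(alleles = character(0), depth = depth,
                fractions = numeric(0), status = "no_call_ambiguous"))
  }
  cand <- cand[order(-counts[cand], cand)]
  if (length(cand) > config$max_alleles_per_locus) {
    warning(sprintf("%d alleles pass the fraction threshold; capping at %d",
                    length(cand), config$max_alleles_per_locus))
    cand <- cand[seq_len(config$max_alleles_per_locus)]
  }
  ord <- sort(cand)
  list(alleles = ord, depth = depth,
       fractions = setNames(as.numeric(frac[ord]), ord), status = "called")
}

#' Genotype a cohort of accessions over a panel
#'
#' Groups assigned reads by accession and locus, collapses sequencing
#' errors, calls alleles, and returns one fingerprint row per accession x
#' panel locus (no-calls included explicitly, so every fingerprint covers
#' the full panel).
#'
#' @param assigned An `mnp_reads` data frame of locus-assigned reads (see
#'   [assign_reads_to_loci()]).
#' @param panel An `mnp_panel`.
#' @param config An [genotyping_config()].
#' @param accessions Optional character vector fixing the accession set
#'   (defaults to those present in `assigned`).
#' @return An `mnp_fingerprints` data frame: `accession`, `locus_id`,
#'   `status`, `depth`, `alleles`, `fractions`.
#' @export
genotype_cohort <- function(assigned, panel, config = genotyping_config(),
                            accessions = NULL) {
  accession <- locus_id <- seq <- count <- NULL  # data.table NSE
  acc <- accessions %||% sort(unique(assigned$accession))
  dt <- data.table::as.data.table(assigned)
  tal <- dt[, list(count = .N), by = list(accession, locus_id, seq)]
  grp <- tal[, list(res = list({
    counts <- setNames(count, seq)
    counts <- collapse_errors(counts, config)
    call_genotype(counts, config)
  })), by = list(accession, locus_id)]

  full <- data.table::CJ(accession = acc, locus_id = panel$locus_id,
                         unique = TRUE)
  grp_key <- paste(grp$accession, grp$locus_id)
  m <- match(paste(full$accession, full$locus_id), grp_key)
  res <- grp$res[m]
  fp <- data.frame(
    accession = full$accession,
    locus_id = full$locus_id,
    status = vapply(res, function(r)
      if (is.null(r)) "no_call_low_depth" else r$status, character(1)),
    depth = vapply(res, function(r)
      if (is.null(r)) 0L else as.integer(r$depth), integer(1)),
    alleles = vapply(res, function(r)
      if (is.null(r)) "" else paste(r$alleles, collapse = ";"), character(1)),
    fractions = vapply(res, function(r)
      if (is.null(r)) "" else
        paste(sprintf("%.4f", r$fractions), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  fp <- fp[order(fp$accession, fp$locus_id), ]
  rownames(fp) <- NULL
  class(fp) <- c("mnp_fingerprints", "data.frame")
  fp
}

#' Per-sample locus detection rate
#'
#' Detected loci divided by the panel size, per accession.
#'
#' @param fingerprints An `mnp_fingerprints` data frame.
#' @param panel_size Total target loci (defaults to the loci present in
#'   the table).
#' @return Named numeric vector of fractions, one per accession.
#' @export
#' @examples
#' # 308 of 505 loci detected
#' 308 / 505
detection_rate <- function(fingerprints, panel_size = NULL) {
  ps <- panel_size %||% length(unique(fingerprints$locus_id))
  if (ps < 1L) stop_data("panel_size must be >= 1")
  called <- tapply(fingerprints$status == "called", fingerprints$accession, sum)
  setNames(as.numeric(called) / ps, names(called))
}

#' Per-sample genotyping summary
#'
#' One row per accession: total assigned reads, detected loci, detection
#' rate, and mean locus coverage (mean depth over detected loci).
#'
#' @param fingerprints An `mnp_fingerprints` data frame.
#' @param panel_size Total target loci.
#' @return Data frame with columns `accession`, `total_reads`,
#'   `detected_loci`, `detection_rate`, `mean_locus_coverage`.
#' @export
sample_summary <- function(fingerprints, panel_size = NULL) {
  ps <- panel_size %||% length(unique(fingerprints$locus_id))
  sp <- split(fingerprints, fingerprints$accession)
  out <- do.call(rbind, lapply(names(sp), function(a) {
    f <- sp[[a]]
    called <- f$status == "called"
    data.frame(accession = a,
               total_reads = sum(f$depth),
               detected_loci = sum(called),
               detection_rate = sum(called) / ps,
               mean_locus_coverage = if (any(called))
                 mean(f$depth[called]) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
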