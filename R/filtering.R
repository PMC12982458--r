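#' SNP filter configuration
#'
#' Retention thresholds applied to population SNPs before marker screening:
#' minor allele frequency >= 0.05, genotype call rate >= 80%, exact
#' Hardy--Weinberg test p >= 0.01, no copy-number-variation signal, and host
#' contig longer than 250 bp.
#'
#' The CNV rule is a depth-ratio heuristic (no formula is standard): a
#' locus is flagged when its mean depth exceeds `cnv_depth_ratio_max` times
#' the cohort median locus depth, or when more than
#' `cnv_sample_fraction_max` of samples exceed that ratio against their own
#' median depth. It is skipped (with a message) when depths are absent.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param call_rate_min Minimum fraction of non-missing genotype calls.
#' @param hwe_p_min Minimum exact Hardy--Weinberg p-value.
#' @param cnv_depth_ratio_max Depth ratio above which a locus looks
#'   duplicated.
#' @param cnv_sample_fraction_max Maximum tolerated fraction of
#'   high-ratio samples.
#' @param min_contig_length_bp Contigs must be longer than
#'   `min_contig_length_bp - 1` (default keeps contigs > 250 bp).
#' @return A list of class `mnp_filter_config`.
#' @export
filter_config <- function(maf_min = 0.05,
                          call_rate_min = 0.80,
                          hwe_p_min = 0.01,
                          cnv_depth_ratio_max = 2.0,
                          cnv_sample_fraction_max = 0.10,
                          min_contig_length_bp = 251L) {
  cfg <- list(maf_min = maf_min, call_rate_min = call_rate_min,
              hwe_p_min = hwe_p_min,
              cnv_depth_ratio_max = cnv_depth_ratio_max,
              cnv_sample_fraction_max = cnv_sample_fraction_max,
              min_contig_length_bp = as.integer(min_contig_length_bp))
  if (maf_min < 0 || maf_min > 0.5)
    stop_config("maf_min must be in [0, 0.5]")
  for (f in c("call_rate_min", "hwe_p_min", "cnv_sample_fraction_max")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config("'%s' must be in [0, 1]", f)
  }
  if (cfg$cnv_depth_ratio_max <= 0) stop_config("cnv_depth_ratio_max must be > 0")
  class(cfg) <- "mnp_filter_config"
  cfg
}

#' Genotype call rate of one variant
#'
#' Fraction of samples with a non-missing diploid call.
#'
#' @param genotypes Integer vector of codes (0/1/2, `NA` = missing).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' compute_call_rate(c(0, 1, 2, NA))
compute_call_rate <- function(genotypes) {
  if (length(genotypes) == 0L) stop_data("empty cohort")
  mean(!is.na(genotypes))
}

#' Minor allele frequency of one variant
#'
#' Each non-missing diploid call contributes two allele observations;
#' missing calls are excluded (not imputed).
#'
#' @param genotypes Integer vector of codes (0/1/2, `NA` = missing).
#' @return `min(p, 1 - p)` with `p` the alt-allele frequency; in
#'   \[0, 0.5\].
#' @export
compute_maf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0L) stop_data("all genotypes missing")
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Exact Hardy--Weinberg equilibrium test
#'
#' Exact conditional test on diploid genotype counts: conditioning on the
#' observed allele totals, the p-value sums the probabilities of every
#' heterozygote count (same parity as the observed one) whose conditional
#' probability does not exceed that of the observed count. Computed with
#' the standard heterozygote-count recurrence, so probabilities are exact
#' up to floating point.
#'
#' @param n_homref,n_het,n_homalt Genotype counts.
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  if (any(c(n_homref, n_het, n_homalt) < 0))
    stop_data("genotype counts must be non-negative")
  n <- n_homref + n_het + n_homalt
  if (n < 1L) stop_data("at least one genotype required")
  n_a <- 2L * n_homalt + n_het        # minor-ish allele copies
  n_b <- 2L * n_homref + n_het
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1.0)         # monomorphic: single configuration
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # Unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = [ (na-h)(nb-h) ] / [ (h+2)(h+1) ] with na+nb = 2n fixed.
  probs <- numeric(length(hets))
  probs[1L] <- 1.0
  if (length(hets) > 1L) {
    for (i in seq_len(length(hets) - 1L)) {
      h <- hets[i]
      probs[i + 1L] <- probs[i] *
        ((rare - h) * (2L * n - rare - h)) / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop_data("heterozygote count inconsistent with totals")
  min(1.0, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

#' Copy-number-variation flags for all variants
#'
#' Applies the depth-ratio heuristic of [filter_config()] to every site.
#' When the variants object carries no depth matrix, all flags are `FALSE`
#' and a message is emitted.
#'
#' @param variants An `mnp_variants` object.
#' @param config An `mnp_filter_config`.
#' @return Logical vector, one flag per site.
#' @export
cnv_flags <- function(variants, config = filter_config()) {
  if (is.null(variants$depth)) {
    message("cnv_flags: no per-sample depths available; CNV filter disabled")
    return(rep(FALSE, n_sites(variants)))
  }
  dep <- variants$depth
  locus_mean <- rowMeans(dep, na.rm = TRUE)
  cohort_median <- median(locus_mean, na.rm = TRUE)
  flag_a <- locus_mean > config$cnv_depth_ratio_max * cohort_median
  sample_median <- apply(dep, 2L, median, na.rm = TRUE)
  ratio_hi <- sweep(dep, 2L, config$cnv_depth_ratio_max * sample_median, ">")
  flag_b <- rowMeans(ratio_hi, na.rm = TRUE) > config$cnv_sample_fraction_max
  flag_a | flag_b
}

#' Filter population SNPs
#'
#' Retains each record iff call rate, MAF, Hardy--Weinberg p-value, the
#' CNV flag and the host contig length all satisfy the thresholds of
#' `config`. The rejection tally attributes every removed record to its
#' first failing rule in the fixed order
#' `maf -> call_rate -> hwe -> cnv -> contig_length`, so reports are
#' reproducible.
#'
#' @param variants An `mnp_variants` object, sites sorted by (contig, pos).
#' @param config An [filter_config()] object.
#' @return A list: `variants` (retained records, same class) and `tally`
#'   (named integer vector of first-failure counts).
#' @export
filter_variants <- function(variants, config = filter_config()) {
  stopifnot(inherits(variants, "mnp_variants"))
  s <- variants$sites
  ord <- order(match(s$contig, unique(s$contig)), s$pos)
  if (is.unsorted(ord)) stop_data("variants must be sorted by (contig, position)")
  n <- n_sites(variants)
  tally <- c(maf = 0L, call_rate = 0L, hwe = 0L, cnv = 0L, contig_length = 0L)
  if (n == 0L) return(list(variants = variants, tally = tally))

  g <- variants$geno
  call_rate <- rowMeans(!is.na(g))
  n_called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0

  hwe_p <- vapply(seq_len(n), function(i) {
    gi <- g[i, ]
    if (all(is.na(gi))) return(1.0)
    hwe_exact_test(sum(gi == 0L, na.rm = TRUE),
                   sum(gi == 1L, na.rm = TRUE),
                   sum(gi == 2L, na.rm = TRUE))
  }, numeric(1))

  cnv <- if (is.null(variants$depth)) rep(FALSE, n) else cnv_flags(variants, config)
  clen <- variants$contig_lengths[s$contig]
  clen[is.na(clen)] <- .Machine$integer.max
  contig_ok <- clen > (config$min_contig_length_bp - 1L)

  fail_maf <- maf < config$maf_min
  fail_cr <- call_rate < config$call_rate_min
  fail_hwe <- hwe_p < config$hwe_p_min
  fail_cnv <- cnv
  fail_len <- !contig_ok
  keep <- !(fail_maf | fail_cr | fail_hwe | fail_cnv | fail_len)

  first <- rep(NA_character_, n)
  first[fail_len] <- "contig_length"
  first[fail_cnv] <- "cnv"
  first[fail_hwe] <- "hwe"
  first[fail_cr] <- "call_rate"
  first[fail_maf] <- "maf"
  tb <- table(factor(first, levels = names(tally)))
  tally[names(tb)] <- as.integer(tb)

  list(variants = subset_variants(variants, keep), tally = tally)
}
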