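#' Screening configuration
#'
#' Parameters of the sliding-window MNP locus screen: a `window_bp` window
#' advanced by `step_bp` must contain strictly more than
#' `min_snps_exclusive` SNPs and reach a discriminative power of at least
#' `dp_min`; the final amplicon must fall in
#' `[amplicon_min_bp, amplicon_max_bp]` with `flank_clear_bp` SNP-free
#' bases at each end (a primer-landing feasibility proxy), and selected
#' loci keep `min_spacing_bp` start-to-start spacing per contig so the
#' panel spreads over the genome.
#'
#' @param window_bp Window length (default 300).
#' @param step_bp Step size (default 1).
#' @param min_snps_exclusive Window qualifies only with *more than* this
#'   many SNPs (default 3, i.e. >= 4 SNPs).
#' @param dp_min Minimum discriminative power (default 0.2).
#' @param amplicon_min_bp,amplicon_max_bp Amplicon length bounds
#'   (default 200--300), chosen so loci co-amplify without competition.
#' @param flank_clear_bp SNP-free flank length at each amplicon end.
#' @param min_spacing_bp Minimum start-to-start spacing of panel loci on a
#'   contig.
#' @param target_panel_size Panel size cap (default 505).
#' @return A list of class `mnp_screening_config`.
#' @export
screening_config <- function(window_bp = 300L,
                             step_bp = 1L,
                             min_snps_exclusive = 3L,
                             dp_min = 0.2,
                             amplicon_min_bp = 200L,
                             amplicon_max_bp = 300L,
                             flank_clear_bp = 20L,
                             min_spacing_bp = 10000L,
                             target_panel_size = 505L) {
  cfg <- list(window_bp = as.integer(window_bp),
              step_bp = as.integer(step_bp),
              min_snps_exclusive = as.integer(min_snps_exclusive),
              dp_min = dp_min,
              amplicon_min_bp = as.integer(amplicon_min_bp),
              amplicon_max_bp = as.integer(amplicon_max_bp),
              flank_clear_bp = as.integer(flank_clear_bp),
              min_spacing_bp = as.integer(min_spacing_bp),
              target_panel_size = as.integer(target_panel_size))
  if (cfg$step_bp < 1L) stop_config("step_bp must be >= 1")
  if (cfg$dp_min < 0 || cfg$dp_min > 1) stop_config("dp_min must be in [0, 1]")
  if (cfg$amplicon_min_bp > cfg$amplicon_max_bp ||
      cfg$amplicon_max_bp > cfg$window_bp)
    stop_config("need amplicon_min <= amplicon_max <= window_bp")
  class(cfg) <- "mnp_screening_config"
  cfg
}

# Haplotype labels for all samples from a codes matrix (SNPs x samples).
hap_labels_from_codes <- function(gmat, ref, alt) {
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = 1L)
  het <- IUPAC_HET[paste0(ref, alt)]
  sym <- matrix(NA_character_, nrow(gmat), ncol(gmat))
  i0 <- which(gmat == 0L); i1 <- which(gmat == 1L); i2 <- which(gmat == 2L)
  row_of <- function(i) ((i - 1L) %% nrow(gmat)) + 1L
  sym[i0] <- ref[row_of(i0)]
  sym[i2] <- alt[row_of(i2)]
  sym[i1] <- het[row_of(i1)]
  labs <- apply(sym, 2L, function(col) {
    if (anyNA(col)) NA_character_ else paste(col, collapse = "")
  })
  as.character(labs)
}

#' Multi-SNP haplotype label of one sample
#'
#' Concatenates per-SNP genotype symbols into the unphased window haplotype
#' used for discriminative-power scoring: the reference base for hom-ref,
#' the alternate base for hom-alt, the IUPAC ambiguity code for a
#' heterozygous call. Any missing constituent call makes the whole label
#' missing.
#'
#' @param genotypes Integer codes (0/1/2/`NA`) at the window SNPs.
#' @param ref,alt Reference and alternate bases per SNP.
#' @return A character scalar, or `NA_character_`.
#' @export
#' @examples
#' haplotype_of(c(0, 1, 0, 0), c("A", "A", "G", "T"), c("C", "G", "A", "C"))
haplotype_of <- function(genotypes, ref, alt) {
  stopifnot(length(genotypes) >= 1L,
            length(ref) == length(genotypes),
            length(alt) == length(genotypes))
  hap_labels_from_codes(matrix(as.integer(genotypes), ncol = 1L), ref, alt)
}

#' Discriminative power of a locus
#'
#' Fraction of unordered accession pairs whose genotype labels differ,
#' computed with the closed form `1 - sum(choose(n_i, 2)) / choose(n, 2)`
#' over label multiplicities `n_i`. Missing labels are excluded from both
#' numerator and denominator.
#'
#' @param labels Character vector of genotype labels (`NA` = missing).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' discriminative_power(c("g1", "g1", "g2", "g2"))
discriminative_power <- function(labels) {
  l <- labels[!is.na(labels)]
  n <- length(l)
  if (n < 2L) stop_data("discriminative power needs >= 2 non-missing labels")
  tab <- table(l)
  1 - sum(choose(tab, 2)) / choose(n, 2)
}

dp_or_na <- function(labels) {
  if (sum(!is.na(labels)) < 2L) return(NA_real_)
  discriminative_power(labels)
}

#' Sliding-window scan for SNP-dense, discriminating windows
#'
#' Slides a `window_bp` window in `step_bp` steps across every contig and
#' emits each window position holding strictly more than
#' `min_snps_exclusive` SNPs whose joint haplotype reaches `dp_min`
#' discriminative power. Implemented as an event sweep (the SNP content of
#' the window is piecewise constant in the start position), which is
#' exactly equivalent to evaluating every start independently.
#'
#' @param variants Filtered `mnp_variants`.
#' @param config An [screening_config()].
#' @return Data frame of qualifying windows: `contig`, `window_start`,
#'   `window_end` (1-based inclusive), `n_snps`, `dp`, `snp_pos`
#'   (comma-joined positions).
#' @export
scan_windows <- function(variants, config = screening_config()) {
  stopifnot(inherits(variants, "mnp_variants"))
  w <- config$window_bp
  step <- config$step_bp
  out <- list()
  for (ctg in unique(variants$sites$contig)) {
    L <- variants$contig_lengths[[ctg]]
    if (is.na(L)) next
    if (L < w) {
      warning(sprintf("contig %s (%d bp) shorter than the %d-bp window; skipped",
                      ctg, L, w))
      next
    }
    idx <- which(variants$sites$contig == ctg)
    pos <- variants$sites$pos[idx]
    if (length(pos) == 0L) next
    max_start <- L - w + 1L
    brk <- sort(unique(pmax(1L, pmin(max_start + 1L,
                                     c(1L, pos - w + 1L, pos + 1L)))))
    brk <- brk[brk <= max_start]
    seg_end <- c(brk[-1L] - 1L, max_start)
    for (si in seq_along(brk)) {
      a <- brk[si]; b <- seg_end[si]
      i_lo <- findInterval(a - 1L, pos) + 1L
      i_hi <- findInterval(a + w - 1L, pos)
      cnt <- i_hi - i_lo + 1L
      if (cnt <= config$min_snps_exclusive) next
      sub <- idx[i_lo:i_hi]
      labs <- hap_labels_from_codes(variants$geno[sub, , drop = FALSE],
                                    variants$sites$ref[sub],
                                    variants$sites$alt[sub])
      dp <- dp_or_na(labs)
      if (is.na(dp) || dp < config$dp_min) next
      s0 <- a + ((step - ((a - 1L) %% step)) %% step)
      starts <- if (s0 > b) integer(0) else seq.int(s0, b, by = step)
      if (!length(starts)) next
      out[[length(out) + 1L]] <- data.table::data.table(
        contig = ctg, window_start = starts, window_end = starts + w - 1L,
        n_snps = cnt, dp = dp,
        snp_pos = paste(pos[i_lo:i_hi], collapse = ","))
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), window_start = integer(0),
                      window_end = integer(0), n_snps = integer(0),
                      dp = numeric(0), snp_pos = character(0)))
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Merge overlapping qualifying windows into candidate loci
#'
#' A 1-bp-step scan emits long runs of near-duplicate windows over each
#' SNP cluster. Overlapping windows on a contig are merged into runs; the
#' run is represented by the best window in (DP, then SNP count, then
#' leftmost start) order *whose amplicon is feasible*: the tightest span
#' covering the window's SNPs plus a `flank_clear_bp` SNP-free flank on
#' each side, extended to `amplicon_min_bp`, must fit
#' `[amplicon_min_bp, amplicon_max_bp]` and keep both flanks free of any
#' SNP. A run with no feasible representative is dropped with a message.
#' The reported DP and SNP count are recomputed over the full amplicon SNP
#' set (length extension can take in additional SNPs), and the amplicon DP
#' must still reach `dp_min`.
#'
#' @param windows Output of [scan_windows()].
#' @param variants The same filtered `mnp_variants` (for flank checks and
#'   contig lengths).
#' @param config An [screening_config()].
#' @return Candidate loci as an `mnp_panel`-shaped data frame.
#' @export
merge_to_candidates <- function(windows, variants,
                                config = screening_config()) {
  if (nrow(windows) == 0L) {
    return(structure(data.frame(
      locus_id = character(0), contig = character(0),
      amplicon_start = integer(0), amplicon_end = integer(0),
      window_start = integer(0), window_end = integer(0),
      dp = numeric(0), n_snps = integer(0), snp_pos = character(0),
      stringsAsFactors = FALSE), class = c("mnp_panel", "data.frame")))
  }
  w <- config$window_bp
  res <- list()
  for (ctg in unique(windows$contig)) {
    ww <- windows[windows$contig == ctg, , drop = FALSE]
    ww <- ww[order(ww$window_start), , drop = FALSE]
    run <- cumsum(c(1L, as.integer(
      ww$window_start[-1L] > head(ww$window_end, -1L))))
    all_pos <- variants$sites$pos[variants$sites$contig == ctg]
    L <- variants$contig_lengths[[ctg]]
    for (r in unique(run)) {
      sub <- ww[run == r, , drop = FALSE]
      # Candidate representative windows in priority order; windows sharing
      # one SNP set share amplicon and score, so deduplicate by SNP set
      # keeping the leftmost start of each.
      sub <- sub[order(-sub$dp, -sub$n_snps, sub$window_start), , drop = FALSE]
      sub <- sub[!duplicated(sub$snp_pos), , drop = FALSE]
      placed <- FALSE
      for (ci in seq_len(nrow(sub))) {
        best <- sub[ci, ]
        snp_pos <- as.integer(strsplit(best$snp_pos, ",", fixed = TRUE)[[1L]])
        span <- amplicon_span(min(snp_pos), max(snp_pos), L,
                              config$amplicon_min_bp, config$amplicon_max_bp,
                              config$flank_clear_bp)
        if (is.null(span)) next
        fl <- config$flank_clear_bp
        flank_hit <- any(
          (all_pos >= span[["start"]] & all_pos < span[["start"]] + fl) |
          (all_pos > span[["end"]] - fl & all_pos <= span[["end"]]))
        if (flank_hit) next
        # The amplicon may take in SNPs beyond the representative window
        # (length extension); score the locus on its full amplicon SNP set.
        inside <- which(variants$sites$contig == ctg &
                        variants$sites$pos >= span[["start"]] &
                        variants$sites$pos <= span[["end"]])
        labs <- hap_labels_from_codes(variants$geno[inside, , drop = FALSE],
                                      variants$sites$ref[inside],
                                      variants$sites$alt[inside])
        dp <- dp_or_na(labs)
        if (is.na(dp) || dp < config$dp_min) next
        res[[length(res) + 1L]] <- data.frame(
          locus_id = sprintf("MNP_%s_%06d", ctg, span[["start"]]),
          contig = ctg,
          amplicon_start = span[["start"]], amplicon_end = span[["end"]],
          window_start = best$window_start, window_end = best$window_end,
          dp = dp, n_snps = length(inside),
          snp_pos = paste(sort(variants$sites$pos[inside]), collapse = ","),
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        message(sprintf(
          "candidate run at %s:%d dropped: no representative window with a feasible amplicon",
          ctg, min(sub$window_start)))
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(locus_id = character(0), contig = character(0),
               amplicon_start = integer(0), amplicon_end = integer(0),
               window_start = integer(0), window_end = integer(0),
               dp = numeric(0), n_snps = integer(0), snp_pos = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mnp_panel", "data.frame")
  out
}

#' Select a genome-spaced panel from candidate loci
#'
#' Greedy selection in descending (DP, SNP count, leftmost start,
#' contig) order; a candidate within `min_spacing_bp` (start-to-start) of
#' an already selected locus on the same contig is skipped. Selection
#' stops at `target_panel_size`; fewer loci may be returned.
#'
#' @param candidates Output of [merge_to_candidates()].
#' @param config An [screening_config()].
#' @return An `mnp_panel` sorted by (contig, amplicon_start).
#' @export
space_panel <- function(candidates, config = screening_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$dp, -candidates$n_snps,
               candidates$amplicon_start, candidates$contig)
  cand <- candidates[ord, , drop = FALSE]
  sel <- integer(0)
  sel_start <- split(integer(0), character(0))
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= config$target_panel_size) break
    ctg <- cand$contig[i]
    st <- cand$amplicon_start[i]
    prev <- sel_start[[ctg]]
    if (!is.null(prev) && any(abs(prev - st) < config$min_spacing_bp)) next
    sel <- c(sel, i)
    sel_start[[ctg]] <- c(prev, st)
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$contig, out$amplicon_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mnp_panel", "data.frame")
  out
}

#' Full screening pipeline: scan, merge, space
#'
#' @param variants Filtered `mnp_variants`.
#' @param config An [screening_config()].
#' @return An `mnp_panel`.
#' @export
screen_panel <- function(variants, config = screening_config()) {
  space_panel(merge_to_candidates(scan_windows(variants, config),
                                  variants, config),
              config)
}
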