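# Canonical allele-set string matrix: loci x accessions, NA when not
# called. The canonical form (sorted, semicolon-joined sequences) makes
# allele-set equality a string comparison.
fingerprint_matrix <- function(fingerprints) {
  loci <- sort(unique(fingerprints$locus_id))
  acc <- sort(unique(fingerprints$accession))
  m <- matrix(NA_character_, length(loci), length(acc),
              dimnames = list(loci, acc))
  called <- fingerprints$status == "called"
  f <- fingerprints[called, , drop = FALSE]
  m[cbind(match(f$locus_id, loci), match(f$accession, acc))] <- f$alleles
  m
}

#' Genetic similarity between two accessions
#'
#' A locus counts as identical when it is called in both accessions and
#' the two allele-sequence sets are equal. Genetic similarity (GS) divides
#' the identical-locus count by the full panel size (`"panel"` mode, the
#' default reading of "total number of core MNP sequences") or by the
#' number of loci called in both (`"shared_called"`). The differentiation
#' ratio is always differential loci over loci compared in both.
#'
#' @param fpA,fpB `mnp_fingerprints` rows for one accession each, over the
#'   same panel.
#' @param denominator `"panel"` or `"shared_called"`.
#' @param panel_size Panel size used in `"panel"` mode (defaults to the
#'   loci present).
#' @return A one-row data frame: `accession_a`, `accession_b`,
#'   `n_compared`, `n_identical`, `n_differential`, `gs`,
#'   `differentiation_ratio`.
#' @export
genetic_similarity <- function(fpA, fpB,
                               denominator = c("panel", "shared_called"),
                               panel_size = NULL) {
  denominator <- match.arg(denominator)
  la <- sort(unique(fpA$locus_id)); lb <- sort(unique(fpB$locus_id))
  if (!identical(la, lb)) stop_data("fingerprints cover different panels")
  both <- rbind(fpA, fpB)
  m <- fingerprint_matrix(both)
  compare_columns(m[, unique(fpA$accession)], m[, unique(fpB$accession)],
                  unique(fpA$accession), unique(fpB$accession),
                  denominator, panel_size %||% nrow(m))
}

compare_columns <- function(a, b, id_a, id_b, denominator, panel_size) {
  both <- !is.na(a) & !is.na(b)
  n_compared <- sum(both)
  n_identical <- sum(both & a == b, na.rm = TRUE)
  n_diff <- n_compared - n_identical
  gs <- if (denominator == "panel") n_identical / panel_size
        else if (n_compared > 0) n_identical / n_compared else NA_real_
  data.frame(accession_a = id_a, accession_b = id_b,
             n_compared = n_compared, n_identical = n_identical,
             n_differential = n_diff, gs = gs,
             differentiation_ratio = if (n_compared > 0)
               n_diff / n_compared else NA_real_,
             stringsAsFactors = FALSE)
}

#' All pairwise accession comparisons
#'
#' Exactly `choose(n, 2)` comparisons in deterministic order (sorted
#' accession-id pairs).
#'
#' @param fingerprints An `mnp_fingerprints` data frame for the cohort.
#' @param denominator See [genetic_similarity()].
#' @param panel_size Panel size for `"panel"` mode.
#' @return Data frame of comparison rows, one per unordered pair.
#' @export
pairwise_compare <- function(fingerprints,
                             denominator = c("panel", "shared_called"),
                             panel_size = NULL) {
  denominator <- match.arg(denominator)
  per_acc <- table(fingerprints$accession)
  if (length(unique(per_acc)) > 1L)
    stop_data("accessions cover different numbers of loci")
  m <- fingerprint_matrix(fingerprints)
  acc <- colnames(m)
  if (length(acc) < 2L) stop_data("need at least two accessions")
  if (anyDuplicated(fingerprints[, c("accession", "locus_id")]))
    stop_data("duplicate accession x locus rows")
  ps <- panel_size %||% nrow(m)
  pairs <- utils::combn(acc, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    compare_columns(m[, pairs[1L, k]], m[, pairs[2L, k]],
                    pairs[1L, k], pairs[2L, k], denominator, ps)
  })
  do.call(rbind, out)
}

#' Reproducibility between two genotyping runs
#'
#' Compares the accession x locus cells called in both runs; a cell is
#' reproducible when the allele sets are identical.
#'
#' @param run1,run2 `mnp_fingerprints` over the same accessions and panel.
#' @return A list: `n_compared`, `n_reproducible`, `fraction`.
#' @export
reproducibility <- function(run1, run2) {
  if (!setequal(unique(run1$accession), unique(run2$accession)))
    stop_data("the two runs cover different accession sets")
  m1 <- fingerprint_matrix(run1)
  m2 <- fingerprint_matrix(run2)
  if (!identical(dimnames(m1), dimnames(m2)))
    stop_data("the two runs cover different panels")
  both <- !is.na(m1) & !is.na(m2)
  n_compared <- sum(both)
  if (n_compared == 0L) stop_data("no locus called in both runs; ratio undefined")
  n_rep <- sum(both & m1 == m2, na.rm = TRUE)
  list(n_compared = n_compared, n_reproducible = n_rep,
       fraction = n_rep / n_compared)
}

#' Genotyping accuracy from reproducibility
#'
#' With two independent replicate runs, a discordant cell means exactly
#' one of the two calls is wrong, so the per-run accuracy is
#' `1 - (1 - reproducibility) / 2`: an affine map sending reproducibility
#' 0 to accuracy 0.5 and 1 to 1.
#'
#' @param r Reproducible-locus fraction in \[0, 1\].
#' @return Accuracy in \[0.5, 1\].
#' @export
#' @examples
#' accuracy_from_reproducibility(0.9980)  # 0.9990
#' accuracy_from_reproducibility(0.9978)  # 0.9989
accuracy_from_reproducibility <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r > 1))
    stop_data("reproducibility must be in [0, 1]")
  1 - (1 - r) / 2
}

#' Polymorphism information content
#'
#' Botstein's PIC from population allele frequencies:
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return PIC in \[0, 1).
#' @export
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
pic <- function(freqs) {
  if (length(freqs) == 0L) stop_data("empty frequency vector")
  if (any(freqs < 0)) stop_data("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop_data("frequencies must sum to 1")
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - s4)
}

#' Per-locus allele counts, frequencies, PIC and detection rates
#'
#' Counts the distinct allele sequences observed per locus across the
#' cohort. Frequencies treat each accession's called allele set as one
#' observation per member allele (no ploidy weighting). Summaries use the
#' sample (n-1) standard deviation; the count of loci with more than 10
#' alleles is reported as the conventional high-polymorphism tally.
#'
#' @param fingerprints An `mnp_fingerprints` data frame.
#' @return A list with `per_locus` (data frame: `locus_id`,
#'   `allele_count`, `pic`, `detection_rate`) and `summary` (list:
#'   `mean_alleles`, `sd_alleles`, `mean_pic`, `sd_pic`,
#'   `n_loci_gt10_alleles`).
#' @export
allele_stats <- function(fingerprints) {
  if (nrow(fingerprints) == 0L) stop_data("empty fingerprint table")
  m <- fingerprint_matrix(fingerprints)
  n_acc <- ncol(m)
  per <- lapply(rownames(m), function(l) {
    sets <- m[l, ]
    called <- !is.na(sets)
    alleles <- unlist(strsplit(sets[called], ";", fixed = TRUE),
                      use.names = FALSE)
    if (length(alleles) == 0L) {
      return(data.frame(locus_id = l, allele_count = 0L, pic = NA_real_,
                        detection_rate = 0, stringsAsFactors = FALSE))
    }
    tab <- table(alleles)
    data.frame(locus_id = l,
               allele_count = length(tab),
               pic = pic(as.numeric(tab) / sum(tab)),
               detection_rate = mean(called),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  detected <- per[per$allele_count > 0L, , drop = FALSE]
  list(per_locus = per,
       summary = list(
         mean_alleles = mean(detected$allele_count),
         sd_alleles = sd(detected$allele_count),
         mean_pic = mean(detected$pic),
         sd_pic = sd(detected$pic),
         n_loci_gt10_alleles = sum(detected$allele_count > 10L)))
}

#' Molecular ID codes
#'
#' Assigns each accession a canonical fingerprint string and a stable
#' hexadecimal digest of it. The panel allele registry maps every locus's
#' distinct allele sequences to integer indices in lexicographic order;
#' the canonical string concatenates, in locus order, the sorted allele
#' indices of the accession (`.` for a no-call). Alleles absent from a
#' supplied registry extend it deterministically (appended in
#' lexicographic order) with a warning. The canonical string, not the
#' digest, is the normative identifier.
#'
#' @param fingerprints An `mnp_fingerprints` data frame.
#' @param registry Optional registry (named list locus_id -> sorted
#'   character vector of alleles), e.g. from a reference cohort.
#' @return A list: `ids` (data frame `accession`, `canonical`, `digest`)
#'   and `registry` (possibly extended).
#' @export
molecular_id <- function(fingerprints, registry = NULL) {
  m <- fingerprint_matrix(fingerprints)
  loci <- rownames(m)
  observed <- lapply(loci, function(l) {
    sort(unique(unlist(strsplit(m[l, !is.na(m[l, ])], ";", fixed = TRUE),
                       use.names = FALSE)))
  })
  names(observed) <- loci
  if (is.null(registry)) {
    registry <- observed
  } else {
    for (l in loci) {
      new <- setdiff(observed[[l]], registry[[l]] %||% character(0))
      if (length(new)) {
        warning(sprintf("locus %s: %d alleles absent from registry; extended",
                        l, length(new)))
        registry[[l]] <- c(registry[[l]] %||% character(0), sort(new))
      }
    }
  }
  ids <- lapply(colnames(m), function(a) {
    parts <- vapply(loci, function(l) {
      s <- m[l, a]
      if (is.na(s)) return(".")
      idx <- match(strsplit(s, ";", fixed = TRUE)[[1L]], registry[[l]])
      paste(sort(idx), collapse = ",")
    }, character(1))
    canonical <- paste(parts, collapse = ";")
    data.frame(accession = a, canonical = canonical,
               digest = digest_string(canonical), stringsAsFactors = FALSE)
  })
  list(ids = do.call(rbind, ids), registry = registry)
}
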