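#' Multi-sample SNP genotype container
#'
#' Holds biallelic SNP sites and a diploid-coded genotype matrix for a
#' cohort: 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing. Positions are
#' 1-based (VCF convention); coordinates are converted to 0-based half-open
#' only in BED-like panel files.
#'
#' @param sites Data frame with columns `contig`, `pos`, `ref`, `alt`,
#'   sorted by (contig, pos).
#' @param geno Integer matrix, one row per site, one column per sample,
#'   values in \{0, 1, 2, NA\}.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param depth Optional numeric matrix of per-sample read depths, same
#'   shape as `geno`; used by the copy-number filter.
#' @return An object of class `mnp_variants`.
#' @export
mnp_variants <- function(sites, geno, contig_lengths, depth = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(geno))
  if (any(sites$pos < 1L)) stop_data("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop_data("ref and alt alleles must differ")
  if (is.null(colnames(geno))) stop_data("geno must have sample names")
  structure(list(sites = sites, geno = geno,
                 samples = colnames(geno),
                 contig_lengths = contig_lengths,
                 depth = depth),
            class = "mnp_variants")
}

#' @export
print.mnp_variants <- function(x, ...) {
  cat(sprintf("mnp_variants: %d SNPs x %d samples on %d contigs\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$contig))))
  invisible(x)
}

n_sites <- function(x) nrow(x$sites)

subset_variants <- function(x, idx) {
  mnp_variants(x$sites[idx, , drop = FALSE],
               x$geno[idx, , drop = FALSE],
               x$contig_lengths,
               if (!is.null(x$depth)) x$depth[idx, , drop = FALSE])
}

#' Write / read reference FASTA
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] and
#' [Biostrings::readDNAStringSet()].
#'
#' @param x A `DNAStringSet`.
#' @param path Output path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` a
#'   `DNAStringSet`.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write amplicon reads as FASTQ
#'
#' Reads carry accession and locus identity in their names
#' (`accession|locus|serial`); a constant high base quality is written, as
#' the genotyper does not use base qualities.
#'
#' @param reads An `mnp_reads` data frame.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(s)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read amplicon reads from FASTQ
#'
#' Parses `accession|locus|serial` read names back into the tagged
#' `mnp_reads` layout; names without the delimiter yield `NA` tags (such
#' reads can still be assigned by flank matching).
#'
#' @param path FASTQ path.
#' @return An `mnp_reads` data frame.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- names(s)
  parts <- strsplit(ids, "|", fixed = TRUE)
  acc <- vapply(parts, function(p) if (length(p) >= 3L) p[1L] else NA_character_,
                character(1))
  loc <- vapply(parts, function(p) if (length(p) >= 3L) p[2L] else NA_character_,
                character(1))
  reads <- data.frame(read_id = ids, accession = acc, locus_id = loc,
                      seq = as.character(s), stringsAsFactors = FALSE)
  class(reads) <- c("mnp_reads", "data.frame")
  reads
}

#' Write genotypes as multi-sample VCF v4.2
#'
#' @param variants An `mnp_variants` object.
#' @param path Output path; `vcfR` writes gzip-compressed VCF, so a
#'   `.vcf.gz` suffix is conventional.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(variants),
               ncol = length(variants$samples))
  ok <- !is.na(variants$geno)
  gt[ok] <- gt_code[variants$geno[ok] + 1L]
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", variants$samples)
  fix <- cbind(
    CHROM = variants$sites$contig,
    POS = as.character(variants$sites$pos),
    ID = ".",
    REF = variants$sites$ref,
    ALT = variants$sites$alt,
    QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##source=mnpkit",
            sprintf("##contig=<ID=%s,length=%d>",
                    names(variants$contig_lengths),
                    as.integer(variants$contig_lengths)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a multi-sample VCF into an `mnp_variants` object
#'
#' Biallelic SNP records only; others are dropped with a message. Contig
#' lengths are taken from `##contig` header lines when present.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @return An `mnp_variants` object.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  if (!all(keep))
    message(sum(!keep), " non-biallelic-SNP records dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  code[norm == "0/0"] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm == "1/1"] <- 2L
  colnames(code) <- colnames(gt)
  sites <- data.frame(contig = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  meta <- v@meta
  cl <- meta[grepl("^##contig=", meta)]
  lens <- NULL
  if (length(cl)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", cl)
    ln <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", cl)))
    lens <- setNames(ln, ids)
  }
  if (is.null(lens) || anyNA(lens)) {
    lens <- tapply(sites$pos, sites$contig, max)
    lens <- setNames(as.integer(lens), names(lens))
  }
  ord <- order(match(sites$contig, unique(sites$contig)), sites$pos)
  mnp_variants(sites[ord, , drop = FALSE], code[ord, , drop = FALSE], lens)
}

#' Write / read an MNP panel as BED-like TSV
#'
#' Columns: `contig`, `amplicon_start`, `amplicon_end` (0-based half-open,
#' BED convention), `locus_id`, `dp`, `n_snps`, `snp_positions`
#' (comma-separated, 0-based). In memory the panel uses 1-based inclusive
#' coordinates; conversion happens only here.
#'
#' @param panel An `mnp_panel` data frame.
#' @param path Output TSV path.
#' @return `write_panel` returns `path` invisibly; `read_panel` an
#'   `mnp_panel`.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(
    contig = panel$contig,
    amplicon_start = panel$amplicon_start - 1L,
    amplicon_end = panel$amplicon_end,
    locus_id = panel$locus_id,
    dp = panel$dp,
    n_snps = panel$n_snps,
    snp_positions = vapply(strsplit(panel$snp_pos, ",", fixed = TRUE),
                           function(p) paste(as.integer(p) - 1L, collapse = ","),
                           character(1)),
    window_start = panel$window_start - 1L,
    window_end = panel$window_end,
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines("# mnpkit panel; coordinates 0-based half-open (BED)", con)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  p <- data.frame(
    locus_id = d$locus_id,
    contig = d$contig,
    amplicon_start = d$amplicon_start + 1L,
    amplicon_end = d$amplicon_end,
    window_start = d$window_start + 1L,
    window_end = d$window_end,
    dp = d$dp,
    n_snps = d$n_snps,
    snp_pos = vapply(strsplit(as.character(d$snp_positions), ",", fixed = TRUE),
                     function(x) paste(as.integer(x) + 1L, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  class(p) <- c("mnp_panel", "data.frame")
  p
}

#' Write / read fingerprint tables as TSV
#'
#' One row per accession x panel locus: `accession`, `locus_id`, `status`,
#' `depth`, `alleles` (semicolon-joined, lexicographically sorted haplotype
#' sequences), `fractions` (semicolon-joined read fractions).
#'
#' @param fp An `mnp_fingerprints` data frame.
#' @param path TSV path.
#' @return `write_fingerprints` returns `path` invisibly;
#'   `read_fingerprints` an `mnp_fingerprints`.
#' @export
write_fingerprints <- function(fp, path) {
  write.table(fp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = "NA")
  d$alleles[is.na(d$alleles)] <- ""
  if ("fractions" %in% names(d)) d$fractions[is.na(d$fractions)] <- ""
  class(d) <- c("mnp_fingerprints", "data.frame")
  d
}
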