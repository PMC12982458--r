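#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# Unordered-pair IUPAC ambiguity codes used for heterozygous calls.
IUPAC_HET <- c(
  "AG" = "R", "GA" = "R",
  "CT" = "Y", "TC" = "Y",
  "CG" = "S", "GC" = "S",
  "AT" = "W", "TA" = "W",
  "GT" = "K", "TG" = "K",
  "AC" = "M", "CA" = "M"
)

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("mnp_config_error", "error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("mnp_data_error", "error")))
}

#' Hamming distance between two equal-length strings
#'
#' Substitution-only distance; used when folding rare, error-derived read
#' sequences into abundant haplotypes. Strings of unequal length are
#' incomparable and return `NA_integer_`.
#'
#' @param a,b Character scalars.
#' @return Integer distance, or `NA_integer_` when lengths differ.
#' @export
#' @examples
#' hamming("ACGT", "ACGA")
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Stable hex digest of a string (md5 of its bytes). Used for molecular ID
# codes and output manifests; the canonical string, not the digest, is the
# normative identifier.
digest_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, open = "wb")
  writeBin(charToRaw(x), con)
  close(con)
  unname(tools::md5sum(tf))
}

digest_file <- function(path) unname(tools::md5sum(path))

# Stage-specific deterministic seeds so each generator stage is reproducible
# in isolation as well as inside the pipeline.
stage_seed <- function(seed, stage) {
  offsets <- c(reference = 11L, variants = 23L, reads = 37L, pipeline = 53L)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}
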