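# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths.

# Exact HWE test by direct closed-form enumeration over all heterozygote
# counts with the observed allele totals (log-factorial form, no
# recurrence).
oracle_hwe <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  n_a <- 2L * n_homalt + n_het
  n_b <- 2L * n_homref + n_het
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1.0)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    homa <- (rare - h) / 2
    homb <- (2L * n - rare - h) / 2
    lfactorial(n) - lfactorial(homa) - lfactorial(h) - lfactorial(homb) +
      h * log(2) + lfactorial(rare) + lfactorial(2L * n - rare) -
      lfactorial(2L * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1.0, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

# Discriminative power by explicit enumeration of unordered pairs.
oracle_dp <- function(labels) {
  l <- labels[!is.na(labels)]
  n <- length(l)
  diff <- 0L; tot <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    tot <- tot + 1L
    if (l[i] != l[j]) diff <- diff + 1L
  }
  diff / tot
}

# Sliding-window scan by brute force: evaluate every start independently.
oracle_scan <- function(variants, config) {
  w <- config$window_bp
  out <- list()
  for (ctg in unique(variants$sites$contig)) {
    L <- variants$contig_lengths[[ctg]]
    if (L < w) next
    idx <- which(variants$sites$contig == ctg)
    pos <- variants$sites$pos[idx]
    for (s in seq.int(1L, L - w + 1L, by = config$step_bp)) {
      inside <- idx[pos >= s & pos <= s + w - 1L]
      if (length(inside) <= config$min_snps_exclusive) next
      labs <- apply(variants$geno[inside, , drop = FALSE], 2L, function(g) {
        haplotype_of(g, variants$sites$ref[inside], variants$sites$alt[inside])
      })
      if (sum(!is.na(labs)) < 2L) next
      dp <- oracle_dp(labs)
      if (dp < config$dp_min) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, window_start = s, window_end = s + w - 1L,
        n_snps = length(inside), dp = dp,
        snp_pos = paste(variants$sites$pos[inside], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Naive O(n^3) UPGMA; returns the cophenetic (merge-distance) matrix.
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  sizes <- rep(1L, length(labs))
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  cur <- d
  while (length(clusters) > 1L) {
    n <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (cur[i, j] < best[1]) best <- c(cur[i, j], i, j)
    }
    i <- best[2]; j <- best[3]; h <- best[1]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    merged_row <- (sizes[i] * cur[i, ] + sizes[j] * cur[j, ]) /
      (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(n), c(i, j))
    new <- matrix(0, n - 1L, n - 1L)
    new[seq_along(keep), seq_along(keep)] <- cur[keep, keep]
    new[n - 1L, seq_along(keep)] <- merged_row[keep]
    new[seq_along(keep), n - 1L] <- merged_row[keep]
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    cur <- new
  }
  coph
}

# Small simulation shared by several tests.
tiny_sim <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_contigs = 12L, planted_locus_count = 10L, n_accessions = 12L,
         n_founder_haplotypes = 8L, cluster_count = 2L,
         read_depth_mean = 60L, seq_error_rate = 0, dropout_rate = 0,
         snp_rate = 0.0005, rng_seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Build an mnp_variants object from a compact spec: positions plus a
# genotype matrix (rows = SNPs, cols = samples).
make_variants <- function(pos, geno, ref = NULL, alt = NULL,
                          contig = "ctg", contig_len = 10000L) {
  n <- length(pos)
  ref <- ref %||% rep(c("A", "C", "G", "T"), length.out = n)
  alt <- alt %||% rep(c("G", "T", "A", "C"), length.out = n)
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%02d", seq_len(ncol(geno)))
  mnp_variants(
    data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    geno, setNames(as.integer(contig_len), contig))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truth-set fingerprints recast as a called mnp_fingerprints table.
make_truth_fp <- function(truth) {
  fp <- data.frame(accession = truth$fingerprints$accession,
                   locus_id = truth$fingerprints$locus_id,
                   status = "called", depth = 100L,
                   alleles = truth$fingerprints$alleles,
                   fractions = "", stringsAsFactors = FALSE)
  class(fp) <- c("mnp_fingerprints", "data.frame")
  fp
}

# Minimal fingerprint table from a matrix of canonical allele strings
# (rows = loci, cols = accessions; NA = no call).
make_fingerprints <- function(m) {
  fp <- do.call(rbind, lapply(colnames(m), function(a) {
    data.frame(accession = a, locus_id = rownames(m),
               status = ifelse(is.na(m[, a]), "no_call_low_depth", "called"),
               depth = ifelse(is.na(m[, a]), 0L, 100L),
               alleles = ifelse(is.na(m[, a]), "", m[, a]),
               fractions = "", stringsAsFactors = FALSE)
  }))
  class(fp) <- c("mnp_fingerprints", "data.frame")
  fp
}
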