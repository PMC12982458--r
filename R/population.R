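#' Distance matrix from pairwise genetic similarity
#'
#' Builds the symmetric dissimilarity matrix `1 - GS` from pairwise
#' comparison rows ([pairwise_compare()]).
#'
#' @param comparisons Data frame with `accession_a`, `accession_b`, `gs`.
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   accession.
#' @export
gs_distance <- function(comparisons) {
  acc <- sort(unique(c(comparisons$accession_a, comparisons$accession_b)))
  d <- matrix(0, length(acc), length(acc), dimnames = list(acc, acc))
  i <- match(comparisons$accession_a, acc)
  j <- match(comparisons$accession_b, acc)
  d[cbind(i, j)] <- 1 - comparisons$gs
  d[cbind(j, i)] <- 1 - comparisons$gs
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_data("distance matrix must be square")
  if (is.null(rownames(d))) stop_data("distance matrix must be labelled")
  if (any(d < 0)) stop_data("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-12) stop_data("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_data("distance matrix diagonal must be 0")
  invisible(d)
}

#' UPGMA clustering
#'
#' Standard unweighted pair-group method with arithmetic mean: repeatedly
#' merge the closest cluster pair; the distance of the merged cluster to
#' the rest is the size-weighted arithmetic mean. Node heights are half
#' the merge distance, so cophenetic distances on the returned ultrametric
#' tree reproduce the UPGMA merge distances. Labels are ordered
#' lexicographically before clustering so equal-distance ties resolve
#' reproducibly.
#'
#' @param d Symmetric distance matrix with zero diagonal, labelled.
#' @return An [ape::as.phylo()] tree (class `phylo`) with branch lengths.
#' @export
upgma <- function(d) {
  check_distance_matrix(d)
  if (nrow(d) < 2L) stop_data("need at least two accessions")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Newick export
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; when given the Newick string is also written
#'   there.
#' @return The Newick string (terminated with `;`), invisibly when writing
#'   to a file.
#' @export
to_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical multidimensional scaling: double-center `-D^2/2`,
#' eigendecompose, return the top axes scaled by the square root of their
#' eigenvalues. Negative eigenvalues (a non-Euclidean distance matrix) are
#' truncated with a message; explained fractions are relative to the sum
#' of positive eigenvalues, hence non-increasing and summing to at most 1.
#' Each axis's sign is fixed by making its largest-magnitude coordinate
#' positive.
#'
#' @param d Symmetric distance matrix with zero diagonal, labelled.
#' @param n_axes Number of axes to return; must be `< nrow(d)`.
#' @return A list: `coordinates` (matrix, accessions x axes), `explained`
#'   (fractions for the returned axes), `eigenvalues` (all positive
#'   eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2L) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n_axes >= n) stop_data("n_axes must be smaller than the number of points")
  # cmdscale warns when fewer than k eigenvalues are positive; truncation
  # is handled (and reported) below.
  mds <- suppressWarnings(cmdscale(as.dist(d), k = n - 1L, eig = TRUE))
  eig <- mds$eig
  if (any(eig < -1e-8 * max(abs(eig))))
    message(sprintf("pcoa: %d negative eigenvalues truncated",
                    sum(eig < -1e-8 * max(abs(eig)))))
  pos <- eig[eig > 1e-12 * max(abs(eig), 1)]
  k <- min(n_axes, length(pos), ncol(mds$points))
  coords <- mds$points[, seq_len(k), drop = FALSE]
  if (k < n_axes) {
    pad <- matrix(0, n, n_axes - k)
    coords <- cbind(coords, pad)
  }
  for (j in seq_len(ncol(coords))) {
    big <- which.max(abs(coords[, j]))
    if (length(big) && coords[big, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  explained <- c(pos[seq_len(k)] / sum(pos),
                 rep(0, n_axes - k))[seq_len(n_axes)]
  list(coordinates = coords, explained = explained, eigenvalues = pos)
}

#' One-hot allele PCA input matrix
#'
#' Alternative ordination input: a binary accession x (locus, allele)
#' presence matrix of called alleles, for a plain PCA instead of PCoA on
#' the similarity matrix.
#'
#' @param fingerprints An `mnp_fingerprints` data frame.
#' @return Binary matrix, accessions in rows.
#' @export
allele_onehot <- function(fingerprints) {
  called <- fingerprints[fingerprints$status == "called", , drop = FALSE]
  al <- strsplit(called$alleles, ";", fixed = TRUE)
  long <- data.frame(
    accession = rep(called$accession, lengths(al)),
    feature = paste(rep(called$locus_id, lengths(al)),
                    unlist(al, use.names = FALSE), sep = ":"),
    stringsAsFactors = FALSE)
  acc <- sort(unique(fingerprints$accession))
  feats <- sort(unique(long$feature))
  m <- matrix(0L, length(acc), length(feats), dimnames = list(acc, feats))
  m[cbind(match(long$accession, acc), match(long$feature, feats))] <- 1L
  m
}
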