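# Oligonucleotide-frequency (ONF) signatures and their PCA ordination.

#' Oligonucleotide frequency matrix
#'
#' Overlapping k-mer counts on the given strand (16S genes are oriented,
#' so no strand canonicalization by default), normalized to relative
#' frequencies per sequence. k-mers containing N are skipped; sequences
#' shorter than k or without countable k-mers are rejected with a message.
#'
#' @param seqs named character vector of DNA sequences.
#' @param k k-mer size (1-6; tetranucleotides by default).
#' @param canonical also count the reverse-complement strand (for
#'   unoriented contig input).
#' @return Matrix (sequences x 4^k k-mers) of relative frequencies, rows
#'   summing to 1, with attribute `k`.
#' @export
onf_matrix <- function(seqs, k = 4, canonical = FALSE) {
  if (k < 1 || k > 6) rb_invalid("k must be in 1..6")
  keep <- nchar(seqs) >= k
  if (!all(keep)) {
    message("onf_matrix: dropped ", sum(!keep), " sequence(s) shorter than k")
    seqs <- seqs[keep]
  }
  if (length(seqs) == 0) rb_invalid("no usable sequences")
  nms <- names(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  if (canonical) {
    counts <- counts +
      Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(set),
                                           width = k)
  }
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    message("onf_matrix: dropped ", sum(tot == 0),
            " sequence(s) with no countable k-mers")
    counts <- counts[tot > 0, , drop = FALSE]
    nms <- nms[tot > 0]
    tot <- tot[tot > 0]
  }
  if (nrow(counts) == 0) rb_invalid("no usable sequences")
  out <- counts / tot
  rownames(out) <- nms
  attr(out, "k") <- k
  out
}

#' PCA of an ONF matrix
#'
#' Column-mean centering (no scaling) followed by an eigendecomposition of
#' the covariance; components are ordered by decreasing variance. Sign
#' convention: the largest-magnitude entry of each loading vector is
#' positive.
#'
#' @param X numeric matrix (sequences x features).
#' @param n_components number of components to return.
#' @return List with `scores` (n x n_components), `loadings`,
#'   `explained_variance` (fractions of total variance) and `center`.
#' @export
onf_pca <- function(X, n_components = 2) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_components > rank)
    rb_invalid(sprintf("n_components (%d) exceeds matrix rank (%d)",
                       n_components, rank))
  idx <- seq_len(n_components)
  load <- pc$rotation[, idx, drop = FALSE]
  sco <- pc$x[, idx, drop = FALSE]
  for (j in idx) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = load,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[idx],
       center = pc$center)
}
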