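# Multiple alignment (progressive, UPGMA guide tree on k-mer cosine
# distances, profile-profile Needleman-Wunsch) and per-column Shannon
# entropy profiling.

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under linear gap penalties. Traceback ties are
#' broken deterministically: diagonal > up (gap in `b`) > left (gap in
#' `a`).
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap scores (linear gap).
#' @return List with aligned strings `a`, `b` and the optimal `score`.
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  if (!nzchar(a) || !nzchar(b)) rb_invalid("sequences must be non-empty")
  .nw_align_cpp(a, b, match, mismatch, gap)
}

# 5 x L frequency profile (rows A,C,G,T,gap) of an alignment; N counts as
# gap mass (it contributes to no residue state)
.profile_of <- function(aln) {
  m <- aln_matrix(aln)
  L <- ncol(m)
  pr <- matrix(0, 5, L)
  for (r in 1:4) pr[r, ] <- colSums(m == .BASES[r])
  pr[5, ] <- nrow(m) - colSums(pr[1:4, , drop = FALSE])
  pr / nrow(m)
}

# apply a merge path to an alignment: moves 2 (resp. 3) insert gap columns
# into the other block
.apply_path <- function(aln, path, own_move, gap_move) {
  m <- aln_matrix(aln)
  out <- matrix("-", nrow(m), length(path))
  keep <- path %in% c(1, own_move)
  out[, keep] <- m
  rownames(out) <- rownames(m)
  matrix_to_aln(out)
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from UPGMA on k-mer (k = 6) cosine distances; profiles are
#' merged bottom-up with profile-profile Needleman-Wunsch using
#' column-average scoring ("once a gap, always a gap").
#'
#' @param seqs named character vector of ungapped DNA sequences.
#' @param match,mismatch,gap scores.
#' @return A [dna_alignment()].
#' @export
progressive_msa <- function(seqs, match = 1, mismatch = -1, gap = -1) {
  if (length(seqs) == 0) rb_invalid("no sequences")
  if (length(seqs) == 1) return(dna_alignment(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    rb_invalid("sequences must have unique names")
  km <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(gsub("[^ACGT]", "", toupper(seqs))), width = 6)
  nrm <- sqrt(rowSums(km^2))
  cosd <- 1 - (km %*% t(km)) / (nrm %o% nrm)
  cosd[cosd < 0] <- 0
  diag(cosd) <- 0
  dimnames(cosd) <- list(names(seqs), names(seqs))
  merges <- .upgma_merges(cosd)$merges
  blocks <- lapply(names(seqs), function(nm) dna_alignment(seqs[nm]))
  names(blocks) <- names(seqs)
  key <- as.list(names(seqs))
  names(key) <- names(seqs)
  for (mg in merges) {
    a <- blocks[[mg$a]]; b <- blocks[[mg$b]]
    res <- .profile_nw_cpp(.profile_of(a), .profile_of(b), match, mismatch, gap)
    merged <- c(unclass(.apply_path(a, res$path, 2, 3)),
                unclass(.apply_path(b, res$path, 3, 2)))
    blocks[[mg$a]] <- NULL; blocks[[mg$b]] <- NULL
    blocks[[mg$new]] <- dna_alignment(merged)
  }
  final <- blocks[[1]]
  dna_alignment(unclass(final)[names(seqs)])
}

#' Per-column Shannon entropy of an alignment
#'
#' H = -sum(p log2 p) over the observed states of each column, in bits.
#' With `gap_mode = "exclude"` (default) gaps and N are removed before
#' computing the frequencies (range 0-2 bits); with `"fifth_state"` the
#' gap is a fifth state (range 0-log2(5)); N is never counted as a state.
#' All-gap columns get entropy 0 and are flagged.
#'
#' @param aln a [dna_alignment()].
#' @param gap_mode `"exclude"` or `"fifth_state"`.
#' @param smooth_window width of the sliding-mean smoother (columns).
#' @param regions optional `data.frame(label, start, end)` (0-based
#'   half-open, alignment coordinates) annotating variable regions.
#' @return An `entropy_profile`: list with `entropy`, `smoothed`,
#'   `gap_mode`, `all_gap` (logical flags) and `regions`.
#' @export
column_entropy <- function(aln, gap_mode = c("exclude", "fifth_state"),
                           smooth_window = 10, regions = NULL) {
  gap_mode <- match.arg(gap_mode)
  m <- aln_matrix(aln)
  L <- ncol(m)
  counts <- matrix(0, 5, L)
  for (r in 1:4) counts[r, ] <- colSums(m == .BASES[r])
  counts[5, ] <- colSums(m == "-")
  states <- if (gap_mode == "exclude") 1:4 else 1:5
  tot <- colSums(counts[states, , drop = FALSE])
  H <- numeric(L)
  for (r in states) {
    p <- ifelse(tot > 0, counts[r, ] / tot, 0)
    H <- H - ifelse(p > 0, p * log2(p), 0)
  }
  all_gap <- tot == 0
  H[all_gap] <- 0
  sm <- vapply(seq_len(L), function(i) {
    lo <- max(1, i - floor(smooth_window / 2) + 1)
    hi <- min(L, i + ceiling(smooth_window / 2))
    mean(H[lo:hi])
  }, numeric(1))
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    if (any(regions$start < 0) || any(regions$end > L))
      rb_invalid("region annotation outside alignment bounds")
  }
  structure(list(entropy = H, smoothed = sm, gap_mode = gap_mode,
                 all_gap = all_gap, regions = regions),
            class = "entropy_profile")
}

#' Mean and maximum entropy per annotated region
#'
#' @param profile an `entropy_profile` with region annotations.
#' @return `data.frame(region_label, mean_entropy, max_entropy)`.
#' @export
region_entropy_summary <- function(profile) {
  stopifnot(inherits(profile, "entropy_profile"))
  reg <- profile$regions
  if (is.null(reg) || nrow(reg) == 0)
    rb_invalid("entropy profile has no region annotations")
  data.frame(
    region_label = reg$label,
    mean_entropy = vapply(seq_len(nrow(reg)), function(i)
      mean(profile$entropy[(reg$start[i] + 1):reg$end[i]]), numeric(1)),
    max_entropy = vapply(seq_len(nrow(reg)), function(i)
      max(profile$entropy[(reg$start[i] + 1):reg$end[i]]), numeric(1)))
}

#' Entropy profile as a TSV-ready table
#'
#' @param profile an `entropy_profile`.
#' @return `data.frame(column, entropy, smoothed, region_label)` with
#'   1-based column numbers.
#' @export
entropy_table <- function(profile) {
  L <- length(profile$entropy)
  lab <- rep(NA_character_, L)
  if (!is.null(profile$regions)) {
    for (i in seq_len(nrow(profile$regions)))
      lab[(profile$regions$start[i] + 1):profile$regions$end[i]] <-
        profile$regions$label[i]
  }
  data.frame(column = seq_len(L), entropy = profile$entropy,
             smoothed = profile$smoothed, region_label = lab)
}
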