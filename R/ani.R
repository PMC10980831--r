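# Fragment-based average nucleotide identity (OrthoANI-style): the query
# is cut into non-overlapping windows, each seeded onto the subject by
# shared k-mers on both strands and aligned with a banded global
# alignment; ANI is the mean identity over aligned fragments, symmetrized
# as the mean of the two directions.

#' Pairwise average nucleotide identity
#'
#' @param a,b genome sequences (strings), both at least `frag_len` long.
#' @param frag_len fragment window length.
#' @param k seed k-mer size.
#' @param min_identity,min_coverage fragment filters: only fragments with
#'   alignment identity and coverage at or above these fractions count as
#'   aligned.
#' @return An `ani_result`: list with `ani` (percent, `NA` if no fragment
#'   aligned in either direction), `n_fragments_aligned`,
#'   `n_fragments_total`, and `fragment_identities` (per direction).
#' @export
pairwise_ani <- function(a, b, frag_len = 1020, k = 16,
                         min_identity = 0.7, min_coverage = 0.7) {
  if (nchar(a) < frag_len || nchar(b) < frag_len)
    rb_invalid(sprintf("both genomes must be at least frag_len (%d) long",
                       frag_len))
  band <- max(1L, as.integer(round(0.1 * frag_len)))
  dir_ids <- function(x, y) {
    fr <- .ani_fragments_cpp(x, y, as.integer(frag_len), as.integer(k), band)
    ok <- fr$found & !is.na(fr$identity) &
      fr$identity >= min_identity & fr$coverage >= min_coverage
    list(ids = fr$identity[ok], total = nrow(fr))
  }
  ab <- dir_ids(a, b)
  ba <- dir_ids(b, a)
  means <- c(if (length(ab$ids)) mean(ab$ids), if (length(ba$ids)) mean(ba$ids))
  ani <- if (length(means)) 100 * mean(means) else NA_real_
  structure(list(ani = ani,
                 n_fragments_aligned = length(ab$ids) + length(ba$ids),
                 n_fragments_total = ab$total + ba$total,
                 fragment_identities = list(ab = ab$ids, ba = ba$ids)),
            class = "ani_result")
}

#' All-pairs ANI for a genome set
#'
#' Same estimator as [pairwise_ani()], batched: each genome's k-mer index
#' is built once and reused across pairs.
#'
#' @param genomes named character vector of genome sequences.
#' @param frag_len,k,min_identity,min_coverage see [pairwise_ani()].
#' @return An `ani_set`: list with `ani` (percent matrix, diagonal 100),
#'   `D` (distance matrix `1 - ani/100`; undefined pairs get distance 1
#'   with a warning), and `fragments` (per-pair pooled fragment
#'   identities, keyed `"a|b"`), usable by [bootstrap_support()].
#' @export
ani_matrix <- function(genomes, frag_len = 1020, k = 16,
                       min_identity = 0.7, min_coverage = 0.7) {
  n <- length(genomes)
  if (n < 2) rb_invalid("need at least 2 genomes")
  if (any(nchar(genomes) < frag_len))
    rb_invalid(sprintf("all genomes must be at least frag_len (%d) long",
                       frag_len))
  ids <- names(genomes)
  ani <- matrix(100, n, n, dimnames = list(ids, ids))
  frags <- list()
  undef <- character(0)
  band <- max(1L, as.integer(round(0.1 * frag_len)))
  res <- .ani_all_pairs_cpp(unname(genomes), as.integer(frag_len),
                            as.integer(k), band, min_identity, min_coverage)
  p <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- p + 1
    r <- res[[p]]
    means <- c(r$mean_ab, r$mean_ba)
    val <- if (all(is.na(means))) NA_real_ else 100 * mean(means, na.rm = TRUE)
    ani[i, j] <- ani[j, i] <- val
    frags[[paste(ids[i], ids[j], sep = "|")]] <- r$identities
    if (is.na(val)) undef <- c(undef, paste(ids[i], ids[j], sep = "|"))
  }
  D <- 1 - ani / 100
  if (length(undef)) {
    warning("ANI undefined (no aligned fragments) for ",
            length(undef), " pair(s); distance set to 1")
    D[is.na(D)] <- 1
  }
  diag(D) <- 0
  structure(list(ani = ani, D = D, fragments = frags), class = "ani_set")
}

# bootstrap resample of an ani_set: per pair, resample fragment
# identities with replacement and recompute the distance matrix
.resample_ani_matrix <- function(aset) {
  D <- aset$D
  ids <- rownames(D)
  for (key in names(aset$fragments)) {
    v <- aset$fragments[[key]]
    if (length(v) == 0) next
    pq <- strsplit(key, "|", fixed = TRUE)[[1]]
    m <- mean(sample(v, length(v), replace = TRUE))
    D[pq[1], pq[2]] <- D[pq[2], pq[1]] <- 1 - m
  }
  D
}

#' ANI distance matrix
#'
#' `d(i, j) = 1 - ani(i, j) / 100`; undefined pairs become distance 1.
#'
#' @param genomes named character vector of genome sequences.
#' @param ... passed to [pairwise_ani()].
#' @return Labeled symmetric distance matrix.
#' @export
ani_distance_matrix <- function(genomes, ...) ani_matrix(genomes, ...)$D

#' ANI groups at an identity threshold
#'
#' Single-linkage connected components of the graph whose edges join
#' genome pairs with `ani >= threshold` (the conventional 95% species
#' threshold by default). Transitive chains are merged into one group.
#'
#' @param D ANI distance matrix (`1 - ani/100`), as from
#'   [ani_distance_matrix()].
#' @param threshold identity threshold in percent.
#' @return An `ani_groups`: list with `groups` (named integer vector,
#'   dense indices from 0 in order of first appearance) and `n_groups`.
#' @export
ani_groups <- function(D, threshold = 95) {
  .check_dist(D)
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  dmax <- (100 - threshold) / 100 + 1e-12
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] <= dmax) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  idx <- match(roots, unique(roots)) - 1L
  structure(list(groups = setNames(idx, rownames(D)),
                 n_groups = length(unique(roots))), class = "ani_groups")
}
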