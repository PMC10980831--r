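# Distance-based tree reconstruction: Jukes-Cantor distances, canonical
# neighbor joining (Q criterion, Studier-Keppler updates, clamp-and-
# transfer for negative branches), UPGMA dendrograms, bootstrap supports,
# and the concatenated marker-gene reference tree. All tie-breaks are
# deterministic so trees are reproducible bit-for-bit.

#' Jukes-Cantor distance matrix from an alignment
#'
#' p-distances are computed over columns where both rows carry A/C/G/T;
#' d = -(3/4) ln(1 - 4p/3). Saturated pairs (p >= 0.75) are capped at
#' `max_distance` with a warning.
#'
#' @param aln a [dna_alignment()] (or named character vector of equal
#'   lengths).
#' @param max_distance cap for saturated pairs.
#' @return Labeled symmetric distance matrix (zero diagonal).
#' @export
jc_distance_matrix <- function(aln, max_distance = 5) {
  if (!inherits(aln, "dna_alignment")) aln <- dna_alignment(aln)
  if (length(aln) < 2) rb_invalid("need at least 2 sequences")
  m <- aln_matrix(aln)
  n <- nrow(m)
  # one-hot crossproducts: matches and comparable-column counts for all
  # pairs at once
  matches <- matrix(0, n, n)
  for (b in .BASES) {
    X <- (m == b) * 1
    matches <- matches + tcrossprod(X)
  }
  V <- matrix(0 + (m %in% .BASES), n, ncol(m))
  ncomp <- tcrossprod(V)
  if (any(ncomp[upper.tri(ncomp)] == 0)) {
    bad <- which(ncomp == 0 & upper.tri(ncomp), arr.ind = TRUE)[1, ]
    rb_data_error(sprintf("no comparable columns between %s and %s",
                          rownames(m)[bad[1]], rownames(m)[bad[2]]))
  }
  p <- 1 - matches / ncomp
  sat <- p >= 0.75
  D <- -0.75 * log(1 - 4 * pmin(p, 0.7499) / 3)
  D[sat] <- max_distance
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  if (any(sat[upper.tri(sat)]))
    warning("saturated pair(s): JC distance capped at ", max_distance)
  D
}

.check_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    rb_invalid("distance matrix must be square")
  if (is.null(rownames(D))) rb_invalid("distance matrix must be labeled")
  if (any(!is.finite(D))) rb_invalid("distance matrix has non-finite entries")
  D
}

.fmt_len <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree
#'
#' Canonical NJ: Q-matrix selection with Studier-Keppler distance updates.
#' Among tied Q minima the pair with the smallest (row, column) position is
#' taken (taxa initially ordered by label, joined nodes appended last).
#' Negative branch lengths are clamped to 0 with the deficit transferred
#' to the sibling branch, preserving the path length between the joined
#' taxa.
#'
#' @param D labeled symmetric distance matrix, n >= 3.
#' @return An unrooted `phylo` tree. On additive input matrices the true
#'   topology and branch lengths are recovered exactly.
#' @export
neighbor_joining <- function(D) {
  .check_dist(D)
  n <- nrow(D)
  if (n < 3) rb_invalid("neighbor joining needs at least 3 taxa")
  ord <- order(rownames(D))
  Dm <- D[ord, ord, drop = FALSE]
  nwk <- rownames(Dm)
  while (nrow(Dm) > 3) {
    r <- nrow(Dm)
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- Dm[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- dij; li <- 0 }
    if (lj < 0) { li <- dij; lj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], .fmt_len(li),
                       nwk[j], .fmt_len(lj))
    k <- setdiff(seq_len(r), c(i, j))
    dnew <- (Dm[i, k] + Dm[j, k] - dij) / 2
    Dm <- rbind(cbind(Dm[k, k, drop = FALSE], dnew),
                c(dnew, 0))
    nwk <- c(nwk[k], new_nwk)
    rownames(Dm) <- colnames(Dm) <- NULL
  }
  # final three-point join
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], .fmt_len(l1),
                 nwk[2], .fmt_len(l2), nwk[3], .fmt_len(l3))
  ape::read.tree(text = txt)
}

# UPGMA agglomeration; returns the tree plus the merge schedule (used as
# the progressive-MSA guide). Cluster ids: leaf label, or member labels
# joined by "\x01" after a merge. Ties merge the pair whose (smallest
# member label, smallest member label) pair sorts first.
.upgma_merges <- function(D) {
  .check_dist(D)
  n <- nrow(D)
  labs <- sort(rownames(D))
  Dm <- D[labs, labs, drop = FALSE]
  members <- as.list(labs)
  reps <- labs            # smallest member label per cluster
  heights <- rep(0, n)
  nwk <- labs
  ids <- labs
  merges <- list()
  while (length(ids) > 1) {
    r <- length(ids)
    off <- upper.tri(Dm)
    bd <- min(Dm[off])
    cand <- which(Dm <= bd + 1e-12 & off, arr.ind = TRUE)
    # tie-break: smallest (sorted) pair of cluster representative labels
    pr <- cbind(pmin(reps[cand[, 1]], reps[cand[, 2]]),
                pmax(reps[cand[, 1]], reps[cand[, 2]]))
    pick <- order(pr[, 1], pr[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    h <- Dm[i, j] / 2
    bi <- h - heights[i]; bj <- h - heights[j]
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], .fmt_len(bi),
                       nwk[j], .fmt_len(bj))
    new_id <- paste(sort(c(members[[i]], members[[j]])), collapse = "\x01")
    merges[[length(merges) + 1]] <- list(a = ids[i], b = ids[j], new = new_id)
    ni <- length(members[[i]]); nj <- length(members[[j]])
    k <- setdiff(seq_len(r), c(i, j))
    dnew <- (ni * Dm[i, k] + nj * Dm[j, k]) / (ni + nj)
    Dm <- rbind(cbind(Dm[k, k, drop = FALSE], dnew), c(dnew, 0))
    members <- c(members[k], list(c(members[[i]], members[[j]])))
    reps <- c(reps[k], min(reps[c(i, j)]))
    heights <- c(heights[k], h)
    nwk <- c(nwk[k], new_nwk)
    ids <- c(ids[k], new_id)
  }
  tree <- ape::read.tree(text = paste0(nwk[1], ";"))
  list(tree = tree, merges = merges)
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree.
#' Tied merges are resolved toward the pair with the smallest member
#' labels.
#'
#' @param D labeled symmetric distance matrix.
#' @return A rooted `phylo` dendrogram; cophenetic distances of
#'   ultrametric input are reproduced exactly.
#' @export
upgma <- function(D) {
  if (nrow(.check_dist(D)) < 2) rb_invalid("need at least 2 taxa")
  .upgma_merges(D)$tree
}

# clade membership keys of internal nodes (rooted) or split keys
# (unrooted); returns character vector indexed by internal node number
.node_keys <- function(tree, rooted) {
  n <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  post <- ape::postorder(tree)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- match(tree$tip.label[i], taxa)
  for (e in post) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[chi]])
  }
  keys <- rep(NA_character_, n + tree$Nnode)
  for (v in (n + 1):(n + tree$Nnode)) {
    side <- rep(FALSE, length(taxa))
    side[below[[v]]] <- TRUE
    if (sum(side) < 2 || sum(side) > length(taxa) - 2) next
    if (!rooted && side[1]) side <- !side  # canonical split orientation
    keys[v] <- paste0(as.integer(side), collapse = "")
  }
  keys
}

#' Bootstrap support values
#'
#' For alignments, columns are resampled with replacement and the tree is
#' rebuilt (JC distances + the chosen builder); for an ANI set, each
#' pair's per-fragment identities are resampled and the matrix recomputed.
#' Support is the percentage of replicate trees containing each internal
#' bipartition (each cluster, for rooted dendrograms), attached as node
#' labels.
#'
#' @param data a [dna_alignment()] or an `ani_set` (see [ani_matrix()]).
#' @param builder `"nj"` or `"upgma"`.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed.
#' @return The tree built on the original data, with `node.label` set to
#'   integer support percentages (root/unresolved nodes: `""`).
#' @export
bootstrap_support <- function(data, builder = c("nj", "upgma"),
                              n_reps = 100, seed = 1) {
  builder <- match.arg(builder)
  if (n_reps < 1) rb_invalid("n_reps must be >= 1")
  build <- function(D) if (builder == "nj") neighbor_joining(D) else upgma(D)
  if (inherits(data, "dna_alignment")) {
    base_D <- jc_distance_matrix(data)
    mat <- aln_matrix(data)
    resample <- function() {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      suppressWarnings(jc_distance_matrix(matrix_to_aln(
        mat[, idx, drop = FALSE])))
    }
  } else if (inherits(data, "ani_set")) {
    base_D <- data$D
    resample <- function() .resample_ani_matrix(data)
  } else rb_invalid("data must be a dna_alignment or an ani_set")
  base_tree <- build(base_D)
  rooted <- builder == "upgma"
  keys <- .node_keys(base_tree, rooted)
  count <- setNames(rep(0, sum(!is.na(keys))), keys[!is.na(keys)])
  ok_reps <- 0
  with_seed(seed, for (b in seq_len(n_reps)) {
    Db <- tryCatch(resample(), error = function(e) NULL)
    if (is.null(Db)) next
    tb <- build(Db)
    kb <- .node_keys(tb, rooted)
    ok_reps <- ok_reps + 1
    hit <- intersect(names(count), kb)
    count[hit] <- count[hit] + 1
  })
  supp <- round(100 * count / max(1, ok_reps))
  labels <- vapply(keys[(length(base_tree$tip.label) + 1):length(keys)],
                   function(k) if (is.na(k)) "" else as.character(supp[[k]]),
                   character(1))
  base_tree$node.label <- unname(labels)
  base_tree
}

#' Concatenated single-copy marker-gene tree
#'
#' Marker alignments over the same genomes are concatenated column-wise
#' (genomes missing from a marker are gap-filled), then a JC +
#' neighbor-joining tree with bootstrap supports is built.
#'
#' @param marker_alignments list of [dna_alignment()] objects.
#' @param n_reps bootstrap replicates (0 = no supports).
#' @param seed integer seed for the bootstrap.
#' @return An unrooted `phylo` tree over the union of genomes.
#' @export
scmg_tree <- function(marker_alignments, n_reps = 100, seed = 1) {
  if (length(marker_alignments) == 0) rb_invalid("no marker alignments")
  sets <- lapply(marker_alignments, names)
  if (length(sets) > 1) {
    for (i in seq_len(length(sets) - 1)) for (j in (i + 1):length(sets))
      if (length(intersect(sets[[i]], sets[[j]])) == 0)
        rb_data_error(sprintf(
          "marker alignments %d and %d share no genomes", i, j))
  }
  genomes <- sort(Reduce(union, sets))
  rows <- setNames(rep("", length(genomes)), genomes)
  for (aln in marker_alignments) {
    L <- aln_ncol(aln)
    gapfill <- strrep("-", L)
    rows <- paste0(rows, ifelse(genomes %in% names(aln),
                                unclass(aln)[match(genomes, names(aln))],
                                gapfill))
  }
  names(rows) <- genomes
  cat_aln <- dna_alignment(rows)
  if (n_reps > 0) bootstrap_support(cat_aln, "nj", n_reps, seed)
  else neighbor_joining(jc_distance_matrix(cat_aln))
}
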