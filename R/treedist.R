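# Tree comparison metrics: classic Robinson-Foulds, generalized
# Jaccard-Robinson-Foulds (JRF) and mutual clustering information (MCI).
# Both generalized metrics score all pairs of bipartitions and solve an
# optimal one-to-one matching (Hungarian algorithm); a brute-force matcher
# over all partial matchings serves as an independent oracle for testing.

#' Non-trivial splits (bipartitions) of a tree
#'
#' Rooted trees are unrooted first. Each internal edge contributes one
#' bipartition, encoded canonically as the side not containing the first
#' taxon (taxa sorted by label). Trivial splits (a side with < 2 taxa)
#' are dropped; duplicates are collapsed.
#'
#' @param tree a `phylo` tree.
#' @return A `split_set`: list with `taxa` (sorted labels) and `sides`
#'   (logical matrix, one row per split).
#' @export
tree_splits <- function(tree) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- ape::collapse.singles(tree)
  taxa <- sort(tree$tip.label)
  n <- length(taxa)
  keys <- .node_keys(tree, rooted = FALSE)
  keys <- unique(keys[!is.na(keys)])
  sides <- if (length(keys) == 0) {
    matrix(FALSE, 0, n)
  } else {
    do.call(rbind, lapply(strsplit(keys, ""), function(x) x == "1"))
  }
  colnames(sides) <- taxa
  structure(list(taxa = taxa, sides = sides), class = "split_set")
}

.split_keys <- function(ss) {
  if (nrow(ss$sides) == 0) return(character(0))
  apply(ss$sides, 1, function(x) paste0(as.integer(x), collapse = ""))
}

.check_same_leaves <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    miss <- c(setdiff(a, b), setdiff(b, a))
    rb_invalid(sprintf("leaf sets differ: %s", paste(miss, collapse = ", ")))
  }
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' non-trivial split
#' sets.
#'
#' @param t1,t2 `phylo` trees on the same leaves.
#' @return Integer count.
#' @export
rf_distance <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  k1 <- .split_keys(tree_splits(t1))
  k2 <- .split_keys(tree_splits(t2))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# pairwise intersection counts between two split sets via crossprod;
# returns the building blocks for Jaccard and mutual-information scores
.split_pair_counts <- function(s1, s2) {
  M1 <- s1$sides * 1; M2 <- s2$sides * 1
  n <- length(s1$taxa)
  a <- rowSums(M1); c_ <- rowSums(M2)
  I11 <- M1 %*% t(M2)                      # |A n C|
  IAD <- outer(a, rep(1, nrow(M2))) - I11  # |A n D|
  IBC <- outer(rep(1, nrow(M1)), c_) - I11 # |B n C|
  IBD <- n - outer(a, rep(1, nrow(M2))) - outer(rep(1, nrow(M1)), c_) + I11
  list(n = n, a = a, c = c_, I11 = I11, IAD = IAD, IBC = IBC, IBD = IBD)
}

# Jaccard pair-score matrix: best orientation, min of the two within-
# orientation Jaccards, raised to the concavity power k
.jrf_scores <- function(s1, s2, k) {
  ct <- .split_pair_counts(s1, s2)
  n <- ct$n
  A <- outer(ct$a, rep(1, length(ct$c)))
  C <- outer(rep(1, length(ct$a)), ct$c)
  jacAC <- ct$I11 / (A + C - ct$I11)
  jacBD <- ct$IBD / (n - ct$I11)
  jacAD <- ct$IAD / (A + (n - C) - ct$IAD)
  jacBC <- ct$IBC / (n - ct$IAD)
  J <- pmax(pmin(jacAC, jacBD), pmin(jacAD, jacBC))
  J[is.nan(J)] <- 0
  J^k
}

# mutual information (bits) between all split pairs viewed as binary leaf
# labelings
.mci_scores <- function(s1, s2) {
  ct <- .split_pair_counts(s1, s2)
  n <- ct$n
  A <- outer(ct$a, rep(1, length(ct$c)))
  C <- outer(rep(1, length(ct$a)), ct$c)
  term <- function(nij, ri, cj) {
    v <- (nij / n) * log2(n * nij / (ri * cj))
    v[!is.finite(v) | nij == 0] <- 0
    v
  }
  term(ct$I11, A, C) + term(ct$IAD, A, n - C) +
    term(ct$IBC, n - A, C) + term(ct$IBD, n - A, n - C)
}

# binary entropy (bits) of each split in a set
.split_entropies <- function(ss) {
  n <- length(ss$taxa)
  if (nrow(ss$sides) == 0) return(numeric(0))
  p <- rowSums(ss$sides) / n
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

# Hungarian algorithm (shortest augmenting path), minimizing; square cost
.hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1)     # p[j] = row matched to column j (index n+1 virtual)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      js <- which(!used[seq_len(n)])
      if (length(js)) {
        cur <- cost[i0, js] - u[i0] - v[js]
        upd <- cur < minv[js]
        if (any(upd)) {
          minv[js[upd]] <- cur[upd]
          way[js[upd]] <- j0
        }
        j1 <- js[which.min(minv[js])]
        delta <- minv[j1]
      } else {
        delta <- Inf; j1 <- 0L
      }
      uj <- which(used)
      rows <- p[uj]
      u[rows[rows > 0]] <- u[rows[rows > 0]] + delta
      v[uj] <- v[uj] - delta
      nu <- which(!used)
      minv[nu] <- minv[nu] - delta
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  match_of_row <- integer(n)
  for (j in seq_len(n)) match_of_row[p[j]] <- j
  match_of_row
}

# optimal one-to-one (partial) matching maximizing the total of a
# nonnegative score matrix; returns total and the matched pairs
.assignment_max <- function(S) {
  m1 <- nrow(S); m2 <- ncol(S)
  if (m1 == 0 || m2 == 0)
    return(list(total = 0, pairs = cbind(integer(0), integer(0))))
  q <- max(m1, m2)
  Sq <- matrix(0, q, q)
  Sq[seq_len(m1), seq_len(m2)] <- S
  assign <- .hungarian_min(max(Sq) - Sq)
  pairs <- cbind(seq_len(q), assign)
  pairs <- pairs[pairs[, 1] <= m1 & pairs[, 2] <= m2, , drop = FALSE]
  list(total = sum(S[pairs]), pairs = pairs)
}

#' Generalized Jaccard-Robinson-Foulds distance
#'
#' Each pair of bipartitions (A|B) from `t1` and (C|D) from `t2` is scored
#' `J^k` where `J = max(min(jac(A,C), jac(B,D)), min(jac(A,D), jac(B,C)))`
#' (best orientation, `jac` = Jaccard index). An optimal one-to-one
#' matching maximizes the total score `s`; the distance is
#' `(|S1| + |S2| - 2 s) / (|S1| + |S2|)`, in `[0, 1]`. Two split-free
#' (star) trees have distance 0; a star versus a resolved tree has
#' distance 1.
#'
#' @param t1,t2 `phylo` trees on the same leaves.
#' @param k concavity parameter (> 0); large `k` approaches the classic
#'   RF distance normalized by `|S1| + |S2|`.
#' @return Normalized distance in `[0, 1]`.
#' @export
jrf_distance <- function(t1, t2, k = 1) {
  if (k <= 0) rb_invalid("concavity k must be > 0")
  .check_same_leaves(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  m1 <- nrow(s1$sides); m2 <- nrow(s2$sides)
  if (m1 == 0 && m2 == 0) return(0)
  if (m1 == 0 || m2 == 0) return(1)
  total <- .assignment_max(.jrf_scores(s1, s2, k))$total
  (m1 + m2 - 2 * total) / (m1 + m2)
}

#' Mutual clustering information between two trees
#'
#' Pair score is the mutual information (bits) between two bipartitions
#' viewed as binary leaf labelings; an optimal one-to-one matching
#' maximizes the total. MCI is the matched total; the normalized distance
#' is `1 - MCI / max(sum H(S1), sum H(S2))` with `H` the binary split
#' entropy.
#'
#' @param t1,t2 `phylo` trees on the same leaves.
#' @return List with `mci` (bits) and `distance` (normalized, `[0, 1]`).
#' @export
mci <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  H1 <- sum(.split_entropies(s1)); H2 <- sum(.split_entropies(s2))
  hmax <- max(H1, H2)
  if (nrow(s1$sides) == 0 || nrow(s2$sides) == 0) {
    return(list(mci = 0, distance = if (hmax > 0) 1 else 0))
  }
  total <- .assignment_max(.mci_scores(s1, s2))$total
  list(mci = total, distance = 1 - total / hmax)
}

#' Brute-force optimal matching (test oracle)
#'
#' Exact optimum over all one-to-one partial matchings of a score matrix,
#' by dynamic programming over column subsets. Intended as an independent
#' oracle for the assignment solver on small inputs.
#'
#' @param S score matrix (`|S1|`, `|S2|` at most ~12).
#' @return The optimal total score (unmatched splits contribute 0).
#' @export
brute_force_match <- function(S) {
  m1 <- nrow(S); m2 <- ncol(S)
  if (m1 == 0 || m2 == 0) return(0)
  if (m2 > 20) rb_invalid("brute-force matcher is limited to small inputs")
  nmask <- bitwShiftL(1L, m2)
  f <- rep(-Inf, nmask)
  f[1] <- 0
  for (i in seq_len(m1)) {
    g <- f  # skipping row i
    for (mask in 0:(nmask - 1)) {
      if (!is.finite(f[mask + 1])) next
      for (j in seq_len(m2)) {
        bit <- bitwShiftL(1L, j - 1)
        if (bitwAnd(mask, bit) == 0) {
          nm <- bitwOr(mask, bit) + 1
          val <- f[mask + 1] + S[i, j]
          if (val > g[nm]) g[nm] <- val
        }
      }
    }
    f <- g
  }
  max(f)
}
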