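# Shared fixtures and independent oracles used across test files.

# random unrooted binary topology on n leaves (labels L1..Ln)
random_topology <- function(n, seed) {
  with_seed2(seed, ape::unroot(ape::rtree(n, tip.label = paste0("L", seq_len(n)))))
}

with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# additive distance matrix of a tree (exact path lengths)
additive_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[sort(rownames(D)), sort(rownames(D))]
}

# are two partitions identical up to label permutation?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  identical(match(a, unique(a)), match(b, unique(b)))
}

# independent Wilcoxon signed-rank oracle: full sign enumeration via a
# {-1, +1}^n design matrix; p = share of sign patterns at least as far
# from the null center as the observed positive-rank sum
wilcoxon_enum_oracle <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  S <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  w <- as.vector(signs %*% r)
  obs <- sum(r[d > 0])
  mean(abs(w - S / 2) >= abs(obs - S / 2) - 1e-12)
}

# independent homogeneity/completeness oracle: explicit double loop over
# the joint distribution, conditional entropies written out directly
hc_oracle <- function(pred, truth) {
  n <- length(truth)
  pu <- unique(pred); tu <- unique(truth)
  H_t <- 0
  for (t in tu) { p <- sum(truth == t) / n; H_t <- H_t - p * log(p) }
  H_p <- 0
  for (q in pu) { p <- sum(pred == q) / n; H_p <- H_p - p * log(p) }
  H_t_given_p <- 0
  for (q in pu) for (t in tu) {
    joint <- sum(pred == q & truth == t) / n
    if (joint > 0) H_t_given_p <- H_t_given_p - joint *
        log(joint / (sum(pred == q) / n))
  }
  H_p_given_t <- 0
  for (q in pu) for (t in tu) {
    joint <- sum(pred == q & truth == t) / n
    if (joint > 0) H_p_given_t <- H_p_given_t - joint *
        log(joint / (sum(truth == t) / n))
  }
  c(h = if (H_t > 0) 1 - H_t_given_p / H_t else 1,
    c = if (H_p > 0) 1 - H_p_given_t / H_p else 1)
}

# random iid DNA string
random_dna <- function(n, seed) {
  with_seed2(seed, paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# copy of a sequence with iid substitutions at a given rate
mutate_seq <- function(seq, rate, seed) {
  with_seed2(seed, {
    v <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste0(v, collapse = "")
  })
}

# enumerate all unrooted binary topologies on n leaves (L1..Ln) by
# sequential leaf insertion into every edge; n = 6 gives 105 trees
all_topologies <- function(n) {
  insert_all <- function(node, leaf) {
    out <- list()
    for (i in seq_along(node)) {
      joined <- node
      joined[[i]] <- list(node[[i]], leaf)
      out <- c(out, list(joined))
      if (is.list(node[[i]])) {
        for (sub in insert_all(node[[i]], leaf)) {
          deeper <- node
          deeper[[i]] <- sub
          out <- c(out, list(deeper))
        }
      }
    }
    out
  }
  to_newick <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, ""), collapse = ","), ")")
  }
  trees <- list(list("L1", "L2", "L3"))
  for (leaf in paste0("L", seq_len(n))[-(1:3)]) {
    trees <- do.call(c, lapply(trees, insert_all, leaf = leaf))
  }
  lapply(trees, function(tr)
    ape::read.tree(text = paste0(to_newick(tr), ";")))
}
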