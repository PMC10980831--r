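# Benchmark orchestration: per-genus region-vs-ANI JRF rows, z-scores,
# best-region calls, ANI-vs-SCMG adequacy with paired Wilcoxon tests,
# dereplicated subsampling, and the supporting statistics (exact Wilcoxon
# signed-rank, homogeneity/completeness, heatmap clustering, correlation).

#' Benchmark one genus: region trees versus the ANI dendrogram
#'
#' For each tree source (full-length 16S and each variable region) a JC +
#' neighbor-joining tree is built from the alignment, both trees are
#' pruned to their shared genomes, and the JRF distance to the ANI
#' dendrogram is recorded. Cells with fewer than `min_shared` shared
#' genomes are `NA`.
#'
#' @param alignments named list of [dna_alignment()] objects; the
#'   full-gene alignment should be named `"16S full"` and the regions by
#'   their panel labels.
#' @param ani_dendrogram rooted `phylo` dendrogram from the ANI distance
#'   matrix.
#' @param k JRF concavity parameter.
#' @param min_shared minimum shared genomes per cell.
#' @return Named numeric vector of JRF distances (one per tree source),
#'   with a `drops` attribute listing pruned genomes per cell.
#' @export
genus_benchmark <- function(alignments, ani_dendrogram, k = 1, min_shared = 4) {
  out <- setNames(rep(NA_real_, length(alignments)), names(alignments))
  drops <- list()
  for (nm in names(alignments)) {
    aln <- alignments[[nm]]
    shared <- intersect(names(aln), ani_dendrogram$tip.label)
    dropped <- setdiff(union(names(aln), ani_dendrogram$tip.label), shared)
    drops[[nm]] <- dropped
    if (length(shared) < min_shared) next
    aln_s <- dna_alignment(unclass(aln)[shared])
    tr <- neighbor_joining(suppressWarnings(jc_distance_matrix(aln_s)))
    den <- if (length(shared) < length(ani_dendrogram$tip.label)) {
      ape::keep.tip(ani_dendrogram, shared)
    } else ani_dendrogram
    out[nm] <- jrf_distance(tr, den, k = k)
  }
  attr(out, "drops") <- drops
  out
}

#' Row-wise z-scores of a benchmark table
#'
#' Per row, `z = (x - mean) / sd` with the sample (n-1) standard
#' deviation over non-missing cells; rows with zero sd map to all zeros.
#'
#' @param table numeric matrix (genera x tree sources).
#' @return Matrix of z-scores with the same dimensions and missingness.
#' @export
zscore_rows <- function(table) {
  t(apply(table, 1, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) { x[ok] <- 0; return(x) }
    s <- sd(x[ok])
    x[ok] <- if (s > 0) (x[ok] - mean(x[ok])) / s else 0
    x
  }))
}

#' Best variable region of a benchmark row
#'
#' Argmin of the raw JRF distance over the variable-region columns (the
#' full-gene column is excluded); ties resolve to the earliest label in
#' canonical panel order.
#'
#' @param row named numeric vector (one benchmark row).
#' @param region_order candidate region labels, in tie-break order.
#' @return The winning region label.
#' @export
best_region <- function(row, region_order = REGION_ORDER) {
  cand <- row[names(row) %in% region_order]
  cand <- cand[order(match(names(cand), region_order))]
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0) rb_invalid("all region cells are missing")
  names(cand)[which.min(cand)]
}

#' ANI adequacy versus the SCMG reference
#'
#' For each genus, the JRF distance of the ANI dendrogram and of every
#' 16S-derived tree to the SCMG tree is computed; a paired two-sided
#' Wilcoxon signed-rank test (pairing unit = genus) compares the ANI
#' column with each other column.
#'
#' @param genera named list; each element is a list with `scmg` (tree),
#'   `ani` (dendrogram) and `trees` (named list of 16S/region trees).
#' @param k JRF concavity parameter.
#' @return List with `table` (genera x sources JRF matrix, first column
#'   `ANI`), `ani_mean` (mean of the ANI column) and `tests`
#'   (`data.frame(column, W, p)`).
#' @export
ani_adequacy <- function(genera, k = 1) {
  if (length(genera) < 2)
    rb_invalid("ANI adequacy testing needs at least 2 genera")
  src <- c("ANI", names(genera[[1]]$trees))
  tab <- matrix(NA_real_, length(genera), length(src),
                dimnames = list(names(genera), src))
  for (g in names(genera)) {
    gd <- genera[[g]]
    tab[g, "ANI"] <- jrf_distance(gd$ani, gd$scmg, k = k)
    for (nm in names(gd$trees))
      tab[g, nm] <- jrf_distance(gd$trees[[nm]], gd$scmg, k = k)
  }
  tests <- do.call(rbind, lapply(src[-1], function(nm) {
    w <- wilcoxon_signed_rank(tab[, "ANI"], tab[, nm])
    data.frame(column = nm, W = w$W, p = w$p)
  }))
  list(table = tab, ani_mean = mean(tab[, "ANI"]), tests = tests)
}

#' Dereplicated subsampling benchmark
#'
#' Per repeat, one genome is drawn uniformly from each ANI group, the
#' full-16S tree and the ANI dendrogram are rebuilt on the subset, and
#' their JRF distance recorded; the full-set distance is reported
#' alongside.
#'
#' @param ssu_aln full-16S [dna_alignment()] over all genomes.
#' @param ani_set an `ani_set` from [ani_matrix()] over the same genomes.
#' @param groups an `ani_groups` partition.
#' @param repeats number of subsampling repeats.
#' @param seed integer seed.
#' @param k JRF concavity parameter.
#' @return A `subsample_result`: list with `full_set_jrf`,
#'   `replicate_jrf` (length `repeats`) and `n_ani_groups`.
#' @export
dereplicate_benchmark <- function(ssu_aln, ani_set, groups, repeats = 10,
                                  seed = 1, k = 1) {
  if (repeats < 1) rb_invalid("repeats must be >= 1")
  stopifnot(inherits(ani_set, "ani_set"), inherits(groups, "ani_groups"))
  if (groups$n_groups < 4)
    rb_invalid("need at least 4 ANI groups to compare subset trees")
  gids <- names(groups$groups)
  full_tree <- neighbor_joining(suppressWarnings(jc_distance_matrix(ssu_aln)))
  full_den <- upgma(ani_set$D)
  full_jrf <- jrf_distance(full_tree, full_den, k = k)
  reps <- with_seed(seed, vapply(seq_len(repeats), function(b) {
    pick <- vapply(split(gids, groups$groups), function(members)
      if (length(members) == 1) members else sample(members, 1),
      character(1))
    pick <- sort(unname(pick))
    sub_aln <- dna_alignment(unclass(ssu_aln)[pick])
    sub_tree <- neighbor_joining(suppressWarnings(jc_distance_matrix(sub_aln)))
    sub_den <- upgma(ani_set$D[pick, pick])
    jrf_distance(sub_tree, sub_den, k = k)
  }, numeric(1)))
  structure(list(full_set_jrf = full_jrf, replicate_jrf = reps,
                 n_ani_groups = groups$n_groups),
            class = "subsample_result")
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped; absolute
#' differences are mid-ranked. For up to 12 non-zero pairs the p-value is
#' exact, by enumeration of all 2^n sign assignments of the observed
#' ranks; beyond that a normal approximation with tie-corrected variance
#' and continuity correction is used.
#'
#' @param x,y paired numeric vectors.
#' @return List with `W` (the smaller of the positive/negative rank sums)
#'   and `p` (two-sided). All-zero differences give `p = 1` with a
#'   warning.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) rb_invalid("x and y must have equal length")
  if (length(x) < 2) rb_invalid("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences are zero; p = 1")
    return(list(W = 0, p = 1))
  }
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  S <- sum(r)
  W <- min(wpos, S - wpos)
  n <- length(d)
  if (n <= 12) {
    obs_dev <- abs(wpos - S / 2)
    masks <- 0:(2^n - 1)
    devs <- vapply(masks, function(m) {
      abs(sum(r[bitwAnd(bitwShiftR(m, seq_len(n) - 1), 1L) == 1L]) - S / 2)
    }, numeric(1))
    p <- mean(devs >= obs_dev - 1e-12)
  } else {
    mu <- S / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(wpos - mu) - 0.5) / sigma
    p <- 2 * pnorm(-max(0, z))
  }
  list(W = W, p = min(1, p))
}

#' Homogeneity and completeness of a clustering
#'
#' Conditional-entropy scores comparing a predicted partition to reference
#' classes: `h = 1 - H(truth|pred) / H(truth)` and
#' `c = 1 - H(pred|truth) / H(pred)`; a zero-entropy denominator gives a
#' score of 1.
#'
#' @param predicted,truth equal-length label vectors.
#' @return List with `homogeneity` and `completeness`.
#' @export
homogeneity_completeness <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    rb_invalid("partitions must have equal length")
  n <- length(truth)
  tab <- table(predicted, truth)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  Ht <- H(colSums(tab) / n)
  Hp <- H(rowSums(tab) / n)
  # conditional entropies from the joint
  Hjoint <- H(as.vector(tab) / n)
  Ht_given_p <- Hjoint - Hp
  Hp_given_t <- Hjoint - Ht
  list(homogeneity = if (Ht > 0) 1 - Ht_given_p / Ht else 1,
       completeness = if (Hp > 0) 1 - Hp_given_t / Hp else 1)
}

#' Cluster genera by their z-score rows
#'
#' Hierarchical average-linkage clustering of the rows of a z-score
#' matrix under Euclidean distance, cut into `k` clusters.
#'
#' @param z z-score matrix (genera x tree sources).
#' @param k number of clusters.
#' @return Named integer vector of cluster indices.
#' @export
heatmap_clusters <- function(z, k = 4) {
  if (k > nrow(z)) rb_invalid("k exceeds the number of rows")
  hc <- hclust(dist(z, method = "euclidean"), method = "average")
  cutree(hc, k = k)
}

#' Correlation with two-sided p-value
#'
#' @param x,y numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `R` and `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (sd(x) == 0 || sd(y) == 0)
    rb_invalid("correlation undefined for constant input")
  ct <- if (method == "pearson") cor.test(x, y, method = "pearson")
        else cor.test(x, y, method = "spearman", exact = FALSE)
  list(R = unname(ct$estimate), p = ct$p.value)
}
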