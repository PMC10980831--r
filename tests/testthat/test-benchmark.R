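test_that("z-scores are row-standardized with missing-cell handling", {
  z <- zscore_rows(matrix(c(0.2, 0.4, 0.6), 1))
  expect_equal(as.vector(z), c(-1, 0, 1), tolerance = 1e-12)
  expect_identical(as.vector(zscore_rows(matrix(0.3, 1, 4))), rep(0, 4))
  z <- zscore_rows(matrix(c(0.2, NA, 0.6), 1))
  expect_identical(is.na(as.vector(z)), c(FALSE, TRUE, FALSE))
  expect_equal(sum(z, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("best_region uses raw minima with panel-order ties", {
  row <- c("16S full" = 0.01, "V1-V3" = 0.5, "V3-V4" = 0.4, "V4" = 0.6,
           "V4-V5" = 0.6, "V6-V8" = 0.7, "V6-V9" = 0.3)
  expect_identical(best_region(row), "V6-V9")
  row["V1-V3"] <- row["V6-V9"] <- 0.3
  expect_identical(best_region(row), "V1-V3")  # tie -> earliest in panel order
  row[] <- NA
  expect_error(best_region(row), class = "rb_invalid_argument")
})

test_that("exact Wilcoxon signed-rank matches enumeration and the base test", {
  expect_warning(w <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_identical(w$p, 1)

  w <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_identical(w$W, 0)
  expect_equal(w$p, 2 / 32, tolerance = 1e-12)

  # agreement with stats::wilcox.test on tie-free data
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1, 2), class = "rb_invalid_argument")
})

test_that("homogeneity and completeness follow the entropy identities", {
  hc <- homogeneity_completeness(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(hc$homogeneity, 1)
  expect_equal(hc$completeness, 1)

  hc <- homogeneity_completeness(rep(1, 4), c(1, 1, 2, 2))
  expect_equal(hc$homogeneity, 0)
  expect_equal(hc$completeness, 1)

  for (s in 1:10) {
    set.seed(s)
    n <- sample(10:30, 1)
    pred <- sample(1:4, n, TRUE); truth <- sample(1:3, n, TRUE)
    hc <- homogeneity_completeness(pred, truth)
    oracle <- hc_oracle(pred, truth)
    expect_equal(hc$homogeneity, unname(oracle["h"]), tolerance = 1e-12)
    expect_equal(hc$completeness, unname(oracle["c"]), tolerance = 1e-12)
  }
})

test_that("heatmap clustering separates clean row blocks", {
  z <- rbind(matrix(rep(c(1, -1, 0), each = 4), 4),
             matrix(rep(c(-1, 1, 0), each = 4), 4))
  rownames(z) <- paste0("g", 1:8)
  part <- heatmap_clusters(z, k = 2)
  expect_identical(length(unique(part[1:4])), 1L)
  expect_identical(length(unique(part[5:8])), 1L)
  expect_false(part[1] == part[5])
  expect_error(heatmap_clusters(z, k = 9), class = "rb_invalid_argument")
})

test_that("correlation handles linear, constant and random input", {
  expect_equal(correlate(1:10, 2 * (1:10) + 3)$R, 1, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), class = "rb_invalid_argument")
  set.seed(2)
  x <- rnorm(30); y <- rnorm(30)
  cc <- correlate(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(28 / (1 - r^2))
  expect_equal(cc$R, r, tolerance = 1e-12)
  expect_equal(cc$p, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
  expect_equal(correlate(x, y, method = "spearman")$R,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("genus_benchmark prunes to shared genomes and flags thin cells", {
  g <- simulate_genus(sim_config(n_species = 6, strains_per_species = 1,
                                 genome_length = 2100, seed = 30))
  aset <- ani_matrix(g$genomes)
  den <- upgma(aset$D)
  full <- dna_alignment(g$ssu)

  # identical alignments in every column give identical cells
  alns <- list("16S full" = full, "V1-V3" = full, "V3-V4" = full)
  row <- genus_benchmark(alns, den)
  expect_equal(unname(row["V1-V3"]), unname(row[["16S full"]]), tolerance = 1e-12)
  expect_equal(unname(row["V3-V4"]), unname(row[["16S full"]]), tolerance = 1e-12)

  # a region observed in too few genomes yields a missing cell
  thin <- dna_alignment(unclass(full)[1:3])
  row <- genus_benchmark(list("16S full" = full, "V4" = thin), den)
  expect_true(is.na(row["V4"]))
  expect_false(is.na(row["16S full"]))

  # pruning: a region missing one genome is still scored on the rest
  part <- dna_alignment(unclass(full)[-1])
  row <- genus_benchmark(list("16S full" = full, "V4-V5" = part), den)
  expect_false(is.na(row["V4-V5"]))
  expect_identical(attr(row, "drops")[["V4-V5"]], names(g$ssu)[1])
})

test_that("ani_adequacy distinguishes ANI from noisy 16S trees", {
  mk_genus <- function(seed) {
    g <- simulate_genus(sim_config(n_species = 6, strains_per_species = 1,
                                   genome_length = 1100, n_marker_genes = 3,
                                   marker_length = 900, seed = seed))
    scmg <- scmg_tree(g$markers, n_reps = 0)
    # ANI proxy: dendrogram from the true tree's own distances (low noise)
    den <- upgma(ape::cophenetic.phylo(g$true_tree))
    # a short, conserved gene slice gives a noisy within-genus tree
    slice <- dna_alignment(substr(g$ssu, 251, 450))
    tr16 <- neighbor_joining(suppressWarnings(jc_distance_matrix(slice)))
    list(scmg = scmg, ani = den, trees = list("16S full" = tr16))
  }
  genera <- setNames(lapply(1:6, mk_genus), paste0("genus", 1:6))
  ad <- ani_adequacy(genera)
  expect_identical(colnames(ad$table), c("ANI", "16S full"))
  expect_lt(ad$ani_mean, mean(ad$table[, "16S full"]))
  expect_identical(nrow(ad$tests), 1L)

  expect_error(ani_adequacy(genera[1]), class = "rb_invalid_argument")

  # identical inputs everywhere: all distances 0, Wilcoxon p = 1
  same <- lapply(genera, function(gd) {
    gd$ani <- gd$scmg; gd$trees <- list("16S full" = gd$scmg); gd
  })
  expect_warning(ad0 <- ani_adequacy(same), "zero")
  expect_identical(unname(ad0$table[, "ANI"]), rep(0, 6))
  expect_identical(ad0$tests$p, 1)
})

test_that("dereplication with singleton groups reproduces the full set", {
  g <- simulate_genus(sim_config(n_species = 6, strains_per_species = 1,
                                 genome_length = 2100, seed = 33))
  aset <- ani_matrix(g$genomes)
  gr <- ani_groups(aset$D)
  expect_identical(gr$n_groups, 6L)
  sub <- dereplicate_benchmark(dna_alignment(g$ssu), aset, gr,
                               repeats = 5, seed = 4)
  expect_length(sub$replicate_jrf, 5)
  expect_identical(var(sub$replicate_jrf), 0)
  expect_identical(sub$replicate_jrf[1], sub$full_set_jrf)
  expect_error(dereplicate_benchmark(dna_alignment(g$ssu), aset, gr, repeats = 0),
               class = "rb_invalid_argument")
})
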