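test_that("JC distances follow the closed form, with saturation cap", {
  aln <- dna_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA"))
  expect_identical(unname(jc_distance_matrix(aln)["a", "b"]), 0)

  # 30% observed difference over 10 comparable columns
  aln <- dna_alignment(c(a = "AAAAAAAAAA", b = "CCCAAAAAAA"))
  expect_equal(unname(jc_distance_matrix(aln)["a", "b"]),
               -0.75 * log(1 - 0.4), tolerance = 1e-12)

  aln <- dna_alignment(c(a = "AAAAAAAAAA", b = "CCCCCCCCAA"))
  expect_warning(D <- jc_distance_matrix(aln), "capped")
  expect_identical(unname(D["a", "b"]), 5)

  # gaps and N are excluded pairwise
  aln <- dna_alignment(c(a = "ACGT-N", b = "ACTTAA"))
  expect_equal(unname(jc_distance_matrix(aln)["a", "b"]),
               -0.75 * log(1 - (1 / 4) * 4 / 3), tolerance = 1e-12)

  aln <- dna_alignment(c(a = "NNNN", b = "ACGT"))
  expect_error(jc_distance_matrix(aln), "comparable", class = "rb_data_error")
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: three-point formulas
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  br <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(br["A"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(br["B"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(br["C"]), 0.4, tolerance = 1e-12)

  # 4 taxa with known branch lengths
  t4 <- read_newick(text = "((A:1,B:2):1,C:3,D:4);")
  rec <- neighbor_joining(additive_matrix(t4))
  expect_identical(rf_distance(rec, t4), 0L)
  expect_equal(additive_matrix(rec), additive_matrix(t4), tolerance = 1e-9)

  for (s in 1:10) {
    tr <- with_seed2(s, ape::rtree(8, tip.label = paste0("L", 1:8)))
    rec <- neighbor_joining(additive_matrix(tr))
    expect_identical(rf_distance(rec, tr), 0L)
    expect_equal(additive_matrix(rec), additive_matrix(tr), tolerance = 1e-9)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               class = "rb_invalid_argument")
})

test_that("neighbor joining agrees with the ape reference on topology", {
  skip_if_not_installed("phangorn")
  for (s in 1:5) {
    g <- simulate_genus(sim_config(n_species = 6, strains_per_species = 1,
                                   genome_length = 1100, seed = 70 + s))
    D <- jc_distance_matrix(dna_alignment(g$ssu))
    mine <- neighbor_joining(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(mine, ref), 0)
  }
})

test_that("UPGMA is ultrametric and deterministic on ties", {
  D <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(D)
  expect_equal(tr$edge.length, c(0.05, 0.05), tolerance = 1e-12)

  # tie between (A,B) and (C,D) merges the smallest label pair first
  D <- matrix(0.4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 0.1
  D["C", "D"] <- D["D", "C"] <- 0.1
  diag(D) <- 0
  merges <- regionbench:::.upgma_merges(D)$merges
  expect_identical(sort(c(merges[[1]]$a, merges[[1]]$b)), c("A", "B"))

  ut <- upgma(D)
  coph <- ape::cophenetic.phylo(ut)
  depths <- ape::node.depth.edgelength(ut)[seq_along(ut$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(coph[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("bootstrap supports are deterministic and detect deep splits", {
  g <- simulate_genus(sim_config(n_species = 4, strains_per_species = 1,
                                 genome_length = 1100, seed = 15))
  aln <- dna_alignment(g$ssu)
  t1 <- bootstrap_support(aln, "nj", n_reps = 30, seed = 5)
  t2 <- bootstrap_support(aln, "nj", n_reps = 30, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_error(bootstrap_support(aln, "nj", n_reps = 0),
               class = "rb_invalid_argument")

  # 4 identical sequences: degenerate, must not crash
  same <- dna_alignment(setNames(rep(strrep("ACGT", 50), 4), paste0("s", 1:4)))
  expect_no_error(bootstrap_support(same, "nj", n_reps = 10, seed = 1))

  # two clearly separated clades: the deep split gets full support
  deep <- read_newick(text = "(((A:0.01,B:0.01):0.5,(C:0.01,D:0.01):0.5):0.0);")
  aln <- evolve_alignment(ape::unroot(deep), 2000, seed = 8)
  bt <- bootstrap_support(aln, "nj", n_reps = 100, seed = 9)
  key_split <- regionbench:::.node_keys(bt, rooted = FALSE)
  supports <- suppressWarnings(as.numeric(bt$node.label))
  expect_gte(max(supports, na.rm = TRUE), 95)
})

test_that("ANI dendrogram bootstrap resamples fragment identities", {
  g <- simulate_genus(sim_config(n_species = 5, strains_per_species = 1,
                                 genome_length = 3060, seed = 16))
  aset <- ani_matrix(g$genomes)
  bt <- bootstrap_support(aset, "upgma", n_reps = 50, seed = 2)
  expect_identical(sort(bt$tip.label), sort(names(g$genomes)))
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  expect_identical(write_newick(bt),
                   write_newick(bootstrap_support(aset, "upgma", 50, seed = 2)))
})

test_that("scmg_tree concatenates markers with gap-fill", {
  g <- simulate_genus(sim_config(n_species = 5, strains_per_species = 1,
                                 genome_length = 1100, n_marker_genes = 3,
                                 marker_length = 400, seed = 17))
  # single marker behaves like a direct build
  one <- scmg_tree(g$markers[1], n_reps = 0)
  direct <- neighbor_joining(jc_distance_matrix(g$markers[[1]]))
  expect_identical(rf_distance(one, direct), 0L)

  # a genome missing from one marker is gap-filled, tree covers all
  m2 <- g$markers
  m2[[2]] <- dna_alignment(unclass(m2[[2]])[-1])
  tr <- scmg_tree(m2, n_reps = 0)
  expect_setequal(tr$tip.label, names(g$genomes))

  # markers over disjoint genome sets cannot be concatenated
  a <- dna_alignment(c(x = "ACGTACGT", y = "ACGTACGA"))
  b <- dna_alignment(c(p = "ACGTACGT", q = "ACGTACGA"))
  expect_error(scmg_tree(list(a, b)), class = "rb_data_error")
})

test_that("marker trees recover the true species tree", {
  hits <- 0
  for (s in 1:5) {
    g <- simulate_genus(sim_config(n_species = 8, strains_per_species = 1,
                                   genome_length = 1100, n_marker_genes = 5,
                                   marker_length = 1200, seed = 80 + s))
    tr <- scmg_tree(g$markers, n_reps = 0)
    if (rf_distance(tr, g$true_tree) == 0) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
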