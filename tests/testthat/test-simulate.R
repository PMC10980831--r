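test_that("simulate_tree rescales depth and is seed-deterministic", {
  t2 <- simulate_tree(2, 1, 0.1, seed = 1)
  expect_equal(sum(t2$edge.length), 0.2, tolerance = 1e-12)

  a <- write_newick(simulate_tree(8, 1, 0.05, seed = 7))
  b <- write_newick(simulate_tree(8, 1, 0.05, seed = 7))
  expect_identical(a, b)
  c <- write_newick(simulate_tree(8, 1, 0.05, seed = 8))
  expect_false(identical(a, c))

  tr <- simulate_tree(12, 1, 0.25, seed = 3)
  depths <- ape::node.depth.edgelength(tr)[1:12]
  expect_equal(mean(depths), 0.25, tolerance = 1e-12)
  expect_identical(sort(tr$tip.label), sort(paste0("T", 1:12)))

  expect_error(simulate_tree(1), class = "rb_invalid_argument")
})

test_that("evolve_alignment honors rates, model saturation and seeds", {
  tr <- simulate_tree(6, 1, 0.2, seed = 2)
  frozen <- evolve_alignment(tr, 300, site_rates = rep(0, 300), seed = 5)
  expect_length(unique(unclass(frozen)), 1)  # rate 0 => invariant sites

  # JC69 saturation: two leaves at patristic distance 0.3
  pair <- read_newick(text = "(L1:0.15,L2:0.15);")
  aln <- evolve_alignment(pair, 100000, seed = 3)
  p <- mean(strsplit(aln[[1]], "")[[1]] != strsplit(aln[[2]], "")[[1]])
  expect_equal(p, 0.75 * (1 - exp(-4 * 0.3 / 3)), tolerance = 0.01)

  expect_identical(unclass(evolve_alignment(tr, 200, seed = 9)),
                   unclass(evolve_alignment(tr, 200, seed = 9)))
  expect_error(evolve_alignment(tr, 10, site_rates = rep(-1, 10)),
               class = "rb_invalid_argument")
  expect_error(evolve_alignment(tr, 10, site_rates = rep(1, 5)),
               class = "rb_invalid_argument")
})

test_that("K80 transition bias shows at moderate divergence", {
  pair <- read_newick(text = "(L1:0.1,L2:0.1);")
  aln <- evolve_alignment(pair, 50000, model = "K80", kappa = 8, seed = 4)
  a <- strsplit(aln[[1]], "")[[1]]; b <- strsplit(aln[[2]], "")[[1]]
  diff <- a != b
  ts <- (a %in% c("A", "G") & b %in% c("A", "G")) |
        (a %in% c("C", "T") & b %in% c("C", "T"))
  expect_gt(sum(diff & ts), 2 * sum(diff & !ts))  # kappa = 8 >> 1
})

test_that("simulate_genus builds the configured genus with ground truth", {
  rr <- setNames(rep(1, 6), REGION_ORDER); rr[["V1-V3"]] <- 5
  cfg <- sim_config(seed = 7, region_rate = rr)
  g <- simulate_genus(cfg)
  expect_identical(g$planted_best_region, "V1-V3")
  expect_length(g$genomes, 30)
  expect_length(unique(g$true_species_partition), 10)
  expect_identical(length(g$true_tree$tip.label), 30L)
  expect_setequal(names(g$genomes), names(g$true_species_partition))

  # byte-identical rerun
  g2 <- simulate_genus(cfg)
  expect_identical(g$ssu, g2$ssu)
  expect_identical(g$genomes, g2$genomes)
  expect_identical(write_newick(g$true_tree), write_newick(g2$true_tree))

  expect_error(simulate_genus(sim_config(n_species = 1)),
               class = "rb_invalid_argument")
  bad_map <- data.frame(label = "X", start = 10, end = 10)
  expect_error(sim_config(region_map = bad_map, embed_primers = FALSE),
               class = "rb_invalid_argument")
})

test_that("raising a region's rate raises its pairwise divergence", {
  # monotonicity over multipliers {0, 1, 5}, averaged over 10 seeds
  win <- synthetic_region_layout()$regions
  idx <- (win$start[3] + 1):win$end[3]
  mean_div <- function(mult) {
    mean(vapply(1:10, function(s) {
      rr <- setNames(rep(1, 6), REGION_ORDER); rr[["V4"]] <- mult
      g <- simulate_genus(sim_config(n_species = 4, strains_per_species = 1,
                                     genome_length = 1100, n_marker_genes = 1,
                                     marker_length = 100, seed = 40 + s,
                                     region_rate = rr))
      m <- do.call(rbind, strsplit(unname(g$ssu), ""))[, idx]
      cmp <- utils::combn(nrow(m), 2)
      mean(vapply(seq_len(ncol(cmp)), function(q)
        mean(m[cmp[1, q], ] != m[cmp[2, q], ]), numeric(1)))
    }, numeric(1)))
  }
  d0 <- mean_div(0); d1 <- mean_div(1); d5 <- mean_div(5)
  expect_identical(d0, 0)
  expect_lt(d1, d5)
})

test_that("simulated ANI decays with patristic distance", {
  g <- simulate_genus(sim_config(n_species = 6, strains_per_species = 2,
                                 genome_length = 3060, seed = 13))
  aset <- ani_matrix(g$genomes)
  pat <- ape::cophenetic.phylo(g$true_tree)[rownames(aset$ani), colnames(aset$ani)]
  ut <- upper.tri(pat)
  rho <- suppressWarnings(cor(aset$ani[ut], pat[ut], method = "spearman"))
  expect_lt(rho, -0.9)
})

test_that("multi-copy mode emits divergent intragenomic copies", {
  g <- simulate_genus(sim_config(n_species = 3, strains_per_species = 1,
                                 genome_length = 1100, copies = 2, seed = 5))
  copies <- g$ssu_by_genome[[1]]
  expect_length(copies, 2)
  expect_false(identical(copies[[1]], copies[[2]]))
  picked <- choose_copy(copies)
  expect_identical(names(picked), names(copies)[1])  # equal lengths, id tie-break
})

test_that("write_genus emits the full artifact set", {
  dir <- withr::local_tempdir()
  g <- simulate_genus(sim_config(n_species = 3, strains_per_species = 1,
                                 genome_length = 1100, n_marker_genes = 2,
                                 marker_length = 150, seed = 2))
  write_genus(g, dir)
  expect_setequal(list.files(dir),
                  c("genomes.fasta", "ssu.fasta", "markers", "truth.nwk",
                    "truth.tsv", "panel.tsv"))
  expect_length(list.files(file.path(dir, "markers")), 2)
  expect_identical(read_fasta(file.path(dir, "ssu.fasta")), g$ssu)
})
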