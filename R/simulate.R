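# Synthetic-genus generator. Produces a known species tree with grafted
# strain subtrees, 16S genes whose variability is concentrated in
# configurable hot regions (with conserved primer-binding sites embedded so
# in-silico PCR works on the output), neutral whole-genome backbones whose
# pairwise ANI decays with tree distance, and single-copy marker genes --
# everything needed to exercise the benchmark with full ground truth.

# Concrete, mutually dissimilar 20-mers used as the synthetic panel's
# primer-binding sites (pairwise Hamming distance >= 8, also vs reverse
# complements). Fixed constants so simulator output is reproducible.
.SYN_PRIMER_SITES <- c(
  "AAAACTCCATGTGTAACTCC", "GGAAGTAGAATCTTGCACTC",
  "GGCCTTTCCATATCTCGTGA", "ACCCCCTGCACGCCCTAAAG",
  "TACAATTAGGATATTCATCC", "CTACACTGTATATGCCGAAC",
  "GTTCTAATAAACGACTTAGC", "AACAAGTCGCCTAGAAAGGT",
  "ACCGCTGGCATATCACGCCT", "CCCGCTTGCCGTCTTCAACT",
  "TCATGACCCTCGTGCATCAC", "AAAGCCTCAAGCCGGAGTCT")

#' Synthetic 16S gene layout
#'
#' The synthetic gene carries six disjoint 180-bp variable windows, each
#' flanked by its own conserved 20-bp primer sites. Real 16S variable
#' regions are heavily nested (V4 lies inside both V3-V4 and V4-V5
#' amplicons), which makes a planted hot region unidentifiable from
#' amplicon trees alone; disjoint windows keep the ground truth
#' recoverable. Window labels reuse the conventional region names so the
#' benchmark's column layout is identical on synthetic and real data.
#'
#' @return List with `regions` (`data.frame(label, start, end)`, 0-based
#'   half-open), `footprints` (primer site intervals), `sites` (concrete
#'   site sequences) and `min_gene_length`.
#' @export
synthetic_region_layout <- function() {
  i <- 0:5
  regions <- data.frame(label = REGION_ORDER,
                        start = 50L + 240L * i, end = 230L + 240L * i)
  fwd <- data.frame(start = 30L + 240L * i, end = 50L + 240L * i)
  rev <- data.frame(start = 230L + 240L * i, end = 250L + 240L * i)
  list(regions = regions,
       footprints = rbind(fwd, rev)[order(c(fwd$start, rev$start)), ],
       fwd_sites = .SYN_PRIMER_SITES[2 * i + 1],
       rev_sites = .SYN_PRIMER_SITES[2 * i + 2],
       fwd_starts = fwd$start, rev_starts = rev$start,
       min_gene_length = 1460L)
}

#' The synthetic primer panel matching [synthetic_region_layout()]
#'
#' @param max_mismatch mismatch tolerance.
#' @return List of [primer_pair()] objects (concrete, non-degenerate).
#' @export
synthetic_primer_panel <- function(max_mismatch = 2) {
  lay <- synthetic_region_layout()
  lapply(seq_len(6), function(j)
    primer_pair(lay$regions$label[j], lay$fwd_sites[j],
                revcomp(lay$rev_sites[j]), max_mismatch))
}

#' Simulation configuration
#'
#' @param n_species number of species in the genus.
#' @param strains_per_species strains (genomes) per species.
#' @param birth_rate per-lineage speciation rate of the pure-birth species
#'   tree.
#' @param tree_depth_target expected root-to-tip path length of the
#'   species tree, substitutions/site.
#' @param gene_length 16S gene length in bases.
#' @param region_map `data.frame(label, start, end)` of non-overlapping
#'   0-based half-open intervals on the gene; defaults to the six windows
#'   of [synthetic_region_layout()].
#' @param region_rate named nonnegative rate multipliers per region label
#'   (background = 1). The region with the (unique, > 1) largest
#'   multiplier is the planted most-variable region.
#' @param genome_length length of the neutral genome backbone.
#' @param n_marker_genes,marker_length single-copy marker genes evolved on
#'   the same tree.
#' @param seed integer seed; identical configurations and seeds give
#'   byte-identical output.
#' @param min_species_divergence minimum interspecies patristic distance
#'   (substitutions/site) enforced by stretching terminal branches; keeps
#'   between-species ANI below the 95% species threshold.
#' @param within_species_height height of each within-species strain
#'   subtree; `NULL` = 0.2 x the shortest interspecies branch, capped at
#'   0.008 so within-species genome identity stays above 95%.
#' @param ssu_rate overall rate scaling of the 16S gene relative to the
#'   neutral genome. The default 0.1 emulates the strong conservation of
#'   the rRNA gene: background 16S columns carry little within-genus
#'   signal, so resolution is concentrated in the hot regions.
#' @param embed_primers embed the synthetic panel's conserved primer sites
#'   (rate 0) into the gene so in-silico PCR recovers the windows.
#' @param copies 16S copies per genome (copies > 1 adds small intragenomic
#'   divergence to exercise copy selection).
#' @param model substitution model, `"JC69"` or `"K80"`.
#' @param kappa transition/transversion rate ratio for K80.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_species = 10, strains_per_species = 3,
                       birth_rate = 1, tree_depth_target = 0.1,
                       gene_length = 1550,
                       region_map = synthetic_region_layout()$regions,
                       region_rate = NULL,
                       genome_length = 10000,
                       n_marker_genes = 5, marker_length = 1200,
                       seed = 1,
                       min_species_divergence = 0.10,
                       within_species_height = NULL,
                       ssu_rate = 0.1, embed_primers = TRUE,
                       copies = 1, model = c("JC69", "K80"), kappa = 2) {
  model <- match.arg(model)
  if (n_species < 2) rb_invalid("n_species must be >= 2")
  if (strains_per_species < 1) rb_invalid("strains_per_species must be >= 1")
  if (gene_length < 1 || genome_length < 1) rb_invalid("lengths must be positive")
  region_map <- as.data.frame(region_map)
  if (nrow(region_map)) {
    if (any(region_map$end <= region_map$start))
      rb_invalid("zero- or negative-length region in region_map")
    if (any(region_map$start < 0) || any(region_map$end > gene_length))
      rb_invalid("region_map intervals must lie within [0, gene_length)")
    o <- order(region_map$start)
    rm2 <- region_map[o, ]
    if (nrow(rm2) > 1 && any(rm2$start[-1] < rm2$end[-nrow(rm2)]))
      rb_invalid("region_map intervals must not overlap")
  }
  if (is.null(region_rate))
    region_rate <- setNames(rep(1, nrow(region_map)), region_map$label)
  if (any(region_rate < 0)) rb_invalid("rate multipliers must be >= 0")
  if (!all(names(region_rate) %in% region_map$label))
    rb_invalid("region_rate names must match region_map labels")
  if (embed_primers && gene_length < synthetic_region_layout()$min_gene_length)
    rb_invalid(sprintf("gene_length must be >= %d to embed the synthetic panel",
                       synthetic_region_layout()$min_gene_length))
  structure(list(
    n_species = n_species, strains_per_species = strains_per_species,
    birth_rate = birth_rate, tree_depth_target = tree_depth_target,
    gene_length = gene_length, region_map = region_map,
    region_rate = region_rate, genome_length = genome_length,
    n_marker_genes = n_marker_genes, marker_length = marker_length,
    seed = as.integer(seed),
    min_species_divergence = min_species_divergence,
    within_species_height = within_species_height,
    ssu_rate = ssu_rate, embed_primers = embed_primers,
    copies = copies, model = model, kappa = kappa), class = "sim_config")
}

# pure-birth topology with branch lengths rescaled to the depth target;
# uses the ambient RNG stream
.sim_tree <- function(n_taxa, birth_rate, depth_target, labels = NULL) {
  tr <- if (n_taxa == 2) {
    ape::read.tree(text = "(T1:1,T2:1);")
  } else {
    ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  }
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_taxa)]
  f <- depth_target / mean(depths)
  tr$edge.length <- tr$edge.length * f
  tr$tip.label <- labels %||% paste0("T", seq_len(n_taxa))
  tr
}

#' Simulate a random species tree
#'
#' Pure-birth (Yule) topology conditioned on `n_taxa` tips, with branch
#' lengths rescaled so the mean root-to-tip path equals `depth_target`.
#' Leaves are labeled `T1..Tn`.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate per-lineage speciation rate.
#' @param depth_target mean root-to-tip path, substitutions/site.
#' @param seed integer seed.
#' @return A `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, depth_target = 0.1, seed = 1) {
  if (n_taxa < 2) rb_invalid("n_taxa must be >= 2")
  with_seed(seed, .sim_tree(n_taxa, birth_rate, depth_target))
}

# one JC69/K80 branch step for an integer-coded sequence (1..4 = A,C,G,T)
.evolve_branch <- function(seq_int, d_sites, model, kappa) {
  n <- length(seq_int)
  if (model == "JC69") {
    p <- 0.75 * (1 - exp(-4 * d_sites / 3))
    hit <- which(runif(n) < p)
    if (length(hit)) {
      off <- sample.int(3L, length(hit), replace = TRUE)
      seq_int[hit] <- ((seq_int[hit] - 1L + off) %% 4L) + 1L
    }
  } else {
    # K80: A<->G and C<->T are transitions
    e1 <- exp(-4 * d_sites / (kappa + 2))
    e2 <- exp(-2 * d_sites * (kappa + 1) / (kappa + 2))
    p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    p_tv <- 0.25 - 0.25 * e1          # each of the two transversions
    u <- runif(n)
    ts_partner <- c(3L, 4L, 1L, 2L)   # A->G, C->T, G->A, T->C
    hit_ts <- which(u < p_ts)
    seq_int[hit_ts] <- ts_partner[seq_int[hit_ts]]
    hit_tv <- which(u >= p_ts & u < p_ts + 2 * p_tv)
    if (length(hit_tv)) {
      # the two transversion partners of base b are the two bases of the
      # opposite purine/pyrimidine class
      pick <- sample.int(2L, length(hit_tv), replace = TRUE)
      old <- seq_int[hit_tv]
      tv1 <- c(2L, 1L, 2L, 1L); tv2 <- c(4L, 3L, 4L, 3L)
      seq_int[hit_tv] <- ifelse(pick == 1L, tv1[old], tv2[old])
    }
  }
  seq_int
}

.BASES <- c("A", "C", "G", "T")

.evolve_on_tree <- function(tree, length, site_rates, model, kappa, root_seq) {
  root_int <- if (is.null(root_seq)) {
    sample.int(4L, length, replace = TRUE)
  } else {
    m <- match(strsplit(toupper(root_seq), "")[[1]], .BASES)
    if (anyNA(m) || length(m) != length)
      rb_invalid("root_seq must be an ACGT string of the requested length")
    m
  }
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root_node]] <- root_int
  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    seqs[[chi]] <- .evolve_branch(seqs[[par]],
                                  site_rates * tree$edge.length[e],
                                  model, kappa)
  }
  out <- vapply(seq_len(n_tip),
                function(i) paste0(.BASES[seqs[[i]]], collapse = ""),
                character(1))
  dna_alignment(setNames(out, tree$tip.label))
}

#' Evolve sequences along a tree
#'
#' Site-independent evolution under JC69 or K80, with per-site rate
#' multipliers. A site with multiplier 0 is invariant. Branch lengths are
#' expected substitutions/site at multiplier 1.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param length sequence length.
#' @param site_rates vector of `length` nonnegative multipliers (default
#'   all 1).
#' @param model `"JC69"` (default) or `"K80"`.
#' @param kappa K80 transition/transversion ratio.
#' @param seed integer seed.
#' @param root_seq optional root sequence (ACGT string); random uniform
#'   otherwise.
#' @return A [dna_alignment()] of ungapped leaf sequences.
#' @export
evolve_alignment <- function(tree, length, site_rates = NULL,
                             model = c("JC69", "K80"), kappa = 2,
                             seed = 1, root_seq = NULL) {
  model <- match.arg(model)
  site_rates <- site_rates %||% rep(1, length)
  if (length(site_rates) != length)
    rb_invalid("site_rates must have one entry per site")
  if (any(site_rates < 0)) rb_invalid("site rates must be >= 0")
  with_seed(seed, .evolve_on_tree(tree, length, site_rates, model, kappa, root_seq))
}

#' Simulate a synthetic genus
#'
#' Builds a species tree, enforces a minimum interspecies divergence,
#' grafts coalescent strain subtrees of small height (so ANI groups
#' coincide with species at the 95% threshold), and evolves the 16S gene
#' (with region-structured rates and conserved primer sites), a neutral
#' genome backbone, and marker genes on the resulting strain tree.
#'
#' @param cfg a [sim_config()].
#' @return A `synthetic_genus`: list with `true_tree`, `genomes`, `ssu`
#'   (one entry per copy; names are genome ids when `copies == 1`),
#'   `ssu_by_genome` (list of copies per genome), `markers` (list of
#'   [dna_alignment()]), `planted_best_region`,
#'   `true_species_partition` (named integer vector), `panel`, `region_map`
#'   and `cfg`.
#' @export
simulate_genus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, .simulate_genus_impl(cfg))
}

.simulate_genus_impl <- function(cfg) {
  ns <- cfg$n_species; m <- cfg$strains_per_species
  sp_labels <- sprintf("sp%03d", seq_len(ns))
  sp <- .sim_tree(ns, cfg$birth_rate, cfg$tree_depth_target, sp_labels)

  # enforce the minimum interspecies patristic distance by stretching
  # every terminal branch equally
  pat <- ape::cophenetic.phylo(sp)
  dmin <- min(pat[upper.tri(pat)])
  if (dmin < cfg$min_species_divergence) {
    add <- (cfg$min_species_divergence - dmin) / 2
    term <- tree_terminal_edges(sp)
    sp$edge.length[term] <- sp$edge.length[term] + add
  }
  h_w <- cfg$within_species_height %||%
    min(0.2 * min(sp$edge.length), 0.008)

  # graft strain subtrees by newick substitution (labels are fixed-width,
  # so plain string replacement is unambiguous)
  nwk <- ape::write.tree(sp, digits = 12)
  gids <- character(0)
  part <- integer(0)
  for (i in seq_len(ns)) {
    ids <- sprintf("g%03d_%d", i, seq_len(m))
    gids <- c(gids, ids)
    part <- c(part, rep(i, m))
    sub_nwk <- if (m == 1) {
      ids
    } else {
      sub <- ape::rcoal(m, tip.label = ids)
      depth <- max(ape::node.depth.edgelength(sub))
      sub$edge.length <- sub$edge.length * (h_w / depth)
      sub("\\);$", ")", ape::write.tree(sub, digits = 12))
    }
    nwk <- sub(paste0(sp_labels[i], ":"), paste0(sub_nwk, ":"), nwk, fixed = TRUE)
  }
  true_tree <- ape::read.tree(text = nwk)
  names(part) <- gids

  # 16S site rates: background * ssu_rate, region multipliers, primer
  # footprints invariant
  rates <- rep(cfg$ssu_rate, cfg$gene_length)
  for (j in seq_len(nrow(cfg$region_map))) {
    lab <- cfg$region_map$label[j]
    mult <- if (lab %in% names(cfg$region_rate)) cfg$region_rate[[lab]] else 1
    idx <- (cfg$region_map$start[j] + 1):cfg$region_map$end[j]
    rates[idx] <- cfg$ssu_rate * mult
  }
  root16 <- NULL
  panel <- NULL
  if (cfg$embed_primers) {
    lay <- synthetic_region_layout()
    panel <- synthetic_primer_panel()
    root16 <- .BASES[sample.int(4L, cfg$gene_length, replace = TRUE)]
    for (j in seq_len(6)) {
      fs <- lay$fwd_starts[j]; rs <- lay$rev_starts[j]
      root16[(fs + 1):(fs + 20)] <- strsplit(lay$fwd_sites[j], "")[[1]]
      root16[(rs + 1):(rs + 20)] <- strsplit(lay$rev_sites[j], "")[[1]]
      rates[c((fs + 1):(fs + 20), (rs + 1):(rs + 20))] <- 0
    }
    root16 <- paste0(root16, collapse = "")
  }
  ssu <- .evolve_on_tree(true_tree, cfg$gene_length, rates,
                         cfg$model, cfg$kappa, root16)
  ssu_by_genome <- lapply(setNames(gids, gids), function(g) {
    if (cfg$copies == 1) return(setNames(unclass(ssu)[g], g))
    copies <- setNames(
      vapply(seq_len(cfg$copies), function(ci) {
        s <- match(strsplit(unclass(ssu)[[g]], "")[[1]], .BASES)
        if (ci > 1)  # small fixed intragenomic divergence
          s <- .evolve_branch(s, (rates > 0) * 0.005, cfg$model, cfg$kappa)
        paste0(.BASES[s], collapse = "")
      }, character(1)),
      paste0(g, "_rrn", LETTERS[seq_len(cfg$copies)]))
    copies
  })
  genomes <- .evolve_on_tree(true_tree, cfg$genome_length,
                             rep(1, cfg$genome_length), cfg$model, cfg$kappa,
                             NULL)
  markers <- lapply(seq_len(cfg$n_marker_genes), function(j)
    .evolve_on_tree(true_tree, cfg$marker_length, rep(1, cfg$marker_length),
                    cfg$model, cfg$kappa, NULL))
  names(markers) <- sprintf("marker%02d", seq_len(cfg$n_marker_genes))

  rr <- cfg$region_rate
  planted <- if (length(rr) && max(rr) > 1 && sum(rr == max(rr)) == 1) {
    names(rr)[which.max(rr)]
  } else NA_character_
  structure(list(
    true_tree = true_tree,
    genomes = unclass(genomes),
    ssu = if (cfg$copies == 1) setNames(unclass(ssu)[gids], gids)
          else unlist(unname(ssu_by_genome)),
    ssu_by_genome = ssu_by_genome,
    markers = markers,
    planted_best_region = planted,
    true_species_partition = part,
    panel = panel %||% default_primer_panel(),
    region_map = cfg$region_map,
    cfg = cfg), class = "synthetic_genus")
}

# indices of edges leading to tips
tree_terminal_edges <- function(tree) {
  which(tree$edge[, 2] <= length(tree$tip.label))
}

#' Write a synthetic genus to disk
#'
#' Writes `genomes.fasta`, `ssu.fasta`, `markers/markerNN.aln.fasta`,
#' `truth.nwk`, `truth.tsv` (genome_id, species, planted region) and
#' `panel.tsv` into a directory.
#'
#' @param genus a `synthetic_genus`.
#' @param dir output directory (created if needed).
#' @export
write_genus <- function(genus, dir) {
  stopifnot(inherits(genus, "synthetic_genus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "markers"), showWarnings = FALSE)
  write_fasta(genus$genomes, file.path(dir, "genomes.fasta"))
  write_fasta(genus$ssu, file.path(dir, "ssu.fasta"))
  for (nm in names(genus$markers))
    write_fasta(unclass(genus$markers[[nm]]),
                file.path(dir, "markers", paste0(nm, ".aln.fasta")))
  write_newick(genus$true_tree, file.path(dir, "truth.nwk"))
  write_tsv(data.frame(genome_id = names(genus$true_species_partition),
                       species = unname(genus$true_species_partition),
                       planted_region = genus$planted_best_region),
            file.path(dir, "truth.tsv"))
  write_panel(genus$panel, file.path(dir, "panel.tsv"))
  invisible(dir)
}
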