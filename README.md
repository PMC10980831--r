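# regionbench

Which variable region of the 16S rRNA gene should you sequence to
resolve the taxa you actually care about? The answer is genus-specific:
mutational hot spots sit in different regions in different lineages, so
a primer pair that separates species cleanly in one genus can be almost
uninformative in another. regionbench is an R package for answering the
question quantitatively for a genome collection of one or more genera.

For each genus it:

1. extracts the six standard amplicons (V1-V3, V3-V4, V4, V4-V5, V6-V8,
   V6-V9; any panel can be supplied as TSV) from full-length 16S genes
   by in-silico PCR with degenerate, mismatch-tolerant primers;
2. builds a phylogeny from each amplicon and from the full gene
   (Jukes-Cantor distances + neighbor joining);
3. builds whole-genome references: a fragment-based ANI matrix, its
   UPGMA dendrogram (with fragment-resampling bootstrap), 95%-threshold
   ANI groups, and a concatenated single-copy-marker-gene (SCMG) tree;
4. scores every gene tree against the genome-level references with the
   generalized Jaccard-Robinson-Foulds (JRF) distance

   d = (|S1| + |S2| - 2 * max-matching of Jaccard^k pair scores) / (|S1| + |S2|),

   an optimal-assignment softening of Robinson-Foulds on the two split
   sets (mutual clustering information, MCI, is available as an
   alternative similarity);
5. reports per-genus JRF rows, row z-scores, the best region per genus,
   Shannon-entropy profiles with region annotations, an ANI-vs-SCMG
   adequacy check (paired exact Wilcoxon across genera), and a
   dereplication experiment that resamples one genome per ANI group to
   remove strain-redundancy bias.

A synthetic-genus generator (`simulate_genus()`) provides full ground
truth -- known species tree, planted hot region, controllable ANI-group
structure -- so the entire pipeline is testable without downloading a
single genome. See the methods vignette
(`vignettes/regionbench-methods.Rmd`) for the model, parameter defaults
and design decisions.

## Worked example

Simulate a genus of 40 single-strain species whose V3-V4 window evolves
at 5x the gene background, then benchmark every region against the ANI
dendrogram:

```r
library(regionbench)

rates <- setNames(rep(1, 6), REGION_ORDER)
rates[["V3-V4"]] <- 5
g <- simulate_genus(sim_config(n_species = 40, strains_per_species = 1,
                               genome_length = 5100, seed = 101,
                               region_rate = rates))
res <- run_genus_benchmark(g$ssu, g$genomes, panel = g$panel,
                           seed = 101, repeats = 0)
round(res$raw[1:7], 3)
#> 16S full    V1-V3    V3-V4       V4    V4-V5    V6-V8    V6-V9
#>    0.122    0.446    0.173    0.550    0.484    0.450    0.402
res$best_region
#> [1] "V3-V4"
```

The row is read like one row of a region-ranking heatmap: the full-length
gene tree is closest to the whole-genome dendrogram (JRF 0.122), the
planted V3-V4 window is by far the best single amplicon (0.173), and the
cold regions hover around 0.4-0.55 -- their 180-bp windows simply do not
carry enough within-genus signal. `res$z` holds the row z-scores,
`res$entropy` the per-column entropy profile in bits (here 0.357 bits for the hot window versus 0.061-0.080 for the
background windows), and with
`markers = g$markers` the result also contains the ANI-vs-SCMG adequacy
distances.

A command-line interface wraps the same functions
(`inst/scripts/regionbench`): `simulate`, `extract`, `entropy`, `ani`,
`trees`, `compare`, `onf`, `benchmark`, each writing TSV/FASTA/newick
artifacts plus an echo of its configuration.

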