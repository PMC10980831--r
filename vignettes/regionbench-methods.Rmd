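---
title: "Benchmarking 16S rRNA variable regions against whole-genome phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking 16S rRNA variable regions against whole-genome phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Amplicon surveys of bacterial communities target one of the nine variable
regions (V1-V9) of the ~1500-bp 16S rRNA gene. The regions differ in how
much taxonomic signal they carry, and that difference is itself
taxon-dependent: a primer pair that resolves one genus to species level
may be nearly uninformative in another. regionbench quantifies this
directly: for a set of genomes from one genus it builds a phylogeny from
each primer-defined amplicon and from the full gene, builds whole-genome
reference structures -- an average-nucleotide-identity (ANI) dendrogram
and a concatenated single-copy-marker-gene (SCMG) tree -- and ranks the
regions by how closely their trees match the genome-level references.

## Tree comparison: generalized Jaccard-Robinson-Foulds and MCI

The classic Robinson-Foulds (RF) distance counts bipartitions (splits)
present in one tree but not the other. It is maximally strict: a split
differing by one leaf counts the same as an unrelated one. The
generalized Jaccard-Robinson-Foulds (JRF) distance used here softens
this. For splits $A|B$ of tree 1 and $C|D$ of tree 2 the pair score is

$$ s = J^k, \qquad
   J = \max\left\{\min(\mathrm{jac}(A,C), \mathrm{jac}(B,D)),\;
                  \min(\mathrm{jac}(A,D), \mathrm{jac}(B,C))\right\} $$

with $\mathrm{jac}$ the Jaccard index and $k > 0$ a concavity parameter
(default 1; as $k \to \infty$ the metric approaches RF normalized by the
split count, which the test suite verifies at $k = 64$). An optimal
one-to-one matching between the two split sets maximizing $\sum s$ is
solved exactly with the Hungarian algorithm, and

$$ d_{\mathrm{JRF}} = \frac{|S_1| + |S_2| - 2\sum s}{|S_1| + |S_2|}
   \in [0, 1]. $$

Conventions for degenerate inputs: two star trees have distance 0; a
star versus a resolved tree has distance 1, so the metric is total.
Rooted dendrograms are unrooted before split extraction so that all
comparisons share one split universe. Mutual clustering information
(MCI) uses the same optimal matching with pair score equal to the mutual
information (bits) of the two splits viewed as binary leaf labelings;
the normalized MCI distance is $1 - \mathrm{MCI}/\max(\sum H_1, \sum
H_2)$ over the split entropies. An exhaustive matcher over all partial
matchings (`brute_force_match()`) is kept as an independent oracle; the
acceptance suite checks assignment-vs-oracle equality over the complete
enumeration of 6-leaf topologies and random 8-leaf pairs.

Published JRF variants differ in pair scoring and normalization; the
definition above is fixed exactly so results are reproducible
bit-for-bit, and externally computed trees can be imported as newick for
users who prefer another implementation.

## Trees

All trees are distance-based: Jukes-Cantor distances (pairwise deletion
of gaps/N; saturated pairs with $p \ge 0.75$ capped at 5
substitutions/site with a warning), canonical neighbor joining
(Q-criterion, Studier-Keppler updates) for gene trees and the SCMG tree,
and average-linkage UPGMA for the ANI dendrogram. NJ ties are broken by
matrix position with taxa sorted by label; negative NJ branches are
clamped to zero with the deficit moved to the sibling branch. These
choices make every tree a deterministic function of its input, which the
byte-level determinism test exercises end to end. Maximum-likelihood
inference is deliberately out of scope: the comparison layer is agnostic
to the tree builder, and an import path accepts external newick trees.

Bootstrap supports resample alignment columns, or -- for the ANI
dendrogram -- each pair's per-fragment identities, and report the
percentage of replicates containing each split (cluster, for rooted
dendrograms).

## ANI

`pairwise_ani()` is a fragment-mapping estimator: the query is cut into
non-overlapping 1020-bp windows, each window is placed on the subject by
shared 16-mer diagonal voting on both strands, and the best locus is
aligned with a banded global alignment (band 0.1 x fragment length;
match +1, mismatch -1, gap -2). Fragments with alignment identity and
coverage of at least 70% count as aligned; ANI is the mean identity over
aligned fragments, symmetrized as the mean of the two directions. Pairs
with no aligned fragment have undefined ANI and are assigned distance
1.0 (with a warning) so distance matrices stay complete. ANI groups are
single-linkage connected components at a 95% identity threshold -- the
conventional bacterial species boundary -- so transitive chains merge,
and raising the threshold can only increase the number of groups.

## In-silico PCR

Primer matching is IUPAC-aware (two codes are compatible when their base
sets intersect), allows at most 2 mismatches by default, and requires a
perfect match in the primer's 3'-terminal 5 bases, mimicking the
polymerase extension requirement. Amplicons use the leftmost forward and
rightmost compatible reverse site; the extracted region is the interior
between the primer footprints, because primer-binding bases are
conserved by design and would depress entropy estimates. Interiors must
be 50-1200 bp. The default panel (27F/534R, 341F/805R, 515F/806R,
515F/926R, 926F/1392R, 926F/1492R) is a conventional choice for the six
named windows and is fully configurable via TSV.

## Entropy

Per-column Shannon entropy is reported in bits (base 2). Gaps are
excluded by default (`gap_mode = "exclude"`, range 0-2 bits) because in
this pipeline gaps are alignment artifacts rather than states; a
fifth-state mode is available. N never counts as a state. The smoother
is a plain 10-column sliding mean reported alongside the raw values.
Region annotations are mapped onto alignment coordinates through the
alphabetically first genome's extracted-region coordinates.

## The synthetic genus generator

Because the real benchmark needs thousands of genomes and external
databases, every stage is testable on synthetic genera with known ground
truth:

* **Species tree** -- pure-birth topology conditioned on `n_species`,
  branch lengths rescaled so the mean root-to-tip path equals
  `tree_depth_target` (default 0.1 substitutions/site). Terminal
  branches are stretched so every interspecies patristic distance is at
  least `min_species_divergence` (default 0.10), which keeps
  between-species ANI safely below the 95% species threshold while
  staying above the 70% fragment-identity floor of the estimator.
* **Strains** -- each species leaf is replaced by a coalescent subtree
  of height `within_species_height` (default: 0.2 x the shortest
  interspecies branch, capped at 0.008), keeping within-species genome
  identity above ~98%, so ANI groups coincide with species.
* **Sequences** -- a neutral genome backbone (default 10 kb; a
  deliberately scaled-down stand-in for a real chromosome that keeps
  all-pairs ANI affordable), `n_marker_genes` marker genes, and a 16S
  gene, all evolved site-independently under JC69 (default; K80
  optional). Identical configuration and seed give byte-identical
  output.
* **Hot regions** -- the 16S gene carries six disjoint 180-bp variable
  windows, each flanked by its own conserved 20-bp primer sites
  (mutation rate 0, concrete site sequences embedded at the root). Real
  16S amplicons are heavily nested -- V4 lies inside both the V3-V4 and
  V4-V5 amplicons -- which makes a planted most-variable region
  formally unidentifiable from amplicon trees; disjoint windows keep
  the ground truth recoverable while the benchmark's column layout
  stays identical to the real panel. The gene-wide rate is scaled by
  `ssu_rate` (default 0.1 of the neutral genomic rate), emulating rRNA
  conservation: background 16S columns carry little within-genus
  signal, so resolution concentrates in whichever window gets a rate
  multiplier above 1. The window with the unique largest multiplier is
  the planted best region.

What the generator does **not** emulate: rRNA secondary-structure
constraints, GC heterogeneity, horizontal transfer, intragenomic copy
variation beyond a simple fixed-divergence copy mode, and indels
(an optional mode exists only to exercise the aligner). Passing tests
therefore demonstrate correctness of the computational pipeline and the
internal consistency of the method, not performance on real genomes.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen so each experiment is statistically decisive
at desk scale:

* Planted-region recovery: 40 species x 1 strain, 5.1-kb genomes, one
  window at 5x rate, ten configurations cycling through the six
  windows. Single strains and a larger species count are used because
  strain-level structure is unresolvable by any 180-bp window (by
  design) and only adds identical noise to every column of the
  benchmark row, while more species give the split matching more
  material to average over.
* ANI-group recovery: the generator defaults (10 species x 3 strains,
  10-kb genomes), ten seeds.
* Dereplicated subsampling: 10 species x 10 strains, ten repeats (one
  genome per ANI group per repeat), ten seeds; 3-kb genomes with 510-bp
  fragments keep the 4950-pair ANI matrix affordable.
* ANI calibration: 30.6-kb random genomes with 5% i.i.d. substitutions,
  twenty seeds, so the binomial standard error (~0.13 ANI points) is
  well inside the +/-0.5 acceptance band.

## Numerical conventions

Branch lengths are serialized with 15 significant digits; alignments,
entropy tables and benchmark tables are written as TSV with `.` decimal
separators; all user-facing coordinates are 1-based inclusive while
internal coordinates are 0-based half-open. Every random step takes an
explicit seed, and the end-to-end pipeline is byte-identical across
reruns with the same seed.

## Known limitations

* Distance-based trees (no ML/Bayesian inference, no rate-heterogeneity
  fitting).
* The ANI estimator is exact but quadratic in genome count and linear in
  genome length; it targets desk-scale synthetic data and small real
  genome sets, not thousands of real genomes.
* The progressive aligner is a textbook profile-NW implementation meant
  for near-identical rRNA sequence sets; heavily gapped or highly
  divergent inputs deserve a dedicated MSA tool, and aligned FASTA can
  be supplied directly.
* Wilcoxon tests are exact only up to 12 non-zero pairs (a normal
  approximation with tie correction is used beyond).
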