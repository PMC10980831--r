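# End-to-end per-genus pipeline: extraction -> alignments -> ANI ->
# trees -> benchmark tables. Deterministic for a fixed seed; all tabular
# output is TSV.

# map a 0-based ungapped coordinate to a 0-based alignment column via the
# gap pattern of one reference row
.map_to_alignment <- function(ref_row, pos0) {
  chars <- strsplit(ref_row, "")[[1]]
  unmapped <- cumsum(chars != "-")
  vapply(pos0, function(p) {
    col <- which(unmapped == p + 1)[1]
    if (is.na(col)) length(chars) else col - 1L
  }, integer(1))
}

#' Run the full benchmark for one genus
#'
#' Extracts the panel amplicons from the 16S sequences, aligns the full
#' gene and each region (sequence sets that are already equal-length and
#' gap-free are used as-is), computes the ANI matrix, groups and
#' dendrogram, benchmarks every tree source against the dendrogram,
#' z-scores the row, calls the best region, profiles column entropy with
#' region annotations, runs the dereplicated subsampling experiment, and
#' (when markers are given) compares the ANI dendrogram and 16S tree to
#' the SCMG reference tree.
#'
#' @param ssu named character vector: one 16S sequence per genome.
#' @param genomes named character vector of genome sequences.
#' @param markers optional list of marker [dna_alignment()]s.
#' @param panel list of [primer_pair()]s.
#' @param seed integer seed (subsampling).
#' @param repeats dereplication repeats.
#' @param jrf_k JRF concavity parameter.
#' @param frag_len,kmer ANI fragment length and seed k-mer size.
#' @param ani_threshold ANI grouping threshold (percent).
#' @param out_dir optional output directory for TSV/newick artifacts.
#' @return A `genus_benchmark_result` list (raw row, z row, best region,
#'   ANI set and groups, dendrogram, entropy profile, subsample result,
#'   SCMG comparisons, drop report).
#' @export
run_genus_benchmark <- function(ssu, genomes, markers = NULL,
                                panel = default_primer_panel(),
                                seed = 1, repeats = 10, jrf_k = 1,
                                frag_len = 1020, kmer = 16,
                                ani_threshold = 95, out_dir = NULL) {
  align_or_pass <- function(seqs) {
    if (length(unique(nchar(seqs))) == 1) dna_alignment(seqs)
    else progressive_msa(seqs)
  }
  ex <- extract_panel(ssu, panel)
  region_seqs <- region_sequences(ex)
  full_aln <- align_or_pass(ssu)
  alns <- c(list("16S full" = full_aln),
            lapply(region_seqs[vapply(region_seqs, length, 1L) >= 2],
                   align_or_pass))

  aset <- ani_matrix(genomes, frag_len = frag_len, k = kmer)
  groups <- ani_groups(aset$D, threshold = ani_threshold)
  den <- upgma(aset$D)

  row <- genus_benchmark(alns, den, k = jrf_k)
  zrow <- as.vector(zscore_rows(matrix(row, 1, dimnames = list("genus", names(row)))))
  names(zrow) <- names(row)
  best <- best_region(row)

  # entropy with region windows mapped through the alphabetically first
  # genome's row
  ref <- sort(names(ssu))[1]
  reg_ann <- NULL
  hits_ref <- lapply(ex$hits, function(rh) rh[[ref]])
  hits_ref <- hits_ref[!vapply(hits_ref, is.null, logical(1))]
  if (length(hits_ref)) {
    ref_row <- unclass(full_aln)[[ref]]
    reg_ann <- data.frame(
      label = vapply(hits_ref, `[[`, character(1), "region_label"),
      start = .map_to_alignment(ref_row,
                                vapply(hits_ref, `[[`, numeric(1), "start")),
      end = .map_to_alignment(ref_row,
                              vapply(hits_ref, `[[`, numeric(1), "end")))
  }
  prof <- column_entropy(full_aln, regions = reg_ann)

  sub <- if (groups$n_groups >= 4 && repeats >= 1) {
    dereplicate_benchmark(full_aln, aset, groups, repeats, seed, k = jrf_k)
  } else NULL

  scmg <- NULL
  if (!is.null(markers) && length(markers)) {
    ref_tree <- scmg_tree(markers, n_reps = 0)
    tr16 <- neighbor_joining(suppressWarnings(jc_distance_matrix(full_aln)))
    scmg <- list(tree = ref_tree,
                 jrf_ani = jrf_distance(den, ref_tree, k = jrf_k),
                 jrf_16s = jrf_distance(tr16, ref_tree, k = jrf_k))
  }

  res <- structure(list(
    raw = row, z = zrow, best_region = best,
    ani = aset, groups = groups, dendrogram = den,
    entropy = prof, subsample = sub, scmg = scmg,
    drops = ex$drops), class = "genus_benchmark_result")
  if (!is.null(out_dir)) write_benchmark_result(res, out_dir)
  res
}

#' Write a genus benchmark result as TSV/newick artifacts
#'
#' @param res a `genus_benchmark_result`.
#' @param out_dir output directory (created if needed).
#' @export
write_benchmark_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  raw <- res$raw
  write_tsv(data.frame(source = names(raw), jrf = unname(round(raw, 10)),
                       z = unname(round(res$z, 10))),
            file.path(out_dir, "benchmark_raw.tsv"))
  write_tsv(data.frame(best_region = res$best_region),
            file.path(out_dir, "best_regions.tsv"))
  ani <- res$ani$ani
  ids <- rownames(ani)
  pairs <- which(upper.tri(ani), arr.ind = TRUE)
  write_tsv(data.frame(a = ids[pairs[, 1]], b = ids[pairs[, 2]],
                       ani = round(ani[pairs], 6),
                       frags = vapply(seq_len(nrow(pairs)), function(r)
                         length(res$ani$fragments[[paste(ids[pairs[r, 1]],
                                                         ids[pairs[r, 2]],
                                                         sep = "|")]]),
                         integer(1))),
            file.path(out_dir, "ani.tsv"))
  write_tsv(data.frame(genome_id = names(res$groups$groups),
                       group = unname(res$groups$groups)),
            file.path(out_dir, "ani_groups.tsv"))
  write_newick(res$dendrogram, file.path(out_dir, "ani_dendrogram.nwk"))
  write_tsv(entropy_table(res$entropy), file.path(out_dir, "entropy.tsv"))
  if (!is.null(res$subsample)) {
    write_tsv(data.frame(replicate = seq_along(res$subsample$replicate_jrf),
                         jrf = round(res$subsample$replicate_jrf, 10),
                         full_set_jrf = round(res$subsample$full_set_jrf, 10),
                         n_ani_groups = res$subsample$n_ani_groups),
              file.path(out_dir, "subsample.tsv"))
  }
  stats <- data.frame(
    metric = c("n_genomes", "n_ani_groups", "best_region", "jrf_full_16s",
               if (!is.null(res$scmg)) c("jrf_ani_vs_scmg", "jrf_16s_vs_scmg")),
    value = c(length(res$groups$groups), res$groups$n_groups,
              res$best_region, round(res$raw[["16S full"]], 10),
              if (!is.null(res$scmg)) c(round(res$scmg$jrf_ani, 10),
                                        round(res$scmg$jrf_16s, 10))))
  write_tsv(stats, file.path(out_dir, "stats.tsv"))
  if (nrow(res$drops))
    write_tsv(res$drops, file.path(out_dir, "drops.tsv"))
  invisible(out_dir)
}
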