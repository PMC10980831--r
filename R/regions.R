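# In-silico PCR: degenerate-primer matching and variable-region amplicon
# extraction. Coordinates are 0-based half-open internally; extracted
# regions are the amplicon interior (primer footprints excluded), because
# primer-binding bases are conserved by construction and would depress
# entropy estimates.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# 17 x 17 logical: do two IUPAC codes share at least one concrete base?
.iupac_compat <- local({
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (a in codes) for (b in codes)
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0
  m
})

#' Reverse complement of an IUPAC DNA string
#' @param x DNA string (IUPAC codes allowed).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Define a primer pair
#'
#' @param region_label label of the amplified region (e.g. `"V1-V3"`).
#' @param forward forward primer, 5'->3' on the plus strand (IUPAC codes).
#' @param reverse reverse primer, 5'->3' on the minus strand.
#' @param max_mismatch maximum mismatches tolerated per primer (none are
#'   allowed in the 3'-terminal 5 bases, mimicking the polymerase-extension
#'   requirement).
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(region_label, forward, reverse, max_mismatch = 2) {
  for (p in c(forward, reverse)) {
    if (!nzchar(p)) rb_invalid("empty primer sequence")
    if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), p))
      rb_invalid(sprintf("primer contains non-IUPAC characters: %s", p))
  }
  structure(list(region_label = region_label, forward = toupper(forward),
                 reverse = toupper(reverse), max_mismatch = max_mismatch),
            class = "primer_pair")
}

#' The default primer panel
#'
#' Standard published primer pairs for the six amplicon windows V1-V3,
#' V3-V4, V4, V4-V5, V6-V8 and V6-V9 (27F/534R, 341F/805R, 515F/806R,
#' 515F/926R, 926F/1392R, 926F/1492R). The panel is fully configurable via
#' TSV ([read_panel()]); these defaults are conventional choices for the
#' named windows, not a claim about any particular study's supplementary
#' panel.
#'
#' @param max_mismatch mismatch tolerance applied to every pair.
#' @return List of [primer_pair()] objects, in canonical panel order.
#' @export
default_primer_panel <- function(max_mismatch = 2) {
  list(
    primer_pair("V1-V3", "AGAGTTTGATCMTGGCTCAG", "ATTACCGCGGCTGCTGG", max_mismatch),
    primer_pair("V3-V4", "CCTACGGGNGGCWGCAG", "GACTACHVGGGTATCTAATCC", max_mismatch),
    primer_pair("V4",    "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT", max_mismatch),
    primer_pair("V4-V5", "GTGYCAGCMGCCGCGGTAA", "CCGYCAATTYMTTTRAGTTT", max_mismatch),
    primer_pair("V6-V8", "AAACTYAAAKGAATTGRCGG", "ACGGGCGGTGTGTRC", max_mismatch),
    primer_pair("V6-V9", "AAACTYAAAKGAATTGRCGG", "TACGGYTACCTTGTTACGACTT", max_mismatch))
}

#' Canonical panel order of the six variable-region labels
#' @export
REGION_ORDER <- c("V1-V3", "V3-V4", "V4", "V4-V5", "V6-V8", "V6-V9")

#' Locate a primer on a sequence
#'
#' Scans the plus strand of `seq` for IUPAC-compatible occurrences of the
#' primer. For `strand = "-"` the primer is reverse-complemented first, so
#' reported positions are the plus-strand coordinates of the binding site.
#' A hit needs at most `max_mismatch` mismatches overall and zero
#' mismatches in the primer's 3'-terminal 5 bases.
#'
#' @param seq DNA string to scan.
#' @param primer IUPAC primer, 5'->3' on its own strand.
#' @param max_mismatch allowed mismatches outside the 3' window.
#' @param strand `"+"` or `"-"`.
#' @return `data.frame(position, mismatches)` with 0-based positions,
#'   sorted by position.
#' @export
match_primer <- function(seq, primer, max_mismatch = 2, strand = "+") {
  if (!nzchar(primer)) rb_invalid("empty primer")
  if (!nzchar(seq)) rb_invalid("empty sequence")
  strand <- match.arg(strand, c("+", "-"))
  site <- if (strand == "+") primer else revcomp(primer)
  L <- nchar(site)
  if (L >= nchar(seq))
    return(data.frame(position = integer(0), mismatches = integer(0)))
  sv <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  pv <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  n_win <- length(sv) - L + 1
  mm <- integer(n_win)
  mm3 <- integer(n_win)
  # primer 3'-terminal 5 bases: last 5 of the site on "+", first 5 on "-"
  idx3 <- if (strand == "+") seq(L - min(5, L) + 1, L) else seq_len(min(5, L))
  for (i in seq_len(L)) {
    row <- .iupac_compat[pv[i], ]
    ok <- row[sv[i:(i + n_win - 1)]]   # NA for non-IUPAC characters
    ok[is.na(ok)] <- FALSE
    mm <- mm + !ok
    if (i %in% idx3) mm3 <- mm3 + !ok
  }
  pos <- which(mm <= max_mismatch & mm3 == 0)
  data.frame(position = pos - 1L, mismatches = mm[pos])
}

#' Extract one variable-region amplicon
#'
#' Uses the leftmost forward-primer hit and the rightmost reverse-primer
#' hit to its right; the extracted region is the interval strictly between
#' the two primer footprints. Amplicon interiors must be 50-1200 bases.
#'
#' @param seq 16S sequence (string).
#' @param pair a [primer_pair()].
#' @param genome_id identifier carried into the result and error messages.
#' @return A `region_hit`: list with `genome_id`, `region_label`, `start`,
#'   `end` (0-based half-open on `seq`), `sequence`, `fwd_mismatches`,
#'   `rev_mismatches`.
#' @export
extract_region <- function(seq, pair, genome_id = "seq") {
  stopifnot(inherits(pair, "primer_pair"))
  fhits <- match_primer(seq, pair$forward, pair$max_mismatch, "+")
  if (nrow(fhits) == 0)
    rb_stop(sprintf("no forward primer site for %s in %s",
                    pair$region_label, genome_id),
            class = "rb_no_amplicon",
            region_label = pair$region_label, genome_id = genome_id)
  rhits <- match_primer(seq, pair$reverse, pair$max_mismatch, "-")
  f <- fhits$position[1]
  fp_end <- f + nchar(pair$forward)
  rhits <- rhits[rhits$position >= fp_end, , drop = FALSE]
  if (nrow(rhits) == 0)
    rb_stop(sprintf("no reverse primer site for %s in %s",
                    pair$region_label, genome_id),
            class = "rb_no_amplicon",
            region_label = pair$region_label, genome_id = genome_id)
  r <- rhits$position[nrow(rhits)]
  len <- r - fp_end
  if (len < 50 || len > 1200)
    rb_stop(sprintf("amplicon length %d outside [50, 1200] for %s in %s",
                    len, pair$region_label, genome_id),
            class = "rb_amplicon_length",
            region_label = pair$region_label, genome_id = genome_id)
  structure(list(genome_id = genome_id, region_label = pair$region_label,
                 start = fp_end, end = r,
                 sequence = substr(seq, fp_end + 1, r),
                 fwd_mismatches = fhits$mismatches[1],
                 rev_mismatches = rhits$mismatches[nrow(rhits)]),
            class = "region_hit")
}

#' Select one 16S copy per genome
#'
#' Returns the longest copy; ties are broken by the lexicographically
#' smallest copy identifier.
#'
#' @param copies named character vector of 16S copies for one genome.
#' @return A single named sequence.
#' @export
choose_copy <- function(copies) {
  if (length(copies) == 0) rb_invalid("no 16S copies supplied")
  ord <- order(-nchar(copies), names(copies))
  copies[ord[1]]
}

#' Extract a primer panel across genomes
#'
#' @param ssu named character vector of 16S sequences (one per genome).
#' @param panel list of [primer_pair()] objects.
#' @return List with `hits` (per region, a named list of `region_hit`s) and
#'   `drops` (`data.frame(genome_id, region_label, reason)`). A genome
#'   dropped in one region is still reported in the others.
#' @export
extract_panel <- function(ssu, panel = default_primer_panel()) {
  hits <- list()
  drops <- data.frame(genome_id = character(0), region_label = character(0),
                      reason = character(0))
  for (pair in panel) {
    rh <- list()
    for (gid in names(ssu)) {
      h <- tryCatch(extract_region(ssu[[gid]], pair, gid),
                    rb_no_amplicon = function(e) e,
                    rb_amplicon_length = function(e) e)
      if (inherits(h, "region_hit")) {
        rh[[gid]] <- h
      } else {
        drops <- rbind(drops, data.frame(
          genome_id = gid, region_label = pair$region_label,
          reason = conditionMessage(h)))
      }
    }
    hits[[pair$region_label]] <- rh
  }
  list(hits = hits, drops = drops)
}

#' Region hits as alignment-ready sequence sets
#'
#' @param panel_hits output of [extract_panel()].
#' @return Named list (per region) of named character vectors of amplicon
#'   sequences.
#' @export
region_sequences <- function(panel_hits) {
  lapply(panel_hits$hits, function(rh)
    vapply(rh, `[[`, character(1), "sequence"))
}
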