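# FASTA / newick / TSV readers and writers. Sequence identifiers are the
# first whitespace-delimited token of each FASTA header; coordinates in all
# human-readable tables are 1-based inclusive (0-based half-open internally).

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Read a FASTA file
#'
#' @param path path to a (plain-text) FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first token of each header line.
#' @details Duplicate identifiers and non-IUPAC characters are errors (the
#'   offending position is named). Lowercase input is uppercased with a
#'   message.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rb_data_error(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) rb_data_error(sprintf("no sequences in %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    rb_data_error(sprintf("duplicate sequence id in %s: %s", path,
                          ids[duplicated(ids)][1]))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    message("read_fasta: lowercase characters uppercased")
    seqs <- toupper(seqs)
  }
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    rb_data_error(sprintf("non-IUPAC character in %s, sequence %s, position %d",
                          path, ids[i], bad[i]))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70) {
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a newick tree
#'
#' Supports branch lengths and internal-node (support) labels. Unbalanced
#' parentheses and duplicate leaf labels are reported with their position.
#'
#' @param path path to a newick file, or a newick string via `text`.
#' @param text optional newick string (used instead of `path`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) rb_data_error(sprintf("file not found: %s", path))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  depth <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                         ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (any(depth < 0))
    rb_data_error(sprintf("unbalanced ')' at offset %d", which(depth < 0)[1]))
  if (length(depth) && depth[length(depth)] != 0)
    rb_data_error(sprintf("unbalanced '(' (depth %d at end of input)",
                          depth[length(depth)]))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) rb_data_error(
                   sprintf("newick parse error: %s", conditionMessage(e))))
  if (is.null(tr)) rb_data_error("newick parse error: empty tree")
  if (anyDuplicated(tr$tip.label))
    rb_data_error(sprintf("duplicate leaf label: %s",
                          tr$tip.label[duplicated(tr$tip.label)][1]))
  tr
}

#' Write a tree to newick
#'
#' @param tree a `phylo` object.
#' @param path output path (omit to return the string).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Read a primer panel TSV
#'
#' Columns: `region_label`, `forward`, `reverse`, `max_mismatch`.
#'
#' @param path TSV path.
#' @return A list of [primer_pair()] objects.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) rb_data_error(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("region_label", "forward", "reverse", "max_mismatch")
  if (!all(need %in% names(df)))
    rb_data_error(sprintf("panel TSV must have columns: %s",
                          paste(need, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$region_label[i], df$forward[i], df$reverse[i],
                df$max_mismatch[i]))
}

#' Write a primer panel to TSV
#' @param panel list of [primer_pair()] objects.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(
    region_label = vapply(panel, `[[`, character(1), "region_label"),
    forward = vapply(panel, `[[`, character(1), "forward"),
    reverse = vapply(panel, `[[`, character(1), "reverse"),
    max_mismatch = vapply(panel, `[[`, numeric(1), "max_mismatch"))
  write_tsv(df, path)
}

# deterministic TSV writer: tab-separated, header, no quoting, "." decimal
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
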