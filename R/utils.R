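# Internal helpers: classed error conditions, seed scoping, alignment class.

rb_stop <- function(msg, class = "rb_error", ...) {
  stop(structure(
    class = c(class, "rb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

rb_invalid <- function(msg, ...) rb_stop(msg, class = "rb_invalid_argument", ...)
rb_data_error <- function(msg, ...) rb_stop(msg, class = "rb_data_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Construct a DNA alignment
#'
#' An alignment is a named character vector of equal-length strings over
#' the IUPAC DNA alphabet plus `-` (gap). Names are the sequence labels and
#' must be unique. Ungapped, equal-length sequence sets (e.g. simulator
#' output) are valid alignments as-is.
#'
#' @param x named character vector of equal-length sequences.
#' @return An object of class `dna_alignment`.
#' @export
dna_alignment <- function(x) {
  if (!is.character(x) || length(x) == 0)
    rb_invalid("alignment must be a non-empty character vector")
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(names(x) == ""))
    rb_invalid("alignment sequences must have unique non-empty names")
  if (length(unique(nchar(x))) != 1)
    rb_invalid("alignment rows must all have the same length")
  structure(toupper(x), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment: %d sequences x %d columns>\n",
              length(x), nchar(x[[1]])))
  invisible(x)
}

# character matrix view (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

aln_ncol <- function(aln) nchar(aln[[1]])

matrix_to_aln <- function(m) {
  dna_alignment(setNames(apply(m, 1, paste0, collapse = ""), rownames(m)))
}

# subset alignment columns (1-based indices), keeping labels
aln_subset_cols <- function(aln, idx) {
  matrix_to_aln(aln_matrix(aln)[, idx, drop = FALSE])
}
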