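## Shared low-level helpers: alphabet handling, seeded evaluation, TSV IO.

#' Normalize a nucleotide string
#'
#' Uppercases, converts RNA U to DNA T and validates the alphabet
#' (`ACGTN`). All internal sequence handling is in DNA space.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector of normalized DNA sequences.
#' @keywords internal
normalize_nt <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector", call. = FALSE)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains non-ACGTUN characters (first offender: ",
         x[which(bad)[1]], ")", call. = FALSE)
  }
  if (any(!nzchar(x))) stop(what, " contains empty strings", call. = FALSE)
  x
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards so simulation helpers are
#' referentially transparent: the same config always yields byte-identical
#' output regardless of surrounding RNG use.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Random DNA sequence
#' @keywords internal
random_dna <- function(n_len) {
  paste(sample(c("A", "C", "G", "T"), n_len, replace = TRUE), collapse = "")
}

#' Read / write a TSV with a header row
#'
#' Thin wrappers fixing the dialect used by every pipeline artifact:
#' tab-separated, header, no quoting, no row names.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv()` returns a data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
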