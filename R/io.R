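## File-format plumbing: FASTA/FASTQ via Biostrings, a minimal GFF3 layer
## for mature-miRNA loci, and the JSON run configs.

#' Write sequences to FASTA / FASTQ
#'
#' FASTQ records get constant dummy qualities (`I`, Phred+33 Q40): the
#' simulator does not model base-calling error, and nothing downstream
#' consumes qualities.
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(seqs),
                                         function(w) strrep("I", w), ""))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read FASTA / FASTQ into a named character vector
#'
#' Sequences are normalized to the DNA alphabet (U becomes T); FASTQ
#' qualities are discarded.
#'
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(normalize_nt(as.character(s)), sub("\\s.*$", "", names(s)))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(normalize_nt(as.character(s)), sub("\\s.*$", "", names(s)))
}

#' Write mature-miRNA loci as GFF3
#'
#' One `miRNA` feature per locus; `Name` carries the mature miRNA name so
#' multi-locus miRNAs appear as repeated `Name`s with distinct `ID`s. Start
#' and end span the mature sequence; the 5' start is `start` on `+` and
#' `end` on `-`.
#'
#' @param annotations data.frame with columns `name`, `seqid`, `strand`,
#'   `five_prime_start`, `length`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mirna_gff3 <- function(annotations, path) {
  req <- c("name", "seqid", "strand", "five_prime_start", "length")
  stopifnot(all(req %in% names(annotations)))
  start <- ifelse(annotations$strand == "+",
                  annotations$five_prime_start,
                  annotations$five_prime_start - annotations$length + 1L)
  end <- start + annotations$length - 1L
  lines <- sprintf("%s\tmirecip\tmiRNA\t%d\t%d\t.\t%s\t.\tID=locus%d;Name=%s",
                   annotations$seqid, start, end, annotations$strand,
                   seq_len(nrow(annotations)), annotations$name)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read mature-miRNA loci from GFF3
#'
#' Inverse of [write_mirna_gff3()]: returns one row per locus with the
#' 5'-start already resolved per strand.
#'
#' @param path GFF3 file.
#' @return data.frame with `name`, `seqid`, `strand`, `five_prime_start`,
#'   `length`.
#' @export
read_mirna_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no feature lines in ", path, call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) {
    stop("malformed GFF3 line ", which(lengths(f) != 9L)[1], " in ", path,
         call. = FALSE)
  }
  f <- do.call(rbind, f)
  strand <- f[, 7]
  if (!all(strand %in% c("+", "-"))) stop("GFF3 strand must be + or -", call. = FALSE)
  start <- as.integer(f[, 4]); end <- as.integer(f[, 5])
  name <- sub("^.*Name=([^;]+).*$", "\\1", f[, 9])
  data.frame(name = name, seqid = f[, 1], strand = strand,
             five_prime_start = ifelse(strand == "+", start, end),
             length = end - start + 1L, stringsAsFactors = FALSE)
}

#' Read a JSON run configuration
#' @param path JSON file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
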