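## Small RNA-seq processing: 3'-adapter trimming, 15-27 nt length filter,
## exact alignment, the +/-5 nt 5'-window counting rule with multi-locus
## collapsing and equal apportionment, RPM, presence filter and QC gates.

#' Adapter specification for 3'-adapter trimming
#'
#' @param adapter adapter sequence (RNA or DNA alphabet; stored as DNA).
#' @param min_overlap minimum read/adapter overlap (bases) for a suffix
#'   match to be trimmed. Default 7.
#' @param max_error_rate maximum fraction of mismatching bases within the
#'   overlap. Default 0 (error-free synthetic reads); set 0.1 to mimic the
#'   usual trimmer default on real data.
#' @return an `adapter_spec` object.
#' @export
adapter_spec <- function(adapter, min_overlap = 7L, max_error_rate = 0) {
  adapter <- normalize_nt(adapter, "adapter")
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L || nchar(adapter) < min_overlap) {
    stop("need length(adapter) >= min_overlap >= 1", call. = FALSE)
  }
  if (max_error_rate < 0 || max_error_rate >= 1) {
    stop("max_error_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(adapter = adapter, min_overlap = min_overlap,
                 max_error_rate = max_error_rate),
            class = "adapter_spec")
}

#' Trim the 3' adapter from reads
#'
#' For each read, the earliest position where the remainder of the read
#' matches a prefix of the adapter is found and everything from that
#' position onward is removed. A full internal adapter occurrence
#' therefore removes the adapter and all trailing bases; a partial match
#' at the read end must cover at least `min_overlap` adapter bases.
#' Mismatches up to `max_error_rate` of the overlap are tolerated. Reads
#' with no qualifying match are returned unchanged; a read that is pure
#' adapter trims to the empty string.
#'
#' @param reads character vector of read sequences (names preserved).
#' @param spec an [adapter_spec()].
#' @return character vector of trimmed reads.
#' @export
trim_3p_adapter <- function(reads, spec) {
  stopifnot(inherits(spec, "adapter_spec"))
  reads <- normalize_nt(reads, "read")
  ad <- strsplit(spec$adapter, "")[[1]]
  alen <- length(ad)
  out <- vapply(seq_along(reads), function(i) {
    r <- strsplit(reads[i], "")[[1]]
    L <- length(r)
    for (pos in seq_len(L)) {
      o <- min(alen, L - pos + 1L)
      if (o < alen && o < spec$min_overlap) break
      mism <- sum(r[pos:(pos + o - 1L)] != ad[seq_len(o)])
      if (mism <= floor(spec$max_error_rate * o)) {
        return(substr(reads[i], 1L, pos - 1L))
      }
    }
    reads[i]
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(reads)
  out
}

#' Length-filter trimmed reads
#'
#' Retains reads whose insert length is within `[min_len, max_len]`
#' inclusive (default 15-27 nt, the small-RNA window that captures mature
#' miRNAs while excluding adapter dimers and longer RNA fragments).
#'
#' @param reads character vector of trimmed reads.
#' @param min_len,max_len inclusive bounds.
#' @return the retained subset, names preserved.
#' @export
length_filter <- function(reads, min_len = 15L, max_len = 27L) {
  reads[nchar(reads) >= min_len & nchar(reads) <= max_len]
}

#' Exact alignment of reads to a reference
#'
#' Reports every full-length, zero-mismatch occurrence of each read on
#' both strands of the reference sequences (U treated as T). The reported
#' position is the genomic coordinate of the read's 5' end: the leftmost
#' matched base on `+`, the rightmost on `-` (1-based).
#'
#' @param reads named character vector of read sequences.
#' @param reference a `mirna_reference` (its `$genome` is used) or a named
#'   character vector / `DNAStringSet` of reference sequences.
#' @return data.frame with columns `read_id`, `seqid`, `strand`,
#'   `five_prime`; zero rows when nothing aligns.
#' @export
align_exact <- function(reads, reference) {
  genome <- if (inherits(reference, "mirna_reference")) reference$genome else reference
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  genome <- normalize_nt(genome, "reference")
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- normalize_nt(reads, "read")

  ## search unique sequences once, then fan hits back out to read ids
  useq <- unique(unname(reads))
  hit1 <- function(s) {
    rows <- list()
    rc <- revcomp(s)
    for (chr in names(genome)) {
      fwd <- gregexpr(s, genome[[chr]], fixed = TRUE)[[1]]
      if (fwd[1] != -1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = chr, strand = "+", five_prime = as.integer(fwd),
          stringsAsFactors = FALSE)
      }
      rev <- gregexpr(rc, genome[[chr]], fixed = TRUE)[[1]]
      if (rev[1] != -1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = chr, strand = "-",
          five_prime = as.integer(rev) + nchar(s) - 1L,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  hits_by_seq <- lapply(useq, hit1)
  names(hits_by_seq) <- useq

  out <- lapply(seq_along(reads), function(i) {
    h <- hits_by_seq[[reads[[i]]]]
    if (is.null(h)) return(NULL)
    cbind(read_id = names(reads)[i], h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(read_id = character(), seqid = character(),
                      strand = character(), five_prime = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assign aligned reads to mature miRNAs (+/- window rule)
#'
#' A genomic hit is attributed to a mature miRNA when it lies on the same
#' reference sequence and strand and its 5' end falls within `window`
#' nucleotides (inclusive) of the annotated mature 5'-start. Per read,
#' multiple hits to loci of the *same* miRNA collapse to a single count;
#' a read attributed to `k` distinct miRNAs contributes `1/k` to each.
#' Reads with genomic hits but no miRNA within the window are mappable
#' but unassigned.
#'
#' @param hits data.frame from [align_exact()].
#' @param annotations data.frame with `name`, `seqid`, `strand`,
#'   `five_prime_start` (one row per locus), e.g. from
#'   [read_mirna_gff3()] or `make_mirna_reference()$annotations`.
#' @param window inclusive 5'-offset window, default 5.
#' @return an `assignment_result`: list with `counts` (named numeric,
#'   fractional counts per miRNA), `n_assigned_reads`,
#'   `n_mappable_reads`, and `audit` (per-read data.frame of matched
#'   miRNAs and fractions).
#' @export
assign_counts <- function(hits, annotations, window = 5L) {
  window <- as.integer(window)
  if (is.na(window) || window < 0L) stop("window must be >= 0", call. = FALSE)
  if (!nrow(annotations)) stop("annotations must be nonempty", call. = FALSE)
  counts <- setNames(numeric(length(unique(annotations$name))),
                     unique(annotations$name))
  mappable <- unique(hits$read_id)
  audit <- list()
  if (nrow(hits)) {
    ann_key <- paste(annotations$seqid, annotations$strand)
    for (rid in mappable) {
      h <- hits[hits$read_id == rid, , drop = FALSE]
      matched <- character()
      for (j in seq_len(nrow(h))) {
        sel <- ann_key == paste(h$seqid[j], h$strand[j]) &
          abs(annotations$five_prime_start - h$five_prime[j]) <= window
        matched <- c(matched, annotations$name[sel])
      }
      matched <- unique(matched)   # multi-locus collapsing
      k <- length(matched)
      if (k > 0L) {
        counts[matched] <- counts[matched] + 1 / k
        audit[[rid]] <- data.frame(read_id = rid, mirna = matched,
                                   fraction = 1 / k, stringsAsFactors = FALSE)
      }
    }
  }
  audit <- if (length(audit)) do.call(rbind, c(audit, make.row.names = FALSE))
           else data.frame(read_id = character(), mirna = character(),
                           fraction = numeric(), stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 n_assigned_reads = length(unique(audit$read_id)),
                 n_mappable_reads = length(mappable),
                 audit = audit),
            class = "assignment_result")
}

#' Feature x sample count table
#'
#' Light container coupling a (possibly fractional) count matrix with the
#' per-sample mappable-read totals used as the RPM denominator and by the
#' QC gates.
#'
#' @param counts numeric matrix, features x samples, with dimnames.
#' @param library_sizes per-sample mappable-read totals; defaults to
#'   column sums.
#' @param kind `"miRNA"` or `"mRNA"` (selects QC-gate threshold).
#' @return a `count_table` object.
#' @export
count_table <- function(counts, library_sizes = colSums(counts),
                        kind = c("miRNA", "mRNA")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts needs column names", call. = FALSE)
  if (is.null(rownames(counts))) stop("counts needs row names", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  library_sizes <- setNames(as.numeric(library_sizes), colnames(counts))
  structure(list(counts = counts, library_sizes = library_sizes, kind = kind),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s: %d features x %d samples\n",
              x$kind, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Reads-per-million normalization
#'
#' `RPM(f, s) = count(f, s) / library_size(s) * 1e6`, with the library
#' size taken from the table's per-sample mappable-read totals.
#'
#' @param table a [count_table()].
#' @return numeric matrix of RPM values.
#' @export
compute_rpm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (any(table$library_sizes <= 0)) {
    stop("library sizes must be positive for RPM", call. = FALSE)
  }
  sweep(table$counts, 2, table$library_sizes, "/") * 1e6
}

#' Presence filter: nonzero in at least half of each group
#'
#' A feature is retained only if, within every treatment group of the
#' design, it is nonzero (RPM > 0 for miRNA, TPM > 0 for mRNA) in at
#' least `ceiling(n_group / 2)` replicates. Equivalently, features that
#' are zero in more than half of any group's samples are omitted.
#'
#' @param table a [count_table()].
#' @param design data.frame with columns `sample`, `group`.
#' @param mode `"miRNA-RPM"` filters on RPM computed from the table;
#'   `"mRNA-TPM"` treats the table values as TPM and filters directly.
#' @return the filtered [count_table()].
#' @export
presence_filter <- function(table, design, mode = c("miRNA-RPM", "mRNA-TPM")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "count_table"))
  if (!all(colnames(table$counts) %in% design$sample)) {
    stop("design lacks labels for some samples", call. = FALSE)
  }
  grp <- design$group[match(colnames(table$counts), design$sample)]
  if (anyNA(grp)) stop("unknown group label in design", call. = FALSE)
  vals <- if (mode == "miRNA-RPM") compute_rpm(table) else table$counts
  keep <- rep(TRUE, nrow(vals))
  for (g in unique(grp)) {
    cols <- grp == g
    need <- ceiling(sum(cols) / 2)
    keep <- keep & rowSums(vals[, cols, drop = FALSE] > 0) >= need
  }
  count_table(table$counts[keep, , drop = FALSE], table$library_sizes,
              table$kind)
}

#' Library-size QC gate
#'
#' Drops samples whose mappable-read total does not exceed the per-assay
#' threshold: strictly more than 1e6 mappable reads for miRNA libraries,
#' strictly more than 3e7 for mRNA libraries. Dropped samples are
#' reported via `message()`. When a design is supplied and a group loses
#' all of its samples the comparison is impossible and this is an error.
#'
#' @param table a [count_table()].
#' @param design optional data.frame (`sample`, `group`).
#' @return the gated [count_table()].
#' @export
library_qc_gate <- function(table, design = NULL) {
  stopifnot(inherits(table, "count_table"))
  thr <- if (table$kind == "miRNA") 1e6 else 3e7
  keep <- table$library_sizes > thr
  if (any(!keep)) {
    message("library_qc_gate: dropping ", sum(!keep), " ", table$kind,
            " sample(s) at threshold >", format(thr, scientific = FALSE),
            ": ", paste(names(keep)[!keep], collapse = ", "))
  }
  if (!is.null(design)) {
    grp <- design$group[match(colnames(table$counts), design$sample)]
    lost <- tapply(keep, grp, function(z) !any(z))
    if (any(lost)) {
      stop("library_qc_gate: all samples of group(s) ",
           paste(names(lost)[lost], collapse = ", "),
           " fail the mappable-read gate; comparison impossible",
           call. = FALSE)
    }
  }
  count_table(table$counts[, keep, drop = FALSE], table$library_sizes[keep],
              table$kind)
}

#' Quantify small-RNA reads end to end
#'
#' Convenience wrapper chaining [trim_3p_adapter()], [length_filter()],
#' [align_exact()] and [assign_counts()] for a single library.
#'
#' @param reads named character vector of raw reads.
#' @param reference a `mirna_reference` (or list with `$genome` and
#'   `$annotations`).
#' @param spec an [adapter_spec()].
#' @param window counting window, default 5.
#' @param min_len,max_len length-filter bounds.
#' @return the `assignment_result` for the library.
#' @export
quantify_library <- function(reads, reference, spec, window = 5L,
                             min_len = 15L, max_len = 27L) {
  trimmed <- trim_3p_adapter(reads, spec)
  kept <- length_filter(trimmed, min_len, max_len)
  hits <- align_exact(kept, reference)
  assign_counts(hits, reference$annotations, window)
}
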