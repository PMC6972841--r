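## Seed-site scanning of 3'-UTRs and the reciprocal-expression
## miRNA-mRNA integration producing table-style pair outputs.

seed_site_span <- function(type) ifelse(type == "8mer", 8L, 7L)

#' Scan 3'-UTRs for canonical miRNA seed sites
#'
#' For each miRNA the three canonical site sequences are derived from the
#' seed region (miRNA nucleotides 2-7/2-8, Watson-Crick only, no G:U
#' wobble), written 5'->3' on the target strand:
#'
#' * `8mer`: reverse complement of nt 2-8 followed by an `A` opposite
#'   miRNA position 1 (8 nt);
#' * `7mer-m8`: reverse complement of nt 2-8 (7 nt);
#' * `7mer-A1`: reverse complement of nt 2-7 plus the `A1` adenosine
#'   (7 nt).
#'
#' The `A1` requirement is an `A` in the target regardless of miRNA
#' nucleotide 1. Candidates of a lower-precedence type that overlap a
#' higher-precedence candidate of the same miRNA are suppressed
#' (precedence `8mer > 7mer-m8 > 7mer-A1`), so each locus reports only
#' its best classification. Positions are 1-based inclusive on the UTR.
#' UTRs shorter than 7 nt yield no sites. 6mer-class sites are not
#' reported.
#'
#' @param mirnas named character vector of mature sequences (5'->3', RNA
#'   or DNA alphabet), each >= 8 nt.
#' @param utrs named character vector of 3'-UTR sequences.
#' @return data.frame with columns `mirna`, `utr`, `type`, `start`,
#'   `end`, sorted by utr, miRNA, position.
#' @export
scan_seed_sites <- function(mirnas, utrs) {
  mirnas <- normalize_nt(mirnas, "miRNA")
  utrs <- normalize_nt(utrs, "UTR")
  if (any(nchar(mirnas) < 8L)) stop("mature miRNAs must be >= 8 nt", call. = FALSE)
  if (is.null(names(mirnas)) || is.null(names(utrs))) {
    stop("mirnas and utrs must be named", call. = FALSE)
  }
  empty <- data.frame(mirna = character(), utr = character(),
                      type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out <- list()
  for (u in names(utrs)) {
    useq <- utrs[[u]]
    if (nchar(useq) < 7L) next
    for (m in names(mirnas)) {
      seed8 <- revcomp(substr(mirnas[[m]], 2L, 8L))
      sites <- rbind(
        find_sites(useq, paste0(seed8, "A"), "8mer"),
        find_sites(useq, seed8, "7mer-m8"),
        find_sites(useq, paste0(substr(seed8, 2L, 7L), "A"), "7mer-A1"))
      if (!nrow(sites)) next
      prec <- match(sites$type, c("8mer", "7mer-m8", "7mer-A1"))
      keep <- vapply(seq_len(nrow(sites)), function(i) {
        higher <- prec < prec[i]
        !any(higher & sites$start <= sites$end[i] & sites$end >= sites$start[i])
      }, logical(1))
      sites <- sites[keep, , drop = FALSE]
      if (nrow(sites)) {
        out[[length(out) + 1L]] <- cbind(mirna = m, utr = u, sites,
                                         stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)[, c("mirna", "utr", "type", "start", "end")]
  res <- res[order(res$utr, res$mirna, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## all fixed-string matches of `pat` in `x`, allowing overlaps
find_sites <- function(x, pat, type) {
  pos <- integer(); from <- 1L
  repeat {
    hit <- regexpr(pat, substr(x, from, nchar(x)), fixed = TRUE)
    if (hit == -1L) break
    pos <- c(pos, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  data.frame(type = rep(type, length(pos)), start = pos,
             end = pos + nchar(pat) - 1L, stringsAsFactors = FALSE)
}

#' Integrate inversely expressed miRNA-mRNA pairs through seed sites
#'
#' Emits one row per (mRNA, miRNA, site) triple in which the mRNA is
#' called differentially expressed (FDR < `fdr_max` and linear FC >
#' `mrna_fc_min` or < `1/mrna_fc_min`), the miRNA is called (FDR <
#' `fdr_max`), the two move in opposite directions, and the miRNA has a
#' seed site in the mRNA's 3'-UTR. With `conserved_only = TRUE`, sites
#' (and miRNAs, via their `conserved` flag if present in `de_mirna`)
#' must be annotated conserved. Rows are ordered like the published
#' tables: up-regulated mRNAs by descending FC, then down-regulated by
#' ascending FC, then miRNA FC, miRNA name, and site position.
#'
#' @param de_mrna data.frame with `feature`, `fc`, `fdr` (and optionally
#'   `direction`; derived from `fc` otherwise).
#' @param de_mirna same layout for miRNAs; optional `conserved` logical.
#' @param sites data.frame with `mirna`, `utr` (mRNA feature id), `type`,
#'   `start`, `end`, and optionally `conserved`.
#' @param conserved_only restrict to conserved sites/miRNAs.
#' @param fdr_max,mrna_fc_min thresholds (defaults 0.01 and 2).
#' @return a `reciprocal_pairs` data.frame with columns `mrna`,
#'   `mrna_fc`, `mrna_fdr`, `mirna`, `mirna_fc`, `mirna_fdr`,
#'   `seed_type`, `start`, `end`.
#' @export
integrate_reciprocal <- function(de_mrna, de_mirna, sites,
                                 conserved_only = FALSE,
                                 fdr_max = 0.01, mrna_fc_min = 2) {
  for (d in list(de_mrna, de_mirna)) {
    stopifnot(all(c("feature", "fc", "fdr") %in% names(d)))
  }
  stopifnot(all(c("mirna", "utr", "type", "start", "end") %in% names(sites)))
  if (nrow(sites)) {
    bad_m <- setdiff(sites$utr, de_mrna$feature)
    bad_i <- setdiff(sites$mirna, de_mirna$feature)
    if (length(bad_m) || length(bad_i)) {
      stop("sites reference unknown feature(s): ",
           paste(c(bad_m, bad_i), collapse = ", "), call. = FALSE)
    }
  }
  mr <- de_mrna[de_mrna$fdr < fdr_max &
                  (de_mrna$fc > mrna_fc_min | de_mrna$fc < 1 / mrna_fc_min), ,
                drop = FALSE]
  mi <- de_mirna[de_mirna$fdr < fdr_max, , drop = FALSE]
  if (conserved_only && "conserved" %in% names(mi)) {
    mi <- mi[mi$conserved, , drop = FALSE]
  }
  st <- sites
  if (conserved_only && "conserved" %in% names(st)) {
    st <- st[st$conserved, , drop = FALSE]
  }
  out <- merge(merge(st, mr, by.x = "utr", by.y = "feature"),
               mi, by.x = "mirna", by.y = "feature",
               suffixes = c("_mrna", "_mirna"))
  cols <- data.frame(mrna = character(), mrna_fc = numeric(),
                     mrna_fdr = numeric(), mirna = character(),
                     mirna_fc = numeric(), mirna_fdr = numeric(),
                     seed_type = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  if (nrow(out)) {
    opposite <- (out$fc_mrna > 1) != (out$fc_mirna > 1)
    out <- out[opposite & out$fc_mrna != 1 & out$fc_mirna != 1, , drop = FALSE]
  }
  if (nrow(out)) {
    cols <- data.frame(mrna = out$utr, mrna_fc = out$fc_mrna,
                       mrna_fdr = out$fdr_mrna, mirna = out$mirna,
                       mirna_fc = out$fc_mirna, mirna_fdr = out$fdr_mirna,
                       seed_type = out$type, start = out$start,
                       end = out$end, stringsAsFactors = FALSE)
    up <- cols$mrna_fc > 1
    ord <- order(!up,
                 ifelse(up, -cols$mrna_fc, cols$mrna_fc),
                 cols$mrna,
                 cols$mirna_fc, cols$mirna, cols$start)
    cols <- cols[ord, , drop = FALSE]
    rownames(cols) <- NULL
  }
  class(cols) <- c("reciprocal_pairs", class(cols))
  cols
}

#' Summarize a reciprocal-pair table
#'
#' @param pairs output of [integrate_reciprocal()].
#' @return list with `n_mrnas`, `n_mirnas`, `n_rows` (distinct counts).
#' @export
summarize_pairs <- function(pairs) {
  list(n_mrnas = length(unique(pairs$mrna)),
       n_mirnas = length(unique(pairs$mirna)),
       n_rows = nrow(pairs))
}

#' Split a printed pair table into integration inputs
#'
#' Decomposes a [load_printed_table()] fixture into the three inputs of
#' [integrate_reciprocal()] (per-feature DE records and the site list),
#' allowing the integration logic to be re-run against the published
#' rows.
#'
#' @param tab a `printed_pair_table`.
#' @return list with `de_mrna`, `de_mirna`, `sites`.
#' @export
printed_table_to_inputs <- function(tab) {
  stopifnot(inherits(tab, "printed_pair_table"))
  de_mrna <- unique(data.frame(feature = tab$mrna, fc = tab$mrna_fc,
                               fdr = tab$mrna_fdr, stringsAsFactors = FALSE))
  de_mirna <- unique(data.frame(feature = tab$mirna, fc = tab$mirna_fc,
                                fdr = tab$mirna_fdr, conserved = TRUE,
                                stringsAsFactors = FALSE))
  if (anyDuplicated(de_mrna$feature) || anyDuplicated(de_mirna$feature)) {
    stop("printed table carries inconsistent FC/FDR for a feature",
         call. = FALSE)
  }
  sites <- data.frame(mirna = tab$mirna, utr = tab$mrna,
                      type = tab$seed_type, start = tab$start, end = tab$end,
                      conserved = TRUE, stringsAsFactors = FALSE)
  list(de_mrna = de_mrna, de_mirna = de_mirna, sites = sites)
}
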