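# Independent oracles and shared simulation fixtures. Oracles are written
# against the definitions, not against the implementation: the seed-site
# oracle classifies every window by direct character comparison, and the
# alignment oracle is a naive position-by-position substring scan.

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# brute-force seed-site scan for one miRNA against one UTR
oracle_scan_one <- function(mirna, utr) {
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]]
  u <- strsplit(chartr("Uu", "Tt", toupper(utr)), "")[[1]]
  L <- length(u)
  # target 5'->3' pairing of miRNA nt 8..2 is the complement in reverse order
  pair_ok <- function(pos, mir_nts) {
    # window starting at pos pairs target base i with miRNA nt rev(mir_nts)[i]
    k <- length(mir_nts)
    if (pos < 1 || pos + k - 1 > L) return(FALSE)
    all(u[pos:(pos + k - 1)] == comp_base[m[rev(mir_nts)]])
  }
  rows <- list()
  for (pos in seq_len(L)) {
    if (pair_ok(pos, 2:8) && pos + 7 <= L && u[pos + 7] == "A") {
      rows[[length(rows) + 1]] <- data.frame(type = "8mer", start = pos,
                                             end = pos + 7)
    } else if (pair_ok(pos, 2:8)) {
      rows[[length(rows) + 1]] <- data.frame(type = "7mer-m8", start = pos,
                                             end = pos + 6)
    } else if (pair_ok(pos, 2:7) && pos + 6 <= L && u[pos + 6] == "A") {
      rows[[length(rows) + 1]] <- data.frame(type = "7mer-A1", start = pos,
                                             end = pos + 6)
    }
  }
  if (!length(rows)) {
    return(data.frame(type = character(), start = integer(), end = integer()))
  }
  cand <- do.call(rbind, rows)
  prec <- match(cand$type, c("8mer", "7mer-m8", "7mer-A1"))
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    higher <- prec < prec[i]
    !any(higher & cand$start <= cand$end[i] & cand$end >= cand$start[i])
  }, logical(1))
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# naive exact aligner: scan every offset on both strands
oracle_align_one <- function(read, genome_seq) {
  read <- chartr("Uu", "Tt", toupper(read))
  g <- toupper(genome_seq)
  n <- nchar(read); L <- nchar(g)
  rc <- paste(rev(comp_base[strsplit(read, "")[[1]]]), collapse = "")
  hits <- list()
  for (pos in seq_len(L - n + 1)) {
    win <- substr(g, pos, pos + n - 1)
    if (win == read) hits[[length(hits) + 1]] <- c(strand = "+", fp = pos)
    if (win == rc) hits[[length(hits) + 1]] <- c(strand = "-", fp = pos + n - 1)
  }
  if (!length(hits)) {
    return(data.frame(strand = character(), five_prime = integer()))
  }
  h <- do.call(rbind, hits)
  data.frame(strand = h[, "strand"], five_prime = as.integer(h[, "fp"]),
             stringsAsFactors = FALSE)
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# 2,000 null-feature p-values under the stated world (n = 5/group,
# mean 200, dispersion 0.05); computed once and reused by the uniformity
# example and the type-I acceptance criterion.
null_pvals_2000 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(seed = 2025, n_genes = 2000,
                             n_samples_per_group = 5,
                             groups = c("TA", "NAWD"), k_unwanted = 0,
                             nb_dispersion = 0.05)
    sim <- simulate_count_matrix(cfg, kind = "mRNA", baseline_log_sd = 0)
    res <- nb_wald_test(sim$table, sim$design, contrast = c("NAWD", "TA"))
    cache <<- res$p
    cache
  }
})
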