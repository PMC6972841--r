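## Synthetic-data generators: a toy mature-miRNA reference with a
## multi-locus miRNA and a paralog pair, small-RNA reads with 5'-end
## heterogeneity plus adapter, NB count matrices with planted fold
## changes and latent unwanted factors, and 3'-UTRs with planted seed
## sites. Every generator records ground truth for recovery tests.

default_offset_probs <- function() {
  ## 5'-end heterogeneity concentrated at the annotated start, symmetric,
  ## with 2% of reads starting outside the +/-5 counting window
  p <- c(0.005, 0.010, 0.020, 0.040, 0.080, 0.670,
         0.080, 0.040, 0.020, 0.010, 0.005)
  names(p) <- as.character(-5:5)
  c(p, out = 0.02)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic world in one validated object.
#' Defaults mirror the design the pipeline assumes: 4-5 replicates per
#' group, negative-binomial counts with moderate brain-tissue dispersion,
#' three latent unwanted factors, small-RNA reads with 5'-end
#' heterogeneity mostly inside the +/-5 nt counting window, and the
#' standard Illumina small-RNA 3' adapter.
#'
#' @param seed integer RNG seed (mandatory).
#' @param n_mirnas number of mature miRNAs in the toy reference.
#' @param n_genes number of features in simulated count matrices.
#' @param n_samples_per_group replicates per treatment group (>= 2).
#' @param groups treatment group labels; the first is the reference.
#' @param adapter 3' sequencing adapter (>= 7 nt).
#' @param read_5p_offset_probs probability over 5' offsets `-5..5` plus an
#'   `out` component for starts beyond the window; must sum to 1.
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param effect_fold_changes named numeric of planted linear fold changes
#'   (feature -> FC, treatment vs reference).
#' @param k_unwanted number of latent unwanted-variation factors.
#' @param factor_loadings_scale SD of per-feature factor loadings on the
#'   log scale.
#' @param decoy_fraction fraction of reads drawn as unmappable decoys.
#' @param read_length sequencer read length for simulated small-RNA reads.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(seed,
                              n_mirnas = 20L,
                              n_genes = 500L,
                              n_samples_per_group = 5L,
                              groups = c("TA", "Nic", "NAWD"),
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              read_5p_offset_probs = default_offset_probs(),
                              nb_dispersion = 0.05,
                              effect_fold_changes = numeric(),
                              k_unwanted = 3L,
                              factor_loadings_scale = 0.25,
                              decoy_fraction = 0.05,
                              read_length = 36L) {
  if (missing(seed) || length(seed) != 1L || is.na(suppressWarnings(as.integer(seed)))) {
    stop("a single integer seed is required", call. = FALSE)
  }
  seed <- as.integer(seed)
  n_mirnas <- as.integer(n_mirnas); n_genes <- as.integer(n_genes)
  n_samples_per_group <- as.integer(n_samples_per_group)
  if (n_mirnas < 1L) stop("n_mirnas must be >= 1", call. = FALSE)
  if (n_samples_per_group < 2L) {
    stop("n_samples_per_group must be >= 2", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  p <- read_5p_offset_probs
  need <- c(as.character(-5:5), "out")
  if (!all(need %in% names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("read_5p_offset_probs must cover -5..5 plus 'out' and sum to 1",
         call. = FALSE)
  }
  if (any(effect_fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (k_unwanted < 0L) stop("k_unwanted must be >= 0", call. = FALSE)
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    stop("decoy_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(seed = seed, n_mirnas = n_mirnas, n_genes = n_genes,
                 n_samples_per_group = n_samples_per_group, groups = groups,
                 adapter = normalize_nt(adapter, "adapter"),
                 read_5p_offset_probs = p[need],
                 nb_dispersion = nb_dispersion,
                 effect_fold_changes = effect_fold_changes,
                 k_unwanted = as.integer(k_unwanted),
                 factor_loadings_scale = factor_loadings_scale,
                 decoy_fraction = decoy_fraction,
                 read_length = as.integer(read_length)),
            class = "simulation_config")
}

#' Generate a toy mature-miRNA reference
#'
#' Builds `n_mirnas` mature sequences (19-23 nt) embedded in a synthetic
#' chromosome with random spacers. The construction guarantees the two
#' situations the counting rule must handle: miRNA 1 is annotated at two
#' genomic loci with identical sequence, and (for `n_mirnas >= 3`)
#' miRNAs 2 and 3 are paralogs sharing an identical >= 16 nt 5' stretch,
#' so short reads can hit both. The last miRNA is placed on the minus
#' strand to exercise the strand-aware 5'-end convention.
#'
#' @param config a [simulation_config()].
#' @return a `mirna_reference`: list with `mature` (named character),
#'   `annotations` (data.frame: `name`, `seqid`, `strand`,
#'   `five_prime_start`, `length`), and `genome` (named character).
#' @export
make_mirna_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_mirnas
    lens <- sample(19:23, n, replace = TRUE)
    mat <- vapply(lens, random_dna, character(1))
    if (n >= 3L) {
      ## paralogs: identical except the final 3 nt
      lens[3L] <- lens[2L]
      tail3 <- random_dna(3L)
      while (tail3 == substr(mat[2L], lens[2L] - 2L, lens[2L])) {
        tail3 <- random_dna(3L)
      }
      mat[3L] <- paste0(substr(mat[2L], 1L, lens[2L] - 3L), tail3)
    }
    ## reject accidental duplicates / containment among distinct matures
    for (i in seq_len(n)) {
      repeat {
        clash <- any(vapply(seq_len(n)[-i], function(j) {
          grepl(mat[i], mat[j], fixed = TRUE) || grepl(mat[j], mat[i], fixed = TRUE)
        }, logical(1)))
        if (!clash || (n >= 3L && i %in% 2:3)) break
        mat[i] <- random_dna(lens[i])
      }
    }
    names(mat) <- sprintf("syn-miR-%d", seq_len(n))

    ## lay out loci: miRNA 1 twice, last miRNA on the minus strand
    pieces <- character(); ann <- list(); pos <- 1L
    add_locus <- function(name, seq, strand) {
      spacer <- random_dna(sample(40:60, 1L))
      pieces[[length(pieces) + 1L]] <<- spacer
      pos <<- pos + nchar(spacer)
      embedded <- if (strand == "+") seq else revcomp(seq)
      pieces[[length(pieces) + 1L]] <<- embedded
      fp <- if (strand == "+") pos else pos + nchar(seq) - 1L
      ann[[length(ann) + 1L]] <<- data.frame(
        name = name, seqid = "chrS1", strand = strand,
        five_prime_start = fp, length = nchar(seq), stringsAsFactors = FALSE)
      pos <<- pos + nchar(seq)
    }
    for (i in seq_len(n)) {
      strand <- if (i == n && n > 1L) "-" else "+"
      add_locus(names(mat)[i], mat[[i]], strand)
      if (i == 1L) add_locus(names(mat)[1L], mat[[1L]], "+")
    }
    pieces[[length(pieces) + 1L]] <- random_dna(50L)
    genome <- c(chrS1 = paste(pieces, collapse = ""))
    structure(list(mature = mat,
                   annotations = do.call(rbind, ann),
                   genome = genome),
              class = "mirna_reference")
  })
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("<mirna_reference> %d mature miRNAs, %d loci, genome %d nt\n",
              length(x$mature), nrow(x$annotations), nchar(x$genome[[1]])))
  invisible(x)
}

#' Simulate small-RNA reads with 5'-end heterogeneity
#'
#' Non-decoy reads are genomic windows anchored at a mature locus and
#' shifted by a 5' offset drawn from the configured distribution (the
#' `out` mass draws offsets of 6-10 nt beyond the counting window, on a
#' random side). The 3' adapter is appended and the read padded with
#' random bases to the configured read length. Decoy reads are random
#' 15-27-mers rejected against the genome (both strands), so they are
#' unmappable by construction.
#'
#' @param config a [simulation_config()]; `nchar(adapter)` must be >= 7 so
#'   trimming can satisfy its minimum overlap.
#' @param reference a `mirna_reference` from [make_mirna_reference()].
#' @param n_reads number of reads to simulate.
#' @return list with `reads` (named character) and `truth` (data.frame:
#'   `read_id`, `source`, `offset`, `is_decoy`).
#' @export
simulate_small_rna_reads <- function(config, reference, n_reads = 10000L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(reference, "mirna_reference"))
  if (nchar(config$adapter) < 7L) {
    stop("adapter must be >= 7 nt to satisfy the trimming overlap",
         call. = FALSE)
  }
  if (!length(reference$mature)) stop("reference is empty", call. = FALSE)
  with_seed(config$seed + 1L, {
    n_reads <- as.integer(n_reads)
    genome <- reference$genome[[1]]
    glen <- nchar(genome)
    ann <- reference$annotations
    is_decoy <- runif(n_reads) < config$decoy_fraction
    p <- config$read_5p_offset_probs
    choices <- names(p)

    reads <- character(n_reads); src <- rep(NA_character_, n_reads)
    off <- rep(NA_integer_, n_reads)
    for (i in seq_len(n_reads)) {
      if (is_decoy[i]) {
        repeat {
          s <- random_dna(sample(15:27, 1L))
          if (!grepl(s, genome, fixed = TRUE) &&
              !grepl(revcomp(s), genome, fixed = TRUE)) break
        }
        insert <- s
      } else {
        a <- ann[sample(nrow(ann), 1L), ]
        d <- sample(choices, 1L, prob = p)
        d <- if (d == "out") sample(6:10, 1L) * sample(c(-1L, 1L), 1L)
             else as.integer(d)
        L <- a$length
        if (a$strand == "+") {
          s0 <- a$five_prime_start + d
          if (s0 < 1L || s0 + L - 1L > glen) { d <- 0L; s0 <- a$five_prime_start }
          insert <- substr(genome, s0, s0 + L - 1L)
        } else {
          e0 <- a$five_prime_start - d
          if (e0 > glen || e0 - L + 1L < 1L) { d <- 0L; e0 <- a$five_prime_start }
          insert <- revcomp(substr(genome, e0 - L + 1L, e0))
        }
        src[i] <- a$name; off[i] <- d
      }
      full <- paste0(insert, config$adapter)
      if (nchar(full) < config$read_length) {
        full <- paste0(full, random_dna(config$read_length - nchar(full)))
      }
      reads[i] <- substr(full, 1L, config$read_length)
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, source = src, offset = off,
                            is_decoy = is_decoy, stringsAsFactors = FALSE))
  })
}

#' Simulate an NB count matrix with planted effects and latent factors
#'
#' Counts are drawn as
#' `NB(mu = baseline * FC(group) * exp(loadings . scores) * size_factor,
#' dispersion = alpha)` with per-feature lognormal baselines, planted
#' fold changes applied to `effect_group` samples, `k_unwanted` latent
#' factors with N(0, scale) loadings and unit-variance scores, and
#' lognormal library size factors. The full truth (fold changes, factor
#' scores and loadings, size factors, baselines) is returned for
#' recovery tests.
#'
#' @param config a [simulation_config()].
#' @param kind `"miRNA"` or `"mRNA"` (table metadata only).
#' @param groups which groups to simulate; default first and last of
#'   `config$groups`.
#' @param effect_group group receiving the planted fold changes; default
#'   the last of `groups`.
#' @param baseline_log_mean,baseline_log_sd lognormal baseline
#'   parameters (defaults give a median of ~200 counts).
#' @return list with `table` (a [count_table()]), `design` (data.frame
#'   `sample`, `group`) and `truth`.
#' @export
simulate_count_matrix <- function(config, kind = c("miRNA", "mRNA"),
                                  groups = config$groups[c(1, length(config$groups))],
                                  effect_group = groups[length(groups)],
                                  baseline_log_mean = log(200),
                                  baseline_log_sd = 1) {
  stopifnot(inherits(config, "simulation_config"))
  kind <- match.arg(kind)
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (baseline_log_sd < 0) stop("baseline_log_sd must be >= 0", call. = FALSE)
  with_seed(config$seed + 2L, {
    nf <- config$n_genes
    ns <- config$n_samples_per_group * length(groups)
    feat <- sprintf("feat%04d", seq_len(nf))
    grp <- rep(groups, each = config$n_samples_per_group)
    samp <- paste0(grp, "_", sequence(rep(config$n_samples_per_group,
                                          length(groups))))
    baseline <- rlnorm(nf, baseline_log_mean, baseline_log_sd)
    if (baseline_log_sd == 0 && baseline_log_mean <= -Inf) {
      stop("non-positive baseline", call. = FALSE)
    }
    fc <- setNames(rep(1, nf), feat)
    pf <- config$effect_fold_changes
    if (length(pf)) {
      unknown <- setdiff(names(pf), feat)
      if (length(unknown)) stop("planted FC for unknown feature(s): ",
                                paste(unknown, collapse = ", "), call. = FALSE)
      fc[names(pf)] <- pf
    }
    k <- config$k_unwanted
    loadings <- matrix(rnorm(nf * k, 0, config$factor_loadings_scale), nf, k)
    scores <- matrix(rnorm(ns * k), ns, k)
    if (k > 0L) scores <- scale(scores)  # unit variance per factor
    sf <- rlnorm(ns, 0, 0.2)
    lmu <- log(baseline) %o% rep(1, ns) +
      log(fc) %o% as.numeric(grp == effect_group)
    if (k > 0L) lmu <- lmu + loadings %*% t(scores)
    lmu <- sweep(lmu, 2, log(sf), "+")
    counts <- matrix(rnbinom(nf * ns, mu = exp(lmu),
                             size = 1 / config$nb_dispersion), nf, ns,
                     dimnames = list(feat, samp))
    list(table = count_table(counts, kind = kind),
         design = data.frame(sample = samp, group = grp,
                             stringsAsFactors = FALSE),
         truth = list(fold_changes = fc, effect_group = effect_group,
                      factor_scores = scores, factor_loadings = loadings,
                      size_factors = setNames(sf, samp),
                      baseline = setNames(baseline, feat)))
  })
}

#' Plant seed sites into synthetic 3'-UTRs
#'
#' Background sequence is rejection-sampled so that it contains no seed
#' match (8mer, 7mer-m8 or 7mer-A1) for any planned miRNA; planned sites
#' are then written at their exact 1-based positions and the result is
#' re-verified with the scanner, locally re-randomizing any junction
#' artifact. The scanner therefore must report exactly the returned
#' truth list.
#'
#' @param utr_lengths named integer vector (UTR id -> length).
#' @param plan data.frame with columns `mirna`, `utr`, `type`
#'   (`8mer`/`7mer-m8`/`7mer-A1`) and `start` (1-based).
#' @param mirnas named character vector of mature miRNA sequences
#'   (5'->3', RNA or DNA alphabet) covering every planned miRNA.
#' @param seed integer seed for the background sampling.
#' @return list with `utrs` (named character) and `truth` (data.frame
#'   `mirna`, `utr`, `type`, `start`, `end`).
#' @export
plant_mre_sites <- function(utr_lengths, plan, mirnas, seed = 1L) {
  mirnas <- normalize_nt(mirnas, "miRNA")
  if (nrow(plan)) {
    stopifnot(all(c("mirna", "utr", "type", "start") %in% names(plan)),
              all(plan$mirna %in% names(mirnas)),
              all(plan$utr %in% names(utr_lengths)),
              all(plan$type %in% c("8mer", "7mer-m8", "7mer-A1")))
  }
  span <- function(type) ifelse(type == "8mer", 8L, 7L)
  plan$end <- if (nrow(plan)) plan$start + span(plan$type) - 1L else integer()
  if (nrow(plan) && any(plan$start < 1L | plan$end > utr_lengths[plan$utr])) {
    stop("planned site does not fit inside its UTR", call. = FALSE)
  }
  ## same-miRNA overlap within a UTR is a planning error
  if (nrow(plan) > 1L) {
    for (key in unique(paste(plan$mirna, plan$utr))) {
      p <- plan[paste(plan$mirna, plan$utr) == key, , drop = FALSE]
      if (nrow(p) > 1L) {
        p <- p[order(p$start), ]
        if (any(p$start[-1L] <= p$end[-nrow(p)])) {
          stop("overlapping planned sites for ", key, call. = FALSE)
        }
      }
    }
  }
  site_seq <- function(mirna, type) {
    m <- mirnas[[mirna]]
    switch(type,
           "8mer"    = paste0(revcomp(substr(m, 2L, 8L)), "A"),
           "7mer-m8" = revcomp(substr(m, 2L, 8L)),
           "7mer-A1" = paste0(revcomp(substr(m, 2L, 7L)), "A"))
  }
  with_seed(seed, {
    utrs <- setNames(vector("character", length(utr_lengths)),
                     names(utr_lengths))
    for (u in names(utr_lengths)) {
      L <- utr_lengths[[u]]
      x <- strsplit(random_dna(L), "")[[1]]
      planted <- plan[plan$utr == u, , drop = FALSE]
      protected <- unlist(lapply(seq_len(nrow(planted)), function(j) {
        seq(planted$start[j], planted$end[j])
      }))
      write_planned <- function(x) {
        for (j in seq_len(nrow(planted))) {
          s <- strsplit(site_seq(planted$mirna[j], planted$type[j]), "")[[1]]
          x[seq(planted$start[j], planted$end[j])] <- s
        }
        x
      }
      for (iter in 1:1000) {
        x <- write_planned(x)
        found <- scan_seed_sites(mirnas, setNames(paste(x, collapse = ""), u))
        extras <- found
        if (nrow(planted)) {
          key_t <- paste(planted$mirna, planted$type, planted$start)
          key_f <- paste(found$mirna, found$type, found$start)
          extras <- found[!key_f %in% key_t, , drop = FALSE]
          if (nrow(found[key_f %in% key_t, , drop = FALSE]) < nrow(planted) &&
              iter == 1000) break
        }
        if (!nrow(extras)) break
        for (j in seq_len(nrow(extras))) {
          idx <- setdiff(seq(extras$start[j], extras$end[j]), protected)
          if (!length(idx)) {
            stop("conflicting overlapping sites for different miRNAs in ",
                 u, call. = FALSE)
          }
          x[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
        }
      }
      seq_final <- paste(x, collapse = "")
      found <- scan_seed_sites(mirnas, setNames(seq_final, u))
      if (nrow(found) != nrow(planted) ||
          (nrow(planted) && !setequal(paste(found$mirna, found$type, found$start),
                                      paste(planted$mirna, planted$type, planted$start)))) {
        stop("could not realize the planned sites in ", u, call. = FALSE)
      }
      utrs[[u]] <- seq_final
    }
    truth <- plan[, c("mirna", "utr", "type", "start", "end"), drop = FALSE]
    rownames(truth) <- NULL
    list(utrs = utrs, truth = truth)
  })
}

#' Load a printed miRNA-mRNA pair table fixture
#'
#' Reads a TSV transcription of a published reciprocal-pair table (one
#' row per predicted MRE) and validates every row: known seed type, span
#' of 8 nt for 8mer sites and 7 nt otherwise, positive fold changes,
#' FDR < 0.01 on both sides, and the mRNA fold-change rule (> 2 or
#' < 0.5). Malformed rows are reported with their line number.
#'
#' @param path TSV with columns `mrna`, `mrna_fc`, `mrna_fdr`, `mirna`,
#'   `mirna_fc`, `mirna_fdr`, `seed_type`, `start`, `end`.
#' @param region label attached to the table (e.g. `"IPN"`, `"MHb"`).
#' @return a `printed_pair_table` (data.frame with a `region` attribute).
#' @export
load_printed_table <- function(path, region = c("IPN", "MHb")) {
  region <- match.arg(region)
  if (!file.exists(path)) stop("fixture not found: ", path, call. = FALSE)
  tab <- tryCatch(read_tsv(path), error = function(e) {
    stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  req <- c("mrna", "mrna_fc", "mrna_fdr", "mirna", "mirna_fc", "mirna_fdr",
           "seed_type", "start", "end")
  if (!nrow(tab) || !all(req %in% names(tab))) {
    stop("fixture ", path, " is empty or lacks required columns",
         call. = FALSE)
  }
  fail <- function(i, why) {
    stop("fixture ", path, " line ", i + 1L, ": ", why, call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$seed_type %in% c("8mer", "7mer-m8", "7mer-A1")) {
      fail(i, paste("unknown seed type", r$seed_type))
    }
    want <- if (r$seed_type == "8mer") 8L else 7L
    if (is.na(r$start) || is.na(r$end) || r$end - r$start + 1L != want) {
      fail(i, "site span inconsistent with seed type")
    }
    if (anyNA(c(r$mrna_fc, r$mirna_fc, r$mrna_fdr, r$mirna_fdr)) ||
        r$mrna_fc <= 0 || r$mirna_fc <= 0) fail(i, "non-positive fold change")
    if (r$mrna_fdr >= 0.01 || r$mirna_fdr >= 0.01) fail(i, "FDR >= 0.01")
    if (r$mrna_fc <= 2 && r$mrna_fc >= 0.5) fail(i, "mRNA FC inside (0.5, 2)")
  }
  attr(tab, "region") <- region
  class(tab) <- c("printed_pair_table", class(tab))
  tab
}

#' Path to a packaged printed-table fixture
#' @param region `"IPN"` or `"MHb"`.
#' @return file path inside the installed package.
#' @export
printed_table_path <- function(region = c("IPN", "MHb")) {
  region <- match.arg(region)
  f <- if (region == "IPN") "table1_ipn_pairs.tsv" else "table2_mhb_pairs.tsv"
  system.file("extdata", f, package = "mirecip", mustWork = TRUE)
}
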