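adapter <- "TGGAATTCTCGGGTGCCAAGG"
spec7 <- adapter_spec(adapter, min_overlap = 7)

test_that("adapter trimming follows the overlap-7 rule", {
  insert <- "ACGTACGTACGTACGTACGT"              # 20 nt
  expect_identical(trim_3p_adapter(paste0(insert, substr(adapter, 1, 10)),
                                   spec7),
                   insert)
  # 6-base suffix overlap fails the 7-bp minimum: read unchanged
  read6 <- paste0(insert, substr(adapter, 1, 6))
  expect_identical(trim_3p_adapter(read6, spec7), read6)
  # 7-base suffix overlap is trimmed
  expect_identical(trim_3p_adapter(paste0(insert, substr(adapter, 1, 7)),
                                   spec7),
                   insert)
  # pure adapter trims to empty
  expect_identical(trim_3p_adapter(adapter, spec7), "")
  # full internal occurrence removes everything from the match onward
  expect_identical(trim_3p_adapter(paste0(insert, adapter, "GGGGGTTTTT"),
                                   spec7),
                   insert)
  # no qualifying match leaves the read alone
  expect_identical(trim_3p_adapter(insert, spec7), insert)
})

test_that("trimming is idempotent and tolerates configured mismatches", {
  set.seed(4)
  reads <- vapply(1:50, function(i) {
    paste0(mirecip:::random_dna(sample(15:25, 1)),
           substr(adapter, 1, sample(0:21, 1)))
  }, character(1))
  once <- trim_3p_adapter(reads, spec7)
  expect_identical(trim_3p_adapter(once[nzchar(once)], spec7),
                   once[nzchar(once)])
  # one mismatch in a 10-base overlap passes at max_error_rate = 0.1
  lax <- adapter_spec(adapter, 7, max_error_rate = 0.1)
  ad10 <- substr(adapter, 1, 10)
  substr(ad10, 5, 5) <- if (substr(ad10, 5, 5) == "A") "C" else "A"
  expect_identical(trim_3p_adapter(paste0("ACGTACGTACGTACGT", ad10), lax),
                   "ACGTACGTACGTACGT")
  expect_identical(trim_3p_adapter(paste0("ACGTACGTACGTACGT", ad10), spec7),
                   paste0("ACGTACGTACGTACGT", ad10))
})

test_that("adapter_spec validates", {
  expect_error(adapter_spec("ACGT", 7), "min_overlap")
  expect_error(adapter_spec(adapter, 0), "min_overlap")
  expect_error(adapter_spec(adapter, 7, 1.2), "error_rate")
})

test_that("length filter keeps exactly 15-27 nt", {
  reads <- setNames(vapply(c(14, 15, 20, 27, 28), function(n) strrep("A", n),
                           character(1)),
                    paste0("r", c(14, 15, 20, 27, 28)))
  expect_identical(names(length_filter(reads)), c("r15", "r20", "r27"))
  expect_length(length_filter(character()), 0)
})

test_that("align_exact equals the brute-force substring oracle", {
  set.seed(11)
  genome <- c(chrA = mirecip:::random_dna(800),
              chrB = mirecip:::random_dna(400))
  # embed a read twice on chrA (one copy reverse-complemented)
  probe <- mirecip:::random_dna(20)
  substr(genome[["chrA"]], 101, 120) <- probe
  substr(genome[["chrA"]], 301, 320) <- mirecip:::revcomp(probe)
  reads <- c(p = probe,
             u = substr(genome[["chrB"]], 51, 70),
             d = strrep("ACGT", 5))
  hits <- align_exact(reads, genome)
  for (nm in names(reads)) {
    got <- hits[hits$read_id == nm, c("seqid", "strand", "five_prime")]
    exp <- do.call(rbind, lapply(names(genome), function(chr) {
      o <- oracle_align_one(reads[[nm]], genome[[chr]])
      if (nrow(o)) cbind(seqid = chr, o) else NULL
    }))
    if (is.null(exp)) {
      expect_identical(nrow(got), 0L)
    } else {
      key <- function(d) paste(d$seqid, d$strand, d$five_prime)
      expect_setequal(key(got), key(exp))
    }
  }
  expect_true(all(hits$read_id != "d"))   # decoy: 0 hits
})

test_that("U is treated as T in reads", {
  genome <- c(chr = "ACGGTTCAGATTGCCATGCAAGGT")
  hit <- align_exact(c(r1 = "UUCAGAUUGCCA"), genome)
  expect_identical(hit$five_prime, 5L)
  expect_identical(hit$strand, "+")
})

make_window_fixture <- function() {
  # one annotated miRNA on each strand of a known genome
  list(ann = data.frame(name = c("mirP", "mirM"),
                        seqid = "chr", strand = c("+", "-"),
                        five_prime_start = c(100L, 300L),
                        length = c(20L, 20L), stringsAsFactors = FALSE))
}

test_that("window rule is inclusive at +/-5 and excludes +/-6", {
  ann <- make_window_fixture()$ann
  hit_at <- function(fp, strand = "+") {
    data.frame(read_id = "r1", seqid = "chr", strand = strand,
               five_prime = fp, stringsAsFactors = FALSE)
  }
  expect_equal(assign_counts(hit_at(95L), ann)$counts[["mirP"]], 1)
  expect_equal(assign_counts(hit_at(105L), ann)$counts[["mirP"]], 1)
  r <- assign_counts(hit_at(106L), ann)
  expect_equal(unname(r$counts), c(0, 0))
  expect_identical(r$n_mappable_reads, 1L)   # mappable but unassigned
  expect_identical(r$n_assigned_reads, 0L)
  # minus strand: five_prime is the rightmost base
  expect_equal(assign_counts(hit_at(295L, "-"), ann)$counts[["mirM"]], 1)
  expect_equal(assign_counts(hit_at(305L, "-"), ann)$counts[["mirM"]], 1)
  expect_equal(assign_counts(hit_at(294L, "-"), ann)$counts[["mirM"]], 0)
  # wrong strand never matches
  expect_equal(assign_counts(hit_at(100L, "-"), ann)$counts[["mirP"]], 0)
  expect_error(assign_counts(hit_at(100L), ann, window = -1), "window")
})

test_that("multi-locus collapsing and apportionment", {
  ann <- data.frame(name = c("mirA", "mirA", "mirB"),
                    seqid = "chr", strand = "+",
                    five_prime_start = c(100L, 500L, 900L),
                    length = 20L, stringsAsFactors = FALSE)
  two_loci <- data.frame(read_id = "r1", seqid = "chr", strand = "+",
                         five_prime = c(100L, 500L), stringsAsFactors = FALSE)
  r <- assign_counts(two_loci, ann)
  expect_equal(r$counts[["mirA"]], 1)        # single count, not 2
  both <- data.frame(read_id = "r2", seqid = "chr", strand = "+",
                     five_prime = c(100L, 900L), stringsAsFactors = FALSE)
  r2 <- assign_counts(both, ann)
  expect_equal(unname(r2$counts[c("mirA", "mirB")]), c(0.5, 0.5))
  expect_equal(sum(r2$counts), r2$n_assigned_reads)
})

test_that("count conservation holds on arbitrary hit sets", {
  set.seed(99)
  ann <- data.frame(name = paste0("m", 1:6), seqid = "chr", strand = "+",
                    five_prime_start = as.integer(seq(50, 800, length.out = 6)),
                    length = 20L, stringsAsFactors = FALSE)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    hits <- data.frame(read_id = paste0("r", sample(1:15, n, TRUE)),
                       seqid = "chr", strand = "+",
                       five_prime = sample(1:850, n, TRUE),
                       stringsAsFactors = FALSE)
    r <- assign_counts(hits, ann)
    expect_equal(sum(r$counts), r$n_assigned_reads, tolerance = 1e-9)
    expect_true(all(r$audit$fraction > 0 & r$audit$fraction <= 1))
    # every read's fractions are 1/k for its k matched miRNAs
    ks <- table(r$audit$read_id)
    expect_true(all(abs(r$audit$fraction - 1 / ks[r$audit$read_id]) < 1e-12))
  }
})

test_that("RPM arithmetic and scale invariance", {
  m <- matrix(c(10, 0, 4, 6), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- count_table(m, library_sizes = c(2e6, 1e6), kind = "miRNA")
  rpm <- compute_rpm(tab)
  expect_equal(rpm["a", "s1"], 5)
  expect_equal(rpm["b", "s1"], 0)
  tab2 <- count_table(2 * m, library_sizes = c(4e6, 2e6), kind = "miRNA")
  expect_equal(compute_rpm(tab2), rpm)
  expect_error(compute_rpm(count_table(m, library_sizes = c(0, 1), kind = "miRNA")),
               "positive")
})

test_that("presence filter requires nonzero in at least half of each group", {
  counts <- rbind(omitted = c(0, 0, 0, 3, 1, 1, 1, 1),
                  kept    = c(1, 2, 0, 4, 1, 1, 0, 2),
                  allpos  = c(5, 5, 5, 5, 5, 5, 5, 5))
  colnames(counts) <- paste0("s", 1:8)
  design <- data.frame(sample = paste0("s", 1:8),
                       group = rep(c("TA", "NAWD"), each = 4))
  tab <- count_table(counts, library_sizes = rep(1e6, 8), kind = "miRNA")
  out <- presence_filter(tab, design, "miRNA-RPM")
  expect_setequal(rownames(out$counts), c("kept", "allpos"))
  expect_error(presence_filter(tab, design[1:4, ], "miRNA-RPM"), "labels")
})

test_that("library QC gates are strict inequalities at 1e6 / 3e7", {
  m <- matrix(1, 1, 3, dimnames = list("f", c("a", "b", "c")))
  mi <- count_table(m, library_sizes = c(1e6, 1e6 + 1, 5e6), kind = "miRNA")
  expect_message(out <- library_qc_gate(mi), "dropping 1")
  expect_setequal(colnames(out$counts), c("b", "c"))
  mr <- count_table(m, library_sizes = c(2e7, 3e7, 3.1e7), kind = "mRNA")
  expect_message(out2 <- library_qc_gate(mr), "dropping 2")
  expect_identical(colnames(out2$counts), "c")
  design <- data.frame(sample = c("a", "b", "c"),
                       group = c("TA", "TA", "NAWD"))
  low <- count_table(m, library_sizes = c(1e5, 2e5, 5e6), kind = "miRNA")
  expect_error(suppressMessages(library_qc_gate(low, design)), "gate")
})

test_that("fastq/fasta/gff3 round-trips preserve the quantifier inputs", {
  cfg <- simulation_config(seed = 13, n_mirnas = 5)
  ref <- make_mirna_reference(cfg)
  sim <- simulate_small_rna_reads(cfg, ref, n_reads = 40)
  fq <- withr::local_tempfile(fileext = ".fastq")
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fastq(sim$reads, fq)
  write_fasta(ref$genome, fa)
  write_mirna_gff3(ref$annotations, gff)
  expect_identical(read_fastq(fq), sim$reads)
  expect_identical(unname(read_fasta(fa)), unname(ref$genome))
  ann <- read_mirna_gff3(gff)
  expect_identical(ann[order(ann$five_prime_start), ]$five_prime_start,
                   ref$annotations[order(ref$annotations$five_prime_start), ]$five_prime_start)
  expect_setequal(ann$name, ref$annotations$name)
})
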