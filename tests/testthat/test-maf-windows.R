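# MAF parsing, window partitioning and the informative-site filter.

write_lines_maf <- function(lines) {
  p <- tempfile(fileext = ".maf")
  writeLines(lines, p)
  p
}

test_that("a minimal two-taxon MAF block parses", {
  p <- write_lines_maf(c(
    "##maf version=1",
    "a score=0",
    "s ref.chr1 0 8 + 100 ACGTACGT",
    "s other.chr9 5 7 + 50 ACG-ACGT"
  ))
  b <- read_maf(p)
  expect_length(b, 1)
  expect_identical(b[[1]]$taxa, c("ref", "other"))
  expect_identical(unname(nchar(b[[1]]$seqs)), c(8L, 8L))
  expect_equal(b[[1]]$start[["other"]], 5)
  expect_identical(b[[1]]$chrom[["other"]], "chr9")
})

test_that("out-of-order blocks are sorted with a warning", {
  p <- write_lines_maf(c(
    "a", "s ref.chr1 50 4 + 100 ACGT", "s x.c 0 4 + 10 ACGT",
    "a", "s ref.chr1 0 4 + 100 TTTT", "s x.c 4 4 + 10 GGGG"
  ))
  expect_warning(b <- read_maf(p), "out of.*order")
  expect_equal(vapply(b, function(x) x$start[["ref"]], numeric(1)), c(0, 50))
})

test_that("minus-strand rows are normalized into reference orientation", {
  p <- write_lines_maf(c(
    "a",
    "s ref.chr1 0 4 + 100 ACGG",
    "s neg.chr2 2 4 - 10 ACGG"
  ))
  b <- read_maf(p)
  expect_identical(b[[1]]$seqs[["neg"]], "CCGT") # reverse complement
  expect_equal(b[[1]]$start[["neg"]], 10 - 2 - 4)
  expect_identical(b[[1]]$strand[["neg"]], "-")
})

test_that("malformed MAF input is rejected", {
  ragged <- write_lines_maf(c(
    "a", "s ref.chr1 0 4 + 100 ACGT", "s x.c 0 6 + 10 ACGTAA"
  ))
  expect_error(read_maf(ragged), "ragged")
  dup <- write_lines_maf(c(
    "a", "s ref.chr1 0 4 + 100 ACGT", "s ref.chr1 4 4 + 100 ACGT"
  ))
  expect_error(read_maf(dup), "duplicate")
})

test_that("read -> write -> read round-trips the data model", {
  st <- gambiae_complex_tree()
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 6000, c2 = 3000),
                           window_size = 2000, missing_data_rate = 0.05,
                           seed = 8)
  sim <- simulate_maf(cfg)
  p1 <- tempfile(fileext = ".maf")
  write_maf(sim$blocks, p1)
  b1 <- read_maf(p1)
  p2 <- tempfile(fileext = ".maf")
  write_maf(b1, p2)
  b2 <- read_maf(p2)
  expect_identical(b1, b2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("windows tile the chromosome and split blocks at boundaries", {
  sc <- scan_config("fontenillei", "bwambae", "christyi",
                    window_size = 50000)
  # one 100 kb chromosome in a single spanning block
  seq_ref <- strrep("ACGT", 25000)
  blocks <- list(list(
    taxa = c("ref", "x"),
    chrom = c(ref = "chr1", x = "s1"),
    start = c(ref = 0, x = 0),
    size = c(ref = 100000, x = 100000),
    strand = c(ref = "+", x = "+"),
    srcSize = c(ref = 100000, x = 100000),
    seqs = c(ref = seq_ref, x = seq_ref)
  ))
  w <- partition_windows(blocks, sc)
  expect_length(w, 2)
  expect_equal(vapply(w, `[[`, numeric(1), "start"), c(0, 50000))
  expect_equal(vapply(w, `[[`, numeric(1), "end"), c(50000, 100000))
  # column counts conserved across the split
  expect_equal(sum(vapply(w, function(x) ncol(x$mat), numeric(1))), 100000)
  expect_identical(paste(w[[1]]$mat["ref", 1:4], collapse = ""), "ACGT")
})

test_that("per-column bookkeeping assigns every block column to one window", {
  # two discontiguous blocks, one spanning the window boundary, with
  # reference gaps (insertion columns) and a taxon missing from one block
  sc <- scan_config("f", "b", "o", window_size = 10)
  blocks <- list(
    list(taxa = c("ref", "a"),
         chrom = c(ref = "c", a = "s"), start = c(ref = 2, a = 0),
         size = c(ref = 6, a = 8), strand = c(ref = "+", a = "+"),
         srcSize = c(ref = 20, a = 50),
         seqs = c(ref = "AC--GTAC", a = "ACGGGTAC")),
    list(taxa = c("ref", "b"),
         chrom = c(ref = "c", b = "s2"), start = c(ref = 8, b = 0),
         size = c(ref = 6, b = 6), strand = c(ref = "+", b = "+"),
         srcSize = c(ref = 20, b = 30),
         seqs = c(ref = "AACCGG", b = "TTCCGG"))
  )
  w <- partition_windows(blocks, sc)
  expect_length(w, 2) # [0,10) and [10,20)
  total_cols <- sum(vapply(w, function(x) ncol(x$mat), numeric(1)))
  expect_equal(total_cols, 8 + 6)
  # brute-force per-column oracle: reference coordinate of each column
  coords1 <- c(2, 3, 3, 3, 4, 5, 6, 7) # gap columns inherit previous base
  coords2 <- 8:13
  expect_equal(ncol(w[[1]]$mat), sum(coords1 < 10) + sum(coords2 < 10))
  expect_equal(ncol(w[[2]]$mat), sum(coords1 >= 10) + sum(coords2 >= 10))
  # taxa missing from a block are gap-padded over its columns
  expect_true(all(w[[1]]$mat["b", 1:8] == "-"))
  expect_true(all(w[[2]]$mat["a", ] == "-"))
})

test_that("overlapping blocks on the reference are a data error", {
  sc <- scan_config("f", "b", "o", window_size = 10)
  blocks <- list(
    list(taxa = "ref", chrom = c(ref = "c"), start = c(ref = 0),
         size = c(ref = 6), strand = c(ref = "+"), srcSize = c(ref = 20),
         seqs = c(ref = "ACGTAC")),
    list(taxa = "ref", chrom = c(ref = "c"), start = c(ref = 4),
         size = c(ref = 6), strand = c(ref = "+"), srcSize = c(ref = 20),
         seqs = c(ref = "ACGTAC"))
  )
  expect_error(partition_windows(blocks, sc), "overlapping")
})

test_that("the informative-site filter is strict at the 10% boundary", {
  sc <- scan_config("f", "b", "o") # defaults: 50 kb, 10% -> 5,000
  make_window <- function(n_informative) {
    n <- 50000
    mat <- rbind(A = rep("A", n), B = rep("A", n))
    if (n_informative < n) {
      mat["B", (n_informative + 1):n] <- "-"
    }
    window_from_matrix(mat, start = 0, end = n)
  }
  w_4999 <- make_window(4999)
  w_5000 <- make_window(5000)
  expect_equal(w_4999$informative_count, 4999)
  out <- filter_windows(list(w_4999, w_5000), sc)
  expect_length(out$retained, 1)
  expect_equal(out$retained[[1]]$informative_count, 5000)
  expect_equal(out$log$retained, c(FALSE, TRUE))
  # all-gap window excluded
  gap <- window_from_matrix(rbind(A = rep("-", 100), B = rep("-", 100)))
  expect_length(filter_windows(list(gap), sc)$retained, 0)
  # partition into retained/excluded is exhaustive and disjoint
  expect_equal(length(out$retained) + length(out$excluded), 2)
})

test_that("informative columns are conserved from blocks to windows", {
  st <- gambiae_complex_tree()
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 9000),
                           window_size = 2000, missing_data_rate = 0.1,
                           seed = 21)
  sim <- simulate_maf(cfg)
  sc <- scan_config("fontenillei", "bwambae", "christyi",
                    window_size = 2000)
  w <- partition_windows(sim$blocks, sc)
  inf_blocks <- sum(vapply(sim$blocks, function(b) {
    mat <- do.call(rbind, lapply(b$seqs, function(s) strsplit(s, "")[[1]]))
    sum(colSums(matrix(mat %in% c("A", "C", "G", "T"),
                       nrow = nrow(mat))) == nrow(mat))
  }, numeric(1)))
  expect_equal(sum(vapply(w, `[[`, numeric(1), "informative_count")),
               inf_blocks)
  # tiling invariant: disjoint cover of [0, chrom length)
  expect_equal(vapply(w, `[[`, numeric(1), "start"),
               c(0, 2000, 4000, 6000, 8000))
  expect_equal(max(vapply(w, `[[`, numeric(1), "end")), 9000)
})

test_that("alignment statistics match brute-force column accounting", {
  mat <- rbind(
    A = c("A", "A", "-", "C", "G", "-", "T", "A", "C", "G"),
    B = c("A", "C", "-", "C", "G", "-", "T", "T", "C", "G"),
    C = c("A", "A", "-", "C", "N", "-", "T", "A", "C", "G")
  )
  st <- alignment_stats(window_from_matrix(mat))
  expect_equal(st$aligned_length, 10)
  expect_equal(st$length_determined, 8) # two all-gap columns removed
  expect_equal(st$gap_fraction, 6 / 30)
  # brute force distinct-pattern count over the retained columns
  keep <- apply(mat, 2, function(col) any(col %in% c("A", "C", "G", "T")))
  expect_equal(st$n_patterns,
               length(unique(apply(mat[, keep], 2, paste, collapse = ""))))
  # uniform window: one pattern, no gaps
  uni <- window_from_matrix(rbind(A = rep("A", 5), B = rep("A", 5)))
  stu <- alignment_stats(uni)
  expect_equal(stu$n_patterns, 1)
  expect_equal(stu$gap_fraction, 0)
})
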