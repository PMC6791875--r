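# Scaffold grafting: homology search, the unique-hit selection rule, and
# column-preserving insertion of a new taxon row.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("an exact copy of the region yields one full-coverage hit", {
  region <- random_dna(300, 1)
  scaffolds <- c(
    s1 = paste0(random_dna(100, 2), region, random_dna(80, 3)),
    s2 = random_dna(400, 4)
  )
  hits <- search_homologs(region, scaffolds)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$scaffold, "s1")
  expect_identical(hits$strand, "+")
  expect_equal(hits$coverage, 1)
  expect_equal(hits$s_start, 101)
  expect_equal(hits$s_end, 400)
  expect_lt(hits$evalue, 1e-50)
})

test_that("a reverse-complement homolog is found on the minus strand", {
  region <- random_dna(200, 11)
  rc <- phyloscan:::revcomp_chr(region)
  scaffolds <- c(s1 = paste0(random_dna(60, 12), rc, random_dna(60, 13)))
  hits <- search_homologs(region, scaffolds)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$strand, "-")
  expect_equal(hits$s_start, 61)
  expect_equal(hits$s_end, 260)
  expect_equal(hits$coverage, 1)
})

test_that("hit locations match a brute-force Smith-Waterman scan", {
  region <- random_dna(120, 21)
  # two degraded copies at known positions
  degrade <- function(s, rate, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    k <- sample(length(ch), round(rate * length(ch)))
    ch[k] <- vapply(ch[k], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  scaffolds <- c(
    s1 = paste0(random_dna(70, 22), degrade(region, 0.05, 23),
                random_dna(50, 24), degrade(region, 0.10, 25),
                random_dna(40, 26))
  )
  hits <- search_homologs(region, scaffolds)
  hits <- hits[order(hits$s_start), ]
  expect_equal(nrow(hits), 2)
  # quadratic oracle: full local alignment against the whole scaffold
  submat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
  oracle <- Biostrings::pairwiseAlignment(
    pattern = region, subject = scaffolds[["s1"]], type = "local",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2
  )
  sr <- as.data.frame(Biostrings::subject(oracle)@range)
  # the best in-repo hit coincides with the oracle's best local alignment
  best <- hits[which.max(hits$score), ]
  expect_equal(best$s_start, sr$start)
  expect_equal(best$s_end, sr$start + sr$width - 1)
  expect_equal(best$score, Biostrings::score(oracle))
})

test_that("the unique-hit rule reproduces the selection decision table", {
  hit <- function(ev, cov, sc = "s1") {
    data.frame(scaffold = sc, s_start = 1, s_end = 100, strand = "+",
               score = 50, evalue = ev, coverage = cov,
               q_start = 1, q_end = 100, stringsAsFactors = FALSE)
  }
  # single raw hit: selected whatever its quality
  single <- hit(1, 0.05)
  expect_identical(select_unique_hit(single)$decision, "single")
  # two hits, one failing coverage: the other is recovered
  two <- rbind(hit(1e-9, 0.9), hit(1e-9, 0.35, "s2"))
  sel <- select_unique_hit(two)
  expect_identical(sel$decision, "recovered")
  expect_identical(sel$hit$scaffold, "s1")
  # coverage boundary is inclusive: exactly 0.40 is excluded
  boundary <- rbind(hit(1e-9, 0.9), hit(1e-9, 0.40, "s2"))
  expect_identical(select_unique_hit(boundary)$decision, "recovered")
  just_above <- rbind(hit(1e-9, 0.9), hit(1e-9, 0.41, "s2"))
  expect_identical(select_unique_hit(just_above)$decision, "ambiguous")
  # e-value filter
  evf <- rbind(hit(1e-9, 0.9), hit(1e-3, 0.9, "s2"))
  expect_identical(select_unique_hit(evf)$decision, "recovered")
  # both passing -> ambiguous, none passing -> none
  both <- rbind(hit(1e-9, 0.9), hit(1e-9, 0.9, "s2"))
  expect_identical(select_unique_hit(both)$decision, "ambiguous")
  expect_null(select_unique_hit(both)$hit)
  neither <- rbind(hit(1, 0.1), hit(1, 0.1, "s2"))
  expect_identical(select_unique_hit(neither)$decision, "none")
  expect_identical(select_unique_hit(data.frame())$decision, "none")
})

graft_fixture <- function() {
  # two-block alignment; block 2 has a reference gap column
  list(
    list(taxa = c("ref", "x"),
         chrom = c(ref = "c", x = "s"), start = c(ref = 0, x = 0),
         size = c(ref = 20, x = 20), strand = c(ref = "+", x = "+"),
         srcSize = c(ref = 40, x = 40),
         seqs = c(ref = "ACGTACGTACGTACGTACGT",
                  x   = "ACGTACGTACGTACGTACGT")),
    list(taxa = c("ref", "x"),
         chrom = c(ref = "c", x = "s"), start = c(ref = 20, x = 20),
         size = c(ref = 10, x = 11), strand = c(ref = "+", x = "+"),
         srcSize = c(ref = 40, x = 40),
         seqs = c(ref = "ACGTA-CGTAC",
                  x   = "ACGTAACGTAC"))
  )
}

test_that("grafting an exact scaffold copy reproduces the reference row", {
  blocks <- graft_fixture()
  scaffolds <- c(sc1 = "ACGTACGTACGTACGTACGT")
  placements <- data.frame(block = 1, scaffold = "sc1", s_start = 1,
                           s_end = 20, strand = "+",
                           stringsAsFactors = FALSE)
  out <- graft_taxon(blocks, placements, scaffolds, "new")
  expect_identical(out[[1]]$seqs[["new"]], out[[1]]$seqs[["ref"]])
  # unplaced block gets an all-gap row of the same width
  expect_identical(out[[2]]$seqs[["new"]],
                   strrep("-", nchar(out[[2]]$seqs[["ref"]])))
  expect_length(out, 2)
  expect_identical(out[[1]]$taxa, c("ref", "x", "new"))
})

test_that("grafting preserves existing taxa byte-for-byte", {
  blocks <- graft_fixture()
  # scaffold copy with an insertion and a deletion relative to the ref
  scaffolds <- c(sc1 = "ACGTACGTTTACGTACGTAGT") # +TT after base 8, -C
  placements <- data.frame(block = 1, scaffold = "sc1", s_start = 1,
                           s_end = nchar(scaffolds[["sc1"]]), strand = "+",
                           stringsAsFactors = FALSE)
  out <- graft_taxon(blocks, placements, scaffolds, "new")
  ungap <- function(s) gsub("-", "", s, fixed = TRUE)
  for (b in 1:2) {
    for (tx in c("ref", "x")) {
      expect_identical(ungap(out[[b]]$seqs[[tx]]),
                       ungap(blocks[[b]]$seqs[[tx]]))
    }
  }
  # the inserted columns are gap-only for existing taxa
  w <- nchar(out[[1]]$seqs[["ref"]])
  expect_gte(w, 20)
  # deleting the new row restores the original column content
  stripped <- lapply(seq_along(out[[1]]$seqs[c("ref", "x")]), function(i) {
    s <- out[[1]]$seqs[c("ref", "x")][[i]]
    chars <- strsplit(s, "")[[1]]
    other <- strsplit(out[[1]]$seqs[c("ref", "x")][[3 - i]], "")[[1]]
    keep <- !(chars == "-" & other == "-")
    paste(chars[keep], collapse = "")
  })
  expect_identical(stripped[[1]], blocks[[1]]$seqs[["ref"]])
  expect_identical(stripped[[2]], blocks[[1]]$seqs[["x"]])
})

test_that("grafting respects scaffold bounds and minus-strand slices", {
  blocks <- graft_fixture()
  scaffolds <- c(sc1 = "ACGTACGTACGTACGTACGT")
  bad <- data.frame(block = 1, scaffold = "sc1", s_start = 5, s_end = 50,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(graft_taxon(blocks, bad, scaffolds, "new"), "bounds")
  # minus-strand placement: reverse complement is re-oriented before
  # threading
  rc_scaffolds <- c(sc1 = phyloscan:::revcomp_chr("ACGTACGTACGTACGTACGT"))
  plc <- data.frame(block = 1, scaffold = "sc1", s_start = 1, s_end = 20,
                    strand = "-", stringsAsFactors = FALSE)
  out <- graft_taxon(blocks, plc, rc_scaffolds, "new")
  expect_identical(out[[1]]$seqs[["new"]], blocks[[1]]$seqs[["ref"]])
})

test_that("most regions of a fragmented clean assembly are placed", {
  # fragment one taxon's genome into overlapping scaffolds and re-place
  # every window-sized region
  genome <- random_dna(4000, 77)
  regions <- substring(genome, seq(1, 3801, by = 200),
                       seq(200, 4000, by = 200))
  cuts <- c(1, 601, 1201, 2001, 2601, 3201, 3801, 4001)
  scaffolds <- setNames(
    substring(genome, cuts[-length(cuts)], cuts[-1] - 1 + 60),
    paste0("scf", seq_len(length(cuts) - 1))
  )
  placed <- 0
  for (r in regions) {
    sel <- select_unique_hit(search_homologs(r, scaffolds))
    if (!is.null(sel$hit)) placed <- placed + 1
  }
  expect_gte(placed / length(regions), 0.95)
})
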