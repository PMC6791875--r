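# The coalescent simulator: genealogy sampling, sequence emission, MAF
# generation and ground truth.

test_that("forced introgression makes the donor the recipient's nearest leaf", {
  st <- gambiae_complex_tree()
  ev <- list(list(donor = "gambiae", recipient = "fontenillei",
                  chrom = "c1", start = 0, end = 10000, time = 1e5,
                  prob = 1))
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 20000),
                           window_size = 5000,
                           introgression_events = ev, seed = 2)
  for (s in 1:5) {
    g <- sample_window_genealogy(cfg, "c1", c(0, 5000), seed = s)
    expect_identical(attr(g, "label"), "introgressed")
    cm <- ape::cophenetic.phylo(g)
    others <- setdiff(colnames(cm), "fontenillei")
    expect_identical(names(which.min(cm["fontenillei", others])), "gambiae")
    # forced coalescence at exactly the event time: total path 2 * t_e
    expect_equal(min(cm["fontenillei", others]), 2e5, tolerance = 1e-8)
  }
})

test_that("in the zero-ILS limit the genealogy matches the species topology", {
  st <- quartet_tree(ne = 1) # Ne -> 0: coalescence effectively instant
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 10000),
                           window_size = 1000, reference = "A", seed = 1)
  for (s in 1:10) {
    g <- sample_window_genealogy(cfg, "c1", c(0, 1000), seed = s)
    expect_identical(attr(g, "label"), "species")
    rooted <- ape::root(g, "O", resolve.root = TRUE)
    expect_identical(canonical_topology(rooted, drop_outgroup = "O"),
                     "((A,B),C)")
  }
})

test_that("quartet discordance matches the closed-form MSC probability", {
  # internal branch of T generations in a population of haploid size Ne:
  # P(discordant) = (2/3) exp(-T/Ne); here T/Ne = 1
  st <- quartet_tree(t1 = 10000, t2 = 20000, ne = 10000)
  n <- 2000
  set.seed(421)
  disc <- 0
  for (i in seq_len(n)) {
    g <- phyloscan:::msc_genealogy(st$tab)
    topo <- canonical_topology(ape::root(g, "O", resolve.root = TRUE),
                               drop_outgroup = "O")
    if (topo != "((A,B),C)") disc <- disc + 1
  }
  expected <- (2 / 3) * exp(-1)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(disc / n - expected), 3 * se)
})

test_that("species-topology frequency falls as the internal branch shrinks", {
  freq_concordant <- function(t_ratio) {
    st <- quartet_tree(t1 = 10000, t2 = 10000 + t_ratio * 10000, ne = 10000)
    set.seed(77)
    mean(vapply(1:300, function(i) {
      g <- phyloscan:::msc_genealogy(st$tab)
      canonical_topology(ape::root(g, "O", resolve.root = TRUE),
                         drop_outgroup = "O") == "((A,B),C)"
    }, logical(1)))
  }
  f <- vapply(c(2, 0.8, 0.2), freq_concordant, numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("sequence emission follows the Jukes-Cantor expectation", {
  st <- pair_tree(5e6)
  g <- ape::drop.tip(st$phy, "O") # two taxa, total path 1e7 generations
  mu <- 1.1e-9
  # mu = 0: identical sequences
  m0 <- mutate_and_emit(ape::read.tree(text = "(A:100,B:100);"), 50, 0,
                        seed = 1)
  expect_identical(m0["A", ], m0["B", ])
  # small mu * t: mean p-distance ~ 2 t mu within 3 SE
  set.seed(11)
  n_rep <- 30
  L <- 2000
  p_hat <- vapply(seq_len(n_rep), function(i) {
    m <- mutate_and_emit(g, L, mu)
    mean(m["A", ] != m["B", ])
  }, numeric(1))
  p_exp <- 2 * 5e6 * mu # 0.011 per site, low enough to ignore homoplasy
  se <- sqrt(p_exp * (1 - p_exp) / (L * n_rep))
  expect_lt(abs(mean(p_hat) - p_exp), 3 * se + p_exp^2) # second term: double hits
  # missing_data_rate = 1: everything gapped (non-exempt taxa)
  m1 <- mutate_and_emit(g, 20, mu, missing_data_rate = 1, seed = 2)
  expect_true(all(m1 == "-"))
  m2 <- mutate_and_emit(g, 20, mu, missing_data_rate = 1, exempt = "A",
                        seed = 2)
  expect_true(all(m2["B", ] == "-"))
  expect_false(any(m2["A", ] == "-"))
})

test_that("simulate_maf tiles chromosomes and is seed-deterministic", {
  st <- gambiae_complex_tree()
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 100000),
                           window_size = 50000, seed = 9)
  sim <- simulate_maf(cfg)
  expect_length(sim$blocks, 2)
  expect_equal(sim$truth$start, c(0, 50000))
  expect_equal(sim$truth$end, c(50000, 100000))
  # reference coordinates strictly increasing, non-overlapping
  ref_starts <- vapply(sim$blocks, function(b) b$start[["gambiae"]],
                       numeric(1))
  expect_true(all(diff(ref_starts) > 0))
  # identical seed -> byte-identical files
  p1 <- tempfile(fileext = ".maf")
  p2 <- tempfile(fileext = ".maf")
  write_maf(sim$blocks, p1)
  write_maf(simulate_maf(cfg)$blocks, p2)
  expect_identical(readLines(p1), readLines(p2))
  # different seed -> different content
  cfg2 <- simulation_config(st, chrom_lengths = c(c1 = 100000),
                            window_size = 50000, seed = 10)
  p3 <- tempfile(fileext = ".maf")
  write_maf(simulate_maf(cfg2)$blocks, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("chromosome order does not change per-chromosome output", {
  st <- gambiae_complex_tree()
  cfg_a <- simulation_config(st, chrom_lengths = c(c1 = 10000, c2 = 10000),
                             window_size = 5000, seed = 5)
  cfg_b <- simulation_config(st, chrom_lengths = c(c2 = 10000, c1 = 10000),
                             window_size = 5000, seed = 5)
  sim_a <- simulate_maf(cfg_a)
  sim_b <- simulate_maf(cfg_b)
  key <- function(s) {
    k <- vapply(s$blocks, function(b) {
      paste(b$chrom[[1]], b$start[[1]], b$seqs[[1]])
    }, character(1))
    sort(k)
  }
  expect_identical(key(sim_a), key(sim_b))
})

test_that("ground-truth labels match the configured inversion fraction", {
  st <- gambiae_complex_tree()
  inv <- list(list(chrom = "c1", start = 40000, end = 50000,
                   tree = inversion_override_tree()))
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 50000),
                           window_size = 1000, inversion_regions = inv,
                           seed = 3)
  sim <- simulate_maf(cfg)
  expect_equal(mean(sim$truth$label == "inversion"), 0.2)
  expect_true(all(sim$truth$label[sim$truth$start >= 40000] == "inversion"))
})

test_that("out-of-range windows and bad configurations are rejected", {
  st <- gambiae_complex_tree()
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 10000),
                           window_size = 5000, seed = 1)
  expect_error(sample_window_genealogy(cfg, "c1", c(9000, 11000)),
               "outside chromosome")
  expect_error(sample_window_genealogy(cfg, "nope", c(0, 100)), "unknown")
  expect_error(
    simulation_config(st, chrom_lengths = c(c1 = 1000), mu = 0),
    "mu"
  )
  expect_error(
    simulation_config(st, chrom_lengths = c(c1 = 1000),
                      introgression_events = list(list(
                        donor = "gambiae", recipient = "fontenillei",
                        chrom = "c1", start = 0, end = 500, time = 1e5,
                        prob = 1.5))),
    "probability"
  )
  # introgression after the recipient's own species split is meaningless
  expect_error(
    simulation_config(st, chrom_lengths = c(c1 = 1000),
                      introgression_events = list(list(
                        donor = "gambiae", recipient = "fontenillei",
                        chrom = "c1", start = 0, end = 500, time = 6e6,
                        prob = 0.5))),
    "predate"
  )
})

test_that("ground truth round-trips through BED and ages files", {
  st <- gambiae_complex_tree()
  cfg <- simulation_config(st, chrom_lengths = c(c1 = 10000),
                           window_size = 5000, seed = 4)
  sim <- simulate_maf(cfg)
  bed <- tempfile(fileext = ".bed")
  ages <- tempfile(fileext = ".tsv")
  write_ground_truth(sim, bed, ages)
  re_bed <- read.table(bed, sep = "\t")
  expect_equal(re_bed$V2, sim$truth$start)
  re_ages <- read.table(ages, sep = "\t", header = TRUE)
  fb <- re_ages[re_ages$taxon_a == "bwambae" &
                  re_ages$taxon_b == "fontenillei", ]
  expect_equal(fb$split_ma, 0.53)
})
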