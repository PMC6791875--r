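# Orchestration: one flat YAML configuration drives
# simulate -> windows -> trees -> scan -> date, with deterministic,
# resumable stage outputs under one output directory.

#' Read a pipeline configuration file
#'
#' @param path YAML configuration path (see `inst/extdata/demo_config.yaml`
#'   for the shipped template).
#' @return the configuration as a nested list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks: required sections and fields, positive
#' rates, taxa known to the species tree, intervals within chromosome
#' bounds, non-overlapping region definitions. Violations are returned,
#' not raised.
#'
#' @param config configuration list (from [read_pipeline_config()]) or a
#'   path to a YAML file.
#' @return character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  v <- character(0)
  say <- function(...) v <<- c(v, paste0(...))
  sim <- config$simulate
  if (is.null(sim)) {
    say("missing 'simulate' section")
    return(v)
  }
  taxa <- gambiae_complex_tree()$phy$tip.label
  mu <- sim$mu %||% 1.1e-9
  if (!is.numeric(mu) || mu <= 0) say("simulate.mu must be > 0")
  g <- sim$gens_per_year %||% 10
  if (!is.numeric(g) || g <= 0) say("simulate.gens_per_year must be > 0")
  ws <- sim$window_size %||% 50000
  if (!is.numeric(ws) || ws <= 0) say("simulate.window_size must be > 0")
  mdr <- sim$missing_data_rate %||% 0
  if (!is.numeric(mdr) || mdr < 0 || mdr > 1) {
    say("simulate.missing_data_rate must be in [0,1]")
  }
  cl <- sim$chrom_lengths
  if (is.null(cl) || length(cl) == 0) {
    say("simulate.chrom_lengths missing")
    cl <- list()
  }
  ref <- sim$reference %||% "gambiae"
  if (!ref %in% taxa) say("simulate.reference unknown taxon: ", ref)
  in_bounds <- function(x, what) {
    if (!x$chrom %in% names(cl)) {
      say(what, " on unknown chromosome ", x$chrom)
    } else if (x$start < 0 || x$end > cl[[x$chrom]] || x$start >= x$end) {
      say(what, " interval outside chromosome ", x$chrom)
    }
  }
  for (ev in sim$introgression_events %||% list()) {
    for (lab in c(ev$donor, ev$recipient)) {
      if (!lab %in% taxa) say("introgression taxon unknown: ", lab)
    }
    if (!is.numeric(ev$prob) || ev$prob < 0 || ev$prob > 1) {
      say("introgression prob must be in [0,1]")
    }
    in_bounds(ev, "introgression event")
  }
  invs <- sim$inversion_regions %||% list()
  for (inv in invs) in_bounds(inv, "inversion region")
  if (length(invs) > 1) {
    for (i in seq_along(invs)) {
      for (j in seq_along(invs)) {
        if (i < j && invs[[i]]$chrom == invs[[j]]$chrom &&
            interval_overlap(invs[[i]]$start, invs[[i]]$end,
                             invs[[j]]$start, invs[[j]]$end) > 0) {
          say("overlapping inversion regions on ", invs[[i]]$chrom)
        }
      }
    }
  }
  scan <- config$scan
  if (is.null(scan)) {
    say("missing 'scan' section")
  } else {
    for (f in c("focal", "expected_sister", "outgroup")) {
      if (is.null(scan[[f]])) {
        say("scan.", f, " missing")
      } else if (!scan[[f]] %in% taxa) {
        say("scan.", f, " unknown taxon: ", scan[[f]])
      }
    }
    mif <- scan$min_informative_fraction %||% 0.1
    if (!is.numeric(mif) || mif < 0 || mif > 1) {
      say("scan.min_informative_fraction must be in [0,1]")
    }
    for (nm in names(scan$clades %||% list())) {
      bad <- setdiff(unlist(scan$clades[[nm]]), taxa)
      if (length(bad)) say("scan.clades.", nm, " unknown taxa: ",
                           paste(bad, collapse = ","))
    }
  }
  dat <- config$dating
  if (!is.null(dat)) {
    if (!is.null(dat$mu) && (!is.numeric(dat$mu) || dat$mu <= 0)) {
      say("dating.mu must be > 0")
    }
    if (!is.null(dat$flank) && dat$flank < 0) say("dating.flank must be >= 0")
    for (p in dat$pairs %||% list()) {
      bad <- setdiff(unlist(p), taxa)
      if (length(bad)) say("dating pair unknown taxa: ",
                           paste(bad, collapse = ","))
    }
  }
  v
}

# instantiate config objects from the validated YAML list
#' @noRd
build_configs <- function(config) {
  sim <- config$simulate
  seed <- config$seed %||% 1L
  ne <- sim$ne %||% 5e3
  g <- sim$gens_per_year %||% 10
  st <- gambiae_complex_tree(ne = ne, gens_per_year = g)
  inv_tree <- inversion_override_tree(ne = ne, gens_per_year = g)
  invs <- lapply(sim$inversion_regions %||% list(), function(x) {
    list(chrom = x$chrom, start = x$start, end = x$end, tree = inv_tree)
  })
  sim_cfg <- simulation_config(
    species_tree = st,
    chrom_lengths = sim$chrom_lengths,
    window_size = sim$window_size %||% 50000,
    mu = sim$mu %||% 1.1e-9,
    gens_per_year = g,
    introgression_events = sim$introgression_events %||% list(),
    inversion_regions = invs,
    missing_data_rate = sim$missing_data_rate %||% 0,
    reference = sim$reference %||% "gambiae",
    seed = seed
  )
  scan <- config$scan
  scan_cfg <- scan_config(
    focal = scan$focal, expected_sister = scan$expected_sister,
    outgroup = scan$outgroup,
    window_size = sim$window_size %||% 50000,
    min_informative_fraction = scan$min_informative_fraction %||% 0.10,
    clade_definitions = lapply(scan$clades %||% list(), unlist),
    n_boot = scan$n_boot %||% 1000
  )
  dat <- config$dating %||% list()
  dat_cfg <- dating_config(
    mu = dat$mu %||% 1.1e-9,
    gens_per_year = dat$gens_per_year %||% 10,
    n_boot = dat$n_boot %||% 1000,
    flank = dat$flank %||% 500000,
    seed = seed
  )
  list(sim = sim_cfg, scan = scan_cfg, dating = dat_cfg, raw = config)
}

#' Run the full scan pipeline from one configuration
#'
#' Executes simulate -> windows -> trees -> scan -> date, writing each
#' stage's outputs under `outdir` (MAF and ground truth; window filter
#' log; Newick trees and index; calls, tally and block tables; dating
#' estimates) plus a run manifest. All randomness derives from the
#' configuration seed, so identical configurations reproduce identical
#' outputs. With `resume = TRUE`, stages whose outputs already exist are
#' skipped and later stages read them back; a missing upstream output
#' raises a stage-dependency error.
#'
#' @param config configuration list or YAML path.
#' @param outdir output directory (created if needed).
#' @param resume skip stages whose outputs exist (default FALSE).
#' @return invisibly, the run manifest (list).
#' @export
run_pipeline <- function(config, outdir, resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  }
  cfgs <- build_configs(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(outdir, ...)
  manifest <- list(seed = config$seed %||% 1L,
                   config_digest = config_digest(config),
                   stages = list())

  # -- stage: simulate -------------------------------------------------
  maf_path <- path("alignment.maf")
  if (resume && file.exists(maf_path)) {
    message("simulate: reusing ", maf_path)
  } else {
    sim <- simulate_maf(cfgs$sim)
    write_maf(sim$blocks, maf_path)
    write_ground_truth(sim, path("truth.bed"), path("truth_ages.tsv"))
  }
  manifest$stages$simulate <- list(maf = maf_path)

  # -- stage: windows --------------------------------------------------
  if (!file.exists(maf_path)) {
    stop("stage dependency missing: ", maf_path, " (run simulate first)")
  }
  blocks <- read_maf(maf_path)
  windows <- partition_windows(blocks, cfgs$scan)
  filt <- filter_windows(windows, cfgs$scan)
  utils::write.table(filt$log, path("window_filter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$windows <- list(
    n_windows = length(windows), n_retained = length(filt$retained),
    n_excluded = length(filt$excluded)
  )

  # -- stage: trees ----------------------------------------------------
  idx_path <- path("trees_index.tsv")
  if (resume && file.exists(idx_path)) {
    message("trees: reusing ", idx_path)
    wt <- read_window_trees(idx_path)
  } else {
    wt <- window_trees(filt$retained, cfgs$scan,
                       seed = config$seed %||% 1L)
    write_window_trees(wt, path("trees"))
    utils::write.table(wt$skipped, path("trees_skipped.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest$stages$trees <- list(
    n_trees = length(wt$trees), n_skipped = nrow(wt$skipped)
  )

  # -- stage: scan -----------------------------------------------------
  cls <- classify_windows(wt, cfgs$scan)
  tl <- tally_topologies(cls$calls)
  blocks_df <- segment_blocks(cls$calls,
                              min_run = config$scan$min_run %||% 1)
  utils::write.table(cls$calls, path("calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tl$genome, path("tally_genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tl$by_chrom, path("tally_by_chrom.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_blocks_bed(blocks_df, path("blocks.bed"))
  manifest$stages$scan <- list(
    n_calls = nrow(cls$calls), n_blocks = nrow(blocks_df),
    sister_pct = tl$sister$pct
  )

  # -- stage: date -----------------------------------------------------
  pairs <- config$dating$pairs %||% list()
  estimates <- lapply(pairs, function(p) {
    p <- unlist(p)
    divergence_estimate(collect_pair_distances(wt, p), p, cfgs$dating)
  })
  if (length(estimates) > 0) {
    write_estimates(estimates, cfgs$dating, path("dating.tsv"))
  }
  manifest$stages$date <- list(n_pairs = length(estimates))

  yaml::write_yaml(manifest, path("manifest.yaml"))
  invisible(manifest)
}

# read back a tree-stage index written by write_window_trees()
#' @noRd
read_window_trees <- function(idx_path) {
  idx <- utils::read.table(idx_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  trees <- lapply(seq_len(nrow(idx)), function(i) {
    list(id = idx$id[i], chrom = idx$chrom[i], start = idx$start[i],
         end = idx$end[i], tree = ape::read.tree(text = idx$newick[i]))
  })
  skipped_path <- file.path(dirname(idx_path), "trees_skipped.tsv")
  skipped <- if (file.exists(skipped_path)) {
    utils::read.table(skipped_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), reason = character())
  }
  list(trees = trees, skipped = skipped)
}

# small order-invariant digest of the configuration for the manifest
#' @noRd
config_digest <- function(config) {
  s <- yaml::as.yaml(config)
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}
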