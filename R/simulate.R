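# Synthetic multi-species alignments: configuration, sequence emission and
# MAF generation with ground truth.

#' Configuration of the alignment simulator
#'
#' Bundles everything the simulator needs: the dated species tree, the
#' mutation process, chromosome layout, and the genealogical
#' heterogeneities (introgression pulses, inversion regions) that the
#' downstream scan is meant to detect.
#'
#' @param species_tree a [species_tree()] object.
#' @param chrom_lengths named numeric vector/list, chromosome lengths in bp.
#' @param window_size window (= MAF block) size in bp.
#' @param mu substitution rate per site per generation (default 1.1e-9).
#' @param gens_per_year generations per year (default 10).
#' @param introgression_events list of events, each a list with elements
#'   `donor`, `recipient` (tip labels), `chrom`, `start`, `end` (0-based
#'   half-open interval), `time` (generations before present) and `prob`
#'   (per-window replacement probability in `[0, 1]`).
#' @param inversion_regions list of regions, each a list with `chrom`,
#'   `start`, `end` and `tree` (the override [species_tree()] describing the
#'   inversion genealogy).
#' @param missing_data_rate fraction of columns gapped i.i.d. per
#'   non-reference taxon (default 0).
#' @param reference reference taxon whose coordinates anchor the MAF
#'   (default `"gambiae"`, the AgamP3-like anchor; never gapped so that
#'   reference coordinates tile the chromosome exactly).
#' @param seed top-level integer seed; every stream the simulator uses is
#'   derived from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(species_tree,
                              chrom_lengths,
                              window_size = 50000,
                              mu = 1.1e-9,
                              gens_per_year = 10,
                              introgression_events = list(),
                              inversion_regions = list(),
                              missing_data_rate = 0,
                              reference = "gambiae",
                              seed = 1L) {
  stopifnot(inherits(species_tree, "species_tree"))
  if (mu <= 0) stop("mu must be > 0")
  if (gens_per_year <= 0) stop("gens_per_year must be > 0")
  if (window_size <= 0) stop("window_size must be > 0")
  if (missing_data_rate < 0 || missing_data_rate > 1) {
    stop("missing_data_rate must be in [0, 1]")
  }
  chrom_lengths <- unlist(chrom_lengths)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named")
  }
  taxa <- species_tree$phy$tip.label
  if (!reference %in% taxa) stop("reference taxon not in species tree")
  tab <- species_tree$tab
  for (ev in introgression_events) {
    if (!all(c(ev$donor, ev$recipient) %in% taxa)) {
      stop("introgression donor/recipient not in species tree")
    }
    if (ev$prob < 0 || ev$prob > 1) stop("replacement probability not in [0,1]")
    check_interval(ev, chrom_lengths, "introgression event")
    for (lab in c(ev$donor, ev$recipient)) {
      i <- match(lab, tab$label)
      if (ev$time >= tab$age[tab$parent[i]]) {
        stop("introgression time must predate the first species split of ", lab)
      }
    }
  }
  for (inv in inversion_regions) {
    stopifnot(inherits(inv$tree, "species_tree"))
    if (!setequal(inv$tree$phy$tip.label, taxa)) {
      stop("inversion override tree must carry the same taxa")
    }
    check_interval(inv, chrom_lengths, "inversion region")
  }
  structure(
    list(
      species_tree = species_tree, chrom_lengths = chrom_lengths,
      window_size = window_size, mu = mu, gens_per_year = gens_per_year,
      introgression_events = introgression_events,
      inversion_regions = inversion_regions,
      missing_data_rate = missing_data_rate,
      reference = reference, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @noRd
check_interval <- function(x, chrom_lengths, what) {
  if (!x$chrom %in% names(chrom_lengths)) {
    stop(what, " on unknown chromosome ", x$chrom)
  }
  if (x$start < 0 || x$end > chrom_lengths[[x$chrom]] || x$start >= x$end) {
    stop(what, " interval outside chromosome ", x$chrom)
  }
}

#' Evolve sequences along a genealogy and emit aligned rows
#'
#' Places substitutions by a Jukes-Cantor process along the genealogy
#' (branch length in generations times `mu` expected substitutions per
#' site), then injects missing data as i.i.d. gap columns per taxon.
#'
#' @param genealogy [ape::phylo] with branch lengths in generations.
#' @param length alignment length in bp (> 0).
#' @param mu substitution rate per site per generation.
#' @param missing_data_rate fraction of columns gapped per taxon.
#' @param exempt taxa never gapped (e.g. the reference anchor).
#' @param seed optional integer seed.
#' @return character matrix, one row per taxon (upper-case A/C/G/T/-).
#' @export
mutate_and_emit <- function(genealogy, length, mu, missing_data_rate = 0,
                            exempt = NULL, seed = NULL) {
  if (length <= 0) stop("length must be > 0")
  emit <- function() {
    phy <- genealogy
    phy$edge.length <- phy$edge.length * mu
    m <- evolve_jc(phy, length)
    if (missing_data_rate > 0) {
      for (tx in setdiff(rownames(m), exempt)) {
        gap <- stats::runif(length) < missing_data_rate
        m[tx, gap] <- "-"
      }
    }
    m[sort(rownames(m)), , drop = FALSE]
  }
  if (is.null(seed)) emit() else with_seed(seed, emit())
}

# exact Jukes-Cantor sequence evolution along a tree whose edge lengths
# are expected substitutions/site: a site changes state along an edge of
# length d with probability (3/4)(1 - exp(-4d/3)), uniformly among the
# three other bases; the root sequence is uniform. Vectorized over sites.
#' @noRd
evolve_jc <- function(phy, length) {
  bases <- c("A", "C", "G", "T")
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  # cladewise edge order guarantees parents are evolved before children
  phy <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1]
    child <- phy$edge[e, 2]
    d <- phy$edge.length[e]
    p_change <- 0.75 * (1 - exp(-4 * d / 3))
    s <- seqs[[parent]]
    if (p_change > 0) {
      hit <- which(stats::runif(length) < p_change)
      if (length(hit) > 0) {
        # jump to one of the three other bases, uniformly
        s[hit] <- ((s[hit] - 1L + sample.int(3L, length(hit),
                                             replace = TRUE)) %% 4L) + 1L
      }
    }
    seqs[[child]] <- s
  }
  m <- do.call(rbind, lapply(seq_len(n_tip), function(i) bases[seqs[[i]]]))
  rownames(m) <- phy$tip.label
  m
}

# stable small hash of a chromosome name, for order-independent streams
#' @noRd
chrom_stream <- function(chrom) {
  v <- utf8ToInt(chrom)
  s <- 7
  for (x in v) s <- (s * 131 + x) %% 1048573
  as.integer(s)
}

#' Simulate a reference-anchored MAF alignment with ground truth
#'
#' Emits one MAF block per window-sized chunk of every configured
#' chromosome. Each chunk receives one genealogy (species tree,
#' introgression pulse, or inversion override, per
#' [sample_window_genealogy()]), sequences are evolved with
#' [mutate_and_emit()], and the chunk is labelled in the ground truth.
#' Output is a pure function of the configuration, including the seed;
#' per-chromosome and per-window streams are derived by seed splitting, so
#' neither chromosome order nor partial regeneration changes results.
#'
#' @param config a [simulation_config()].
#' @return list with elements `blocks` (MAF blocks as used by [read_maf()]),
#'   `truth` (data frame: `chrom`, `start`, `end`, `label`) and `ages`
#'   (true pairwise split ages, from [split_ages()]).
#' @export
simulate_maf <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  taxa <- config$species_tree$phy$tip.label
  ord <- c(config$reference, setdiff(taxa, config$reference))
  blocks <- list()
  truth <- data.frame()
  for (chrom in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[chrom]]
    cs <- derive_seed(config$seed, chrom_stream(chrom))
    starts <- seq(0, L - 1, by = config$window_size)
    for (wi in seq_along(starts)) {
      s <- starts[wi]
      e <- min(s + config$window_size, L)
      ws <- derive_seed(cs, wi)
      block <- with_seed(ws, {
        g <- sample_window_genealogy(config, chrom, c(s, e))
        m <- mutate_and_emit(g, e - s, config$mu,
                             missing_data_rate = config$missing_data_rate,
                             exempt = config$reference)
        list(genealogy_label = attr(g, "label"), mat = m)
      })
      m <- block$mat[ord, , drop = FALSE]
      seqs <- apply(m, 1, paste, collapse = "")
      sizes <- vapply(seqs, function(x) {
        sum(seq_to_chars(x) != "-")
      }, numeric(1))
      blocks[[length(blocks) + 1L]] <- list(
        taxa = ord,
        chrom = setNames(rep(chrom, length(ord)), ord),
        start = setNames(rep(s, length(ord)), ord),
        size = sizes,
        strand = setNames(rep("+", length(ord)), ord),
        srcSize = setNames(rep(L, length(ord)), ord),
        seqs = seqs
      )
      truth <- rbind(truth, data.frame(
        chrom = chrom, start = s, end = e, label = block$genealogy_label,
        stringsAsFactors = FALSE
      ))
    }
  }
  list(
    blocks = blocks, truth = truth,
    ages = split_ages(config$species_tree, config$gens_per_year)
  )
}

#' Write simulator ground truth as BED plus an ages table
#'
#' Window labels go to a BED file (0-based, half-open; label in the name
#' column), true pairwise split ages to a tab-separated table.
#'
#' @param sim result of [simulate_maf()].
#' @param bed_path output BED path.
#' @param ages_path output TSV path.
#' @return invisibly, the two paths.
#' @export
write_ground_truth <- function(sim, bed_path, ages_path) {
  bed <- sim$truth[, c("chrom", "start", "end", "label")]
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$ages, ages_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed_path, ages_path))
}

#' Simulate per-window patristic distances for one taxon pair
#'
#' Calibration utility for recovery experiments: draws `n_windows`
#' independent window genealogies under the multispecies coalescent on
#' `st`, evolves `window_bp` sites per window, infers the
#' neighbor-joining window tree rooted on the outgroup, and returns the
#' patristic distance between the two focal taxa per window. Taxa other
#' than `keep` can be pruned from the species tree first to keep the
#' per-window cost low.
#'
#' @param st a [species_tree()] object.
#' @param pair character vector of two taxon labels.
#' @param outgroup outgroup label used for rooting.
#' @param n_windows number of windows to simulate.
#' @param window_bp sites per window.
#' @param mu substitution rate per site per generation.
#' @param seed integer seed (per-window streams derived from it).
#' @param keep optional taxon subset to retain (must include the pair and
#'   the outgroup); defaults to all taxa.
#' @return numeric vector of `n_windows` patristic distances
#'   (substitutions/site).
#' @export
simulate_pair_distances <- function(st, pair, outgroup, n_windows,
                                    window_bp, mu = 1.1e-9, seed = 1L,
                                    keep = NULL) {
  stopifnot(inherits(st, "species_tree"))
  if (!is.null(keep)) {
    keep <- union(keep, c(pair, outgroup))
    drop <- setdiff(st$phy$tip.label, keep)
    if (length(drop) > 0) {
      st <- species_tree(ape::drop.tip(st$phy, drop),
                         ne = st$ne[1], outgroup = outgroup)
    }
  }
  vapply(seq_len(n_windows), function(i) {
    with_seed(derive_seed(seed, i), {
      g <- msc_genealogy(st$tab)
      m <- mutate_and_emit(g, window_bp, mu)
      tree <- build_tree(pairwise_distances(m), outgroup)
      patristic_distance(tree, pair[1], pair[2])
    })
  }, numeric(1))
}
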