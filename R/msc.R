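# Multispecies-coalescent genealogy sampling on a population tree.
#
# The species tree is held in tabular form (one row per node; the branch
# above node i, from age[i] to age[parent[i]], is a population of haploid
# size ne[i]). One haploid sample per species. Introgression pulses are
# represented by a rewired population table in which the recipient lineage
# is forced to coalesce with the donor lineage at the event time.

# coalesce a set of lineages within one population from t0 to t1 (t1 may be
# Inf for the root). Lineages are rows of a data.frame(nwk, h, minlab).
#' @noRd
coalesce_in_pop <- function(lins, t0, t1, ne) {
  t <- t0
  while (nrow(lins) > 1) {
    k <- nrow(lins)
    wait <- stats::rexp(1, rate = k * (k - 1) / 2 / ne)
    if (t + wait > t1) break
    t <- t + wait
    pair <- sample.int(k, 2)
    lins <- merge_lineages(lins, pair[1], pair[2], t)
  }
  lins
}

#' @noRd
merge_lineages <- function(lins, i, j, t) {
  a <- lins[i, ]
  b <- lins[j, ]
  nwk <- sprintf("(%s:%.8f,%s:%.8f)", a$nwk, t - a$h, b$nwk, t - b$h)
  keep <- lins[-c(i, j), , drop = FALSE]
  rbind(keep, data.frame(
    nwk = nwk, h = t, minlab = min(a$minlab, b$minlab),
    stringsAsFactors = FALSE
  ))
}

# recursive MSC draw over a population table; returns a phylo with branch
# lengths in generations.
#' @noRd
msc_genealogy <- function(tab) {
  children <- split(tab$node, factor(tab$parent, levels = tab$node))
  sim_node <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids) || length(kids) == 0) {
      return(data.frame(
        nwk = tab$label[node], h = tab$age[node], minlab = tab$label[node],
        stringsAsFactors = FALSE
      ))
    }
    lins <- do.call(rbind, lapply(kids, function(k) {
      below <- sim_node(k)
      coalesce_in_pop(below, tab$age[k], tab$age[node], tab$ne[k])
    }))
    if (isTRUE(tab$force[node])) {
      # forced merge (introgression pulse): all lineages entering this node
      # coalesce at exactly the node age, in deterministic label order
      while (nrow(lins) > 1) {
        ord <- order(lins$minlab)
        lins <- merge_lineages(lins, ord[1], ord[2], tab$age[node])
      }
    }
    lins
  }
  root <- tab$node[is.na(tab$parent)]
  lins <- sim_node(root)
  lins <- coalesce_in_pop(lins, tab$age[root], Inf, tab$ne[root])
  ape::read.tree(text = paste0(lins$nwk[1], ";"))
}

# rewire a population table so that `recipient` is forced to coalesce with
# `donor` at time t_e, and the merged lineage continues through the donor's
# ancestral populations (block-replacement model of an introgression pulse).
#' @noRd
introgress_table <- function(tab, donor, recipient, t_e) {
  di <- match(donor, tab$label)
  ri <- match(recipient, tab$label)
  if (is.na(di) || is.na(ri)) stop("donor/recipient not in species tree")
  if (t_e >= tab$age[tab$parent[di]] || t_e >= tab$age[tab$parent[ri]]) {
    stop("introgression time must predate both taxa's first species split")
  }
  if (is.null(tab$force)) tab$force <- FALSE
  new_id <- nrow(tab) + 1L
  x <- data.frame(
    node = new_id, parent = tab$parent[di], age = t_e, ne = tab$ne[di],
    label = NA_character_, force = TRUE, stringsAsFactors = FALSE
  )
  tab <- rbind(tab, x)
  tab$parent[di] <- new_id
  tab$parent[ri] <- new_id
  tab
}

#' Sample one window genealogy under the simulation model
#'
#' Draws the genealogy of a single alignment window. If the window interval
#' overlaps a configured inversion region, the draw is made under that
#' region's override species tree. Otherwise, if an introgression event
#' covers the interval, then with the event's replacement probability the
#' recipient lineage is forced to coalesce with the donor lineage at the
#' event time; in all remaining cases the genealogy follows the neutral
#' multispecies coalescent on the species tree. One genealogy per window —
#' no intra-window recombination.
#'
#' @param config a [simulation_config()].
#' @param chrom chromosome id (must be in `config$chrom_lengths`).
#' @param interval numeric length-2, 0-based half-open window interval.
#' @param seed optional integer; when given, the draw is made under this
#'   seed, otherwise the current RNG state is used.
#' @return an [ape::phylo] genealogy with branch lengths in generations and
#'   attribute `"label"` in `c("species", "introgressed", "inversion")`.
#' @export
sample_window_genealogy <- function(config, chrom, interval, seed = NULL) {
  if (!chrom %in% names(config$chrom_lengths)) {
    stop("unknown chromosome: ", chrom)
  }
  L <- config$chrom_lengths[[chrom]]
  if (interval[1] < 0 || interval[2] > L || interval[1] >= interval[2]) {
    stop("interval outside chromosome ", chrom, " [0,", L, ")")
  }
  draw <- function() {
    for (inv in config$inversion_regions) {
      if (inv$chrom == chrom &&
          interval_overlap(interval[1], interval[2], inv$start, inv$end) > 0) {
        g <- msc_genealogy(inv$tree$tab)
        attr(g, "label") <- "inversion"
        return(g)
      }
    }
    for (ev in config$introgression_events) {
      covered <- ev$chrom == chrom && ev$start <= interval[1] &&
        ev$end >= interval[2]
      if (covered && stats::runif(1) < ev$prob) {
        tab <- introgress_table(config$species_tree$tab,
                                ev$donor, ev$recipient, ev$time)
        g <- msc_genealogy(tab)
        attr(g, "label") <- "introgressed"
        return(g)
      }
    }
    g <- msc_genealogy(config$species_tree$tab)
    attr(g, "label") <- "species"
    g
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
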