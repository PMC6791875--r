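# Per-window tree inference with bootstrap support, and patristic
# distances on inferred trees.

#' Bootstrap a window tree
#'
#' Infers the window tree on the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, re-infers a tree per replicate
#' and reports, for each internal node of the base tree, the percentage of
#' replicate trees containing the same clade (trees compared after rooting
#' on the outgroup). Replicates in which a taxon pair loses all shared
#' determined columns are discarded from the denominator.
#'
#' @param window an `alignment_window` (taxa to include should already be
#'   selected; see [window_trees()] for the missing-data drop rule).
#' @param n_reps bootstrap replicates (>= 1).
#' @param outgroup taxon to root on.
#' @param seed integer seed for the resampling.
#' @return rooted [ape::phylo] with integer `node.label` supports in
#'   `[0, 100]`, or `NULL` if the base distance matrix is incomplete.
#' @export
bootstrap_tree <- function(window, n_reps, outgroup, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  mat <- window$mat
  pd <- pairwise_distances(mat)
  if (any(is.na(pd$d))) return(NULL)
  base <- build_tree(pd$d, outgroup)
  boots <- with_seed(seed, {
    out <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(mat), replace = TRUE)
      pdr <- pairwise_distances(mat[, cols, drop = FALSE])
      if (any(is.na(pdr$d))) next
      out[[r]] <- build_tree(pdr$d, outgroup)
    }
    out[!vapply(out, is.null, logical(1))]
  })
  n_ok <- length(boots)
  if (n_ok == 0) {
    base$node.label <- rep(NA_integer_, base$Nnode)
    return(base)
  }
  counts <- ape::prop.clades(base, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  base$node.label <- as.integer(round(100 * counts / n_ok))
  base
}

#' Patristic distance between two leaves of a tree
#'
#' Sum of branch lengths along the path connecting the two taxa, in the
#' tree's branch-length units (substitutions/site for window trees).
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param taxon_a,taxon_b tip labels.
#' @return numeric path length.
#' @export
patristic_distance <- function(tree, taxon_a, taxon_b) {
  ia <- match(taxon_a, tree$tip.label)
  ib <- match(taxon_b, tree$tip.label)
  if (is.na(ia)) stop("taxon not in tree: ", taxon_a)
  if (is.na(ib)) stop("taxon not in tree: ", taxon_b)
  if (ia == ib) return(0)
  path <- ape::nodepath(tree, ia, ib)
  edges <- cbind(path[-length(path)], path[-1])
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  idx <- match(c(paste(edges[, 1], edges[, 2]), paste(edges[, 2], edges[, 1])),
               key)
  sum(tree$edge.length[idx[!is.na(idx)]])
}

#' Infer trees for a set of windows
#'
#' For every window: taxa with fewer than `min_taxon_determined` determined
#' characters are dropped; the window is skipped (with a logged reason) if
#' the focal, expected sister or outgroup taxon is among the dropped, if
#' fewer than 4 taxa remain, or if any retained pair has a missing or
#' saturated distance. Remaining windows get a neighbor-joining tree rooted
#' on the outgroup, with bootstrap supports when `config$n_boot > 0`.
#'
#' @param windows list of `alignment_window` objects (typically the
#'   `retained` element of [filter_windows()]).
#' @param config a [scan_config()].
#' @param seed integer seed; per-window bootstrap seeds are derived from it.
#' @return list with `trees` (list of entries: `id`, `chrom`, `start`,
#'   `end`, `tree`) and `skipped` (data frame: `id`, `reason`).
#' @export
window_trees <- function(windows, config, seed = 1L) {
  trees <- list()
  skipped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  need <- c(config$focal, config$expected_sister, config$outgroup)
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    id <- sprintf("%s:%d-%d", w$chrom, w$start, w$end)
    skip <- function(reason) {
      data.frame(id = id, reason = reason, stringsAsFactors = FALSE)
    }
    if (ncol(w$mat) == 0) {
      skipped <- rbind(skipped, skip("empty window"))
      next
    }
    det_frac <- rowMeans(matrix(is_determined(w$mat), nrow = nrow(w$mat)))
    keep <- w$taxa[det_frac >= config$min_taxon_determined]
    if (!all(need %in% keep)) {
      skipped <- rbind(skipped, skip("focal/sister/outgroup dropped"))
      next
    }
    if (length(keep) < 4) {
      skipped <- rbind(skipped, skip("fewer than 4 usable taxa"))
      next
    }
    sub <- w
    sub$mat <- w$mat[keep, , drop = FALSE]
    sub$taxa <- keep
    pd <- pairwise_distances(sub$mat)
    if (any(is.na(pd$d))) {
      skipped <- rbind(skipped, skip("missing or saturated pair distance"))
      next
    }
    tree <- if (config$n_boot > 0) {
      bootstrap_tree(sub, config$n_boot, config$outgroup,
                     seed = derive_seed(seed, wi))
    } else {
      build_tree(pd$d, config$outgroup)
    }
    trees[[length(trees) + 1L]] <- list(
      id = id, chrom = w$chrom, start = w$start, end = w$end, tree = tree
    )
  }
  list(trees = trees, skipped = skipped)
}

#' Write window trees as Newick plus an index table
#'
#' One Newick file per chromosome (branch lengths, integer support labels)
#' and a tab-separated index (window id, chrom, start, end, newick).
#'
#' @param wt result of [window_trees()].
#' @param prefix output path prefix; files are written as
#'   `<prefix>_<chrom>.nwk` and `<prefix>_index.tsv`.
#' @return invisibly, the index path.
#' @export
write_window_trees <- function(wt, prefix) {
  idx <- data.frame(
    id = vapply(wt$trees, `[[`, character(1), "id"),
    chrom = vapply(wt$trees, `[[`, character(1), "chrom"),
    start = vapply(wt$trees, `[[`, numeric(1), "start"),
    end = vapply(wt$trees, `[[`, numeric(1), "end"),
    newick = vapply(wt$trees, function(e) {
      ape::write.tree(e$tree)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  for (chrom in unique(idx$chrom)) {
    writeLines(idx$newick[idx$chrom == chrom],
               paste0(prefix, "_", chrom, ".nwk"))
  }
  path <- paste0(prefix, "_index.tsv")
  utils::write.table(idx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
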