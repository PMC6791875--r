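# Topology canonicalization, per-window relationship classification, and
# topology tallies.

#' Canonical string form of a rooted topology
#'
#' Strips branch lengths and supports and renders the topology as a nested
#' parenthesis string in which every node's children are ordered by their
#' smallest descendant leaf label. Two rooted trees have the same canonical
#' string iff they have the same labelled topology.
#'
#' @param tree an [ape::phylo] (rooted).
#' @param drop_outgroup drop this tip before canonicalizing (`NULL` keeps
#'   all tips).
#' @return character scalar, e.g. `"((bwambae,fontenillei),quadriannulatus)"`.
#' @export
canonical_topology <- function(tree, drop_outgroup = NULL) {
  if (!is.null(drop_outgroup) && drop_outgroup %in% tree$tip.label) {
    tree <- ape::drop.tip(tree, drop_outgroup)
  }
  n_tip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1],
                                       levels = seq_len(n_tip + tree$Nnode)))
  canon <- function(node) {
    ch <- kids[[node]]
    if (length(ch) == 0) {
      return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    }
    parts <- lapply(ch, canon)
    mins <- vapply(parts, `[[`, character(1), "min")
    ord <- order(mins)
    list(
      str = paste0("(", paste(vapply(parts[ord], `[[`, character(1), "str"),
                              collapse = ","), ")"),
      min = min(mins)
    )
  }
  canon(n_tip + 1L)$str
}

# descendant tip label sets for every node of a tree
#' @noRd
tip_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

# map a neighbour taxon set to a configured clade name, a single taxon, or
# a sorted comma list
#' @noRd
map_clade_label <- function(set, clade_definitions) {
  if (length(set) == 1) return(set)
  for (nm in names(clade_definitions)) {
    if (setequal(set, clade_definitions[[nm]])) return(nm)
  }
  paste(sort(set), collapse = ",")
}

#' Classify the focal taxon's placement in one window tree
#'
#' Tests, on the outgroup-rooted tree with the outgroup then removed,
#' whether the focal taxon and its expected sister form a clade
#' ("after-speciation" pattern). If they do, the reported neighbour is the
#' smallest clade sister to that pair; if not ("before-speciation"), it is
#' the sister group of the focal taxon alone. Neighbour sets matching a
#' configured clade definition are reported under the clade's name.
#'
#' @param tree rooted window tree containing focal, expected sister and
#'   outgroup.
#' @param config a [scan_config()].
#' @return one-row data frame: `sister_ok`, `after_label`, `before_label`
#'   (exactly one of the labels set), `class`
#'   (`"after:<label>"`/`"before:<label>"`) and `topology` (canonical
#'   ingroup topology string).
#' @export
classify_window <- function(tree, config) {
  need <- c(config$focal, config$expected_sister, config$outgroup)
  if (!all(need %in% tree$tip.label)) {
    stop("tree lacks focal, expected sister or outgroup taxon")
  }
  ing <- ape::drop.tip(tree, config$outgroup)
  sets <- tip_sets(ing)
  n_tip <- ape::Ntip(ing)
  target <- sort(c(config$focal, config$expected_sister))
  fb_node <- NA_integer_
  for (v in (n_tip + 1L):(n_tip + ing$Nnode)) {
    if (length(sets[[v]]) == 2 && identical(sort(sets[[v]]), target)) {
      fb_node <- v
      break
    }
  }
  sibling_set <- function(node) {
    parent <- ing$edge[ing$edge[, 2] == node, 1]
    if (length(parent) == 0) return(character(0)) # node is the root
    sibs <- setdiff(ing$edge[ing$edge[, 1] == parent, 2], node)
    sort(unique(unlist(sets[sibs])))
  }
  sister_ok <- !is.na(fb_node)
  if (sister_ok) {
    nb <- sibling_set(fb_node)
    after <- if (length(nb) == 0) NA_character_
             else map_clade_label(nb, config$clade_definitions)
    before <- NA_character_
    label <- after
  } else {
    nb <- sibling_set(match(config$focal, ing$tip.label))
    before <- if (length(nb) == 0) NA_character_
              else map_clade_label(nb, config$clade_definitions)
    after <- NA_character_
    label <- before
  }
  data.frame(
    sister_ok = sister_ok, after_label = after, before_label = before,
    class = paste0(if (sister_ok) "after:" else "before:", label),
    topology = canonical_topology(ing),
    stringsAsFactors = FALSE
  )
}

#' Classify every window tree of a scan
#'
#' Applies [classify_window()] across the trees from [window_trees()];
#' windows whose trees lack a required taxon are skipped with a reason.
#'
#' @param wt result of [window_trees()].
#' @param config a [scan_config()].
#' @return list with `calls` (data frame: id, chrom, start, end, sister_ok,
#'   after_label, before_label, class, topology) and `skipped` (id,
#'   reason; includes the upstream tree-stage skips).
#' @export
classify_windows <- function(wt, config) {
  calls <- data.frame()
  skipped <- wt$skipped
  for (e in wt$trees) {
    need <- c(config$focal, config$expected_sister, config$outgroup)
    if (!all(need %in% e$tree$tip.label)) {
      skipped <- rbind(skipped, data.frame(
        id = e$id, reason = "required taxon missing from tree",
        stringsAsFactors = FALSE
      ))
      next
    }
    row <- classify_window(e$tree, config)
    calls <- rbind(calls, cbind(
      data.frame(id = e$id, chrom = e$chrom, start = e$start, end = e$end,
                 stringsAsFactors = FALSE),
      row
    ))
  }
  list(calls = calls, skipped = skipped)
}

#' Tally canonical topologies and the sister-clade proportion
#'
#' Counts canonical topology strings genome-wide and per chromosome, and
#' reports the proportion of windows in which the focal taxon and its
#' expected sister form a clade. Percentages are reported to 0.1.
#'
#' @param calls the `calls` data frame from [classify_windows()] (columns
#'   `chrom`, `sister_ok`, `topology`).
#' @return list with `genome` (topology, n, pct), `by_chrom` (chrom,
#'   topology, n, pct within chromosome) and `sister` (n_sister, n_total,
#'   pct).
#' @export
tally_topologies <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) {
    empty <- data.frame(topology = character(), n = integer(),
                        pct = numeric(), stringsAsFactors = FALSE)
    return(list(genome = empty,
                by_chrom = cbind(data.frame(chrom = character()), empty),
                sister = data.frame(n_sister = 0L, n_total = 0L,
                                    pct = NA_real_)))
  }
  tally_one <- function(df) {
    tb <- sort(table(df$topology), decreasing = TRUE)
    data.frame(topology = names(tb), n = as.integer(tb),
               pct = round(100 * as.integer(tb) / nrow(df), 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  genome <- tally_one(calls)
  by_chrom <- do.call(rbind, lapply(split(calls, calls$chrom), function(df) {
    cbind(data.frame(chrom = df$chrom[1], stringsAsFactors = FALSE),
          tally_one(df))
  }))
  rownames(by_chrom) <- NULL
  sister <- data.frame(
    n_sister = sum(calls$sister_ok),
    n_total = nrow(calls),
    pct = round(100 * sum(calls$sister_ok) / nrow(calls), 1)
  )
  list(genome = genome, by_chrom = by_chrom, sister = sister)
}
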