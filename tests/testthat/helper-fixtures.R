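# Shared fixtures and independent oracles for the test suite.

# --- small species trees -------------------------------------------------

# 4-taxon tree for coalescent calibration: ((A,B),C) with outgroup O;
# internal branch duration = t2 - t1 generations
quartet_tree <- function(t1 = 10000, t2 = 20000, t_out = 100000, ne = 1e4) {
  nwk <- sprintf("(O:%d,((A:%d,B:%d):%d,C:%d):%d);",
                 t_out, t1, t1, t2 - t1, t2, t_out - t2)
  species_tree(ape::read.tree(text = nwk), ne = ne, outgroup = "O")
}

# two-taxon-plus-outgroup tree with a known split, for dating round trips
pair_tree <- function(split_gens, t_out = 4e7, ne = 2e4) {
  nwk <- sprintf("(O:%0.f,(A:%0.f,B:%0.f):%0.f);",
                 t_out, split_gens, split_gens, t_out - split_gens)
  species_tree(ape::read.tree(text = nwk), ne = ne, outgroup = "O")
}

# --- random additive matrices --------------------------------------------

# distance matrix that is exactly additive on a random unrooted topology
random_additive <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, rooted = FALSE, br = NULL)
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 1)
  phy$tip.label <- sort(phy$tip.label)[sample.int(n)]
  list(phy = phy, D = ape::cophenetic.phylo(phy))
}

# brute-force least-squares topology search over all unrooted topologies
# (exhaustive; practical for n <= 6)
ls_best_topology <- function(D) {
  labs <- rownames(D)
  all_t <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  ss <- vapply(all_t, function(tr) {
    fit <- phangorn::nnls.tree(as.dist(D), tr)
    sum((ape::cophenetic.phylo(fit)[labs, labs] - D)^2)
  }, numeric(1))
  all_t[[which.min(ss)]]
}

# unrooted topology equality via Robinson-Foulds distance
same_topology <- function(a, b) {
  phangorn::RF.dist(ape::unroot(a), ape::unroot(b)) == 0
}

# --- brute-force oracles -------------------------------------------------

# patristic distance by explicit root-path intersection (LCA)
brute_patristic <- function(tree, a, b) {
  to_root <- function(tip) {
    node <- match(tip, tree$tip.label)
    path <- node
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      node <- tree$edge[e, 1]
      path <- c(path, node)
    }
    path
  }
  pa <- to_root(a)
  pb <- to_root(b)
  lca <- intersect(pa, pb)[1]
  seg <- function(path) {
    out <- 0
    for (k in seq_len(match(lca, path) - 1)) {
      e <- which(tree$edge[, 1] == path[k + 1] & tree$edge[, 2] == path[k])
      out <- out + tree$edge.length[e]
    }
    out
  }
  seg(pa) + seg(pb)
}

# clade-enumeration classification oracle: enumerate all clades of the
# outgroup-rooted, outgroup-pruned tree and apply the relationship rule
brute_classify <- function(tree, config) {
  ing <- ape::drop.tip(tree, config$outgroup)
  n_tip <- ape::Ntip(ing)
  clades <- lapply((n_tip + 1):(n_tip + ing$Nnode), function(v) {
    sort(ing$tip.label[unlist(phangorn::Descendants(ing, v, "tips"))])
  })
  pairset <- sort(c(config$focal, config$expected_sister))
  sister_ok <- any(vapply(clades, function(cl) identical(cl, pairset),
                          logical(1)))
  # neighbour = smallest clade strictly containing the unit, minus the unit
  unit <- if (sister_ok) pairset else config$focal
  wrap <- c(clades, list(sort(ing$tip.label)))
  containing <- wrap[vapply(wrap, function(cl) {
    all(unit %in% cl) && length(cl) > length(unit)
  }, logical(1))]
  smallest <- containing[[which.min(lengths(containing))]]
  list(sister_ok = sister_ok, neighbour = setdiff(smallest, unit))
}

# --- misc ----------------------------------------------------------------

# build an alignment_window directly from a taxa x columns matrix
window_from_matrix <- function(mat, chrom = "chrT", start = 0,
                               end = ncol(mat)) {
  phyloscan:::new_alignment_window(chrom, start, end, mat)
}

# a deterministic clean alignment: identical sequences with fixed
# differences between clades, no homoplasy
clean_alignment <- function(taxa_groups, n_rep = 50,
                            extra_taxa = character()) {
  # taxa_groups: list of character vectors; each group gets a private
  # diagnostic column pattern repeated n_rep times. extra_taxa (e.g. the
  # outgroup) carry the background state everywhere.
  taxa <- unique(c(unlist(taxa_groups), extra_taxa))
  cols <- list()
  for (gi in seq_along(taxa_groups)) {
    col <- setNames(rep("A", length(taxa)), taxa)
    col[taxa_groups[[gi]]] <- "G"
    cols <- c(cols, replicate(n_rep, col, simplify = FALSE))
  }
  cols <- c(cols, replicate(n_rep, setNames(rep("C", length(taxa)), taxa),
                            simplify = FALSE))
  mat <- do.call(cbind, cols)
  rownames(mat) <- taxa
  mat
}
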