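# Species trees for the coalescent simulator: an ultrametric, rooted
# topology with node ages in generations and per-branch haploid effective
# population sizes.

#' Construct a species tree for simulation
#'
#' Wraps a rooted, ultrametric `phylo` tree whose branch lengths are in
#' generations, together with per-branch haploid effective population sizes,
#' into a `species_tree` object understood by the simulator. The designated
#' outgroup must attach at the root.
#'
#' @param phy an [ape::phylo] rooted tree, branch lengths in generations,
#'   ultrametric (all tips at age 0).
#' @param ne haploid effective population size: either a single number used
#'   for every branch (and the root population), or a vector of length
#'   `nrow(phy$edge) + 1` (one per edge, root population last).
#' @param outgroup tip label of the outgroup; must be a child of the root.
#' @return an object of class `species_tree`: list with elements `phy`,
#'   `ne`, `outgroup`, `ages` (node ages in generations) and `tab` (the
#'   tabular population-tree form used by the coalescent sampler).
#' @seealso [gambiae_complex_tree()] for the default nine-taxon tree.
#' @export
species_tree <- function(phy, ne = 2e4, outgroup = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  ages <- node_ages(phy)
  tip_ages <- ages[seq_len(ape::Ntip(phy))]
  if (max(abs(tip_ages)) > 1e-6 * max(ages)) {
    stop("species tree must be ultrametric (all tips at age 0)")
  }
  if (any(ages[-seq_len(ape::Ntip(phy))] <= 0)) {
    stop("all internal node ages must be > 0")
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label) stop("outgroup not in tree: ", outgroup)
    root <- ape::Ntip(phy) + 1L
    og_tip <- match(outgroup, phy$tip.label)
    if (!any(phy$edge[, 1] == root & phy$edge[, 2] == og_tip)) {
      stop("outgroup must attach at the root")
    }
  }
  n_edge <- nrow(phy$edge)
  if (length(ne) == 1) ne <- rep(ne, n_edge + 1L)
  if (length(ne) != n_edge + 1L) {
    stop("ne must be scalar or one value per edge plus the root population")
  }
  if (any(ne <= 0)) stop("effective population sizes must be positive")
  obj <- structure(
    list(phy = phy, ne = ne, outgroup = outgroup, ages = ages),
    class = "species_tree"
  )
  obj$tab <- species_tree_table(obj)
  obj
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", ape::Ntip(x$phy), "taxa, root age",
      format(max(x$ages), big.mark = ","), "generations\n")
  cat("  taxa:", paste(sort(x$phy$tip.label), collapse = ", "), "\n")
  if (!is.null(x$outgroup)) cat("  outgroup:", x$outgroup, "\n")
  cat("  Ne range:", paste(range(x$ne), collapse = " - "), "(haploid)\n")
  invisible(x)
}

# node ages (generations above the tips) for an ultrametric-ish phylo
#' @noRd
node_ages <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  max(depths) - depths
}

# tabular population-tree form: one row per node; the branch above node i
# (from age[i] to age[parent]) is a population with size ne[i].
#' @noRd
species_tree_table <- function(st) {
  phy <- st$phy
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  ne_node <- rep(NA_real_, n_node)
  for (e in seq_len(nrow(phy$edge))) {
    parent[phy$edge[e, 2]] <- phy$edge[e, 1]
    ne_node[phy$edge[e, 2]] <- st$ne[e]
  }
  root <- n_tip + 1L
  ne_node[root] <- st$ne[length(st$ne)]
  data.frame(
    node = seq_len(n_node),
    parent = parent,
    age = st$ages,
    ne = ne_node,
    label = c(phy$tip.label, rep(NA_character_, phy$Nnode)),
    stringsAsFactors = FALSE
  )
}

#' Default nine-taxon species tree of the An. gambiae complex
#'
#' A dated species tree emulating the X-chromosome species topology of the
#' *Anopheles gambiae* complex with the sylvatic taxon *An. fontenillei*
#' placed as sister to *An. bwambae*: outgroup *An. christyi*, a complex
#' radiation at ~2 Ma, the gambiae-coluzzii split at 0.31 Ma and the
#' fontenillei-bwambae split at 0.53 Ma, converted to generations at 10
#' generations per year. Node ages (Ma): christyi 4.0, radiation 2.0,
#' melas 1.9, merus vs (gambiae,coluzzii) 1.8, arabiensis 1.6,
#' quadriannulatus 1.25, fontenillei-bwambae 0.53, gambiae-coluzzii 0.31.
#'
#' @param ne haploid effective population size per branch (default 5e3;
#'   see the methods vignette for the rationale).
#' @param gens_per_year generations per year used to convert ages (default 10).
#' @return a [species_tree()] object.
#' @export
gambiae_complex_tree <- function(ne = 5e3, gens_per_year = 10) {
  scale <- gens_per_year * 1e6 # generations per Ma
  nwk <- sprintf(
    paste0(
      "(christyi:%0.f,((merus:%0.f,(gambiae:%0.f,coluzzii:%0.f):%0.f):%0.f,",
      "(melas:%0.f,(arabiensis:%0.f,(quadriannulatus:%0.f,",
      "(fontenillei:%0.f,bwambae:%0.f):%0.f):%0.f):%0.f):%0.f):%0.f);"
    ),
    4.0 * scale,                       # christyi pendant
    1.8 * scale, 0.31 * scale, 0.31 * scale, (1.8 - 0.31) * scale,
    (2.0 - 1.8) * scale,
    1.9 * scale, 1.6 * scale, 1.25 * scale,
    0.53 * scale, 0.53 * scale, (1.25 - 0.53) * scale,
    (1.6 - 1.25) * scale, (1.9 - 1.6) * scale, (2.0 - 1.9) * scale,
    (4.0 - 2.0) * scale
  )
  species_tree(ape::read.tree(text = nwk), ne = ne, outgroup = "christyi")
}

#' Inversion-genealogy override tree for the 3La-like region
#'
#' Species tree used inside the simulated inversion: the inverted-karyotype
#' clade (fontenillei, bwambae, melas) separates from all standard-karyotype
#' taxa before the complex radiation (2.53 Ma vs 2.0 Ma), emulating an
#' inversion genealogy that predates the radiation. Within the inverted
#' clade, melas joins the fontenillei-bwambae pair at 1.9 Ma; among the
#' standard taxa, arabiensis and quadriannulatus pair at 1.6 Ma.
#'
#' @inheritParams gambiae_complex_tree
#' @return a [species_tree()] object over the same nine taxa.
#' @export
inversion_override_tree <- function(ne = 5e3, gens_per_year = 10) {
  scale <- gens_per_year * 1e6
  nwk <- sprintf(
    paste0(
      "(christyi:%0.f,(((fontenillei:%0.f,bwambae:%0.f):%0.f,melas:%0.f):%0.f,",
      "((merus:%0.f,(gambiae:%0.f,coluzzii:%0.f):%0.f):%0.f,",
      "(arabiensis:%0.f,quadriannulatus:%0.f):%0.f):%0.f):%0.f);"
    ),
    4.0 * scale,
    0.53 * scale, 0.53 * scale, (1.9 - 0.53) * scale, 1.9 * scale,
    (2.53 - 1.9) * scale,
    1.8 * scale, 0.31 * scale, 0.31 * scale, (1.8 - 0.31) * scale,
    (2.0 - 1.8) * scale,
    1.6 * scale, 1.6 * scale, (2.0 - 1.6) * scale, (2.53 - 2.0) * scale,
    (4.0 - 2.53) * scale
  )
  species_tree(ape::read.tree(text = nwk), ne = ne, outgroup = "christyi")
}

#' True pairwise split ages of a species tree
#'
#' @param st a [species_tree()] object.
#' @param gens_per_year generations per year for the Ma conversion.
#' @return data frame with columns `taxon_a`, `taxon_b`, `split_generations`,
#'   `split_ma`.
#' @export
split_ages <- function(st, gens_per_year = 10) {
  phy <- st$phy
  tips <- phy$tip.label
  mrca <- ape::mrca(phy)
  out <- data.frame()
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      if (i < j) {
        age <- st$ages[mrca[tips[i], tips[j]]]
        out <- rbind(out, data.frame(
          taxon_a = min(tips[i], tips[j]), taxon_b = max(tips[i], tips[j]),
          split_generations = age, split_ma = age / (gens_per_year * 1e6),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  out[order(out$taxon_a, out$taxon_b), , drop = FALSE]
}
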