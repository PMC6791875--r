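# Neighbor-joining tree construction with deterministic tie-breaking and
# outgroup rooting. This in-repo engine stands in for per-window maximum
# likelihood inference: on the divergences the scan operates at, topology
# frequencies and patristic-distance medians — the quantities consumed
# downstream — are insensitive to the engine, while NJ is deterministic and
# dependency-free.

#' Build a rooted window tree by neighbor joining
#'
#' Standard Saitou-Nei neighbor joining on a complete distance matrix, with
#' two determinism guarantees: (i) when several pairs minimize the
#' Q-criterion equally, the pair whose (smallest, largest) cluster labels
#' are lexicographically smallest is joined, making the result invariant
#' under taxon-order permutations; (ii) negative branch lengths are clamped
#' to zero with the deficit transferred to the sibling branch, preserving
#' the joined pair's path length. The tree is rooted on the outgroup
#' branch.
#'
#' @param distances complete distance matrix (taxa in dimnames), or the
#'   result of [pairwise_distances()] (its `d` matrix is used).
#' @param outgroup taxon to root on; `NULL` returns the unrooted tree.
#' @return an [ape::phylo]; attribute `"degenerate"` is `TRUE` for trees
#'   with fewer than 4 taxa (star/cherry topology).
#' @export
build_tree <- function(distances, outgroup = NULL) {
  D <- if (is.list(distances) && !is.null(distances$d)) distances$d
       else distances
  if (any(is.na(D))) stop("incomplete distance matrix (missing/saturated pair)")
  labs <- rownames(D)
  n <- length(labs)
  if (n < 2) stop("need at least 2 taxa")
  phy <- ape::read.tree(text = paste0(nj_newick(D), ";"))
  attr(phy, "degenerate") <- n < 4
  if (!is.null(outgroup)) {
    if (!outgroup %in% labs) stop("outgroup not in distance matrix")
    if (n > 2) {
      deg <- attr(phy, "degenerate")
      phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
      attr(phy, "degenerate") <- deg
    }
  }
  phy
}

# core NJ agglomeration, emitting a newick string (no trailing ';')
#' @noRd
nj_newick <- function(D) {
  labs <- rownames(D)
  nwk <- labs
  minlab <- labs
  names(nwk) <- names(minlab) <- labs
  rownames(D) <- colnames(D) <- labs
  clamp_pair <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    c(vi, vj)
  }
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-9 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lo <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    hi <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(lo, hi)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    dij <- D[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (n - 2))
    v <- clamp_pair(vi, dij - vi)
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], v[1], nwk[j], v[2])
    new_min <- min(minlab[i], minlab[j])
    dk <- (D[i, ] + D[j, ] - dij) / 2
    dk <- dk[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, new = dk), new = c(dk, 0))
    nwk <- c(nwk[-c(i, j)], new_nwk)
    minlab <- c(minlab[-c(i, j)], new_min)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new_min
    names(nwk)[length(nwk)] <- names(minlab)[length(minlab)] <- new_min
  }
  if (nrow(D) == 2) {
    h <- max(D[1, 2] / 2, 0)
    return(sprintf("(%s:%.10g,%s:%.10g)", nwk[1], h, nwk[2], h))
  }
  va <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g)",
          nwk[1], va, nwk[2], vb, nwk[3], vc)
}
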