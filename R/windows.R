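# Partitioning a reference-anchored alignment into fixed non-overlapping
# windows, and the informative-site filter.

#' Scan configuration
#'
#' Parameters shared by the windowing, tree-inference and classification
#' stages. Defaults follow the genome-scan conventions for the
#' *An. gambiae* complex: 50 kb non-overlapping windows, windows with fewer
#' than 10% informative positions (absolute threshold
#' `min_informative_fraction * window_size`, i.e. < 5,000 bp at defaults)
#' excluded. An informative position here is an alignment column with a
#' determined base (non-gap, non-N) in every taxon.
#'
#' @param focal focal taxon whose placement is classified per window.
#' @param expected_sister expected sister taxon of the focal taxon.
#' @param outgroup outgroup taxon used to root every window tree.
#' @param window_size window size in bp (default 50,000).
#' @param min_informative_fraction minimum informative fraction of
#'   `window_size` for a window to be retained (default 0.10; exclusion is
#'   strict: a window at exactly the threshold is kept).
#' @param clade_definitions named list of taxon sets; when the neighbour
#'   group of a classified window matches one exactly, its name is reported
#'   (e.g. `list(GC = c("gambiae", "coluzzii"))`).
#' @param min_taxon_determined minimum fraction of determined characters a
#'   taxon needs in a window to be kept in that window's tree (default 0.5).
#' @param n_boot bootstrap replicates per window tree (default 1000).
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(focal, expected_sister, outgroup,
                        window_size = 50000,
                        min_informative_fraction = 0.10,
                        clade_definitions = list(),
                        min_taxon_determined = 0.5,
                        n_boot = 1000) {
  if (anyDuplicated(c(focal, expected_sister, outgroup))) {
    stop("focal, expected_sister and outgroup must be distinct")
  }
  structure(
    list(focal = focal, expected_sister = expected_sister,
         outgroup = outgroup, window_size = window_size,
         min_informative_fraction = min_informative_fraction,
         clade_definitions = clade_definitions,
         min_taxon_determined = min_taxon_determined,
         n_boot = n_boot),
    class = "scan_config"
  )
}

#' @noRd
new_alignment_window <- function(chrom, start, end, mat) {
  structure(
    list(chrom = chrom, start = start, end = end,
         taxa = rownames(mat), mat = mat,
         informative_count = count_informative(mat)),
    class = "alignment_window"
  )
}

#' @export
print.alignment_window <- function(x, ...) {
  cat(sprintf("alignment_window %s:%d-%d  %d taxa, %d columns, %d informative\n",
              x$chrom, x$start, x$end, length(x$taxa), ncol(x$mat),
              x$informative_count))
  invisible(x)
}

# columns with a determined character in every row
#' @noRd
count_informative <- function(mat) {
  if (ncol(mat) == 0) return(0L)
  det <- matrix(is_determined(mat), nrow = nrow(mat))
  sum(colSums(det) == nrow(mat))
}

#' Partition alignment blocks into fixed windows on reference coordinates
#'
#' Tiles each reference chromosome with non-overlapping windows of
#' `config$window_size` bp and assigns every alignment column to the window
#' containing its reference coordinate (columns where the reference is
#' gapped — insertions — are assigned to the window of the preceding
#' reference base). Columns from multiple blocks are concatenated in
#' coordinate order; taxa missing from a block are padded with gaps over
#' that block's columns. The terminal window of a chromosome may be
#' shorter than `window_size`.
#'
#' @param blocks list of alignment blocks from [read_maf()] or
#'   [simulate_maf()], sorted by reference coordinate.
#' @param config a [scan_config()].
#' @return list of `alignment_window` objects ordered by chromosome and
#'   start, tiling `[0, chrom_length)` of every chromosome seen.
#' @export
partition_windows <- function(blocks, config) {
  if (length(blocks) == 0) return(list())
  ws <- config$window_size
  ref_taxon <- blocks[[1]]$taxa[1]
  all_taxa <- unique(unlist(lapply(blocks, `[[`, "taxa")))
  all_taxa <- c(ref_taxon, setdiff(all_taxa, ref_taxon))
  ref_chrom <- vapply(blocks, function(b) b$chrom[[b$taxa[1]]], character(1))
  windows <- list()
  for (chrom in unique(ref_chrom)) {
    bs <- blocks[ref_chrom == chrom]
    starts <- vapply(bs, function(b) b$start[[b$taxa[1]]], numeric(1))
    bs <- bs[order(starts)]
    starts <- sort(starts)
    ends <- vapply(bs, function(b) {
      b$start[[b$taxa[1]]] + b$size[[b$taxa[1]]]
    }, numeric(1))
    if (any(starts[-1] < ends[-length(ends)])) {
      stop("overlapping reference coordinates across MAF blocks on ", chrom)
    }
    chrom_len <- bs[[1]]$srcSize[[bs[[1]]$taxa[1]]]
    win_starts <- seq(0, chrom_len - 1, by = ws)
    acc <- vector("list", length(win_starts))
    for (b in bs) {
      mat <- do.call(rbind, lapply(b$seqs[b$taxa], seq_to_chars))
      rownames(mat) <- b$taxa
      missing <- setdiff(all_taxa, b$taxa)
      if (length(missing) > 0) {
        pad <- matrix("-", nrow = length(missing), ncol = ncol(mat),
                      dimnames = list(missing, NULL))
        mat <- rbind(mat, pad)
      }
      mat <- mat[all_taxa, , drop = FALSE]
      refc <- mat[ref_taxon, ]
      idx <- cumsum(refc != "-")
      coord <- b$start[[ref_taxon]] + pmax(idx - 1, 0)
      wi <- coord %/% ws + 1L
      for (w in unique(wi)) {
        acc[[w]] <- c(acc[[w]], list(mat[, wi == w, drop = FALSE]))
      }
    }
    for (w in seq_along(win_starts)) {
      m <- if (is.null(acc[[w]])) {
        matrix(character(0), nrow = length(all_taxa), ncol = 0,
               dimnames = list(all_taxa, NULL))
      } else {
        do.call(cbind, acc[[w]])
      }
      windows[[length(windows) + 1L]] <- new_alignment_window(
        chrom, win_starts[w], min(win_starts[w] + ws, chrom_len), m
      )
    }
  }
  windows
}

#' Apply the informative-site filter to windows
#'
#' A window is retained iff its number of informative columns (determined
#' base in every taxon) is at least
#' `min_informative_fraction * window_size` — an absolute threshold (5,000
#' bp at defaults) applied to terminal short windows as well. Exclusion is
#' strict: a window exactly at the threshold is retained.
#'
#' @param windows list of `alignment_window` objects.
#' @param config a [scan_config()].
#' @return list with elements `retained`, `excluded` (disjoint, exhaustive)
#'   and `log` (data frame: chrom, start, end, informative, retained).
#' @export
filter_windows <- function(windows, config) {
  thr <- config$min_informative_fraction * config$window_size
  inf <- vapply(windows, `[[`, numeric(1), "informative_count")
  keep <- inf >= thr
  log <- data.frame(
    chrom = vapply(windows, `[[`, character(1), "chrom"),
    start = vapply(windows, `[[`, numeric(1), "start"),
    end = vapply(windows, `[[`, numeric(1), "end"),
    informative = inf,
    retained = keep,
    stringsAsFactors = FALSE
  )
  list(retained = windows[keep], excluded = windows[!keep], log = log)
}

#' Alignment summary statistics of one window
#'
#' Reports the aligned length, the length after removing completely
#' undetermined columns (no determined base in any taxon), the proportion
#' of gap characters, and the number of distinct column patterns among the
#' non-undetermined columns.
#'
#' @param window an `alignment_window`.
#' @return list with `aligned_length`, `length_determined`, `gap_fraction`,
#'   `n_patterns`.
#' @export
alignment_stats <- function(window) {
  mat <- window$mat
  if (ncol(mat) == 0) {
    return(list(aligned_length = 0L, length_determined = 0L,
                gap_fraction = NA_real_, n_patterns = 0L))
  }
  det <- matrix(is_determined(mat), nrow = nrow(mat))
  keep <- colSums(det) > 0
  patterns <- apply(mat[, keep, drop = FALSE], 2, paste, collapse = "")
  list(
    aligned_length = ncol(mat),
    length_determined = sum(keep),
    gap_fraction = mean(mat == "-"),
    n_patterns = length(unique(patterns))
  )
}
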