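# Segmentation of per-window relationship classes into topology blocks,
# and region-wise contrasts (e.g. centromere-proximal vs the rest).

#' Segment classified windows into topology blocks
#'
#' Finds maximal runs of consecutive windows sharing a relationship class,
#' per chromosome. Runs shorter than `min_run` are merged into the longer
#' flanking run (ties and chromosome edges resolve leftward). The
#' breakpoint interval between two adjacent blocks is the gap between the
#' end of the left block's last window and the start of the right block's
#' first window (degenerate when windows are contiguous).
#'
#' @param calls data frame with columns `chrom`, `start`, `end`, `class`,
#'   sorted by coordinate within chromosome (the `calls` element of
#'   [classify_windows()]).
#' @param min_run minimum run length in windows (default 1: no smoothing).
#' @return data frame, one row per block: `chrom`, `class`, `first_start`,
#'   `last_end`, `n_windows`, `left_bp_lo`, `left_bp_hi`, `right_bp_lo`,
#'   `right_bp_hi` (breakpoint intervals in bp; `NA` at chromosome ends).
#' @export
segment_blocks <- function(calls, min_run = 1) {
  if (min_run < 1) stop("min_run must be >= 1")
  out <- data.frame()
  for (chrom in unique(calls$chrom)) {
    df <- calls[calls$chrom == chrom, , drop = FALSE]
    df <- df[order(df$start), , drop = FALSE]
    cls <- df$class
    # absorb sub-minimal runs into the longer flanking run (ties -> left)
    repeat {
      r <- rle(cls)
      short <- which(r$lengths < min_run)
      if (length(short) == 0 || length(r$lengths) == 1) break
      k <- short[1]
      into <- if (k == 1) k + 1
              else if (k == length(r$lengths)) k - 1
              else if (r$lengths[k - 1] >= r$lengths[k + 1]) k - 1
              else k + 1
      idx_end <- cumsum(r$lengths)
      idx <- (idx_end[k] - r$lengths[k] + 1):idx_end[k]
      cls[idx] <- r$values[into]
    }
    r <- rle(cls)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    blocks <- data.frame(
      chrom = chrom, class = r$values,
      first_start = df$start[idx_start],
      last_end = df$end[idx_end],
      n_windows = r$lengths,
      stringsAsFactors = FALSE
    )
    nb <- nrow(blocks)
    blocks$left_bp_lo <- c(NA, blocks$last_end[-nb])
    blocks$left_bp_hi <- c(NA, blocks$first_start[-1])
    blocks$right_bp_lo <- c(blocks$last_end[-nb], NA)
    blocks$right_bp_hi <- c(blocks$first_start[-1], NA)
    out <- rbind(out, blocks)
  }
  rownames(out) <- NULL
  out
}

#' Write topology blocks as BED
#'
#' BED6-style output (0-based, half-open) with the relationship class in
#' the name column.
#'
#' @param blocks result of [segment_blocks()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(blocks$chrom, as.integer(blocks$first_start),
                    as.integer(blocks$last_end), blocks$class,
                    blocks$n_windows, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Contrast relationship classes between genomic region sets
#'
#' Assigns every classified window to exactly one named region by its
#' midpoint (windows matching no region fall into `"other"`), tabulates
#' relationship-class proportions per region, and optionally draws a seeded
#' subsample of windows per region for alignment-quality summaries.
#'
#' @param calls `calls` data frame from [classify_windows()].
#' @param regions data frame with columns `chrom`, `start`, `end`,
#'   `region` (named interval sets, e.g. centromere-proximal intervals);
#'   intervals must not overlap.
#' @param n_sample optional windows to subsample per region class.
#' @param seed seed for the subsample.
#' @param windows optional named list of `alignment_window` objects (names
#'   = window ids) for per-sample [alignment_stats()] summaries.
#' @return list with `counts` (region x class table), `proportions`
#'   (within-region class proportions), `sampled` (data frame of sampled
#'   window ids per region, if requested) and `stats` (mean alignment
#'   statistics over the sampled windows, if `windows` given).
#' @export
region_contrast <- function(calls, regions, n_sample = NULL, seed = 1L,
                            windows = NULL) {
  stopifnot(all(c("chrom", "start", "end", "region") %in% names(regions)))
  for (chrom in unique(regions$chrom)) {
    rg <- regions[regions$chrom == chrom, , drop = FALSE]
    rg <- rg[order(rg$start), , drop = FALSE]
    if (nrow(rg) > 1 && any(rg$start[-1] < rg$end[-nrow(rg)])) {
      stop("overlapping region definitions on ", chrom)
    }
  }
  mid <- (calls$start + calls$end) / 2
  region_of <- rep("other", nrow(calls))
  for (i in seq_len(nrow(regions))) {
    hit <- calls$chrom == regions$chrom[i] & mid >= regions$start[i] &
      mid < regions$end[i]
    region_of[hit] <- regions$region[i]
  }
  counts <- table(region = region_of, class = calls$class)
  proportions <- prop.table(counts, margin = 1)
  sampled <- NULL
  stats <- NULL
  if (!is.null(n_sample)) {
    sampled <- with_seed(seed, {
      do.call(rbind, lapply(unique(region_of), function(rg) {
        ids <- calls$id[region_of == rg]
        take <- ids[sample.int(length(ids), min(n_sample, length(ids)))]
        data.frame(region = rg, id = take, stringsAsFactors = FALSE)
      }))
    })
    if (!is.null(windows)) {
      stats <- do.call(rbind, lapply(split(sampled, sampled$region),
        function(df) {
          st <- lapply(df$id, function(id) alignment_stats(windows[[id]]))
          data.frame(
            region = df$region[1], n = nrow(df),
            mean_aligned = mean(vapply(st, `[[`, numeric(1),
                                       "aligned_length")),
            mean_determined = mean(vapply(st, `[[`, numeric(1),
                                          "length_determined")),
            mean_gap_fraction = mean(vapply(st, `[[`, numeric(1),
                                            "gap_fraction")),
            mean_patterns = mean(vapply(st, `[[`, numeric(1), "n_patterns")),
            stringsAsFactors = FALSE
          )
        }))
      rownames(stats) <- NULL
    }
  }
  list(counts = counts, proportions = proportions, sampled = sampled,
       stats = stats)
}
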