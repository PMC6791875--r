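# Jukes-Cantor pairwise distances from an alignment window.

#' Pairwise Jukes-Cantor distances within a window
#'
#' For each taxon pair, the per-site mismatch proportion `p` is computed
#' over the columns with a determined base (non-gap, non-N) in both taxa
#' and corrected to a Jukes-Cantor distance
#' `d = -3/4 * log(1 - 4p/3)`. Pairs sharing no determined column are
#' flagged missing; pairs at or beyond the JC saturation domain
#' (`p >= 0.75`) are flagged saturated. Both carry `NA` distances.
#'
#' @param window an `alignment_window` (or a plain character matrix with
#'   taxa as rows).
#' @return list with matrices `d` (JC distance), `p` (raw mismatch
#'   proportion), `shared` (column counts) and logical matrices `missing`
#'   and `saturated`; all symmetric with zero/FALSE diagonals.
#' @export
pairwise_distances <- function(window) {
  mat <- if (inherits(window, "alignment_window")) window$mat else window
  taxa <- rownames(mat)
  n <- length(taxa)
  # integer base codes: NA marks gaps/ambiguities, so comparisons stay in
  # fast integer arithmetic; both cases matched directly to avoid a
  # whole-matrix case conversion
  code <- match(mat, c("A", "C", "G", "T", "a", "c", "g", "t"))
  code <- matrix((code - 1L) %% 4L + 1L, nrow = n)
  d <- p <- matrix(0, n, n, dimnames = list(taxa, taxa))
  shared <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  missing <- saturated <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        diff <- code[i, ] - code[j, ]
        ns <- sum(!is.na(diff))
        shared[i, j] <- shared[j, i] <- ns
        if (ns == 0) {
          missing[i, j] <- missing[j, i] <- TRUE
          d[i, j] <- d[j, i] <- p[i, j] <- p[j, i] <- NA_real_
          next
        }
        pij <- sum(diff != 0, na.rm = TRUE) / ns
        p[i, j] <- p[j, i] <- pij
        if (pij >= 0.75) {
          saturated[i, j] <- saturated[j, i] <- TRUE
          d[i, j] <- d[j, i] <- NA_real_
        } else {
          d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * pij / 3)
        }
      }
    }
  }
  list(d = d, p = p, shared = shared, missing = missing,
       saturated = saturated)
}

#' Jukes-Cantor correction of a raw mismatch proportion
#'
#' @param p per-site mismatch proportion in `[0, 0.75)`.
#' @return JC-corrected distance in substitutions/site (`NA` for
#'   `p >= 0.75`).
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}
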