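# Placing de novo assembly scaffolds into a reference-anchored alignment:
# homology search (in-repo seed-and-extend matcher with Karlin-Altschul
# e-values), the unique-hit selection rule, and column-preserving grafting
# of the placed sequence as a new taxon row.

#' Homology search of a query region against a scaffold set
#'
#' Seed-and-extend local alignment: exact seeds of `word_size` bp are
#' located in each scaffold (both strands), clustered by diagonal, and each
#' cluster is refined by gapped local (Smith-Waterman) alignment of the
#' query against the clustered scaffold segment. E-values follow the
#' Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)` with a
#' database-size correction (`n` = total scaffold length); `lambda` and `K`
#' default to standard blastn-like values for the +2/-3 nucleotide scoring
#' scheme. Coverage is the fraction of query bases inside the hit's
#' aligned span.
#'
#' @param query query sequence (character scalar, A/C/G/T).
#' @param scaffolds named character vector of scaffold sequences.
#' @param word_size exact-seed length (default 11).
#' @param match,mismatch match reward / mismatch penalty (default +2/-3).
#' @param gap_open,gap_extend gap penalties (default 5/2, non-negative).
#' @param lambda,karlin_k Karlin-Altschul parameters (defaults 0.625/0.41).
#' @param ungapped_min minimum best ungapped-segment score along a seed
#'   cluster's modal diagonal for the cluster to reach gapped refinement
#'   (default 40; filters isolated chance word matches).
#' @param evalue_ceiling hits with larger e-value are not reported
#'   (default 10).
#' @return data frame of hits: `scaffold`, `s_start`, `s_end` (1-based,
#'   inclusive, forward strand), `strand`, `score`, `evalue`, `coverage`,
#'   `q_start`, `q_end` (query orientation); zero rows when nothing is
#'   found.
#' @export
search_homologs <- function(query, scaffolds, word_size = 11,
                            match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2,
                            lambda = 0.625, karlin_k = 0.41,
                            ungapped_min = 40, evalue_ceiling = 10) {
  if (length(scaffolds) == 0) stop("empty scaffold set")
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds)))) {
    stop("scaffolds must be named")
  }
  query <- toupper(query)
  qlen <- nchar(query)
  db_len <- sum(nchar(scaffolds))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  hits <- data.frame()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp_chr(query)
    qwords <- kmer_positions(q, word_size)
    if (length(qwords) == 0) next
    for (sc in names(scaffolds)) {
      subj <- toupper(scaffolds[[sc]])
      swords <- kmer_positions(subj, word_size)
      common <- intersect(names(qwords), names(swords))
      if (length(common) == 0) next
      seeds <- do.call(rbind, lapply(common, function(w) {
        expand.grid(qpos = qwords[[w]], spos = swords[[w]])
      }))
      seeds$diag <- seeds$spos - seeds$qpos
      # cluster seeds whose diagonals fall within a narrow band
      seeds <- seeds[order(seeds$diag, seeds$spos), , drop = FALSE]
      band <- 2 * word_size
      grp <- cumsum(c(TRUE, diff(seeds$diag) > band))
      for (g in unique(grp)) {
        cl <- seeds[grp == g, , drop = FALSE]
        # ungapped extension along the cluster's modal diagonal: only
        # clusters whose best ungapped segment scores above the floor are
        # refined by gapped alignment (chance word matches stop here)
        diag_tab <- table(cl$diag)
        diag0 <- as.integer(names(diag_tab)[which.max(diag_tab)])
        if (ungapped_score(q, subj, diag0, match, mismatch) < ungapped_min) {
          next
        }
        lo <- max(1, min(cl$spos) - min(cl$qpos) - word_size)
        hi <- min(nchar(subj),
                  max(cl$spos) + (qlen - max(cl$qpos)) + word_size)
        seg <- substr(subj, lo, hi)
        aln <- Biostrings::pairwiseAlignment(
          pattern = q, subject = seg, type = "local",
          substitutionMatrix = submat,
          gapOpening = gap_open, gapExtension = gap_extend
        )
        score <- Biostrings::score(aln)
        if (score <= 0) next
        qr <- as.data.frame(Biostrings::pattern(aln)@range)
        sr <- as.data.frame(Biostrings::subject(aln)@range)
        q_start <- qr$start; q_end <- qr$end
        if (strand == "-") {
          tmp <- qlen - q_end + 1
          q_end <- qlen - q_start + 1
          q_start <- tmp
        }
        ev <- karlin_k * qlen * db_len * exp(-lambda * score)
        if (ev > evalue_ceiling) next
        hits <- rbind(hits, data.frame(
          scaffold = sc,
          s_start = lo + sr$start - 1, s_end = lo + sr$end - 1,
          strand = strand, score = score, evalue = ev,
          coverage = (qr$end - qr$start + 1) / qlen,
          q_start = q_start, q_end = q_end,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (nrow(hits) == 0) return(hits)
  # collapse overlapping hits at one locus, keeping the best score
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j <= i || !keep[j]) next
      same <- hits$scaffold[i] == hits$scaffold[j] &&
        hits$strand[i] == hits$strand[j]
      if (same && interval_overlap(hits$s_start[i], hits$s_end[i] + 1,
                                   hits$s_start[j], hits$s_end[j] + 1) > 0) {
        keep[j] <- FALSE
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# best ungapped-segment score between query and subject along one
# diagonal (maximum-subarray over per-position match/mismatch scores)
#' @noRd
ungapped_score <- function(q, s, diag, match, mismatch) {
  qlen <- nchar(q)
  slen <- nchar(s)
  q_from <- max(1, 1 - diag)
  q_to <- min(qlen, slen - diag)
  if (q_from > q_to) return(0)
  qc <- substring(q, q_from, q_to)
  sc <- substring(s, q_from + diag, q_to + diag)
  hits <- strsplit(qc, "")[[1]] == strsplit(sc, "")[[1]]
  v <- ifelse(hits, match, mismatch)
  best <- cur <- 0
  for (x in v) {
    cur <- max(0, cur + x)
    if (cur > best) best <- cur
  }
  best
}

# positions of every k-mer of a sequence (names = k-mer strings); k-mers
# containing non-ACGT characters are skipped
#' @noRd
kmer_positions <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1)
  words <- substring(s, starts, starts + k - 1)
  ok <- !grepl("[^ACGT]", words)
  split(starts[ok], words[ok])
}

#' Select the unique placement among homology hits
#'
#' The placement rule for adding a region's sequence from a scaffold set:
#' a single raw hit is selected outright; otherwise hits with e-value above
#' `evalue_max` or with query coverage at or below `min_coverage` are
#' excluded, and a region whose hits reduce to exactly one is recovered.
#' Zero or two-plus surviving hits give no placement.
#'
#' @param hits data frame from [search_homologs()] (or an external
#'   tabular-hits adapter; columns `evalue` and `coverage` are required).
#' @param evalue_max e-value cutoff (default 1e-4).
#' @param min_coverage coverage cutoff; exclusion is inclusive at the
#'   boundary (coverage must exceed it; default 0.40).
#' @return list with `hit` (one-row data frame or `NULL`) and `decision`
#'   (`"single"`, `"recovered"`, `"none"` or `"ambiguous"`).
#' @export
select_unique_hit <- function(hits, evalue_max = 1e-4, min_coverage = 0.40) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(hit = NULL, decision = "none"))
  }
  if (nrow(hits) == 1) {
    return(list(hit = hits, decision = "single"))
  }
  surv <- hits[hits$evalue <= evalue_max & hits$coverage > min_coverage, ,
               drop = FALSE]
  if (nrow(surv) == 1) {
    rownames(surv) <- NULL
    return(list(hit = surv, decision = "recovered"))
  }
  list(hit = NULL, decision = if (nrow(surv) == 0) "none" else "ambiguous")
}

#' Read scaffolds from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_scaffolds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Graft a new taxon into alignment blocks from scaffold placements
#'
#' For each placed block, the scaffold slice given by the hit coordinates
#' is cut out, orientation-normalized, aligned to the block's reference row
#' and threaded into the block as a new taxon row. Existing columns are
#' never reordered or edited — the only change to existing taxa is the
#' insertion of gap-only columns where the new sequence carries an
#' insertion. Blocks without a placement receive an all-gap row, so the
#' block count and taxon set stay consistent.
#'
#' @param blocks list of alignment blocks ([read_maf()] model).
#' @param placements data frame with one row per placed block: `block`
#'   (index into `blocks`), `scaffold`, `s_start`, `s_end` (1-based,
#'   inclusive), `strand`.
#' @param scaffolds named character vector of scaffold sequences.
#' @param new_label taxon label of the grafted row.
#' @return the augmented block list.
#' @export
graft_taxon <- function(blocks, placements, scaffolds, new_label) {
  if (new_label %in% unlist(lapply(blocks, `[[`, "taxa"))) {
    stop("taxon label already present: ", new_label)
  }
  placed <- if (nrow(placements) > 0) {
    stats::setNames(seq_len(nrow(placements)), placements$block)
  } else {
    stats::setNames(integer(0), character(0))
  }
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    ref <- b$taxa[1]
    width <- nchar(b$seqs[[ref]])
    pi <- placed[as.character(bi)]
    if (is.na(pi)) {
      new_row <- strrep("-", width)
      new_size <- 0
    } else {
      p <- placements[pi, ]
      scaf <- scaffolds[[p$scaffold]]
      if (is.null(scaf) || p$s_start < 1 || p$s_end > nchar(scaf) ||
          p$s_start > p$s_end) {
        stop("placement outside scaffold bounds (block ", bi, ")")
      }
      slice <- toupper(substr(scaf, p$s_start, p$s_end))
      if (p$strand == "-") slice <- revcomp_chr(slice)
      threaded <- thread_into_block(b, ref, slice)
      blocks[[bi]] <- b <- threaded$block
      new_row <- threaded$row
      new_size <- sum(seq_to_chars(new_row) != "-")
    }
    b$taxa <- c(b$taxa, new_label)
    b$chrom[new_label] <- if (is.na(pi)) "unplaced" else
      placements$scaffold[pi]
    b$start[new_label] <- if (is.na(pi)) 0 else placements$s_start[pi] - 1
    b$size[new_label] <- new_size
    b$strand[new_label] <- if (is.na(pi)) "+" else placements$strand[pi]
    b$srcSize[new_label] <- if (is.na(pi)) 0 else
      nchar(scaffolds[[placements$scaffold[pi]]])
    b$seqs[new_label] <- new_row
    blocks[[bi]] <- b
  }
  blocks
}

# align `slice` to the block's reference row and thread it into the block:
# reference-matching characters land in the reference's columns; insertions
# in the slice become gap-only columns for all existing taxa.
#' @noRd
thread_into_block <- function(block, ref, slice) {
  ref_aln <- block$seqs[[ref]]
  ref_chars <- seq_to_chars(ref_aln)
  ref_ungapped <- paste(ref_chars[ref_chars != "-"], collapse = "")
  if (nchar(ref_ungapped) == 0) {
    stop("reference row is all gaps; cannot thread")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = toupper(ref_ungapped), subject = slice, type = "global",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2
  )
  pat <- seq_to_chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- seq_to_chars(as.character(Biostrings::alignedSubject(aln)))
  ref_col <- which(ref_chars != "-") # block column of each ref base
  out_row <- rep("-", length(ref_chars))
  inserts <- list() # block column after which to insert, and the chars
  ref_i <- 0L
  pending_after <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") {
      ref_i <- ref_i + 1L
      out_row[ref_col[ref_i]] <- sub[k]
      pending_after <- ref_col[ref_i]
    } else if (sub[k] != "-") {
      key <- as.character(pending_after)
      inserts[[key]] <- c(inserts[[key]], sub[k])
    }
  }
  if (length(inserts) > 0) {
    # rebuild all rows with gap-only columns spliced in
    pos <- as.integer(names(inserts))
    ord <- order(pos)
    pos <- pos[ord]
    ins <- inserts[ord]
    new_seqs <- block$seqs
    for (tx in block$taxa) {
      chars <- seq_to_chars(block$seqs[[tx]])
      parts <- character(0)
      prev <- 0L
      for (m in seq_along(pos)) {
        if (pos[m] > prev) parts <- c(parts, chars[(prev + 1L):pos[m]])
        parts <- c(parts, rep("-", length(ins[[m]])))
        prev <- pos[m]
      }
      if (prev < length(chars)) parts <- c(parts, chars[(prev + 1L):length(chars)])
      new_seqs[[tx]] <- paste(parts, collapse = "")
    }
    block$seqs <- new_seqs
    # same splice for the new row, but with the inserted characters
    parts <- character(0)
    prev <- 0L
    for (m in seq_along(pos)) {
      if (pos[m] > prev) parts <- c(parts, out_row[(prev + 1L):pos[m]])
      parts <- c(parts, ins[[m]])
      prev <- pos[m]
    }
    if (prev < length(out_row)) {
      parts <- c(parts, out_row[(prev + 1L):length(out_row)])
    }
    row <- paste(parts, collapse = "")
  } else {
    row <- paste(out_row, collapse = "")
  }
  list(block = block, row = row)
}
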