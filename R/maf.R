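# MAF (Multiple Alignment Format, UCSC dialect) reading and writing.
#
# In-memory model: a list of blocks; each block is a list with elements
#   taxa    character vector, reference taxon first
#   chrom   named character  (per-taxon source chromosome/scaffold)
#   start   named numeric    (0-based start on the source, forward strand)
#   size    named numeric    (ungapped length)
#   strand  named character  ("+"/"-" as stored; see note below)
#   srcSize named numeric    (source sequence length)
#   seqs    named character  (aligned rows, equal length)
# Rows on the minus strand are reverse-complemented into reference
# orientation at read time (coordinates converted to the forward strand);
# the original strand is retained in `strand` for provenance.

#' Read a MAF alignment file
#'
#' Parses a UCSC-dialect MAF file into a list of alignment blocks. Sequence
#' names of the form `taxon.chrom` are split into taxon label and source
#' chromosome; the first `s` line of each block is taken as the reference.
#' Minus-strand rows are reverse-complemented into reference orientation and
#' their start converted to forward-strand coordinates. Blocks are returned
#' sorted by reference chromosome and start; a warning is issued if the file
#' was out of order.
#'
#' @param path path to a MAF file.
#' @return list of alignment blocks (see the block model above).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (is.null(cur) || length(cur$taxa) == 0) return(blocks)
    lens <- nchar(cur$seqs)
    if (length(unique(lens)) != 1) {
      stop("ragged MAF block (unequal row lengths) near taxon ",
           cur$taxa[1])
    }
    blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) {
      blocks <- flush(cur, blocks)
      cur <- list(taxa = character(), chrom = character(),
                  start = numeric(), size = numeric(),
                  strand = character(), srcSize = numeric(),
                  seqs = character())
    } else if (grepl("^s ", ln)) {
      if (is.null(cur)) stop("MAF 's' line outside an 'a' block")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7) stop("malformed MAF 's' line: ", ln)
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      taxon <- if (dot > 0) substr(src, 1, dot - 1) else src
      chrom <- if (dot > 0) substr(src, dot + 1, nchar(src)) else src
      if (taxon %in% cur$taxa) {
        stop("duplicate taxon '", taxon, "' in one MAF block")
      }
      start <- as.numeric(f[3]); size <- as.numeric(f[4])
      strand <- f[5]; srcSize <- as.numeric(f[6]); s <- f[7]
      if (strand == "-") {
        s <- revcomp_chr(s)
        start <- srcSize - start - size
      }
      cur$taxa <- c(cur$taxa, taxon)
      cur$chrom[taxon] <- chrom
      cur$start[taxon] <- start
      cur$size[taxon] <- size
      cur$strand[taxon] <- strand
      cur$srcSize[taxon] <- srcSize
      cur$seqs[taxon] <- s
    }
    # 'i', 'e', 'q' and comment lines are ignored
  }
  blocks <- flush(cur, blocks)
  if (length(blocks) == 0) return(blocks)
  ref_chrom <- vapply(blocks, function(b) b$chrom[[b$taxa[1]]], character(1))
  ref_start <- vapply(blocks, function(b) b$start[[b$taxa[1]]], numeric(1))
  ord <- order(ref_chrom, ref_start)
  if (any(ord != seq_along(blocks))) {
    warning("MAF blocks out of reference-coordinate order; sorted")
    blocks <- blocks[ord]
  }
  blocks
}

#' Write alignment blocks as a MAF file
#'
#' @param blocks list of alignment blocks (block model of [read_maf()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a score=0", con)
    for (tx in b$taxa) {
      # rows read from the minus strand were normalized to reference
      # orientation in memory; restore strand coordinates on write so that
      # read -> write -> read round-trips
      start <- b$start[[tx]]; s <- b$seqs[[tx]]
      if (b$strand[[tx]] == "-") {
        s <- revcomp_chr(s)
        start <- b$srcSize[[tx]] - start - b$size[[tx]]
      }
      writeLines(sprintf("s %s.%s %d %d %s %d %s",
                         tx, b$chrom[[tx]], as.integer(start),
                         as.integer(b$size[[tx]]), b$strand[[tx]],
                         as.integer(b$srcSize[[tx]]), s), con)
    }
  }
  invisible(path)
}
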