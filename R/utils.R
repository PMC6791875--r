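# Shared helpers: seed derivation, interval arithmetic, sequence utilities.

#' Derive a child seed from a top-level seed
#'
#' Deterministic splitting of one user-facing seed into independent
#' sub-stream seeds (per chromosome, per replicate, ...), so that the order
#' in which streams are consumed never changes results. Plain 32-bit-safe
#' integer arithmetic; the result is always a valid `set.seed()` input.
#'
#' @param seed integer top-level seed.
#' @param ... one or more non-negative integer stream indices.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    # affine step modulo the Mersenne prime 2^31 - 1; 48271 is the
    # MINSTD multiplier, applied on numerics (exact below 2^53)
    s <- (s * 48271 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(s)
}

#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# reverse-complement of a character string (A/C/G/T/N/-, case preserved)
#' @noRd
revcomp_chr <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE for determined nucleotide characters (not gap, not N/ambiguity)
#' @noRd
is_determined <- function(x) {
  toupper(x) %in% c("A", "C", "G", "T")
}

# half-open interval overlap length
#' @noRd
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# split an aligned sequence string into a character vector of columns
#' @noRd
seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
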