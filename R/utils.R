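#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif median t.test setNames
#' @importFrom utils write.table read.table head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string (A/C/G/T, case preserved).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## round half away from zero, matching printed kb labels (base round() is
## round-half-even and would turn 9.85 into 9.8)
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## longest common prefix length of two strings, in bases
common_prefix_len <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

## longest common suffix length of two strings, in bases
common_suffix_len <- function(a, b) {
  ra <- rev(charToRaw(a))
  rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

## all start positions of fixed pattern in subject (1-based), non-overlap not
## required; plain exact matching
find_all <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

## a base different from all bases in `avoid`
other_base <- function(avoid) {
  pool <- setdiff(BASES, toupper(avoid))
  pool[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## uniform integer draw on [lo, hi]; safe for degenerate ranges (sample()
## would interpret a scalar as 1:n)
draw_int <- function(lo, hi) {
  if (lo > hi) stop("empty integer range", call. = FALSE)
  if (lo == hi) return(as.integer(lo))
  as.integer(sample(seq.int(lo, hi), 1L))
}
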