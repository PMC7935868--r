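#' Random DNA sequence
#'
#' Uniform i.i.d. sequence over A/C/G/T, drawn from the current RNG stream.
#'
#' @param n Length in bases.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, any case).
#' @return Character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) {
  as.character(revcomp_cpp(x))
}

#' Canonical form of a circular sequence
#'
#' A circular molecule has no intrinsic origin or strand.  The canonical
#' form is the lexicographic minimum over all rotations of the sequence and
#' all rotations of its reverse complement, so any rotation of either strand
#' maps to the same string.  This makes resolved plasmid monomers directly
#' comparable across runs.
#'
#' @param seq A single DNA string.
#' @return The canonical rotation/strand of `seq`.
#' @export
canonical_rotation <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  rot <- function(s) {
    i <- least_rotation_cpp(s)
    if (i == 0) s else paste0(substring(s, i + 1), substring(s, 1, i))
  }
  a <- rot(seq)
  b <- rot(revcomp(seq))
  if (a <= b) a else b
}

# 0-based half-open interval union length
interval_union_len <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
    else ce <- max(ce, end[i])
  }
  tot + (ce - cs)
}

# merge 0-based half-open intervals, returning a tibble(start, end)
interval_merge <- function(start, end) {
  if (length(start) == 0) return(tibble::tibble(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  os <- start[1]; oe <- end[1]; rs <- c(); re <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] > oe) { rs <- c(rs, os); re <- c(re, oe); os <- start[i]; oe <- end[i] }
    else oe <- max(oe, end[i])
  }
  tibble::tibble(start = c(rs, os), end = c(re, oe))
}

# banded global alignment identity of two strings (thin wrapper choosing the
# band from the length difference plus slack)
nw_identity <- function(a, b, slack = NULL, keep_align = FALSE) {
  na <- nchar(a); nb <- nchar(b)
  if (is.null(slack)) slack <- max(30L, ceiling(0.05 * max(na, nb)))
  dlo <- min(0L, nb - na) - slack
  dhi <- max(0L, nb - na) + slack
  nw_band_cpp(a, b, dlo, dhi, keep_align)
}
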