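# Low-level sequence helpers shared by the simulator and the extractor.

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' Positions of CpG dinucleotides
#'
#' Returns the 1-based positions of the C of every CG dinucleotide in a
#' sequence (the top-strand CpG cytosines).
#'
#' @param seq A single DNA string.
#' @return Integer vector of positions (possibly empty).
#' @export
cpg_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  hit <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
  if (hit[1L] == -1L) integer(0) else as.integer(hit)
}

# Reverse a string.
strrev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Semi-global (substring) edit distance: for each end position j in `text`
# (1-based), the minimum Levenshtein distance between `pattern` and any
# substring of `text` ending at j. Row-wise DP; the within-row horizontal
# dependency is resolved with the cummin identity
#   D[i, j] = j + min_{k <= j} (M[k] - k),  M = pmin(diag, vertical) with
#   M[0] = D[i, 0] = i,
# so each row is a constant number of vectorized operations.
edit_end_distances <- function(pattern, text) {
  p <- utf8ToInt(pattern)
  t <- utf8ToInt(text)
  n <- length(t)
  if (n == 0L) return(numeric(0))
  j <- 0:n
  prev <- numeric(n + 1L) # row 0: a match may start anywhere for free
  for (i in seq_along(p)) {
    cand <- pmin(prev[-(n + 1L)] + (t != p[i]), prev[-1L] + 1)
    prev <- cummin(c(i, cand) - j) + j
  }
  prev[-1L]
}

# Minimum edit distance of `pattern` against substrings of `text` starting at
# each position j (computed by running the end-position DP on the reversals).
edit_start_distances <- function(pattern, text) {
  rev(edit_end_distances(strrev(pattern), strrev(text)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

check_dna <- function(x, what) {
  if (!is.character(x) || any(is.na(x)) ||
      any(grepl("[^ACGTNacgtn]", x))) {
    stop(what, " must be a DNA string (A/C/G/T/N)", call. = FALSE)
  }
  toupper(x)
}
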