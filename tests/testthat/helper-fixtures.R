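# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, direct enumeration) so they exercise a different code
# path than the implementation they check.

test_locus <- function(motif = "CGG", max_anchor_edits = 3L) {
  locus_definition(
    "FMR1", "chrX", 147912050L, 147912200L, motif,
    upstream_anchor = "GACGTCTAACTTGTAACCAT",
    downstream_anchor = "TTCAAGTCCGATACGGTGAC",
    max_anchor_edits = max_anchor_edits
  )
}

# Naive quadratic semi-global edit distance: full DP matrix, explicit loops.
naive_edit_end_distances <- function(pattern, text) {
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  m <- length(p); n <- length(t)
  D <- matrix(0, m + 1, n + 1)
  D[, 1] <- 0:m
  for (i in 1:m) {
    for (j in 1:n) {
      D[i + 1, j + 1] <- min(
        D[i, j] + (p[i] != t[j]),
        D[i, j + 1] + 1,
        D[i + 1, j] + 1
      )
    }
  }
  D[m + 1, -1]
}

# Direct-summation instability-index oracle.
brute_ii <- function(size_units, height_rfu, threshold_frac = 0.20) {
  h_max <- max(height_rfu)
  modal_candidates <- which(height_rfu == h_max)
  modal <- modal_candidates[which.min(size_units[modal_candidates])]
  num <- height_rfu[modal] * 0
  den <- height_rfu[modal]
  for (i in seq_along(size_units)) {
    if (size_units[i] > size_units[modal] &&
        height_rfu[i] >= threshold_frac * height_rfu[modal]) {
      num <- num + height_rfu[i] * (size_units[i] - size_units[modal])
      den <- den + height_rfu[i]
    }
  }
  num / den
}

# Brute-force (allele x stutter order) accumulation of raw trace heights.
brute_trace_heights <- function(allele_fracs, motif_len, cfg) {
  acc <- list()
  add <- function(size, h) {
    key <- format(size, digits = 15)
    acc[[key]] <<- (if (is.null(acc[[key]])) 0 else acc[[key]]) + h
  }
  for (a in seq_along(allele_fracs)) {
    u <- as.numeric(names(allele_fracs))[a]
    parent <- allele_fracs[[a]] * exp(-cfg$amp_bias_lambda * u * motif_len)
    add(u, parent)
    if (cfg$max_stutter_order > 0) {
      for (k in 1:cfg$max_stutter_order) {
        add(u + k, parent * cfg$stutter_decay_plus^k)
        if (u - k >= 0) add(u - k, parent * cfg$stutter_decay_minus^k)
      }
    }
  }
  sizes <- as.numeric(names(acc))
  o <- order(sizes)
  list(size_units = sizes[o], height = unlist(acc, use.names = FALSE)[o])
}

random_peak_table <- function(n_peaks) {
  sizes <- sort(sample(50:250, n_peaks))
  peak_table(sizes, stats::runif(n_peaks, 1, 100))
}

read_ids <- function(reads) vapply(reads, `[[`, "", "read_id")
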