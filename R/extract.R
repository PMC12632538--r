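# Flank-anchored per-read repeat extraction: locate the upstream and
# downstream anchor sequences in each read (either orientation, allowing a
# bounded edit distance), take the bases between them as the allele, and
# summarise its length and mean base-call quality.

non_spanning <- function(read_id, msg) {
  stop(errorCondition(paste0("NonSpanningRead [", read_id, "]: ", msg),
                      class = c("nonSpanningRead", "error")))
}

# Best anchor pair on one oriented sequence, or NULL. Upstream anchor: the
# lowest-edit match end (tie -> rightmost); downstream anchor: the
# lowest-edit match start strictly after the upstream end (tie -> leftmost).
# Rightmost/leftmost tie-breaks give the tightest repeat span, keeping
# interruptions inside the allele call.
flank_pair <- function(s, locus) {
  n <- nchar(s)
  if (n == 0L) return(NULL)
  du <- edit_end_distances(locus$upstream_anchor, s)
  d_u <- min(du)
  if (d_u > locus$max_anchor_edits) return(NULL)
  e_u <- max(which(du == d_u)) # 1-based end position == 0-based end offset
  if (e_u >= n) return(NULL)   # nothing can start after it
  ds <- edit_start_distances(locus$downstream_anchor, s)
  cand <- (e_u + 1L):n
  d_cand <- ds[cand]
  d_d <- min(d_cand)
  if (d_d > locus$max_anchor_edits) return(NULL)
  j_d <- cand[which.max(d_cand == d_d)] # leftmost minimal start, 1-based
  list(upstream_end = e_u,              # 0-based half-open end of upstream
       downstream_start = j_d - 1L,     # 0-based start of downstream
       upstream_edits = d_u, downstream_edits = d_d,
       total_edits = d_u + d_d)
}

#' Locate the repeat-flanking anchors in a read
#'
#' Searches both orientations of the read for the locus anchors, allowing
#' up to `max_anchor_edits` Levenshtein edits per anchor; the orientation
#' with the lower combined edit distance wins (tie broken toward forward).
#'
#' @param read A read record (list with at least `read_id`, `sequence`).
#' @param locus A [locus_definition()].
#' @return List with `strand` (`"+"` or `"-"`, the orientation in which the
#'   anchors were found), 0-based `upstream_end` and `downstream_start` on
#'   the oriented read, and the per-anchor edit distances.
#'   Signals a condition of class `nonSpanningRead` if either anchor cannot
#'   be matched within the edit budget or no valid ordered pair exists.
#' @export
locate_flanks <- function(read, locus) {
  stopifnot(inherits(locus, "locus_definition"))
  fwd <- flank_pair(read$sequence, locus)
  rvs <- flank_pair(revcomp(read$sequence), locus)
  if (is.null(fwd) && is.null(rvs)) {
    non_spanning(read$read_id, "anchors not found in either orientation")
  }
  if (is.null(rvs) || (!is.null(fwd) && fwd$total_edits <= rvs$total_edits)) {
    c(fwd, strand = "+")
  } else {
    c(rvs, strand = "-")
  }
}

#' Extract the repeat allele from a spanning read
#'
#' The allele length is the number of bases between the two flank matches on
#' the oriented read; motif units are `floor(repeat_bp / motif_length)`; the
#' mean base-call quality is the arithmetic mean of the Phred values over
#' the repeat span (`NA` for a zero-length span).
#'
#' @inheritParams locate_flanks
#' @return One-row data frame (a repeat call) with columns `read_id`,
#'   `locus_id`, `repeat_bp`, `repeat_units`, `mean_baseq`,
#'   `repeat_sequence`, `upstream_end`, `downstream_start`,
#'   `upstream_edits`, `downstream_edits`, `strand`.
#' @export
extract_repeat <- function(read, locus) {
  fl <- locate_flanks(read, locus)
  s <- read$sequence
  q <- read$base_qualities
  if (fl$strand == "-") {
    s <- revcomp(s)
    q <- rev(q)
  }
  bp <- fl$downstream_start - fl$upstream_end
  rep_seq <- substr(s, fl$upstream_end + 1L, fl$downstream_start)
  mean_baseq <- if (bp > 0 && !is.null(q)) {
    mean(q[(fl$upstream_end + 1L):fl$downstream_start])
  } else {
    NA_real_
  }
  data.frame(
    read_id = read$read_id,
    locus_id = locus$locus_id,
    repeat_bp = as.integer(bp),
    repeat_units = as.integer(floor(bp / nchar(locus$motif))),
    mean_baseq = mean_baseq,
    repeat_sequence = rep_seq,
    upstream_end = fl$upstream_end,
    downstream_start = fl$downstream_start,
    upstream_edits = fl$upstream_edits,
    downstream_edits = fl$downstream_edits,
    strand = fl$strand,
    stringsAsFactors = FALSE
  )
}

#' Call the repeat allele on every read of a locus
#'
#' Every input read appears exactly once in the output: either as a repeat
#' call or as a rejection with a reason (`wrong_locus` for reads assigned to
#' a different locus, `non_spanning` when the anchors cannot be matched).
#'
#' @param reads List of read records (e.g. from [simulate_reads()] or
#'   [read_aligned_reads()]).
#' @param locus A [locus_definition()].
#' @return List with `calls` (data frame of repeat calls, one row per
#'   spanning read) and `rejected` (data frame `read_id`, `reason`).
#' @export
filter_spanning <- function(reads, locus) {
  calls <- vector("list", length(reads))
  rej_id <- character(0)
  rej_why <- character(0)
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    if (!is.null(rd$locus_id) && !is.na(rd$locus_id) &&
        rd$locus_id != locus$locus_id) {
      rej_id <- c(rej_id, rd$read_id)
      rej_why <- c(rej_why, "wrong_locus")
      next
    }
    res <- tryCatch(extract_repeat(rd, locus),
                    nonSpanningRead = function(e) NULL)
    if (is.null(res)) {
      rej_id <- c(rej_id, rd$read_id)
      rej_why <- c(rej_why, "non_spanning")
    } else {
      calls[[i]] <- res
    }
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  calls <- if (length(calls)) do.call(rbind, calls) else data.frame(
    read_id = character(0), locus_id = character(0),
    repeat_bp = integer(0), repeat_units = integer(0),
    mean_baseq = numeric(0), repeat_sequence = character(0),
    upstream_end = integer(0), downstream_start = integer(0),
    upstream_edits = numeric(0), downstream_edits = numeric(0),
    strand = character(0), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls,
       rejected = data.frame(read_id = rej_id, reason = rej_why,
                             stringsAsFactors = FALSE))
}

#' Convert a Phred quality value to percent accuracy
#'
#' `100 * (1 - 10^(-qv / 10))`; e.g. QV 10 is 90% and QV 45 is 99.99684%.
#'
#' @param qv Numeric vector of Phred quality values (>= 0).
#' @return Percent base-call accuracy.
#' @export
qv_to_accuracy <- function(qv) {
  if (any(qv < 0)) stop("qv must be >= 0")
  100 * (1 - 10^(-qv / 10))
}
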