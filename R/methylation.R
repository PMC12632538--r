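# Per-CpG classification, per-read methylation proportion scoring,
# read-level methylation classes, activation ratio, and waterfall export.

#' Methylation scoring configuration
#'
#' CpG sites with probability at or above `meth_cutoff` are methylated, at
#' or below `unmeth_cutoff` unmethylated, and intermediate otherwise.
#' Read-level classes use the per-read methylation proportion:
#' `fully_methylated` at or above `fully_methylated_min`, `unmethylated` at
#' or below `unmethylated_max`, `partial` in between.
#'
#' @param meth_cutoff Per-CpG methylated cutoff (default 0.66).
#' @param unmeth_cutoff Per-CpG unmethylated cutoff (default 0.33).
#' @param fully_methylated_min Read-level fully-methylated bound
#'   (default 0.80).
#' @param unmethylated_max Read-level unmethylated bound (default 0.20).
#' @return An object of class `methylation_config`.
#' @export
methylation_config <- function(meth_cutoff = 0.66, unmeth_cutoff = 0.33,
                               fully_methylated_min = 0.80,
                               unmethylated_max = 0.20) {
  if (!(unmeth_cutoff >= 0 && unmeth_cutoff < meth_cutoff &&
        meth_cutoff <= 1)) {
    stop("cutoffs must satisfy 0 <= unmeth_cutoff < meth_cutoff <= 1")
  }
  stopifnot(fully_methylated_min > 0, fully_methylated_min <= 1,
            unmethylated_max >= 0, unmethylated_max < fully_methylated_min)
  structure(list(meth_cutoff = meth_cutoff, unmeth_cutoff = unmeth_cutoff,
                 fully_methylated_min = fully_methylated_min,
                 unmethylated_max = unmethylated_max),
            class = "methylation_config")
}

#' Classify a CpG site from its methylation probability
#'
#' @param p Numeric vector of methylation probabilities in \[0, 1\].
#' @param cfg A [methylation_config()].
#' @return Character vector in `{"methylated", "unmethylated",
#'   "intermediate"}`. The cutoffs are inclusive: `p >= meth_cutoff` is
#'   methylated and `p <= unmeth_cutoff` is unmethylated.
#' @export
classify_cpg <- function(p, cfg = methylation_config()) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("methylation probabilities must lie in [0, 1]")
  }
  ifelse(p >= cfg$meth_cutoff, "methylated",
         ifelse(p <= cfg$unmeth_cutoff, "unmethylated", "intermediate"))
}

#' Per-read methylation proportion score
#'
#' The proportion of a read's CpG sites classified methylated, with ALL
#' CpGs in the denominator (intermediate sites count in the denominator
#' only): a read with 10 CpGs of which 8 score >= 0.66 has proportion 0.8.
#' A read without CpG information gets proportion `NA`.
#'
#' @param sites Numeric vector of per-CpG methylation probabilities.
#' @param cfg A [methylation_config()].
#' @return List (a methylation call) with `n_cpg`, `n_methylated`,
#'   `n_unmethylated`, `n_intermediate`, `proportion`.
#' @export
read_methylation_proportion <- function(sites, cfg = methylation_config()) {
  sites <- as.numeric(sites)
  n <- length(sites)
  if (n == 0L) {
    return(list(n_cpg = 0L, n_methylated = 0L, n_unmethylated = 0L,
                n_intermediate = 0L, proportion = NA_real_))
  }
  st <- classify_cpg(sites, cfg)
  n_m <- sum(st == "methylated")
  n_u <- sum(st == "unmethylated")
  list(n_cpg = n, n_methylated = n_m, n_unmethylated = n_u,
       n_intermediate = n - n_m - n_u, proportion = n_m / n)
}

#' Methylation calls for a read set
#'
#' @param reads List of read records carrying `cpg_probs`.
#' @param cfg A [methylation_config()].
#' @return Data frame with one row per read: `read_id`, `n_cpg`,
#'   `n_methylated`, `n_unmethylated`, `n_intermediate`, `proportion`.
#' @export
methylation_calls <- function(reads, cfg = methylation_config()) {
  rows <- lapply(reads, function(rd) {
    call <- read_methylation_proportion(rd$cpg_probs, cfg)
    cbind(data.frame(read_id = rd$read_id, stringsAsFactors = FALSE),
          as.data.frame(call))
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    read_id = character(0), n_cpg = integer(0), n_methylated = integer(0),
    n_unmethylated = integer(0), n_intermediate = integer(0),
    proportion = numeric(0))
  rownames(out) <- NULL
  out
}

#' Read-level methylation class
#'
#' @param proportion Numeric vector of per-read methylation proportions (or
#'   a methylation-call data frame with a `proportion` column).
#' @param cfg A [methylation_config()].
#' @return Character vector in `{"unmethylated", "partial",
#'   "fully_methylated", NA}`.
#' @export
classify_read_methylation <- function(proportion,
                                      cfg = methylation_config()) {
  if (is.data.frame(proportion)) proportion <- proportion$proportion
  ifelse(is.na(proportion), NA_character_,
         ifelse(proportion >= cfg$fully_methylated_min, "fully_methylated",
                ifelse(proportion <= cfg$unmethylated_max, "unmethylated",
                       "partial")))
}

#' Activation ratio from normal-length reads
#'
#' The proportion of normal-length alleles on the active (unmethylated) X:
#' among reads whose allele class is `normal` (and that carry methylation
#' information), the fraction whose read-level methylation class is
#' `unmethylated`. `NA` when there are no such reads (e.g. a male
#' premutation case with no normal allele).
#'
#' @param repeat_calls Repeat-call data frame from [filter_spanning()].
#' @param meth_calls Methylation-call data frame from [methylation_calls()].
#' @param classes An [allele_class_config()].
#' @param cfg A [methylation_config()].
#' @return A fraction in \[0, 1\], or `NA`.
#' @export
activation_ratio <- function(repeat_calls, meth_calls,
                             classes = allele_class_config(),
                             cfg = methylation_config()) {
  m <- merge(repeat_calls[, c("read_id", "repeat_units")],
             meth_calls[, c("read_id", "proportion")], by = "read_id")
  m <- m[allele_class(m$repeat_units, classes) == "normal", , drop = FALSE]
  cls <- classify_read_methylation(m$proportion, cfg)
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) return(NA_real_)
  mean(cls == "unmethylated")
}

#' Per-read, per-CpG methylation waterfall matrix
#'
#' Rows are reads ordered by descending allele length (`repeat_bp`, ties
#' broken by `read_id`); columns index CpG sites along each read; cells are
#' methylation probabilities (`NA` where a read has fewer CpGs).
#'
#' @param repeat_calls Repeat-call data frame (supplies the row order).
#' @param reads List of read records carrying `cpg_probs`.
#' @return Numeric matrix with `read_id` rownames.
#' @export
build_waterfall <- function(repeat_calls, reads) {
  ids <- vapply(reads, `[[`, "", "read_id")
  keep <- match(repeat_calls$read_id, ids)
  if (anyNA(keep)) stop("repeat_calls contain read_ids absent from reads")
  ord <- order(-repeat_calls$repeat_bp, repeat_calls$read_id)
  probs <- lapply(reads[keep][ord], function(rd) {
    p <- rd$cpg_probs
    p[order(as.integer(names(p)))]
  })
  ncol <- max(0L, vapply(probs, length, integer(1)))
  mat <- matrix(NA_real_, nrow = length(probs), ncol = ncol,
                dimnames = list(repeat_calls$read_id[ord],
                                if (ncol > 0) seq_len(ncol)))
  for (r in seq_along(probs)) {
    if (length(probs[[r]])) mat[r, seq_along(probs[[r]])] <-
        unname(probs[[r]])
  }
  mat
}

#' Long-format export of a waterfall matrix
#'
#' @param mat Matrix from [build_waterfall()].
#' @return Data frame `read_id`, `cpg_index`, `prob` (row-major, `NA` cells
#'   included), suitable for plotting or TSV export.
#' @export
waterfall_long <- function(mat) {
  if (length(mat) == 0L) {
    return(data.frame(read_id = character(0), cpg_index = integer(0),
                      prob = numeric(0)))
  }
  data.frame(
    read_id = rep(rownames(mat), each = ncol(mat)),
    cpg_index = rep(seq_len(ncol(mat)), times = nrow(mat)),
    prob = as.vector(t(mat)),
    stringsAsFactors = FALSE
  )
}
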