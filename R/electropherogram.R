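# TP-PCR/CE instability (expansion) index from electropherogram peak
# tables: the modal (tallest) peak plus all rightward peaks at or above a
# fraction of the modal height, combined as a height-weighted mean distance
# from the modal allele.

#' Construct a peak table
#'
#' Coincident sizes are merged (heights summed) before any modal detection,
#' and peaks are sorted by ascending size.
#'
#' @param size_units Peak sizes in repeat units (float allowed for
#'   calibrated CE sizes).
#' @param height_rfu Peak heights in relative fluorescence units (>= 0).
#' @param size_bp Optional sizes in base pairs (derived from `motif_len`
#'   when supplied).
#' @param motif_len Optional motif length for the unit-to-bp conversion.
#' @param locus_id Optional locus label.
#' @return Data frame of class `peak_table` with columns `size_units`,
#'   `size_bp`, `height_rfu`, sorted by size.
#' @export
peak_table <- function(size_units, height_rfu, size_bp = NULL,
                       motif_len = NULL, locus_id = NA_character_) {
  stopifnot(length(size_units) == length(height_rfu))
  if (any(height_rfu < 0)) stop("peak heights must be >= 0")
  if (is.null(size_bp)) {
    size_bp <- if (!is.null(motif_len)) size_units * motif_len
               else rep(NA_real_, length(size_units))
  }
  if (length(size_units)) {
    agg_h <- tapply(height_rfu, size_units, sum)
    agg_bp <- tapply(size_bp, size_units, `[`, 1L)
    size_units <- as.numeric(names(agg_h))
    height_rfu <- as.numeric(agg_h)
    size_bp <- as.numeric(agg_bp)
    o <- order(size_units)
    size_units <- size_units[o]; height_rfu <- height_rfu[o]
    size_bp <- size_bp[o]
  }
  out <- data.frame(size_units = size_units, size_bp = size_bp,
                    height_rfu = height_rfu)
  attr(out, "locus_id") <- locus_id
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Read/write peak tables as TSV
#'
#' @param path TSV path with columns `size_units`, `size_bp`, `height_rfu`.
#' @return For `read_peak_table`, a [peak_table()].
#' @export
read_peak_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  peak_table(df$size_units, df$height_rfu, size_bp = df$size_bp)
}

#' @rdname read_peak_table
#' @param table A [peak_table()].
#' @export
write_peak_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Find the modal (reference) allele peak
#'
#' The peak with maximum height; ties are broken toward the smaller size
#' (conservative toward a lower instability index).
#'
#' @param table A [peak_table()] (non-empty).
#' @return One-row data frame: the modal peak.
#' @export
find_modal <- function(table) {
  if (nrow(table) == 0L) stop("peak table is empty")
  h_max <- max(table$height_rfu)
  idx <- which(table$height_rfu == h_max)
  as.data.frame(table)[idx[which.min(table$size_units[idx])], , drop = FALSE]
}

#' Compute the TP-PCR/CE instability (expansion) index
#'
#' The inclusion set is the modal allele plus every peak to its right whose
#' height is at least `threshold_frac` of the modal height (default 20%);
#' leftward peaks are excluded as potential technical stutter. Heights are
#' normalized over the inclusion set and the index is the weighted mean
#' distance from the modal size, in repeat units:
#' \deqn{ii = \sum_{i \in S} \frac{h_i}{\sum_{j \in S} h_j}
#'       (u_i - u_{modal}).}
#' More peaks above the threshold therefore give a more positive index; a
#' modal-only trace scores 0.
#'
#' @param table A [peak_table()] (non-empty).
#' @param threshold_frac Inclusion threshold as a fraction of the modal
#'   height, in (0, 1\]; default 0.20.
#' @return An object of class `instability_result` with fields
#'   `modal_size_units`, `included` (the inclusion-set peaks),
#'   `threshold_frac`, `ii`.
#' @export
compute_instability_index <- function(table, threshold_frac = 0.20) {
  if (nrow(table) == 0L) stop("peak table is empty")
  if (!(threshold_frac > 0 && threshold_frac <= 1)) {
    stop("threshold_frac must be in (0, 1]")
  }
  modal <- find_modal(table)
  right <- table$size_units > modal$size_units &
    table$height_rfu >= threshold_frac * modal$height_rfu
  keep <- right | (table$size_units == modal$size_units &
                   table$height_rfu == modal$height_rfu)
  inc <- as.data.frame(table)[keep, , drop = FALSE]
  w <- inc$height_rfu / sum(inc$height_rfu)
  ii <- sum(w * (inc$size_units - modal$size_units))
  structure(list(modal_size_units = modal$size_units,
                 included = inc, threshold_frac = threshold_frac, ii = ii),
            class = "instability_result")
}

#' @export
print.instability_result <- function(x, ...) {
  cat(sprintf(
    "Instability (expansion) index: %.4f\nModal allele: %g units; %d peak(s) included (threshold %.0f%% of modal)\n",
    x$ii, x$modal_size_units, nrow(x$included), 100 * x$threshold_frac))
  print(x$included, row.names = FALSE)
  invisible(x)
}

#' Call peaks from a sampled CE trace
#'
#' Local maxima of the signal above `floor_rfu` become peaks; adjacent
#' maxima within 0.5 repeat units are merged, keeping the taller.
#'
#' @param trace Data frame with columns `size_units` (strictly increasing
#'   size calibration) and `intensity`.
#' @param floor_rfu Minimum intensity for a maximum to become a peak.
#' @param merge_units Merge radius in repeat units (default 0.5).
#' @return A [peak_table()].
#' @export
peaks_from_trace <- function(trace, floor_rfu = 1, merge_units = 0.5) {
  stopifnot(all(c("size_units", "intensity") %in% names(trace)))
  x <- trace$size_units
  y <- trace$intensity
  if (any(diff(x) <= 0)) stop("size calibration must be strictly increasing")
  n <- length(y)
  if (n < 3L) return(peak_table(numeric(0), numeric(0)))
  is_max <- y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]
  idx <- which(is_max) + 1L
  idx <- idx[y[idx] >= floor_rfu]
  if (length(idx) == 0L) return(peak_table(numeric(0), numeric(0)))
  sz <- x[idx]; h <- y[idx]
  # cluster maxima closer than merge_units; keep the tallest of each run
  grp <- cumsum(c(TRUE, diff(sz) > merge_units))
  keep <- vapply(split(seq_along(idx), grp),
                 function(i) i[which.max(h[i])], integer(1))
  peak_table(sz[keep], h[keep])
}
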