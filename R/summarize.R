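# Allele classification and per-region mosaicism summaries: min/modal/max
# repeat counts, allele ranges in units and bp, full-mutation read
# fractions, and joint allele-class x methylation-class tables.

ALLELE_CLASSES <- c("normal", "intermediate", "premutation", "full")
METH_CLASSES <- c("unmethylated", "partial", "fully_methylated", "NA")

#' Allele class boundaries (in motif units)
#'
#' Defaults: normal <= 44, intermediate (gray zone) 45-54, premutation
#' 55-200, full mutation >= 201. All boundaries are configurable (e.g. a
#' gray-zone lower bound of 41).
#'
#' @param normal_max Largest normal allele (default 44).
#' @param intermediate_max Largest intermediate allele (default 54).
#' @param premutation_max Largest premutation allele (default 200); full
#'   mutations start at `premutation_max + 1`.
#' @return An object of class `allele_class_config`.
#' @export
allele_class_config <- function(normal_max = 44, intermediate_max = 54,
                                premutation_max = 200) {
  if (!(normal_max < intermediate_max && intermediate_max < premutation_max)) {
    stop("class boundaries must be increasing: normal_max < ",
         "intermediate_max < premutation_max")
  }
  structure(list(normal_max = normal_max,
                 intermediate_max = intermediate_max,
                 premutation_max = premutation_max,
                 full_min = premutation_max + 1),
            class = "allele_class_config")
}

#' Classify an allele by repeat-unit count
#'
#' @param units Numeric vector of motif-unit counts (>= 0).
#' @param cfg An [allele_class_config()].
#' @return Factor with levels `normal`, `intermediate`, `premutation`,
#'   `full`.
#' @export
allele_class <- function(units, cfg = allele_class_config()) {
  if (any(units < 0)) stop("repeat-unit counts must be >= 0")
  idx <- findInterval(units, c(cfg$normal_max, cfg$intermediate_max,
                               cfg$premutation_max),
                      left.open = TRUE) + 1L
  factor(ALLELE_CLASSES[idx], levels = ALLELE_CLASSES)
}

#' Per-region mosaicism summary
#'
#' Summarises the spanning-read repeat calls of one region: minimum, modal
#' (most frequent; ties toward the smaller size) and maximum unit counts;
#' allele range in units and bp; full-mutation read fraction over all
#' spanning reads and over mutation-length (premutation + full) reads; and,
#' when methylation calls are supplied, the joint allele-class x
#' read-methylation-class table.
#'
#' @param calls Repeat-call data frame from [filter_spanning()] (non-empty).
#' @param meth Optional methylation-call data frame from
#'   [methylation_calls()].
#' @param region Region label (e.g. `"cerebellum"`, `"BA10"`).
#' @param cfg An [allele_class_config()].
#' @param meth_cfg A [methylation_config()].
#' @return An object of class `region_summary`.
#' @export
region_summary <- function(calls, meth = NULL, region = "region",
                           cfg = allele_class_config(),
                           meth_cfg = methylation_config()) {
  if (nrow(calls) == 0L) stop("no spanning-read calls for region ", region)
  u <- calls$repeat_units
  tab <- table(u)
  modal <- min(as.numeric(names(tab)[tab == max(tab)]))
  cls <- allele_class(u, cfg)
  n <- nrow(calls)
  n_full <- sum(cls == "full")
  n_mut <- sum(cls %in% c("premutation", "full"))
  class_counts <- table(cls)
  meth_table <- NULL
  if (!is.null(meth)) {
    m <- merge(calls[, c("read_id", "repeat_units")],
               meth[, c("read_id", "proportion")], by = "read_id")
    rc <- classify_read_methylation(m$proportion, meth_cfg)
    rc[is.na(rc)] <- "NA"
    meth_table <- table(
      allele_class = allele_class(m$repeat_units, cfg),
      methylation = factor(rc, levels = METH_CLASSES)
    )
  }
  structure(list(
    region = region,
    n_spanning = n,
    min_units = min(u),
    modal_units = modal,
    max_units = max(u),
    allele_range_units = max(u) - min(u),
    min_bp = min(calls$repeat_bp),
    max_bp = max(calls$repeat_bp),
    allele_range_bp = max(calls$repeat_bp) - min(calls$repeat_bp),
    n_full = n_full,
    full_fraction_pct = 100 * n_full / n,
    full_fraction_of_mutation_pct =
      if (n_mut > 0) 100 * n_full / n_mut else NA_real_,
    class_counts = class_counts,
    meth_table = meth_table
  ), class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Region %s: %d spanning reads\n", x$region, x$n_spanning))
  cat(sprintf("  repeat units  min/modal/max: %g / %g / %g (range %g units, %g bp)\n",
              x$min_units, x$modal_units, x$max_units,
              x$allele_range_units, x$allele_range_bp))
  cat(sprintf("  full-mutation reads: %d (%.1f%% of total%s)\n",
              x$n_full, x$full_fraction_pct,
              if (!is.na(x$full_fraction_of_mutation_pct))
                sprintf(", %.1f%% of mutation-length reads",
                        x$full_fraction_of_mutation_pct) else ""))
  cat("  allele classes: ",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(x$meth_table)) {
    cat("  allele class x methylation class:\n")
    print(x$meth_table)
  }
  invisible(x)
}

#' Long-format allele table across regions (violin-plot export)
#'
#' @param region_calls Named list mapping region label to its repeat-call
#'   data frame. Empty regions are omitted with a warning.
#' @return Data frame `region`, `read_id`, `units`, sorted by region then
#'   read id (lossless and invariant to input read order).
#' @export
export_violin_table <- function(region_calls) {
  stopifnot(length(region_calls) >= 1L, !is.null(names(region_calls)))
  rows <- lapply(names(region_calls), function(rg) {
    calls <- region_calls[[rg]]
    if (is.null(calls) || nrow(calls) == 0L) {
      warning("region ", rg, " has no calls; omitted")
      return(NULL)
    }
    data.frame(region = rg, read_id = calls$read_id,
               units = calls$repeat_units, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(region = character(0), read_id = character(0),
                      units = numeric(0)))
  }
  out <- out[order(out$region, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allele length vs read methylation: permutation test
#'
#' Formalises the contrast between methylated and unmethylated reads (the
#' pattern that longer premutation alleles tend to be unmethylated) as a
#' difference of median unit counts between reads classified
#' `fully_methylated` and `unmethylated`, with a two-sided permutation
#' p-value (labels shuffled `n_perm` times under `seed`). Reads classified
#' `partial` or without methylation information are excluded.
#'
#' @param calls Repeat-call data frame.
#' @param meth Methylation-call data frame.
#' @param meth_cfg A [methylation_config()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed (results are deterministic under the seed).
#' @return List `median_methylated`, `median_unmethylated`, `diff`
#'   (methylated minus unmethylated), `p_value`, `n_methylated`,
#'   `n_unmethylated`. All-`NA` result (not an error) when either group has
#'   fewer than 2 reads.
#' @export
length_methylation_association <- function(calls, meth,
                                           meth_cfg = methylation_config(),
                                           n_perm = 10000L, seed = 1L) {
  m <- merge(calls[, c("read_id", "repeat_units")],
             meth[, c("read_id", "proportion")], by = "read_id")
  grp <- classify_read_methylation(m$proportion, meth_cfg)
  u_m <- m$repeat_units[!is.na(grp) & grp == "fully_methylated"]
  u_u <- m$repeat_units[!is.na(grp) & grp == "unmethylated"]
  if (length(u_m) < 2L || length(u_u) < 2L) {
    return(list(median_methylated = NA_real_,
                median_unmethylated = NA_real_,
                diff = NA_real_, p_value = NA_real_,
                n_methylated = length(u_m), n_unmethylated = length(u_u)))
  }
  obs <- median(u_m) - median(u_u)
  pool <- c(u_m, u_u)
  n1 <- length(u_m)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), n1)
    median(pool[idx]) - median(pool[-idx])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(median_methylated = median(u_m), median_unmethylated = median(u_u),
       diff = obs, p_value = p,
       n_methylated = n1, n_unmethylated = length(u_u))
}
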