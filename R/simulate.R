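# Synthetic targeted long-read and CE-trace generator with known ground
# truth. The generator is the validation backbone of the package: it encodes
# the mosaicism structure the analysis assumes (mixture-distributed repeat
# lengths, haplotype-linked CpG methylation with X-inactivation, Phred-like
# base errors, and TP-PCR/CE stutter with length-biased amplification).

#' Allele mixture model for repeat-length mosaicism
#'
#' Somatic length mosaicism is modelled as a finite mixture over repeat-unit
#' counts: a modal allele plus expansion/contraction components (including
#' rare full mutations). Lengths are sampled as `round(Normal(mean, sd))`
#' truncated at 0.
#'
#' @param components Data frame with columns `mean_repeats` (>= 0),
#'   `sd_repeats` (>= 0) and `weight` (weights must sum to 1 within 1e-9).
#'   Optional columns: `haplotype` (label; default `h1`, `h2`, ...) and
#'   `expanded` (logical; default `mean_repeats >= 55`, the premutation
#'   lower bound) marking the haplotype carrying the expansion for
#'   X-inactivation simulation.
#' @param motif Repeat motif, e.g. `"CGG"`.
#' @param interruptions Optional data frame with columns `position_unit`
#'   (insert after this many motif copies) and `sequence` (DNA inserted),
#'   modelling interrupted/complex repeat tracts.
#' @return An object of class `allele_mixture`.
#' @export
allele_mixture <- function(components, motif, interruptions = NULL) {
  components <- as.data.frame(components)
  stopifnot(all(c("mean_repeats", "sd_repeats", "weight")
                %in% names(components)))
  if (any(components$mean_repeats < 0) || any(components$sd_repeats < 0)) {
    stop("component means and sds must be >= 0")
  }
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (within 1e-9)")
  }
  if (is.null(components$haplotype)) {
    components$haplotype <- paste0("h", seq_len(nrow(components)))
  }
  if (is.null(components$expanded)) {
    components$expanded <- components$mean_repeats >= 55
  }
  motif <- check_dna(motif, "motif")
  if (!is.null(interruptions)) {
    interruptions <- as.data.frame(interruptions)
    stopifnot(all(c("position_unit", "sequence") %in% names(interruptions)))
    interruptions$sequence <- check_dna(interruptions$sequence,
                                        "interruption sequence")
    interruptions <- interruptions[order(interruptions$position_unit), ,
                                   drop = FALSE]
  }
  structure(list(components = components, motif = motif,
                 interruptions = interruptions),
            class = "allele_mixture")
}

#' Haplotype-linked CpG methylation model
#'
#' Per-read methylation is driven by which X chromosome the read's allele
#' sits on. A read from the inactive (methylated) X draws its per-CpG
#' probabilities from a Beta concentrated near 1; a read from the active X
#' from a Beta concentrated near 0. For XX cases, `inactive_x_fraction` is
#' the fraction of cells whose *expanded* allele is on the inactive X (so
#' normal-allele reads are methylated in the complementary fraction). With
#' `xx = FALSE` (single X), all reads are drawn from the active state.
#'
#' @param inactive_x_fraction Fraction in \[0, 1\] of cells with the expanded
#'   allele on the inactive X.
#' @param beta_methylated,beta_unmethylated Length-2 Beta shape parameters
#'   for the inactive (near 1) and active (near 0) states.
#' @param cpg_noise_sd Gaussian noise added to each emitted probability
#'   (then clamped to \[0, 1\]).
#' @param xx `TRUE` for an XX (two-X) case with X-inactivation; `FALSE` for
#'   a single-X case (no methylated state).
#' @return An object of class `methylation_model`.
#' @export
methylation_model <- function(inactive_x_fraction = 0.5,
                              beta_methylated = c(20, 2),
                              beta_unmethylated = c(2, 20),
                              cpg_noise_sd = 0.02,
                              xx = TRUE) {
  stopifnot(inactive_x_fraction >= 0, inactive_x_fraction <= 1,
            cpg_noise_sd >= 0,
            length(beta_methylated) == 2L, all(beta_methylated > 0),
            length(beta_unmethylated) == 2L, all(beta_unmethylated > 0))
  structure(list(inactive_x_fraction = inactive_x_fraction,
                 beta_methylated = beta_methylated,
                 beta_unmethylated = beta_unmethylated,
                 cpg_noise_sd = cpg_noise_sd, xx = isTRUE(xx)),
            class = "methylation_model")
}

#' Read-simulation configuration
#'
#' @param n_reads Number of reads to emit (>= 0).
#' @param mean_qv Mean per-base Phred quality (qualities drawn as
#'   `round(Normal(mean_qv, 3))` clipped to \[1, 60\]).
#' @param base_error_rate Per-base substitution probability in \[0, 1).
#' @param reverse_strand_prob Fraction of reads emitted as reverse
#'   complements.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 100L, mean_qv = 45, base_error_rate = 0,
                            reverse_strand_prob = 0.5, seed = 1L) {
  stopifnot(n_reads >= 0, base_error_rate >= 0, base_error_rate < 1,
            reverse_strand_prob >= 0, reverse_strand_prob <= 1)
  structure(list(n_reads = as.integer(n_reads), mean_qv = mean_qv,
                 base_error_rate = base_error_rate,
                 reverse_strand_prob = reverse_strand_prob,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' CE trace-simulation configuration
#'
#' Models the two TP-PCR/CE artifacts that matter for the instability index:
#' stutter peaks a few motif units off the true allele, and preferential
#' amplification of smaller fragments (exponential per-bp efficiency decay),
#' which hides very long expansions below the detection floor.
#'
#' @param stutter_decay_plus,stutter_decay_minus Geometric decay per stutter
#'   order for peaks above/below the parent allele, each in \[0, 1).
#' @param max_stutter_order Maximum stutter order k (peaks at parent +/- k
#'   units).
#' @param amp_bias_lambda Per-bp exponential decay of amplification
#'   efficiency (>= 0); parent peak height is proportional to
#'   `weight * exp(-lambda * bp)`.
#' @param noise_floor_rfu Peaks below this height (after rescaling the
#'   tallest peak to 100 RFU) are dropped.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(stutter_decay_plus = 0.3,
                             stutter_decay_minus = 0.5,
                             max_stutter_order = 3L,
                             amp_bias_lambda = 0,
                             noise_floor_rfu = 1) {
  stopifnot(stutter_decay_plus >= 0, stutter_decay_plus < 1,
            stutter_decay_minus >= 0, stutter_decay_minus < 1,
            max_stutter_order >= 0, amp_bias_lambda >= 0,
            noise_floor_rfu >= 0)
  structure(list(stutter_decay_plus = stutter_decay_plus,
                 stutter_decay_minus = stutter_decay_minus,
                 max_stutter_order = as.integer(max_stutter_order),
                 amp_bias_lambda = amp_bias_lambda,
                 noise_floor_rfu = noise_floor_rfu),
            class = "trace_sim_config")
}

# Build the repeat tract (motif copies plus any interruptions) for a given
# unit count.
make_repeat_seq <- function(motif, units, interruptions = NULL) {
  if (is.null(interruptions) || nrow(interruptions) == 0L) {
    return(strrep(motif, units))
  }
  ins <- interruptions[interruptions$position_unit <= units, , drop = FALSE]
  if (nrow(ins) == 0L) return(strrep(motif, units))
  bounds <- c(0L, ins$position_unit, units)
  parts <- character(0)
  for (k in seq_len(nrow(ins) + 1L)) {
    parts <- c(parts, strrep(motif, bounds[k + 1L] - bounds[k]))
    if (k <= nrow(ins)) parts <- c(parts, ins$sequence[k])
  }
  paste(parts, collapse = "")
}

#' Simulate targeted long reads with ground truth
#'
#' Each read is `upstream_anchor + motif^n (with interruptions) +
#' downstream_anchor`, with uniform substitution errors at
#' `base_error_rate`, per-base qualities around `mean_qv`, and per-CpG
#' methylation probabilities drawn from the read's haplotype state
#' (inactive/active X). A fraction of reads is reverse-complemented, with
#' methylation probabilities following their bases. Ground truth (true unit
#' count, bp length, haplotype, methylation state) is recorded per read.
#'
#' @param locus A [locus_definition()].
#' @param alleles An [allele_mixture()].
#' @param meth A [methylation_model()], or `NULL` for reads without
#'   methylation information.
#' @param cfg A [read_sim_config()].
#' @return List with elements `reads` (list of read records with fields
#'   `read_id`, `sequence`, `base_qualities`, `cpg_probs` (named by 1-based
#'   position of the CpG cytosine), `strand`, `locus_id`) and `truth`
#'   (data frame `read_id`, `true_repeat_units`, `true_bp_length`,
#'   `true_haplotype`, `true_methylation_state`).
#' @export
simulate_reads <- function(locus, alleles, meth = NULL,
                           cfg = read_sim_config()) {
  stopifnot(inherits(locus, "locus_definition"),
            inherits(alleles, "allele_mixture"),
            is.null(meth) || inherits(meth, "methylation_model"),
            inherits(cfg, "read_sim_config"))
  comp <- alleles$components
  if (abs(sum(comp$weight) - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (within 1e-9)")
  }
  n <- cfg$n_reads
  truth_cols <- c("read_id", "true_repeat_units", "true_bp_length",
                  "true_haplotype", "true_methylation_state")
  if (n == 0L) {
    truth <- data.frame(read_id = character(0),
                        true_repeat_units = integer(0),
                        true_bp_length = integer(0),
                        true_haplotype = character(0),
                        true_methylation_state = character(0))
    return(list(reads = list(), truth = truth))
  }
  set.seed(cfg$seed)
  ci <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
  units <- pmax(0L, as.integer(round(rnorm(n, comp$mean_repeats[ci],
                                           comp$sd_repeats[ci]))))
  is_rev <- runif(n) < cfg$reverse_strand_prob
  if (is.null(meth)) {
    on_inactive <- rep(NA, n)
  } else if (!meth$xx) {
    on_inactive <- rep(FALSE, n)
  } else {
    f <- meth$inactive_x_fraction
    # the expanded allele sits on the inactive X in fraction f of cells; the
    # normal allele of the same cell is then on the active X
    on_inactive <- ifelse(comp$expanded[ci], runif(n) < f, runif(n) < 1 - f)
  }
  up <- locus$upstream_anchor
  dn <- locus$downstream_anchor
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    rep_seq <- make_repeat_seq(alleles$motif, units[i], alleles$interruptions)
    template <- paste0(up, rep_seq, dn)
    L <- nchar(template)
    chars <- strsplit(template, "", fixed = TRUE)[[1L]]
    # CpG sites on the error-free template
    sites <- cpg_sites(template)
    probs <- NULL
    if (!is.null(meth) && length(sites)) {
      shp <- if (isTRUE(on_inactive[i])) meth$beta_methylated
           else meth$beta_unmethylated
      p <- rbeta(length(sites), shp[1L], shp[2L])
      if (meth$cpg_noise_sd > 0) {
        p <- p + rnorm(length(sites), 0, meth$cpg_noise_sd)
      }
      probs <- setNames(pmin(1, pmax(0, p)), sites)
    }
    # uniform substitution errors
    if (cfg$base_error_rate > 0) {
      hit <- which(runif(L) < cfg$base_error_rate)
      if (length(hit)) {
        for (h in hit) {
          chars[h] <- sample(setdiff(c("A", "C", "G", "T"), chars[h]), 1L)
        }
      }
    }
    qual <- as.integer(pmin(60, pmax(1, round(rnorm(L, cfg$mean_qv, 3)))))
    seq_out <- paste(chars, collapse = "")
    # keep only methylation calls whose CpG context survived the error model
    if (!is.null(probs) && length(probs)) {
      pos <- as.integer(names(probs))
      keep <- chars[pos] == "C" & chars[pos + 1L] == "G"
      probs <- probs[keep]
    }
    strand <- "+"
    if (is_rev[i]) {
      strand <- "-"
      seq_out <- revcomp(seq_out)
      qual <- rev(qual)
      if (!is.null(probs) && length(probs)) {
        pos <- as.integer(names(probs))
        newpos <- L - pos # CpG (p, p+1) maps to (L-p, L-p+1); C at L-p
        o <- order(newpos)
        probs <- setNames(unname(probs)[o], newpos[o])
      }
    }
    if (is.null(probs)) probs <- setNames(numeric(0), character(0))
    reads[[i]] <- list(
      read_id = sprintf("%s_read_%05d", locus$locus_id, i),
      sequence = seq_out,
      base_qualities = qual,
      cpg_probs = probs,
      strand = strand,
      locus_id = locus$locus_id
    )
  }
  motif_len <- nchar(locus$motif)
  bp <- vapply(seq_len(n), function(i) {
    nchar(make_repeat_seq(alleles$motif, units[i], alleles$interruptions))
  }, integer(1))
  truth <- data.frame(
    read_id = vapply(reads, `[[`, "", "read_id"),
    true_repeat_units = units,
    true_bp_length = bp,
    true_haplotype = comp$haplotype[ci],
    true_methylation_state = ifelse(is.na(on_inactive), NA_character_,
                                    ifelse(on_inactive, "methylated",
                                           "unmethylated")),
    stringsAsFactors = FALSE
  )
  stopifnot(identical(names(truth), truth_cols))
  list(reads = reads, truth = truth)
}

#' Simulate a TP-PCR/CE peak table
#'
#' Each true allele with cell fraction `w` contributes a parent peak of
#' height proportional to `w * exp(-amp_bias_lambda * bp)` plus geometric
#' stutter peaks at +/- k motif units (`height = parent * decay^k`, plus and
#' minus decays independent). Coincident sizes are summed, heights are
#' rescaled so the tallest peak is 100 RFU, and peaks below the noise floor
#' are dropped.
#'
#' @param allele_fracs Named numeric vector: names are repeat-unit lengths,
#'   values are cell fractions summing to 1.
#' @param locus A [locus_definition()] (supplies the motif length for the
#'   unit-to-bp conversion).
#' @param cfg A [trace_sim_config()].
#' @param normalize If `FALSE`, return raw (pre-rescaling) heights and keep
#'   sub-floor peaks; used for validating the height accumulation.
#' @return A [peak_table()] with columns `size_units`, `size_bp`,
#'   `height_rfu`.
#' @export
simulate_trace <- function(allele_fracs, locus, cfg = trace_sim_config(),
                           normalize = TRUE) {
  stopifnot(inherits(locus, "locus_definition"),
            inherits(cfg, "trace_sim_config"))
  if (length(allele_fracs) == 0L) stop("allele_fracs must be non-empty")
  u <- as.numeric(names(allele_fracs))
  w <- as.numeric(allele_fracs)
  if (any(is.na(u)) || any(u < 0)) stop("unit lengths must be >= 0")
  if (abs(sum(w) - 1) > 1e-9) stop("cell fractions must sum to 1")
  motif_len <- nchar(locus$motif)
  k <- seq_len(cfg$max_stutter_order)
  sizes <- heights <- numeric(0)
  for (a in seq_along(u)) {
    parent <- w[a] * exp(-cfg$amp_bias_lambda * u[a] * motif_len)
    sizes <- c(sizes, u[a])
    heights <- c(heights, parent)
    if (cfg$max_stutter_order > 0L) {
      sizes <- c(sizes, u[a] + k, u[a] - k)
      heights <- c(heights, parent * cfg$stutter_decay_plus^k,
                   parent * cfg$stutter_decay_minus^k)
    }
  }
  keep <- sizes >= 0
  sizes <- sizes[keep]; heights <- heights[keep]
  agg <- tapply(heights, sizes, sum)
  sz <- as.numeric(names(agg))
  h <- as.numeric(agg)
  if (normalize) {
    h <- 100 * h / max(h)
    keep <- h >= cfg$noise_floor_rfu
    sz <- sz[keep]; h <- h[keep]
  }
  peak_table(size_units = sz, height_rfu = h,
             size_bp = sz * motif_len, locus_id = locus$locus_id)
}

#' Render a peak table as a Gaussian-bump CE trace
#'
#' A simple continuous stand-in for an electropherogram signal, used to
#' exercise the peak caller: each peak becomes a Gaussian bump of the peak's
#' height centred at its size.
#'
#' @param table A [peak_table()].
#' @param from,to,by Size grid in repeat units (defaults bracket the peaks).
#' @param sd_units Bump standard deviation in repeat units.
#' @return Data frame with columns `size_units`, `intensity`.
#' @export
simulate_gaussian_trace <- function(table, from = NULL, to = NULL, by = 0.02,
                                    sd_units = 0.15) {
  stopifnot(nrow(table) >= 1L)
  if (is.null(from)) from <- min(table$size_units) - 5
  if (is.null(to)) to <- max(table$size_units) + 5
  x <- seq(from, to, by = by)
  y <- numeric(length(x))
  for (i in seq_len(nrow(table))) {
    y <- y + table$height_rfu[i] *
      exp(-(x - table$size_units[i])^2 / (2 * sd_units^2))
  }
  data.frame(size_units = x, intensity = y)
}

#' Write a ground-truth table to TSV
#'
#' @param truth Ground-truth data frame from [simulate_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
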