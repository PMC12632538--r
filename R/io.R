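# Standard-format I/O: SAM/BAM with MM/ML modified-base tags, ground-truth
# and call TSVs, JSON reports, and the end-to-end pipeline driver.

phred_to_ascii <- function(q) intToUtf8(pmin(93L, pmax(0L, q)) + 33L)

# MM/ML encoding for one read. `seq` and `cpg_probs` are in the sequenced
# (original) orientation, which is what the MM tag references per the SAM
# tag specification. Uses the 'C+m?' (no-call-implicit) mode: unlisted Cs
# carry no methylation information.
encode_mm_ml <- function(seq, cpg_probs) {
  if (length(cpg_probs) == 0L) return(NULL)
  pos <- as.integer(names(cpg_probs))
  o <- order(pos)
  pos <- pos[o]
  p <- unname(cpg_probs)[o]
  all_c <- which(strsplit(seq, "", fixed = TRUE)[[1L]] == "C")
  idx <- match(pos, all_c)
  if (anyNA(idx)) stop("cpg_probs positions must point at C bases")
  deltas <- diff(c(0L, idx)) - 1L
  bytes <- as.integer(pmin(255, pmax(0, floor(p * 256))))
  list(
    mm = paste0("MM:Z:C+m?,", paste(deltas, collapse = ","), ";"),
    ml = paste0("ML:B:C,", paste(bytes, collapse = ","))
  )
}

#' Write simulated reads as a SAM file
#'
#' Reads are emitted as minimally aligned records at the locus (CIGAR
#' `<len>M`). Reverse-strand reads are stored in reference orientation with
#' FLAG 16, qualities reversed accordingly, and MM/ML tags referencing the
#' original (sequenced) orientation as the SAM tag specification requires.
#' ML bytes encode probabilities as `floor(p * 256)` (decoded back as the
#' interval midpoint `(byte + 0.5) / 256`).
#'
#' @param reads List of read records from [simulate_reads()].
#' @param locus A [locus_definition()].
#' @param path Output SAM path.
#' @param ref_len Reference length for the `@SQ` header line.
#' @return Invisibly, `path`.
#' @export
write_reads_sam <- function(reads, locus, path,
                            ref_len = locus$end + 100000L) {
  pos <- max(1L, locus$start - nchar(locus$upstream_anchor) + 1L)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", locus$chrom, as.integer(ref_len)),
    "@PG\tID:repeatmosaic\tPN:repeatmosaic"
  )
  recs <- vapply(reads, function(rd) {
    rev <- identical(rd$strand, "-")
    seq_store <- if (rev) revcomp(rd$sequence) else rd$sequence
    qual_store <- if (rev) rev(rd$base_qualities) else rd$base_qualities
    tags <- encode_mm_ml(rd$sequence, rd$cpg_probs)
    fields <- c(
      rd$read_id,
      if (rev) "16" else "0",
      locus$chrom,
      as.character(pos),
      "60",
      paste0(nchar(seq_store), "M"),
      "*", "0", "0",
      seq_store,
      phred_to_ascii(qual_store)
    )
    if (!is.null(tags)) fields <- c(fields, tags$mm, tags$ml)
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(lines, recs), path)
  invisible(path)
}

# Decode the C+m item of an MM/ML tag pair into a named probability vector
# over stored-orientation positions of CpG cytosines (top-strand
# coordinates). `seq_store` is the sequence as stored in the record;
# `reverse` indicates FLAG bit 16.
decode_mm_ml <- function(seq_store, reverse, mm, ml) {
  empty <- setNames(numeric(0), character(0))
  if (is.null(mm) || is.na(mm) || !nzchar(mm) || is.null(ml)) return(empty)
  items <- strsplit(sub(";$", "", mm), ";", fixed = TRUE)[[1L]]
  heads <- sub(",.*$", "", items)
  lens <- vapply(items, function(it) {
    body <- sub("^[^,]*,?", "", it)
    if (!nzchar(body)) 0L
    else length(strsplit(body, ",", fixed = TRUE)[[1L]])
  }, integer(1))
  sel <- which(grepl("^C\\+m", heads))
  if (length(sel) == 0L) return(empty)
  sel <- sel[1L]
  body <- sub("^[^,]*,?", "", items[sel])
  if (!nzchar(body)) return(empty)
  deltas <- as.integer(strsplit(body, ",", fixed = TRUE)[[1L]])
  ml <- as.integer(ml)
  off <- if (sel > 1L) sum(lens[seq_len(sel - 1L)]) else 0L
  bytes <- ml[off + seq_along(deltas)]
  orig <- if (reverse) revcomp(seq_store) else seq_store
  all_c <- which(strsplit(orig, "", fixed = TRUE)[[1L]] == "C")
  idx <- cumsum(deltas + 1L)
  if (any(idx > length(all_c))) {
    stop("malformed MM tag: more skips than C bases in read")
  }
  pos_orig <- all_c[idx]
  probs <- (bytes + 0.5) / 256
  if (reverse) {
    # the 5mC on the original read's C maps to the top-strand CpG cytosine
    # at L - p in the stored orientation
    pos_store <- nchar(seq_store) - pos_orig
    o <- order(pos_store)
    setNames(probs[o], pos_store[o])
  } else {
    setNames(probs, pos_orig)
  }
}

#' Read locus-overlapping reads from SAM/BAM
#'
#' Returns the reads overlapping the locus interval with base qualities and
#' CpG methylation probabilities decoded from MM/ML tags (`C+m`, 5mC at
#' CpG; ML bytes are converted to probabilities as `(byte + 0.5) / 256`).
#' Reads without methylation tags get empty `cpg_probs` (downstream
#' methylation calls become `NA`). SAM input is converted, sorted and
#' indexed on the fly.
#'
#' @param path SAM or BAM file.
#' @param panel A named list of loci from [read_panel()], or a single
#'   [locus_definition()].
#' @param locus_id Which locus to fetch (ignored when `panel` is a single
#'   locus).
#' @return List of read records (fields `read_id`, `sequence`,
#'   `base_qualities`, `cpg_probs`, `strand`, `locus_id`; sequences in
#'   stored/reference orientation, `cpg_probs` named by 1-based top-strand
#'   CpG cytosine position).
#' @export
read_aligned_reads <- function(path, panel, locus_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  locus <- if (inherits(panel, "locus_definition")) panel
           else panel[[locus_id]]
  if (is.null(locus)) stop("locus ", locus_id, " not in panel")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile()
    bam <- Rsamtools::asBam(path, tmp, overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    sorted <- Rsamtools::sortBam(bam, tempfile())
    Rsamtools::indexBam(sorted)
    bam <- sorted
  }
  gr <- GenomicRanges::GRanges(
    locus$chrom, IRanges::IRanges(locus$start + 1L, locus$end))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual"),
    tag = c("MM", "ML"), which = gr)
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(res$qname)
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  lapply(seq_len(n), function(i) {
    reverse <- bitwAnd(res$flag[i], 16L) > 0L
    mm <- if (is.null(res$tag$MM)) NA_character_ else res$tag$MM[i]
    ml <- if (is.null(res$tag$ML)) NULL else res$tag$ML[[i]]
    probs <- tryCatch(
      decode_mm_ml(seqs[i], reverse, mm, ml),
      error = function(e) stop("read ", res$qname[i], ": ",
                               conditionMessage(e), call. = FALSE))
    list(
      read_id = res$qname[i],
      sequence = seqs[i],
      base_qualities = as.integer(charToRaw(quals[i])) - 33L,
      cpg_probs = probs,
      strand = if (reverse) "-" else "+",
      locus_id = locus$locus_id
    )
  })
}

#' Run the end-to-end per-region pipeline
#'
#' For each region: spanning-read extraction, methylation calling, and the
#' region summary; then cross-region exports (violin table) and a JSON run
#' report capturing the configuration, its hash, the seed and per-stage
#' counts. The pipeline itself draws no random numbers, so reruns with an
#' identical configuration are identical.
#'
#' @param cfg List with elements:
#'   * `locus`: a [locus_definition()] (or `panel` + `locus_id` paths).
#'   * `regions`: named list; each element has either `reads` (an in-memory
#'     read list) or `bam` (a SAM/BAM path).
#'   * optional `class_config`, `meth_config`, `seed`, `out_dir`.
#' @return Invisibly, a list with `summaries` (per region), `calls`,
#'   `meth`, `violin`, and `report`. When `cfg$out_dir` is set, TSV/JSON
#'   outputs are written there.
#' @export
run_pipeline <- function(cfg) {
  locus <- cfg$locus
  if (is.null(locus)) {
    panel <- read_panel(cfg$panel$bed, cfg$panel$sidecar)
    locus <- panel[[cfg$locus_id]]
  }
  stopifnot(inherits(locus, "locus_definition"),
            length(cfg$regions) >= 1L, !is.null(names(cfg$regions)))
  class_cfg <- if (!is.null(cfg$class_config)) cfg$class_config
               else if (!is.null(locus$class_config)) locus$class_config
               else allele_class_config()
  meth_cfg <- if (!is.null(cfg$meth_config)) cfg$meth_config
              else methylation_config()
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  calls <- meth <- summaries <- list()
  counts <- list()
  for (rg in names(cfg$regions)) {
    spec <- cfg$regions[[rg]]
    reads <- if (!is.null(spec$reads)) spec$reads
             else read_aligned_reads(spec$bam, locus)
    fs <- filter_spanning(reads, locus)
    mc <- methylation_calls(reads[match(fs$calls$read_id,
                                        vapply(reads, `[[`, "", "read_id"))],
                            meth_cfg)
    summaries[[rg]] <- region_summary(fs$calls, mc, region = rg,
                                      cfg = class_cfg, meth_cfg = meth_cfg)
    calls[[rg]] <- fs$calls
    meth[[rg]] <- mc
    counts[[rg]] <- list(n_reads = length(reads),
                         n_spanning = nrow(fs$calls),
                         n_rejected = nrow(fs$rejected))
    if (!is.null(out_dir)) {
      write.table(fs$calls, file.path(out_dir, paste0(rg, "_calls.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(mc, file.path(out_dir, paste0(rg, "_meth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      wf <- waterfall_long(build_waterfall(fs$calls, reads))
      write.table(wf, file.path(out_dir, paste0(rg, "_waterfall.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  violin <- export_violin_table(calls)
  cfg_ser <- tempfile()
  saveRDS(list(locus = locus, class_cfg = class_cfg, meth_cfg = meth_cfg,
               seed = cfg$seed, regions = names(cfg$regions)),
          cfg_ser, version = 2)
  report <- list(
    package_version = as.character(packageVersion("repeatmosaic")),
    seed = cfg$seed,
    locus_id = locus$locus_id,
    config_hash = unname(tools::md5sum(cfg_ser)),
    regions = counts,
    summaries = lapply(summaries, function(s)
      s[c("region", "n_spanning", "min_units", "modal_units", "max_units",
          "allele_range_units", "allele_range_bp", "n_full",
          "full_fraction_pct")])
  )
  unlink(cfg_ser)
  if (!is.null(out_dir)) {
    write.table(violin, file.path(out_dir, "violin.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(summaries = summaries, calls = calls, meth = meth,
                 violin = violin, report = report))
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the `cfg` list of [run_pipeline()] (`panel`, `locus_id`,
#' `regions` with `bam` paths, `seed`, `out_dir`, and flat class/meth
#' boundary overrides).
#'
#' @param path YAML file.
#' @return A config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$class_config)) {
    y$class_config <- do.call(allele_class_config, y$class_config)
  }
  if (!is.null(y$meth_config)) {
    y$meth_config <- do.call(methylation_config, y$meth_config)
  }
  y
}
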