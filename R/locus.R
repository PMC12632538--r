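# Locus panel: repeat loci with motifs and flanking anchor sequences.

#' Define a tandem-repeat locus
#'
#' A locus couples a genomic interval with the repeat motif and short unique
#' anchor sequences immediately flanking the repeat tract. Anchors are what
#' the per-read extractor searches for; the allele is the sequence between
#' them.
#'
#' @param locus_id Unique locus identifier (e.g. `"FMR1"`).
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open genomic interval of the repeat region.
#' @param motif Repeat motif (e.g. `"CGG"`); for complex loci the primary
#'   motif used to convert base pairs to motif units.
#' @param upstream_anchor,downstream_anchor Flanking anchor sequences
#'   (typically 20 bp) immediately before/after the repeat tract.
#' @param max_anchor_edits Maximum Levenshtein distance tolerated when
#'   matching each anchor within a read (default 3).
#' @param class_config Optional [allele_class_config()] overriding the
#'   default allele class boundaries for this locus.
#' @return An object of class `locus_definition`.
#' @export
locus_definition <- function(locus_id, chrom, start, end, motif,
                             upstream_anchor, downstream_anchor,
                             max_anchor_edits = 3L, class_config = NULL) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end) {
    stop("locus interval must satisfy start < end (0-based half-open)")
  }
  motif <- check_dna(motif, "motif")
  if (nchar(motif) < 1L) stop("motif length must be >= 1")
  upstream_anchor <- check_dna(upstream_anchor, "upstream_anchor")
  downstream_anchor <- check_dna(downstream_anchor, "downstream_anchor")
  if (!nzchar(upstream_anchor) || !nzchar(downstream_anchor)) {
    stop("anchors must be non-empty")
  }
  max_anchor_edits <- as.integer(max_anchor_edits)
  if (max_anchor_edits < 0L) stop("max_anchor_edits must be >= 0")
  structure(
    list(locus_id = locus_id, chrom = chrom, start = start, end = end,
         motif = motif,
         upstream_anchor = upstream_anchor,
         downstream_anchor = downstream_anchor,
         max_anchor_edits = max_anchor_edits,
         class_config = class_config),
    class = "locus_definition"
  )
}

#' @export
print.locus_definition <- function(x, ...) {
  cat(sprintf("<locus %s> %s:%d-%d motif=%s anchors=%d/%d bp (max edits %d)\n",
              x$locus_id, x$chrom, x$start, x$end, x$motif,
              nchar(x$upstream_anchor), nchar(x$downstream_anchor),
              x$max_anchor_edits))
  invisible(x)
}

#' Read a locus panel (BED + motif/anchor sidecar)
#'
#' The panel is a BED file of repeat intervals (`chrom`, `start`, `end`,
#' `name`; 0-based half-open) plus a tab-separated sidecar keyed by
#' `locus_id` with columns `motif`, `upstream_anchor`, `downstream_anchor`
#' and optional `max_anchor_edits`, `normal_max`, `intermediate_max`,
#' `premutation_max` (per-locus allele class boundary overrides).
#'
#' @param bed_path Path to the BED file.
#' @param sidecar_path Path to the sidecar TSV.
#' @return Named list of [locus_definition()] objects.
#' @export
read_panel <- function(bed_path, sidecar_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  ids <- gr$name
  if (anyDuplicated(ids)) stop("locus_ids in panel BED must be unique")
  side <- read.table(sidecar_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, quote = "")
  if (!all(c("locus_id", "motif", "upstream_anchor", "downstream_anchor")
           %in% names(side))) {
    stop("sidecar must have columns locus_id, motif, upstream_anchor, ",
         "downstream_anchor")
  }
  missing <- setdiff(ids, side$locus_id)
  if (length(missing)) {
    stop("panel BED ids without a sidecar row: ",
         paste(missing, collapse = ", "))
  }
  loci <- lapply(seq_along(gr), function(i) {
    row <- side[match(ids[i], side$locus_id), ]
    cls <- NULL
    if (all(c("normal_max", "intermediate_max", "premutation_max")
            %in% names(row)) && !is.na(row$normal_max)) {
      cls <- allele_class_config(row$normal_max, row$intermediate_max,
                                 row$premutation_max)
    }
    locus_definition(
      locus_id = ids[i],
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      start = GenomicRanges::start(gr[i]) - 1L, # GRanges is 1-based
      end = GenomicRanges::end(gr[i]),
      motif = row$motif,
      upstream_anchor = row$upstream_anchor,
      downstream_anchor = row$downstream_anchor,
      max_anchor_edits = if ("max_anchor_edits" %in% names(row) &&
                             !is.na(row$max_anchor_edits))
        row$max_anchor_edits else 3L,
      class_config = cls
    )
  })
  names(loci) <- ids
  loci
}

#' Write a locus panel (BED + sidecar TSV)
#'
#' @param loci Named list of [locus_definition()] objects.
#' @param bed_path,sidecar_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(loci, bed_path, sidecar_path) {
  bed <- data.frame(
    chrom = vapply(loci, `[[`, "", "chrom"),
    start = vapply(loci, `[[`, 0L, "start"),
    end = vapply(loci, `[[`, 0L, "end"),
    name = vapply(loci, `[[`, "", "locus_id")
  )
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  side <- data.frame(
    locus_id = bed$name,
    motif = vapply(loci, `[[`, "", "motif"),
    upstream_anchor = vapply(loci, `[[`, "", "upstream_anchor"),
    downstream_anchor = vapply(loci, `[[`, "", "downstream_anchor"),
    max_anchor_edits = vapply(loci, `[[`, 0L, "max_anchor_edits")
  )
  write.table(side, sidecar_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(bed = bed_path, sidecar = sidecar_path))
}
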