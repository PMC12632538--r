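---
title: "Methods: quantifying repeat-length and methylation mosaicism from targeted long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying repeat-length and methylation mosaicism from targeted long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatmosaic)
```

## The measurement problem

Tandem-repeat disease loci such as the *FMR1* CGG tract are somatically
unstable: within one tissue, cells carry different repeat lengths
(length mosaicism) and different promoter methylation states (methylation
mosaicism). Two assays see this very differently.

Triplet-repeat-primed PCR with capillary electrophoresis (TP-PCR/CE)
measures the bulk population as a ladder of peaks. It is cheap and routine
but PCR preferentially amplifies short fragments, so very long expansions
fade below the detection floor, and the trace only supports a summary
statistic — the instability (expansion) index — rather than per-molecule
calls.

Targeted, amplification-free HiFi sequencing spans each repeat with a
single long read and preserves native 5mC methylation, so each read is a
direct measurement of one molecule's allele length and methylation state.
This package implements the per-read analysis for such data, the CE index
for comparison, and a simulator that ties the two together with known
ground truth.

## Flank-anchored allele sizing

A locus is defined by its repeat motif and two short anchor sequences
(default 20 bp) immediately flanking the repeat tract. For each read we
search both orientations for both anchors with a semi-global edit-distance
scan: for every possible match end position the minimum Levenshtein
distance of the anchor against a substring ending there is computed by
dynamic programming (the within-row dependency is removed with a running
minimum identity, so each anchor-by-read scan is a handful of vectorized
operations). A match is accepted if its best distance is at most
`max_anchor_edits` (default 3).

The allele is the sequence strictly between the upstream match end and the
downstream match start; `repeat_bp` is its length, `repeat_units` is
`floor(repeat_bp / motif_length)`, and `mean_baseq` is the arithmetic mean
of the Phred values over the span (averaged in Phred space; a zero-length
span reports `NA`). Tie-breaking is deliberately asymmetric: among
equally-good upstream matches the rightmost wins, among downstream matches
the leftmost after the upstream end wins. This yields the *tightest* span,
which keeps internal interruptions (e.g. the mononucleotide adenine inserts
of complex GAA loci) inside the reported allele — for such loci the bp
length is the primary quantity and motif units are a floor-derived
convenience. The orientation with the lower combined edit distance wins,
with ties going to the forward strand; a substitution-only error process
never changes the span length, so exactness degrades only through anchor
boundary shifts.

Reads where either anchor cannot be matched within budget are classified
non-spanning. They are data, not errors: `filter_spanning()` returns every
input read exactly once, as a call or as a rejection with a reason.

Coordinates are 0-based half-open throughout (BED-native).

## Methylation scoring

Per-CpG 5mC probabilities come from MM/ML modified-base tags (`C+m` items;
an ML byte *b* decodes to the interval midpoint (*b* + 0.5)/256, so byte
255 is 0.99805). For reverse-aligned records the tag references the
original read orientation; positions are remapped to top-strand CpG
cytosines.

Classification uses inclusive cutoffs: probability ≥ 0.66 methylated,
≤ 0.33 unmethylated, intermediate otherwise. A read's methylation
proportion is `n_methylated / n_cpg` with **all** CpGs in the denominator —
intermediate sites dilute the score but are never counted as methylated.
This is forced by the defining worked example (10 CpGs, 8 methylated →
0.8, regardless of how the other two sites score). A read with no CpG
information scores `NA` and stays `NA` through every downstream table.

Read-level classes use two configurable bounds with no canonical published
values: fully methylated at proportion ≥ 0.80, unmethylated at ≤ 0.20,
partial between. The defaults are symmetric and deliberately far from the
per-CpG cutoffs so that single-site noise cannot flip a read's class.

The **activation ratio** is the fraction of normal-length reads classified
unmethylated — the proportion of the normal allele on the active X of an
XX individual. Reads without methylation information are excluded from the
denominator. All of a read's CpGs are used; a promoter-window restriction
would need per-locus annotation we do not require.

## The instability (expansion) index

From a peak table (sizes in repeat units, heights in RFU), the modal peak
is the tallest (ties toward the smaller size, which is conservative —
it can only lower the index). The inclusion set is the modal peak plus
every peak to its right with height at least 20% of the modal height;
leftward peaks are excluded because minus-stutter from incomplete PCR
fragments contaminates that side. The index is the inclusion-set-normalized
height-weighted mean distance from the modal size:

$$ii = \sum_{i \in S} \frac{h_i}{\sum_{j \in S} h_j}\,(u_i - u_{modal})$$

The literature that uses this index does not print a single canonical
formula; we normalize over included peaks only and measure distances in
repeat units. Both choices are exposed (threshold fraction; unit-vs-bp via
the peak table itself), and because heights are normalized the index is
invariant to overall trace scale, which also makes the 20%-of-modal
threshold scale-free. Consequences worth knowing: ii ≥ 0 always; a
modal-only trace scores 0; adding any rightward above-threshold peak
strictly increases it. Coincident sizes are summed *before* modal
detection, so stutter merging cannot split the modal peak.

`peaks_from_trace()` turns a sampled trace (any strictly increasing size
calibration) into a peak table by local-maxima calling with a 0.5-unit
merge radius, keeping the taller of adjacent maxima.

## Allele classes and region summaries

Default class boundaries in motif units: normal ≤ 44, intermediate
(gray zone) 45–54, premutation 55–200, full mutation ≥ 201. These
reconcile the conventional ~55–200 premutation range, full mutations
"exceeding 200", and the classification of a 45-unit allele as
intermediate; a stricter gray-zone lower bound (e.g. 41) is a
configuration, not the default. Classes are contiguous and exhaustive over
non-negative counts, and every summary's class counts provably partition
its spanning reads.

The modal allele of a region is the most frequent unit count, ties to the
smaller size (mirroring the CE modal rule). Because the literature
alternates between "percent of total reads" and "percent of
mutation-length reads" for full-mutation fractions, the summary reports
both, labelled.

`length_methylation_association()` formalises the qualitative observation
that longer alleles tend to be unmethylated: difference of median unit
counts between fully-methylated and unmethylated reads, with a two-sided
permutation p-value (default 10,000 label shuffles, seeded, p computed
with the add-one correction so it is never exactly zero). Partial and
`NA` reads are excluded; a group with fewer than two reads yields an `NA`
result rather than an error.

## The simulator: what it emulates and what it does not

The generator exists so every pipeline claim can be checked against known
truth. Its defaults are the study conditions the analysis assumes:

* **Length mosaicism** is a finite mixture over unit counts — a modal
  allele plus expansion/contraction components, including rare
  full-mutation components (e.g. weights 0.9/0.1 with means 100/1000).
  Lengths are `round(Normal(mean, sd))` truncated at 0: simple, and
  sufficient for mixture-recovery tests.
* **Methylation** is haplotype-linked. Each read draws per-CpG
  probabilities from one of two Beta states — Beta(20, 2) for the inactive
  (methylated) X, Beta(2, 20) for the active — plus Gaussian noise
  (sd 0.02), clamped to [0, 1]. For XX cases, `inactive_x_fraction` is the
  fraction of cells whose *expanded* allele is on the inactive X; the
  normal allele of the same cell is then on the active X, so
  normal-allele reads are methylated in the complementary fraction and the
  activation ratio recovers `inactive_x_fraction` itself. Single-X cases
  (`xx = FALSE`) emit only the active state. The Beta shapes keep
  per-site misclassification (across the 0.66/0.33 cutoffs) rare enough
  that read classes track haplotype states at realistic CpG counts.
* **Sequencing noise** is uniform substitution at `base_error_rate` with
  per-base qualities `round(Normal(mean_qv, 3))` clipped to [1, 60]
  (default mean QV 45, the headline HiFi accuracy class). There is no
  indel model: substitutions leave span lengths intact, which is exactly
  what makes the exact-recovery invariant sharp. CpG sites are defined on
  the error-free template; a call whose CG context is destroyed by a
  simulated error is dropped, as a real basecaller would not report it.
* **CE traces** get geometric stutter in motif units (plus and minus
  decays independent, because minus-stutter is the reason leftward peaks
  are excluded from the index) and an exponential amplification bias
  `exp(-lambda * bp)`. Heights are rescaled so the tallest peak is
  100 RFU and sub-floor peaks are dropped. No published fit exists for
  stutter or bias magnitudes; the defaults (decays 0.3/0.5, order 3,
  floor 1 RFU) are illustrative, and the tests that depend on bias set it
  explicitly.

Reads are emitted as `anchor + motif^n (+ interruptions) + anchor`; real
reads carry kilobases of additional flank, adapter chimeras, indel errors
and mapping artifacts that this generator deliberately omits. Passing
tests therefore demonstrate the correctness of the *analysis* under the
stated generative assumptions, not the robustness of anchoring on raw
production BAMs.

Determinism is a contract: identical configuration and seed give
byte-identical reads, truth tables and traces (`set.seed` at entry; the
pipeline itself draws no random numbers).

## Numerical and interface choices

* ML byte encoding `floor(p * 256)` clipped to 255, decoding
  `(byte + 0.5)/256`: the standard midpoint convention; round-tripping
  quantizes probabilities to 1/256, which is far below the 0.33/0.66
  cutoff granularity.
* The Phred transform is `100 (1 - 10^{-qv/10})`: QV 45 is 99.99684% at
  5-decimal rounding. (A mean QV of 44.6 corresponds to 99.99653%, not
  99.99684% — when quoting both, consistency is the caller's problem; we
  implement only the transform.)
* Waterfall matrices order reads by descending `repeat_bp` with `read_id`
  as the deterministic tie-break, so exports are invariant to input order.
* Anchor defaults (20 bp, 3 edits) balance specificity against HiFi error
  rates; at 0.1% substitution error ≥ 99% of reads recover their unit
  count within ±1.

## Problem sizes used in validation

The shipped tests validate at deliberately modest scales chosen to make
binomial recovery bands meaningful: 1000–2000 reads for exact/noisy length
recovery and mixture-weight recovery, 400–500 reads per X-inactivation
fraction, 200-table brute-force audits of the instability index
(tolerance 1e-9), and 500-read anchor-search audits against a naive
quadratic dynamic program. Recovery assertions use 3-binomial-SD bands
around the generative parameter, which is the correct width for a seeded
single draw.

## Known limitations

* One motif per locus; complex loci are handled via bp length plus
  explicit interruption specs, not motif decomposition.
* No indel or chimera error model, and no realignment: reads are analysed
  as given.
* The instability index cannot be compared across labs without agreeing
  on the normalization set and units; treat cross-study ii values as
  ordinal.
* CE simulation produces peak tables (optionally Gaussian-bump traces for
  the peak caller), not raw fluorescence waveforms, and no allelic-ladder
  size calling is attempted.
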