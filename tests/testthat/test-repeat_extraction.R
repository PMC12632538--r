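make_read <- function(seq, id = "r1", qual = rep(40L, nchar(seq)),
                      locus_id = NA_character_) {
  list(read_id = id, sequence = seq, base_qualities = qual,
       cpg_probs = setNames(numeric(0), character(0)),
       strand = "+", locus_id = locus_id)
}

test_that("exact flanks give an exact forward call", {
  loc <- test_locus()
  seq <- paste0(loc$upstream_anchor, strrep("CGG", 30), loc$downstream_anchor)
  fl <- locate_flanks(make_read(seq), loc)
  expect_equal(fl$strand, "+")
  expect_equal(fl$upstream_end, 20)
  expect_equal(fl$downstream_start, 20 + 90)
  expect_equal(fl$upstream_edits, 0)
  expect_equal(fl$downstream_edits, 0)
  call <- extract_repeat(make_read(seq), loc)
  expect_equal(call$repeat_bp, 90L)
  expect_equal(call$repeat_units, 30L)
  expect_equal(call$repeat_sequence, strrep("CGG", 30))
  expect_equal(call$mean_baseq, 40)
})

test_that("reverse-complemented reads give the same call with strand minus", {
  loc <- test_locus()
  seq <- paste0(loc$upstream_anchor, strrep("CGG", 30), loc$downstream_anchor)
  fwd <- extract_repeat(make_read(seq), loc)
  rev <- extract_repeat(make_read(revcomp(seq)), loc)
  expect_equal(rev$strand, "-")
  expect_equal(rev$repeat_bp, fwd$repeat_bp)
  expect_equal(rev$repeat_units, fwd$repeat_units)
  expect_equal(rev$repeat_sequence, fwd$repeat_sequence)
  expect_equal(rev$mean_baseq, fwd$mean_baseq)
})

test_that("anchor mismatches are tolerated up to the edit budget", {
  loc <- test_locus()
  u <- loc$upstream_anchor
  mutate <- function(s, at) {
    for (i in at) substr(s, i, i) <- setdiff(c("A", "C", "G", "T"),
                                             substr(s, i, i))[1]
    s
  }
  u2 <- mutate(u, c(3, 9))
  seq2 <- paste0(u2, strrep("CGG", 25), loc$downstream_anchor)
  fl <- locate_flanks(make_read(seq2), loc)
  expect_equal(fl$upstream_edits, 2)
  expect_equal(fl$downstream_start - fl$upstream_end, 75)

  u4 <- mutate(u, c(3, 9, 13, 17))
  seq4 <- paste0(u4, strrep("CGG", 25), loc$downstream_anchor)
  expect_error(locate_flanks(make_read(seq4), loc),
               class = "nonSpanningRead")
})

test_that("anchor search agrees with a naive quadratic DP on random reads", {
  set.seed(99)
  for (i in 1:500) {
    pattern <- random_dna(sample(4:8, 1))
    text <- random_dna(sample(10:40, 1))
    fast <- repeatmosaic:::edit_end_distances(pattern, text)
    slow <- naive_edit_end_distances(pattern, text)
    expect_equal(fast, slow)
  }
})

test_that("a 91-bp span floors to 30 CGG units", {
  loc <- test_locus()
  seq <- paste0(loc$upstream_anchor, strrep("CGG", 30), "A",
                loc$downstream_anchor)
  call <- extract_repeat(make_read(seq), loc)
  expect_equal(call$repeat_bp, 91L)
  expect_equal(call$repeat_units, 30L)
})

test_that("a zero-length span reports NA mean quality", {
  loc <- test_locus()
  seq <- paste0(loc$upstream_anchor, loc$downstream_anchor)
  call <- extract_repeat(make_read(seq), loc)
  expect_equal(call$repeat_bp, 0L)
  expect_true(is.na(call$mean_baseq))
})

test_that("filter_spanning accounts for every read exactly once", {
  loc <- test_locus()
  good <- lapply(1:10, function(i) make_read(
    paste0(loc$upstream_anchor, strrep("CGG", 10 + i),
           loc$downstream_anchor), id = sprintf("ok%02d", i)))
  bad <- lapply(1:2, function(i) make_read(random_dna(80),
                                           id = paste0("bad", i)))
  other <- list(make_read(random_dna(80), id = "other",
                          locus_id = "NOT_FMR1"))
  res <- filter_spanning(c(good, bad, other), loc)
  expect_equal(nrow(res$calls), 10)
  expect_equal(nrow(res$rejected), 3)
  expect_setequal(res$rejected$reason[res$rejected$read_id == "other"],
                  "wrong_locus")
  expect_true(all(res$rejected$reason[grepl("^bad", res$rejected$read_id)]
                  == "non_spanning"))
  empty <- filter_spanning(list(), loc)
  expect_equal(nrow(empty$calls), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("error-free simulated reads are recovered exactly", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = c(30, 100), sd_repeats = c(2, 10),
               weight = c(0.5, 0.5)), "CGG")
  sim <- simulate_reads(loc, mix,
                        cfg = read_sim_config(n_reads = 200, seed = 7,
                                              base_error_rate = 0))
  res <- filter_spanning(sim$reads, loc)
  expect_equal(nrow(res$calls), 200)
  truth <- sim$truth$true_bp_length[match(res$calls$read_id,
                                          sim$truth$read_id)]
  expect_identical(res$calls$repeat_bp, as.integer(truth))
})

test_that("repeat_units is non-decreasing in repeat_bp", {
  loc <- test_locus()
  calls <- lapply(0:20, function(b) extract_repeat(make_read(
    paste0(loc$upstream_anchor, substr(strrep("CGG", 7), 1, b),
           loc$downstream_anchor)), loc))
  units <- vapply(calls, `[[`, integer(1), "repeat_units")
  bp <- vapply(calls, `[[`, integer(1), "repeat_bp")
  expect_identical(bp, 0:20)
  expect_true(all(diff(units[order(bp)]) >= 0))
})

test_that("Phred conversion matches its closed form and rejects negatives", {
  expect_equal(qv_to_accuracy(10), 90)
  expect_equal(qv_to_accuracy(0), 0)
  expect_equal(round(qv_to_accuracy(45), 5), 99.99684)
  expect_error(qv_to_accuracy(-1), ">= 0")
})
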