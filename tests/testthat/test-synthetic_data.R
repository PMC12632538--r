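test_that("degenerate mixture yields exactly the modal allele on every read", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = 30, sd_repeats = 0, weight = 1), "CGG")
  sim <- simulate_reads(loc, mix, meth = NULL,
                        cfg = read_sim_config(n_reads = 50, seed = 3,
                                              base_error_rate = 0))
  expect_length(sim$reads, 50)
  expect_equal(nrow(sim$truth), 50)
  expect_true(all(sim$truth$true_repeat_units == 30))
  expect_true(all(sim$truth$true_bp_length == 90))
})

test_that("an empty request yields empty reads and an empty truth table", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = 30, sd_repeats = 0, weight = 1), "CGG")
  sim <- simulate_reads(loc, mix, cfg = read_sim_config(n_reads = 0))
  expect_length(sim$reads, 0)
  expect_equal(nrow(sim$truth), 0)
  expect_named(sim$truth,
               c("read_id", "true_repeat_units", "true_bp_length",
                 "true_haplotype", "true_methylation_state"))
})

test_that("mixture weights are recovered in the truth table (binomial check)", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = c(100, 1000), sd_repeats = c(2, 10),
               weight = c(0.9, 0.1)), "CGG")
  sim <- simulate_reads(loc, mix,
                        cfg = read_sim_config(n_reads = 2000, seed = 7))
  frac <- mean(sim$truth$true_repeat_units > 200)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 2000))
})

test_that("invalid mixture weights are rejected", {
  expect_error(
    allele_mixture(data.frame(mean_repeats = c(10, 20),
                              sd_repeats = c(0, 0),
                              weight = c(0.6, 0.5)), "CGG"),
    "sum to 1")
})

test_that("simulation is byte-identical under a fixed seed", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = c(30, 100), sd_repeats = c(1, 5),
               weight = c(0.5, 0.5)), "CGG")
  cfg <- read_sim_config(n_reads = 30, seed = 11, base_error_rate = 0.01)
  a <- simulate_reads(loc, mix, methylation_model(0.3), cfg)
  b <- simulate_reads(loc, mix, methylation_model(0.3), cfg)
  expect_identical(a, b)
  tr_a <- simulate_trace(c("100" = 1), loc)
  tr_b <- simulate_trace(c("100" = 1), loc)
  expect_identical(tr_a, tr_b)
})

test_that("number of truth rows always equals number of emitted reads", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = c(5, 60), sd_repeats = c(2, 10),
               weight = c(0.7, 0.3)), "CGG")
  for (n in c(1, 17, 64)) {
    sim <- simulate_reads(loc, mix,
                          cfg = read_sim_config(n_reads = n, seed = n))
    expect_length(sim$reads, n)
    expect_equal(nrow(sim$truth), n)
    expect_identical(sim$truth$read_id, read_ids(sim$reads))
  }
})

test_that("interruptions add their bp to the true length and the sequence", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = 10, sd_repeats = 0, weight = 1), "CGG",
    interruptions = data.frame(position_unit = 4, sequence = "AAAAA"))
  sim <- simulate_reads(loc, mix,
                        cfg = read_sim_config(n_reads = 5, seed = 1,
                                              base_error_rate = 0,
                                              reverse_strand_prob = 0))
  expect_true(all(sim$truth$true_bp_length == 10 * 3 + 5))
  expect_true(grepl("CGGCGGCGGCGGAAAAACGGCGGCGGCGGCGGCGG",
                    sim$reads[[1]]$sequence, fixed = TRUE))
})

test_that("methylation probabilities sit on CpG cytosines in either orientation", {
  loc <- test_locus()
  mix <- allele_mixture(
    data.frame(mean_repeats = 20, sd_repeats = 0, weight = 1), "CGG")
  sim <- simulate_reads(loc, mix, methylation_model(0.5),
                        read_sim_config(n_reads = 20, seed = 5,
                                        reverse_strand_prob = 0.5))
  for (rd in sim$reads) {
    pos <- as.integer(names(rd$cpg_probs))
    expect_true(all(substr(rep(rd$sequence, length(pos)), pos, pos + 1)
                    == "CG"))
    expect_true(all(rd$cpg_probs >= 0 & rd$cpg_probs <= 1))
    expect_equal(length(rd$base_qualities), nchar(rd$sequence))
  }
})

test_that("a single allele with no stutter and no bias is one peak at 100 RFU", {
  loc <- test_locus()
  cfg <- trace_sim_config(stutter_decay_plus = 0, stutter_decay_minus = 0,
                          max_stutter_order = 0, amp_bias_lambda = 0)
  tr <- simulate_trace(c("100" = 1), loc, cfg)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$size_units, 100)
  expect_equal(tr$height_rfu, 100)
  expect_equal(tr$size_bp, 300)
})

test_that("plus-stutter follows the geometric closed form", {
  loc <- test_locus()
  cfg <- trace_sim_config(stutter_decay_plus = 0.5, stutter_decay_minus = 0,
                          max_stutter_order = 2, amp_bias_lambda = 0,
                          noise_floor_rfu = 0)
  raw <- simulate_trace(c("100" = 1), loc, cfg, normalize = FALSE)
  h <- setNames(raw$height_rfu, raw$size_units)
  expect_equal(unname(h["101"] / h["100"]), 0.5)
  expect_equal(unname(h["102"] / h["100"]), 0.25)
  norm <- simulate_trace(c("100" = 1), loc, cfg)
  expect_equal(max(norm$height_rfu), 100)
  expect_equal(norm$height_rfu[norm$size_units == 101], 50)
})

test_that("amplification bias can push a long allele below the noise floor", {
  loc <- test_locus()
  # choose lambda so the 1000-unit peak (3000 bp), after rescaling against
  # the 100-unit peak, falls below a 2-RFU floor:
  # (100 * 0.1 / 0.9) * exp(-lambda * 2700) < 2
  lambda <- 0.002
  cfg <- trace_sim_config(max_stutter_order = 2, amp_bias_lambda = lambda,
                          noise_floor_rfu = 2)
  tr <- simulate_trace(c("100" = 0.9, "1000" = 0.1), loc, cfg)
  expect_true(any(tr$size_units == 100))
  expect_false(any(tr$size_units >= 998))
  # ... while with no bias the same mixture shows the long allele
  tr0 <- simulate_trace(c("100" = 0.9, "1000" = 0.1), loc,
                        trace_sim_config(max_stutter_order = 2,
                                         noise_floor_rfu = 2))
  expect_true(any(tr0$size_units == 1000))
})

test_that("raw trace heights match brute-force accumulation to 1e-9", {
  loc <- test_locus()
  set.seed(42)
  for (rep in 1:20) {
    n_all <- sample(1:4, 1)
    u <- sample(20:300, n_all)
    w <- stats::runif(n_all); w <- w / sum(w)
    cfg <- trace_sim_config(
      stutter_decay_plus = stats::runif(1, 0, 0.8),
      stutter_decay_minus = stats::runif(1, 0, 0.8),
      max_stutter_order = sample(0:4, 1),
      amp_bias_lambda = stats::runif(1, 0, 0.003))
    got <- simulate_trace(setNames(w, u), loc, cfg, normalize = FALSE)
    want <- brute_trace_heights(setNames(as.list(w), u), 3, cfg)
    expect_equal(got$size_units, want$size_units, tolerance = 1e-12)
    expect_equal(got$height_rfu, want$height, tolerance = 1e-9)
  }
})

test_that("empty allele table is rejected", {
  expect_error(simulate_trace(numeric(0), test_locus()), "non-empty")
})

test_that("gaussian-bump trace round-trips through the peak caller", {
  loc <- test_locus()
  tbl <- peak_table(c(100, 102), c(80, 40), motif_len = 3)
  trace <- simulate_gaussian_trace(tbl)
  called <- peaks_from_trace(trace, floor_rfu = 1)
  expect_equal(nrow(called), 2)
  expect_equal(called$size_units, c(100, 102), tolerance = 0.5)
  expect_equal(called$height_rfu, c(80, 40), tolerance = 1)
})
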