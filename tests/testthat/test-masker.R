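# Masking reads against circular consensuses: hit structure, filters,
# divsum summaries, strand/rotation invariances.

# One modest simulation shared across the invariance tests in this file.
masker_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(2e5,
                        data.frame(monomer_length = c(170, 60),
                                   target_occupancy = c(0.05, 0.04),
                                   divergence_rate = c(0.03, 0.10)),
                        coverage = 0.25, seq_error_rate = 0, seed = 41)
      sim <- build_genome(cfg)
      cache <<- list(sim = sim, reads = simulate_reads(sim))
    }
    cache
  }
})

test_that("a perfect monomer window gives one clean full-length hit", {
  set.seed(42)
  mono <- rand_dna(170)
  lib <- sat_library("AaaSat01", mono)
  read <- substr(strrep(mono, 3), 101, 250)  # crosses a monomer junction
  hits <- mask_sequences(c(r1 = read), lib)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kimura_divergence, 0)
  expect_gte(hits$query_end - hits$query_start, 150 - 2 * 5)
  expect_identical(hits$family, "AaaSat01")
})

test_that("chimeric reads produce one hit per constituent family", {
  set.seed(43)
  monoA <- rand_dna(80); monoB <- rand_dna(120)
  lib <- sat_library(c("AaaSat01", "AaaSat02"), c(monoA, monoB))
  read <- paste0(substr(strrep(monoA, 2), 1, 75),
                 substr(strrep(monoB, 2), 1, 75))
  hits <- mask_sequences(c(r1 = read), lib)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$family, c("AaaSat01", "AaaSat02"))
  h <- hits[order(hits$query_start), ]
  expect_lte(h$query_end[1] - h$query_start[2], 0.1 * 75)
})

test_that("satellite-free background reads are almost never masked", {
  set.seed(44)
  lib <- toy_library()
  reads <- Biostrings::DNAStringSet(vapply(1:2000, function(i) rand_dna(150),
                                           character(1)))
  hits <- mask_sequences(reads, lib)
  expect_lte(length(unique(hits$query_id)), 0.01 * 2000)
})

test_that("reverse-strand arrays are found with the mirrored coordinates", {
  set.seed(45)
  mono <- rand_dna(100)
  lib <- sat_library("AaaSat01", mono)
  read <- rc(substr(strrep(mono, 3), 51, 200))
  hits <- mask_sequences(c(r1 = read), lib)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$strand, "-")
  expect_equal(hits$kimura_divergence, 0)
})

test_that("divsum conserves masked bp and computes abundance arithmetic", {
  x <- masker_sim()
  hits <- mask_sequences(x$reads, x$sim)
  dv <- summarize_divsum(hits)
  expect_equal(sum(dv$bp), sum(hits$query_end - hits$query_start))
  expect_true(all(dv$bp >= 0))
  expect_lte(sum(dv$bp), attr(dv, "total_query_bp"))
  # hand-built hits: 60/40 bp on 1000 bp -> abundances 6% and 4%
  toy <- data.frame(query_id = c("a", "b"), family = c("F1", "F2"),
                    query_start = c(0L, 10L), query_end = c(60L, 50L),
                    kimura_divergence = c(4.4, 12.2))
  dv2 <- summarize_divsum(toy, total_query_bp = 1000)
  expect_equal(dv2$bin, c(4L, 12L))
  expect_equal(dv2$bp, c(60, 40))
  fs <- family_stats(cbind(toy, matches = c(55L, 38L), mismatches = c(5L, 2L)),
                     total_query_bp = 1000)
  expect_equal(fs$abundance[fs$family == "F1"], 0.06)
  expect_equal(fs$abundance[fs$family == "F2"], 0.04)
  # divergences at or above 70% clamp into the top bin with a warning
  toy$kimura_divergence <- c(72, 3)
  expect_warning(dv3 <- summarize_divsum(toy, total_query_bp = 1000), "clamp")
  expect_setequal(dv3$bin, c(69L, 3L))
})

test_that("per-family masked bp is strand-symmetric", {
  x <- masker_sim()
  hits_f <- mask_sequences(x$reads$read1, x$sim)
  rc_reads <- Biostrings::reverseComplement(x$reads$read1)
  names(rc_reads) <- names(x$reads$read1)
  hits_r <- mask_sequences(rc_reads, x$sim)
  bp <- function(h) tapply(h$query_end - h$query_start, h$family, sum)
  bf <- bp(hits_f); br <- bp(hits_r)
  expect_setequal(names(bf), names(br))
  expect_equal(as.numeric(bf[sort(names(bf))]),
               as.numeric(br[sort(names(bf))]), tolerance = 0.002)
})

test_that("rotating a consensus barely changes its masked bp", {
  x <- masker_sim()
  lib0 <- sat_library(x$sim$truth$families$name, x$sim$truth$families$consensus)
  lib1 <- lib0
  lib1$consensus[1] <- rotate_seq(lib1$consensus[1], 73)
  h0 <- mask_sequences(x$reads$read1, lib0)
  h1 <- mask_sequences(x$reads$read1, lib1)
  bp <- function(h, f) sum((h$query_end - h$query_start)[h$family == f])
  f <- lib0$name[1]
  expect_lt(abs(bp(h1, f) - bp(h0, f)) / bp(h0, f), 0.01)
})

test_that("hit coordinates and filters respect the scoring scheme", {
  x <- masker_sim()
  hits <- mask_sequences(x$reads, x$sim)
  sc <- scoring_scheme()
  expect_true(all(hits$score >= sc$min_score))
  expect_true(all(hits$query_end - hits$query_start >= sc$min_hit_length))
  expect_true(all(hits$kimura_divergence <= sc$max_divergence))
  expect_true(all(hits$query_start >= 0))
  expect_true(all(hits$query_end <= 150))
  # Kimura divergence never sits below the raw mismatch proportion
  expect_true(all(hits$kimura_divergence >= hits$raw_divergence - 1e-9))
})
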