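# Synthetic genome / read generator: determinism, rate calibration,
# conservation of planted bp, read-pair arithmetic.

test_that("make_consensus respects alphabet, GC content and determinism", {
  s <- make_consensus(60, gc = 0, seed = 1)
  expect_true(grepl("^[AT]+$", s))
  expect_identical(make_consensus(300, 0.5, seed = 42),
                   make_consensus(300, 0.5, seed = 42))
  expect_false(identical(make_consensus(300, 0.5, seed = 42),
                         make_consensus(300, 0.5, seed = 43)))
  # GC count within 4 sd of Binomial(1000, 0.5)
  s <- make_consensus(1000, 0.5, seed = 7)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 500), 4 * sqrt(1000 * 0.25))
  expect_error(make_consensus(9), "length")
})

test_that("mutate_copy with zero rates is the identity", {
  set.seed(2)
  cons <- rand_dna(200)
  expect_identical(mutate_copy(cons, 0, 0), cons)
})

test_that("pooled substitution fraction matches the planted rate", {
  set.seed(3)
  cons <- rand_dna(100)
  cc <- strsplit(cons, "")[[1]]
  mism <- 0L
  for (i in 1:1000) {
    m <- strsplit(mutate_copy(cons, 0.10, 0), "")[[1]]
    mism <- mism + sum(m != cc)
  }
  # central 99.9% binomial interval around p = 0.10, n = 100000
  n <- 100000
  half <- 3.29 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mism / n - 0.10), half)
})

test_that("indel-only mutation introduces no mismatches", {
  set.seed(4)
  cons <- rand_dna(300)
  # mismatch-hostile, gap-cheap scoring: any substitution would surface as a
  # mismatch column, so a clean alignment certifies indel-only differences
  sc <- scoring_scheme(match = 2, mismatch = -10, gap_open = 1, gap_extend = 1)
  for (i in 1:5) {
    m <- mutate_copy(cons, 0, 0.02)
    aln <- local_align(m, cons, sc)
    expect_identical(aln$mismatches, 0L)
    expect_false(identical(m, cons) && aln$gap_columns > 0)
  }
})

test_that("build_genome hits the occupancy target and conserves length", {
  cfg <- sim_config(1e6,
                    data.frame(monomer_length = 170, target_occupancy = 0.05,
                               divergence_rate = 0.05),
                    coverage = 0.1, seed = 9)
  sim <- build_genome(cfg)
  expect_equal(sum(Biostrings::width(sim$genome)), 1e6)
  occ <- sim$truth$families$realized_occupancy
  expect_lt(abs(occ - 0.05), 0.005)
  # planted_bp consistent with array intervals
  arr <- sim$truth$arrays
  expect_equal(sum(arr$end - arr$start), sim$truth$families$planted_bp)
})

test_that("planted arrays are pairwise disjoint and within bounds", {
  cfg <- sim_config(4e5,
                    data.frame(monomer_length = c(57, 170, 300),
                               target_occupancy = c(0.04, 0.05, 0.06)),
                    n_chromosomes = 2, seed = 10)
  sim <- build_genome(cfg)
  arr <- sim$truth$arrays
  for (cn in unique(arr$chrom)) {
    a <- arr[arr$chrom == cn, ]
    a <- a[order(a$start), ]
    expect_true(all(a$end[-nrow(a)] <= a$start[-1]))
    expect_true(all(a$start >= 0))
    expect_true(all(a$end <= Biostrings::width(sim$genome)[names(sim$genome) == cn]))
  }
  # planted intervals really contain monomer-derived sequence: spot check one
  a1 <- arr[which.max(arr$end - arr$start), ]
  seg <- substr(as.character(sim$genome[[a1$chrom]]), a1$start + 1, a1$end)
  fam <- sim$truth$families[sim$truth$families$name == a1$family, ]
  hit <- local_align(substr(seg, 1, 150), tandemize(fam$consensus, 150))
  expect_gt(hit$score, 100)
})

test_that("zero-family config yields a satellite-free background genome", {
  cfg <- sim_config(5e4, seed = 3)
  sim <- build_genome(cfg)
  expect_equal(nrow(sim$truth$arrays), 0L)
  expect_equal(sum(Biostrings::width(sim$genome)), 5e4)
  expect_equal(sum(sim$truth$families$planted_bp), 0)
})

test_that("build_genome is fully reproducible from its config", {
  cfg <- sim_config(1e5, data.frame(monomer_length = 120,
                                    target_occupancy = 0.03), seed = 5)
  s1 <- build_genome(cfg); s2 <- build_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$arrays, s2$truth$arrays)
})

test_that("read-pair count follows floor(coverage * bp / (2 * read_length))", {
  set.seed(6)
  g <- Biostrings::DNAStringSet(c(chr1 = rand_dna(1e6)))
  rd <- simulate_reads(g, coverage = 0.1, read_length = 150,
                       insert_size = 350, seq_error_rate = 0, seed = 1)
  expect_equal(rd$n_pairs, 333)
  expect_true(all(Biostrings::width(rd$read1) == 150))
})

test_that("error-free reads are exact substrings of the genome or its rc", {
  set.seed(7)
  chr <- rand_dna(2e4)
  g <- Biostrings::DNAStringSet(c(chr1 = chr))
  rd <- simulate_reads(g, coverage = 0.3, read_length = 100,
                       insert_size = 200, seq_error_rate = 0, seed = 2)
  both <- paste(chr, rc(chr), sep = "NNN")
  for (i in seq_len(min(20, rd$n_pairs))) {
    expect_true(grepl(as.character(rd$read1[[i]]), both, fixed = TRUE))
    expect_true(grepl(as.character(rd$read2[[i]]), both, fixed = TRUE))
  }
})

test_that("read simulation and FASTQ output are byte-deterministic", {
  set.seed(8)
  g <- Biostrings::DNAStringSet(c(chr1 = rand_dna(5e4)))
  rd1 <- simulate_reads(g, coverage = 0.2, read_length = 150,
                        insert_size = 350, seq_error_rate = 0.01, seed = 3)
  rd2 <- simulate_reads(g, coverage = 0.2, read_length = 150,
                        insert_size = 350, seq_error_rate = 0.01, seed = 3)
  expect_identical(as.character(rd1$read1), as.character(rd2$read1))
  d <- tempfile("reads"); dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  p1 <- write_reads(rd1, file.path(d, "a"))
  p2 <- write_reads(rd2, file.path(d, "b"))
  expect_identical(unname(tools::md5sum(p1[1])), unname(tools::md5sum(p2[1])))
  expect_identical(unname(tools::md5sum(p1[2])), unname(tools::md5sum(p2[2])))
})

test_that("simulate_reads rejects genomes shorter than the insert", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 50)))
  expect_error(simulate_reads(g, coverage = 1, read_length = 150,
                              insert_size = 350), "insert_size")
})

test_that("config invariants are enforced", {
  fam <- data.frame(monomer_length = 100, target_occupancy = 0.6)
  expect_error(sim_config(1e5, rbind(fam, fam)), "< 1")
  expect_error(sim_config(1e5, fam, coverage = 0), "coverage")
  expect_error(sim_config(1e5, fam, read_length = 400, insert_size = 350),
               "insert_size")
  expect_error(sim_config(1e5, data.frame(monomer_length = 100,
                                          target_occupancy = 0.1,
                                          divergence_rate = 1.2)),
               "divergence_rate")
})
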