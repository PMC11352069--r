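# Chromosome-level distribution: windowed masking equivalence, per-
# chromosome percentages, chromosome-specific families.

# Toy assembly: chr1 carries planted arrays of one family, chr2 is clean.
chrom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(81)
      mono <- rand_dna(100)
      arr1 <- make_array(mono, 80, noise = 0.02)   # ~8 kb
      arr2 <- make_array(mono, 60, noise = 0.02)   # ~6 kb
      arr3 <- make_array(mono, 60, noise = 0.02)
      chr1 <- paste0(rand_dna(20000), arr1, rand_dna(25000), arr2,
                     rand_dna(15000), arr3, rand_dna(20000))
      chr2 <- rand_dna(50000)
      asm <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
      lib <- sat_library("ToySat01", mono)
      planted <- nchar(arr1) + nchar(arr2) + nchar(arr3)
      cache <<- list(asm = asm, lib = lib, planted = planted,
                     mono = mono)
    }
    cache
  }
})

test_that("windowed and unwindowed masking give identical atoms", {
  fx <- chrom_fixture()
  m_small <- mask_assembly_windows(fx$asm, fx$lib, window = 20000)
  m_large <- mask_assembly_windows(fx$asm, fx$lib, window = 1e6)
  expect_identical(m_small$atoms, m_large$atoms)
  expect_identical(m_small$hits, m_large$hits)
})

test_that("per-chromosome satellite percent recovers the planted fraction", {
  fx <- chrom_fixture()
  m <- mask_assembly_windows(fx$asm, fx$lib)
  prof <- chromosome_abundance(m)
  p1 <- prof$chromosomes[prof$chromosomes$chromosome == "chr1", ]
  truth_pct <- 100 * fx$planted / p1$length
  expect_lt(abs(p1$satellite_percent - truth_pct), 1)
  p2 <- prof$chromosomes[prof$chromosomes$chromosome == "chr2", ]
  expect_equal(p2$satellite_percent, 0)
  # the family is chromosome-specific to chr1
  expect_identical(prof$specific$chromosome, "chr1")
  expect_true(prof$specific$chromosome_specific)
  # family bp partition the satellite bp
  expect_equal(sum(prof$families$bp), sum(prof$chromosomes$satellite_bp))
})

test_that("chromosome landscapes use the chromosome as denominator", {
  fx <- chrom_fixture()
  m <- mask_assembly_windows(fx$asm, fx$lib)
  ls <- chromosome_landscape(m, "chr1")
  expect_gt(nrow(ls), 0L)
  # planted at 2% substitutions: mode within the first few bins
  pa <- peak_ages(ls)
  expect_lte(pa$mode_bin, 3L)
  # empty chromosome -> empty table; unknown chromosome -> error
  expect_equal(nrow(chromosome_landscape(m, "chr2")), 0L)
  expect_error(chromosome_landscape(m, "chr9"), "unknown")
  # per-chromosome landscapes sum (bp-weighted) to the assembly-wide total
  tot_bp <- 0
  for (cn in names(m$chrom_lengths)) {
    lc <- chromosome_landscape(m, cn)
    tot_bp <- tot_bp + sum(lc$percent) / 100 * m$chrom_lengths[[cn]]
  }
  expect_equal(tot_bp, sum(m$atoms$end - m$atoms$start))
})

test_that("empty assemblies and tiny inputs are handled", {
  fx <- chrom_fixture()
  m <- mask_assembly_windows(Biostrings::DNAStringSet(), fx$lib)
  expect_equal(nrow(m$hits), 0L)
  prof <- chromosome_abundance(m)
  expect_equal(nrow(prof$chromosomes), 0L)
  expect_error(mask_assembly_windows(fx$asm, fx$lib, overlap = 50),
               "monomer")
  expect_error(mask_assembly_windows(fx$asm, fx$lib, segment_length = 150,
                                     overlap = 200), "exceed")
})

test_that("overlapping hits never double-count satellite bp", {
  fx <- chrom_fixture()
  # second library entry: a rotated copy of the same monomer, so both
  # families hit the same arrays and overlap resolution must arbitrate
  lib2 <- sat_library(c("ToySat01", "ToySat02"),
                      c(fx$mono, rotate_seq(fx$mono, 31)))
  m <- mask_assembly_windows(fx$asm, lib2)
  atoms <- m$atoms
  for (cn in unique(atoms$chrom)) {
    a <- atoms[atoms$chrom == cn, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$end[-nrow(a)] <= a$start[-1]))
  }
  prof <- chromosome_abundance(m)
  p1 <- prof$chromosomes[prof$chromosomes$chromosome == "chr1", ]
  expect_lt(p1$satellite_bp, 1.05 * fx$planted)
})
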