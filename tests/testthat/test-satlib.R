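# Library data model: nomenclature, FASTA round-trips, superfamily grouping.

test_that("assign_names ranks by abundance with the stated tie-breaks", {
  # higher abundance gets the lower number
  nm <- assign_names(c(0.03, 0.05), c(170, 200), "Mth")
  expect_identical(nm$name, c("MthSat01", "MthSat02"))
  expect_identical(nm$input_index, c(2L, 1L))
  # equal abundance: longer monomer first, then input order
  nm <- assign_names(c(0.02, 0.02), c(150, 300), "Psu")
  expect_identical(nm$input_index, c(2L, 1L))
  nm <- assign_names(c(0.02, 0.02), c(150, 150), "Psu")
  expect_identical(nm$input_index, c(1L, 2L))
  # empty input, empty output
  expect_equal(nrow(assign_names(numeric(0), integer(0), "Mth")), 0L)
  # numbering switches to three digits at 100
  nm <- assign_names(rev(seq_len(120)), rep(100L, 120), "Mth")
  expect_identical(nm$name[1], "MthSat01")
  expect_identical(nm$name[99], "MthSat99")
  expect_identical(nm$name[100], "MthSat100")
  expect_identical(nm$name[120], "MthSat120")
  expect_error(assign_names(0.1, 100, "MTHX"), "species_code")
})

test_that("library FASTA round-trips and rejects malformed input", {
  set.seed(11)
  lib <- sat_library(sprintf("TstSat%02d", 1:5),
                     vapply(c(50, 120, 170, 300, 80), rand_dna, character(1)),
                     confidence = c("high", "high", "low", "high", "low"))
  f <- tempfile(fileext = ".fasta")
  write_satlib(lib, f)
  lib2 <- read_satlib(f)
  expect_identical(lib2$name, lib$name)
  expect_identical(lib2$consensus, lib$consensus)
  expect_identical(lib2$confidence, lib$confidence)
  # duplicate names rejected
  writeLines(c(">MthSat01", "ACGTACGTACGT", ">MthSat01", "ACGTACGTACGA"), f)
  expect_error(read_satlib(f), "duplicate")
  # non-ACGT residues rejected, naming the record
  writeLines(c(">MthSat01", "ACGTNNGTACGT"), f)
  expect_error(read_satlib(f), "MthSat01")
})

test_that("multi-species library concatenation preserves order", {
  set.seed(12)
  sizes <- c(Aaa = 10, Bbb = 20, Ccc = 5)
  libs <- lapply(names(sizes), function(sp) {
    n <- sizes[[sp]]
    sat_library(paste0(sp, "Sat", sprintf("%02d", seq_len(n))),
                vapply(rep(60, n), rand_dna, character(1)))
  })
  merged <- do.call(rbind, lapply(libs, as.data.frame))
  expect_equal(nrow(merged), 35L)
  expect_identical(merged$name[1:10], libs[[1]]$name)
  expect_identical(merged$name[11:30], libs[[2]]$name)
  expect_identical(merged$name[31:35], libs[[3]]$name)
})

test_that("identical consensuses group into one superfamily", {
  set.seed(13)
  s <- rand_dna(200)
  lib <- sat_library(c("AaaSat01", "AaaSat02"), c(s, s))
  sf <- group_superfamilies(lib)
  expect_equal(sf$membership$superfamily, c(1L, 1L))
})

test_that("reverse-complemented rotated consensus joins the same superfamily", {
  set.seed(14)
  s <- rand_dna(200)
  twin <- rc(rotate_seq(s, 37))
  lib <- sat_library(c("AaaSat01", "AaaSat02", "AaaSat03"),
                     c(s, twin, rand_dna(200)))
  sf <- group_superfamilies(lib)
  m <- sf$membership
  expect_identical(m$superfamily[1], m$superfamily[2])
  expect_false(m$superfamily[3] == m$superfamily[1])
  expect_identical(sf$edges$strand, "-")
})

test_that("independent random consensuses stay singletons", {
  set.seed(15)
  lib <- sat_library(sprintf("RndSat%02d", 1:20),
                     vapply(rep(200, 20), rand_dna, character(1)))
  sf <- group_superfamilies(lib)
  expect_equal(sort(unique(sf$membership$superfamily)), 1:20)
  expect_equal(nrow(sf$edges), 0L)
})

test_that("superfamily partition is invariant to input order and rotation", {
  set.seed(16)
  a <- rand_dna(180)
  b <- rotate_seq(a, 60)            # same family, rotated
  c1 <- rand_dna(180)
  d <- rc(c1)                       # same family, reverse strand
  e <- rand_dna(220)
  lib <- sat_library(c("XxxSat01", "XxxSat02", "XxxSat03", "XxxSat04", "XxxSat05"),
                     c(a, b, c1, d, e))
  canon <- function(sf) {
    m <- sf$membership
    unname(split(sort(m$family), m$superfamily[order(m$family)]))
  }
  base <- canon(group_superfamilies(lib))
  perm <- lib[c(4, 2, 5, 1, 3), ]
  expect_setequal(vapply(canon(group_superfamilies(perm)), paste, character(1),
                         collapse = ","),
                  vapply(base, paste, character(1), collapse = ","))
  # rotating any consensus leaves the partition unchanged
  rot <- lib
  rot$consensus[1] <- rotate_seq(rot$consensus[1], 91)
  expect_setequal(vapply(canon(group_superfamilies(rot)), paste, character(1),
                         collapse = ","),
                  vapply(base, paste, character(1), collapse = ","))
})
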