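# Independent oracles and fixture builders used across the suite.
# These are deliberately naive implementations (full dynamic programming,
# exhaustive enumeration) kept separate from the package's own code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

rotate_seq <- function(x, by) {
  n <- nchar(x)
  by <- by %% n
  if (by == 0) return(x)
  paste0(substr(x, by + 1, n), substr(x, 1, by))
}

# Perfect or noisy tandem array: n_copies of monomer, each independently
# substituted at rate `noise`.
make_array <- function(monomer, n_copies, noise = 0) {
  copies <- vapply(seq_len(n_copies), function(i) {
    if (noise == 0) monomer else mutate_copy(monomer, noise, 0)
  }, character(1))
  paste(copies, collapse = "")
}

# Full affine-gap Smith-Waterman, score only. Plain O(nm) dynamic
# programming; gap of length L costs gap_open + L * gap_extend, matching
# the package's scoring convention.
sw_oracle_score <- function(q, t, match = 2, mismatch = -3, gap_open = 5,
                            gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  NEG <- -1e9
  go <- gap_open + gap_extend
  Hprev <- numeric(m + 1)        # H[i-1, ]
  Fv <- rep(NEG, m + 1)          # F[i-1, j]: gap consuming query, per column
  best <- 0
  for (i in seq_len(n)) {
    H <- numeric(m + 1)
    e <- NEG                     # E[i, j-1]: gap consuming target, per row
    for (j in seq_len(m)) {
      sub <- Hprev[j] + if (qc[i] == tc[j]) match else mismatch
      e <- max(H[j] - go, e - gap_extend)
      Fv[j + 1] <- max(Hprev[j + 1] - go, Fv[j + 1] - gap_extend)
      h <- max(0, sub, e, Fv[j + 1])
      H[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- H
  }
  best
}

# Exhaustive two-sided permutation p-value for Spearman's rho, written
# independently of the package (direct recursion + cor on ranks).
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  n <- length(x)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      total <<- total + 1L
      if (abs(cor(rx, ry[acc])) >= abs(rho_obs) - 1e-12) count <<- count + 1L
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      recurse(remaining[-k], c(acc, remaining[k]))
    }
  }
  recurse(seq_len(n), integer(0))
  count / total
}

# Small deterministic satellite library for masking tests.
toy_library <- function(seed = 5, monomers = c(170, 60)) {
  set.seed(seed)
  sat_library(sprintf("ToySat%02d", seq_along(monomers)),
              vapply(monomers, rand_dna, character(1)))
}
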