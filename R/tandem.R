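# Tandem-structure confirmation: self k-mer dotplots, periodicity,
# monomer-length estimation. Computational analogue of inspecting
# self-dotplots of cluster contigs for ladder patterns.

#' Exact k-mer self-matches of a sequence (dotplot support)
#'
#' All pairs of positions `(i, j)`, `i < j`, carrying identical forward-
#' strand k-mers; the main diagonal is excluded. In a perfect tandem with
#' period p, off-diagonal matches concentrate at offsets `j - i` that are
#' multiples of p.
#'
#' @param seq Sequence (character or `DNAString`), length >= `2k`.
#' @param k K-mer size.
#' @return List of class `dotplot`: `k`, `n_kmers`, `matches` (data frame
#'   `i`, `j`, 1-based k-mer start positions) and `offsets` (integer
#'   multiset of `j - i`).
#' @export
self_kmer_matches <- function(seq, k = 12L) {
  seq <- as_seq_chr(seq)
  k <- as.integer(k)
  L <- nchar(seq)
  if (L < 2L * k) {
    stop(sprintf("sequence length (%d) must be >= 2k (%d)", L, 2L * k),
         call. = FALSE)
  }
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  grp <- split(starts, kmers)
  grp <- grp[lengths(grp) > 1L]
  ii <- integer(0); jj <- integer(0)
  for (g in grp) {
    m <- length(g)
    # all ordered pairs i < j within the group
    a <- rep(g, times = (m - 1):0)
    b <- g[unlist(lapply(seq_len(m - 1L), function(x) (x + 1L):m))]
    ii <- c(ii, a); jj <- c(jj, b)
  }
  structure(list(k = k, n_kmers = length(starts),
                 matches = data.frame(i = ii, j = jj),
                 offsets = jj - ii),
            class = "dotplot")
}

#' Estimate the tandem period from a self-dotplot
#'
#' The period is the smallest candidate offset `p >= k` such that matches at
#' offsets that are multiples of `p` account for at least
#' `support_threshold` of all off-diagonal matches.
#'
#' @param dotplot A [self_kmer_matches()] result.
#' @param support_threshold Minimum fraction of matches explained.
#' @param min_matches Minimum number of off-diagonal matches required before
#'   any period is called: a genuine tandem produces matches for most k-mer
#'   positions of every copy, whereas a chance duplicated k-mer in a random
#'   sequence produces one or two, which would otherwise trivially reach
#'   support 1.
#' @return List with `period` (bp, or `NA` if no offset qualifies) and
#'   `support` (fraction of matches at multiples of the period).
#' @export
estimate_period <- function(dotplot, support_threshold = 0.5,
                            min_matches = 10L) {
  stopifnot(inherits(dotplot, "dotplot"))
  off <- dotplot$offsets
  if (length(off) < min_matches) return(list(period = NA_integer_, support = 0))
  cands <- sort(unique(off))
  cands <- cands[cands >= dotplot$k]
  for (p in cands) {
    sup <- mean(off %% p == 0L)
    if (sup >= support_threshold) {
      return(list(period = as.integer(p), support = sup))
    }
  }
  list(period = NA_integer_, support = 0)
}

#' Call tandem structure for a contig
#'
#' Wraps [self_kmer_matches()] and [estimate_period()]: a contig is called
#' tandem when a qualifying period exists.
#'
#' @param contig Sequence (character or `DNAString`), length >= `2k`.
#' @param k K-mer size.
#' @param support_threshold Minimum fraction of off-diagonal matches at
#'   multiples of the period.
#' @param min_matches Minimum off-diagonal match count (see
#'   [estimate_period()]).
#' @return List of class `tandem_call`: `is_tandem`, `period`, `support`.
#' @export
is_tandem <- function(contig, k = 12L, support_threshold = 0.5,
                      min_matches = 10L) {
  dp <- self_kmer_matches(contig, k)
  est <- estimate_period(dp, support_threshold, min_matches)
  structure(list(is_tandem = !is.na(est$period), period = est$period,
                 support = est$support),
            class = "tandem_call")
}

#' Tandem calls for a set of contigs
#'
#' Convenience wrapper over [is_tandem()]; contigs shorter than `2k` are
#' reported as non-tandem rather than raising an error.
#'
#' @param contigs `DNAStringSet` (or character vector) of contigs.
#' @inheritParams is_tandem
#' @return Data frame: `contig`, `length`, `is_tandem`, `period`, `support`.
#' @export
tandem_scan <- function(contigs, k = 12L, support_threshold = 0.5,
                        min_matches = 10L) {
  contigs <- as_dss(contigs, "contig")
  res <- lapply(seq_along(contigs), function(i) {
    s <- as.character(contigs[[i]])
    if (nchar(s) < 2L * k) {
      return(data.frame(contig = names(contigs)[i], length = nchar(s),
                        is_tandem = FALSE, period = NA_integer_, support = 0))
    }
    tc <- is_tandem(s, k, support_threshold, min_matches)
    data.frame(contig = names(contigs)[i], length = nchar(s),
               is_tandem = tc$is_tandem, period = tc$period,
               support = tc$support)
  })
  do.call(rbind, res)
}
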