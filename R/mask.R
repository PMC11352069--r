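# Tandem-aware masking of reads (or assembly segments) against a satellite
# library, with per-hit Kimura divergence and divsum-style summaries.

#' Mask query sequences against a satellite family library
#'
#' Each query is locally aligned on both strands against the tandemized
#' consensus (see [tandemize()]) of every library family. Candidate hits are
#' filtered by `min_score`, `min_hit_length` and `max_divergence`, then
#' resolved greedily per query: hits are accepted in decreasing score order
#' (ties: earlier query start, earlier target start, fewer gap columns) and
#' a hit overlapping an already accepted hit by more than `overlap_tol` of
#' its own length is discarded.
#'
#' @param queries Sequences to mask: `DNAStringSet`, character vector, or a
#'   `sim_reads` object (both mates are masked).
#' @param library A satellite library ([sat_library()] /
#'   [read_satlib()]), or any data frame with `name` and `consensus`
#'   columns.
#' @param scoring A [scoring_scheme()].
#' @param overlap_tol Maximum tolerated overlap with accepted hits, as a
#'   fraction of the candidate hit's own length.
#' @return A data frame of hits, class `mask_hits`: `query_id`, `family`,
#'   `query_start`, `query_end` (0-based half-open), `strand`, `score`,
#'   `matches`, `mismatches`, `transitions`, `transversions`, `gap_columns`,
#'   `kimura_divergence` (%) and `raw_divergence` (%, mismatch proportion).
#'   The total masked-against bp is attached as attribute `total_query_bp`,
#'   the number of saturated (discarded) alignments as `n_saturated`.
#' @export
mask_sequences <- function(queries, library, scoring = scoring_scheme(),
                           overlap_tol = 0.1) {
  if (inherits(queries, "sim_reads")) {
    queries <- c(queries$read1, queries$read2)
    names(queries) <- paste0(names(queries), rep(c("/1", "/2"),
                                                 each = length(queries) / 2))
  }
  queries <- as_dss(queries, "query")
  library <- as_satlib_df(library)
  if (nrow(library) == 0L) stop("library must contain at least one family", call. = FALSE)
  qchar <- as.character(queries)
  if (!all(is_acgt(qchar))) {
    stop("queries must contain only A/C/G/T", call. = FALSE)
  }
  qlen <- Biostrings::width(queries)
  total_bp <- sum(qlen)
  maxlen <- max(qlen)

  cands <- vector("list", 2L * nrow(library))
  k <- 0L
  for (i in seq_len(nrow(library))) {
    tand <- tandemize(library$consensus[i], maxlen)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") tand else revcomp_chr(tand)
      res <- align_batch(queries, subj, scoring)
      res <- res[res$score >= scoring$min_score &
                   (res$query_end - res$query_start) >= scoring$min_hit_length, ,
                 drop = FALSE]
      if (nrow(res)) {
        res$family <- library$name[i]
        res$strand <- strand
        k <- k + 1L
        cands[[k]] <- res
      }
    }
  }
  empty <- data.frame(query_id = character(), family = character(),
                      query_start = integer(), query_end = integer(),
                      strand = character(), score = numeric(),
                      matches = integer(), mismatches = integer(),
                      transitions = integer(), transversions = integer(),
                      gap_columns = integer(), kimura_divergence = numeric(),
                      raw_divergence = numeric(), stringsAsFactors = FALSE)
  if (k == 0L) {
    return(structure(empty, class = c("mask_hits", "data.frame"),
                     total_query_bp = total_bp, n_saturated = 0L))
  }
  cand <- do.call(rbind, cands[seq_len(k)])
  ungapped <- cand$matches + cand$mismatches
  suppressWarnings(
    cand$kimura_divergence <- kimura2p(cand$transitions / ungapped,
                                       cand$transversions / ungapped))
  n_sat <- sum(is.na(cand$kimura_divergence))
  if (n_sat > 0L) {
    warning(sprintf("discarding %d saturated hit(s)", n_sat), call. = FALSE)
  }
  cand$raw_divergence <- 100 * cand$mismatches / ungapped
  cand <- cand[!is.na(cand$kimura_divergence) &
                 cand$kimura_divergence <= scoring$max_divergence, , drop = FALSE]

  hits <- resolve_overlaps(cand, overlap_tol)
  if (nrow(hits) == 0L) {
    return(structure(empty, class = c("mask_hits", "data.frame"),
                     total_query_bp = total_bp, n_saturated = n_sat))
  }
  hits$query_id <- names(queries)[hits$query]
  hits <- hits[order(hits$query, hits$query_start),
               c("query_id", "family", "query_start", "query_end", "strand",
                 "score", "matches", "mismatches", "transitions",
                 "transversions", "gap_columns", "kimura_divergence",
                 "raw_divergence")]
  rownames(hits) <- NULL
  structure(hits, class = c("mask_hits", "data.frame"),
            total_query_bp = total_bp, n_saturated = n_sat)
}

# Greedy per-query resolution: accept candidates in decreasing score order,
# reject those overlapping accepted hits by > tol of their own length.
#' @noRd
resolve_overlaps <- function(cand, tol) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(cand$query, -cand$score, cand$query_start, cand$target_start,
               cand$gap_columns)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  by_query <- split(seq_len(nrow(cand)), cand$query)
  for (idx in by_query) {
    acc_s <- integer(0); acc_e <- integer(0)
    for (i in idx) {
      s <- cand$query_start[i]; e <- cand$query_end[i]
      ov <- if (length(acc_s)) sum(pmax(0L, pmin(acc_e, e) - pmax(acc_s, s)))
            else 0L
      if (ov <= tol * (e - s)) {
        keep[i] <- TRUE
        acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      }
    }
  }
  cand[keep, , drop = FALSE]
}

#' Summarize hits into a divsum table (family x divergence bin)
#'
#' Each hit contributes its query-span bp to the integer divergence bin
#' `floor(kimura_divergence)`. Divergences of 70% or more are clamped into
#' the top bin (69) with a warning.
#'
#' @param hits A `mask_hits` data frame from [mask_sequences()].
#' @param total_query_bp Denominator bp (defaults to the attribute recorded
#'   by [mask_sequences()]).
#' @return Data frame of class `divsum` with columns `family`, `bin`
#'   (integer, `[0, 70)`), `bp`; attribute `total_query_bp`.
#' @export
summarize_divsum <- function(hits, total_query_bp = attr(hits, "total_query_bp")) {
  if (is.null(total_query_bp) || total_query_bp <= 0) {
    stop("total_query_bp must be a positive number", call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(structure(data.frame(family = character(), bin = integer(),
                                bp = numeric()),
                     class = c("divsum", "data.frame"),
                     total_query_bp = total_query_bp))
  }
  bp <- hits$query_end - hits$query_start
  if (sum(bp) > total_query_bp) {
    stop("hit bp exceed total_query_bp: wrong denominator?", call. = FALSE)
  }
  bin <- floor(hits$kimura_divergence)
  if (any(bin >= 70)) {
    warning(sprintf("clamping %d hit(s) with divergence >= 70%% to top bin",
                    sum(bin >= 70)), call. = FALSE)
    bin <- pmin(bin, 69)
  }
  agg <- aggregate(list(bp = bp),
                   by = list(family = hits$family, bin = as.integer(bin)), sum)
  agg <- agg[order(agg$family, agg$bin), ]
  rownames(agg) <- NULL
  structure(agg, class = c("divsum", "data.frame"),
            total_query_bp = total_query_bp)
}

#' Per-family abundance and mean divergence
#'
#' Abundance is the genome fraction of masked bp (masked bp / total query
#' bp); mean divergence is the bp-weighted mean of per-hit Kimura
#' divergences. Read-bp is the natural denominator when masking reads from
#' an unassembled genome; for assemblies use the assembly bp.
#'
#' @inheritParams summarize_divsum
#' @return Data frame of class `family_stats`: `family`, `abundance`
#'   (fraction of genome), `mean_divergence` (%), `n_hits`, `bp`.
#' @export
family_stats <- function(hits, total_query_bp = attr(hits, "total_query_bp")) {
  if (is.null(total_query_bp) || total_query_bp <= 0) {
    stop("total_query_bp must be a positive number", call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    return(structure(data.frame(family = character(), abundance = numeric(),
                                mean_divergence = numeric(), n_hits = integer(),
                                bp = numeric()),
                     class = c("family_stats", "data.frame")))
  }
  bp <- hits$query_end - hits$query_start
  fam <- hits$family
  tot <- tapply(bp, fam, sum)
  wdiv <- tapply(bp * hits$kimura_divergence, fam, sum) / tot
  n <- tapply(bp, fam, length)
  out <- data.frame(family = names(tot),
                    abundance = as.numeric(tot) / total_query_bp,
                    mean_divergence = as.numeric(wdiv),
                    n_hits = as.integer(n),
                    bp = as.numeric(tot), stringsAsFactors = FALSE)
  out <- out[order(-out$abundance), ]
  rownames(out) <- NULL
  structure(out, class = c("family_stats", "data.frame"))
}

#' Write hits as BED6+1 (divergence in column 7)
#'
#' @param hits A `mask_hits` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$query_id, start = hits$query_start,
                    end = hits$query_end, name = hits$family,
                    score = round(hits$score), strand = hits$strand,
                    divergence = round(hits$kimura_divergence, 2))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
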