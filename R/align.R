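# Local alignment of sequences to circular monomer consensuses, and
# Kimura 2-parameter divergence of the resulting alignments.

#' Alignment scoring and hit-filter parameters
#'
#' Affine-gap Smith-Waterman scoring used throughout the masker, plus the
#' filters applied to candidate hits. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening cost (positive number, subtracted).
#' @param gap_extend Gap extension cost per gapped position (positive).
#' @param min_score Minimum alignment score for a hit to be kept.
#' @param min_hit_length Minimum hit length on the query, bp.
#' @param max_divergence Maximum Kimura divergence (%) for a hit to be kept;
#'   the default 45 sits just above the most diverged satellite copies
#'   reported in comparative satellitome work (~43%).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, min_score = 40,
                           min_hit_length = 30, max_divergence = 45) {
  if (match <= 0) stop("match score must be > 0", call. = FALSE)
  if (mismatch >= 0) stop("mismatch score must be < 0", call. = FALSE)
  if (gap_open < 0 || gap_extend <= 0) {
    stop("gap penalties must be positive costs", call. = FALSE)
  }
  if (min_hit_length < 1) stop("min_hit_length must be >= 1", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score,
                 min_hit_length = min_hit_length,
                 max_divergence = max_divergence),
            class = "scoring_scheme")
}

#' @noRd
substitution_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

#' Linearize a circular monomer for alignment
#'
#' Satellite monomers are effectively circular: a read can start at any
#' rotation. Repeating the consensus `ceil(target_length / monomer_length) +
#' 1` times guarantees that any window of `target_length` bp of a perfect
#' circular array appears contiguously in the result.
#'
#' @param consensus Monomer consensus sequence.
#' @param target_length Length (bp) of the sequences that will be aligned
#'   against the tandemized consensus.
#' @return Character string of at least `target_length + monomer_length` bp.
#' @export
#' @examples
#' nchar(tandemize(strrep("A", 170), 150))  # 340
tandemize <- function(consensus, target_length) {
  consensus <- as_seq_chr(consensus, "consensus")
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < 1L) {
    stop("target_length must be >= 1", call. = FALSE)
  }
  strrep(consensus, ceiling(target_length / nchar(consensus)) + 1L)
}

# Batch local alignment of many queries against one subject. Returns a
# data.frame of per-query optimal local hits with column classes needed for
# Kimura divergence. Coordinates are 0-based half-open on the query.
#' @noRd
align_batch <- function(queries, subject, scoring) {
  pa <- Biostrings::pairwiseAlignment(
    queries, Biostrings::DNAString(subject), type = "local",
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  qp <- Biostrings::pattern(pa)
  sp <- Biostrings::subject(pa)
  ind <- Biostrings::nindel(pa)
  gap_cols <- Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  n_mm <- Biostrings::nmismatch(pa)
  res <- data.frame(
    query = as.integer(seq_along(queries)),
    query_start = IRanges::start(qp) - 1L,
    query_end = IRanges::end(qp),
    target_start = IRanges::start(sp) - 1L,
    target_end = IRanges::end(sp),
    score = Biostrings::score(pa),
    matches = Biostrings::nmatch(pa),
    mismatches = n_mm,
    gap_columns = as.integer(gap_cols),
    transitions = 0L,
    transversions = 0L
  )
  # transition/transversion classification only for alignments with mismatches
  has_mm <- which(n_mm > 0L)
  if (length(has_mm)) {
    mt <- Biostrings::mismatchTable(pa[has_mm])
    pb <- as.character(mt$PatternSubstring)
    sb <- as.character(mt$SubjectSubstring)
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    is_ts <- purine[pb] == purine[sb]
    ts <- tapply(is_ts, mt$PatternId, sum)
    idx <- has_mm[as.integer(names(ts))]
    res$transitions[idx] <- as.integer(ts)
    res$transversions <- res$mismatches - res$transitions
  }
  res
}

#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman optimum (Biostrings engine) with per-column
#' classification, as used by the masker. When several alignments share the
#' optimal score the engine's canonical traceback is reported.
#'
#' @param query,target Sequences (character or `DNAString`).
#' @param scoring A [scoring_scheme()]; `min_score` and the hit filters are
#'   not applied here.
#' @return A list with `score`, `query_start`/`query_end` and
#'   `target_start`/`target_end` (0-based half-open), `matches`,
#'   `mismatches`, `transitions`, `transversions`, `gap_columns`,
#'   `aligned_columns` (ungapped columns), and the `aligned_query` /
#'   `aligned_target` strings.
#' @export
#' @examples
#' local_align("ACGTACGTAC", "TTACGTACGTACTT")$score
local_align <- function(query, target, scoring = scoring_scheme()) {
  query <- as_seq_chr(query, "query")
  target <- as_seq_chr(target, "target")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = substitution_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  res <- align_batch(Biostrings::DNAStringSet(query), target, scoring)
  out <- as.list(res[1L, setdiff(names(res), "query")])
  out$aligned_columns <- out$matches + out$mismatches
  out$aligned_query <- as.character(Biostrings::alignedPattern(pa))
  out$aligned_target <- as.character(Biostrings::alignedSubject(pa))
  out
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, expressed in percent, with
#' `P` and `Q` the transition and transversion proportions over ungapped
#' alignment columns.
#'
#' @param P,Q Transition and transversion proportions (fractions, vectorized).
#' @return Divergence in percent; `NA` with a warning where the distance is
#'   saturated (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#' @export
#' @examples
#' kimura2p(0.10, 0)    # 11.157
#' kimura2p(0, 0.10)    # 10.814
kimura2p <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  bad <- a <= 0 | b <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("%d saturated alignment(s): Kimura distance undefined",
                    sum(bad, na.rm = TRUE)), call. = FALSE)
  }
  k <- ifelse(bad, NA_real_, -0.5 * log(a * sqrt(b)))
  100 * k
}

#' Kimura divergence of a local alignment
#'
#' Gap columns are excluded; `P` and `Q` are computed over the ungapped
#' columns of the alignment.
#'
#' @param alignment Result of [local_align()], or any list with `matches`,
#'   `mismatches`, `transitions` and `transversions` counts.
#' @return Divergence in percent (`NA` when saturated, with a warning).
#' @export
kimura_divergence <- function(alignment) {
  ungapped <- alignment$matches + alignment$mismatches
  if (is.null(ungapped) || any(ungapped < 1)) {
    stop("alignment must have at least one ungapped column", call. = FALSE)
  }
  kimura2p(alignment$transitions / ungapped, alignment$transversions / ungapped)
}
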