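# Chromosome-level satellite distribution on an assembly.
#
# Chromosomes are tiled into fixed segments anchored at position 0 and each
# segment is masked like a read; per-base family assignment then resolves
# overlapping hits so satellite bp are counted exactly once. Because the
# tiling is anchored to chromosome coordinates, results do not depend on
# how segments are batched into processing windows.

#' Mask an assembly against a satellite library
#'
#' @param assembly `DNAStringSet` of chromosomes (or a FASTA path).
#' @param library Satellite library (see [mask_sequences()]).
#' @param scoring A [scoring_scheme()].
#' @param window Processing window in bp: segments are aligned in batches
#'   covering at most this many bp (memory control only; results are
#'   independent of the window).
#' @param overlap Overlap between consecutive segments, bp; must be at
#'   least twice the longest monomer so every hit is seen contiguously in
#'   at least one segment. Default `2 * max(monomer_length)`.
#' @param segment_length Segment size in bp (> `overlap`).
#' @return List of class `assembly_mask`:
#'   * `hits`: per-hit data frame in chromosome coordinates (`chrom`,
#'     `start`, `end` 0-based half-open, `family`, `strand`, `score`,
#'     `kimura_divergence`);
#'   * `atoms`: disjoint per-base assignment (`chrom`, `start`, `end`,
#'     `family`, `kimura_divergence`, `score`) — overlapping hits resolved
#'     to the highest-scoring family, so atom bp sum without double
#'     counting;
#'   * `chrom_lengths`: named integer vector; `total_bp` their sum.
#' @export
mask_assembly_windows <- function(assembly, library,
                                  scoring = scoring_scheme(),
                                  window = 100000L, overlap = NULL,
                                  segment_length = 1000L) {
  if (is.character(assembly) && length(assembly) == 1L && file.exists(assembly)) {
    assembly <- Biostrings::readDNAStringSet(assembly)
  }
  assembly <- as_dss(assembly, "chr")
  library <- as_satlib_df(library)
  max_mono <- max(library$monomer_length)
  overlap <- as.integer(overlap %||% (2L * max_mono))
  if (overlap < 2L * max_mono) {
    stop(sprintf("overlap (%d) must be >= 2 x longest monomer (%d)",
                 overlap, 2L * max_mono), call. = FALSE)
  }
  segment_length <- as.integer(segment_length)
  if (segment_length <= overlap) {
    stop("segment_length must exceed overlap", call. = FALSE)
  }
  chrom_lengths <- setNames(Biostrings::width(assembly), names(assembly))

  empty_hits <- data.frame(chrom = character(), start = integer(),
                           end = integer(), family = character(),
                           strand = character(), score = numeric(),
                           kimura_divergence = numeric(),
                           stringsAsFactors = FALSE)
  if (length(assembly) == 0L || sum(chrom_lengths) == 0L) {
    return(structure(list(hits = empty_hits,
                          atoms = cbind(empty_hits[, c("chrom", "start", "end",
                                                       "family")],
                                        kimura_divergence = numeric(0),
                                        score = numeric(0)),
                          chrom_lengths = chrom_lengths,
                          total_bp = sum(chrom_lengths)),
                     class = "assembly_mask"))
  }

  step <- segment_length - overlap
  seg_chrom <- character(0); seg_off <- integer(0); seg_seq <- character(0)
  chars <- as.character(assembly)
  for (c in seq_along(assembly)) {
    len <- chrom_lengths[c]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    # drop trailing tiles fully contained in the previous one
    ends <- pmin(starts + segment_length, len)
    keep <- !duplicated(ends) | ends - starts == segment_length
    starts <- starts[keep]; ends <- ends[keep]
    keep <- ends - starts >= scoring$min_hit_length
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    seg_chrom <- c(seg_chrom, rep(names(assembly)[c], length(starts)))
    seg_off <- c(seg_off, starts)
    seg_seq <- c(seg_seq, substring(chars[c], starts + 1L, ends))
  }
  seg_names <- sprintf("%s:%d", seg_chrom, seg_off)
  hits_list <- list()
  batch_n <- max(1L, as.integer(window) %/% segment_length)
  for (b in split(seq_along(seg_seq), (seq_along(seg_seq) - 1L) %/% batch_n)) {
    q <- Biostrings::DNAStringSet(seg_seq[b])
    names(q) <- seg_names[b]
    h <- mask_sequences(q, library, scoring)
    if (nrow(h)) {
      seg_idx <- b[match(h$query_id, seg_names[b])]
      hits_list[[length(hits_list) + 1L]] <- data.frame(
        chrom = seg_chrom[seg_idx],
        start = seg_off[seg_idx] + h$query_start,
        end = seg_off[seg_idx] + h$query_end,
        family = h$family, strand = h$strand, score = h$score,
        kimura_divergence = h$kimura_divergence, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits_list)) do.call(rbind, hits_list) else empty_hits
  hits <- hits[!duplicated(hits[, c("chrom", "start", "end", "family", "strand")]), ,
               drop = FALSE]
  hits <- hits[order(hits$chrom, hits$start, hits$end), ]
  rownames(hits) <- NULL

  atoms <- resolve_atoms(hits)
  structure(list(hits = hits, atoms = atoms, chrom_lengths = chrom_lengths,
                 total_bp = sum(chrom_lengths)),
            class = "assembly_mask")
}

# Disjoin overlapping hits per chromosome and assign each disjoint atom to
# the highest-scoring hit covering it.
#' @noRd
resolve_atoms <- function(hits) {
  out <- list()
  for (cn in unique(hits$chrom)) {
    h <- hits[hits$chrom == cn, , drop = FALSE]
    ir <- IRanges::IRanges(start = h$start + 1L, end = h$end)
    dj <- IRanges::disjoin(ir)
    ov <- IRanges::findOverlaps(dj, ir)
    best <- tapply(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov),
                   function(idx) idx[which.max(h$score[idx])])
    ai <- as.integer(names(best)); hi <- as.integer(best)
    out[[length(out) + 1L]] <- data.frame(
      chrom = cn, start = IRanges::start(dj)[ai] - 1L,
      end = IRanges::end(dj)[ai], family = h$family[hi],
      kimura_divergence = h$kimura_divergence[hi], score = h$score[hi],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), kimura_divergence = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  atoms <- do.call(rbind, out)
  atoms <- atoms[order(atoms$chrom, atoms$start), ]
  rownames(atoms) <- NULL
  atoms
}

#' Per-chromosome satellite abundance profile
#'
#' @param mask An `assembly_mask` from [mask_assembly_windows()].
#' @param specific_threshold Fraction of a family's assembly-wide bp that
#'   must fall on one chromosome for the family to be flagged
#'   chromosome-specific.
#' @return List of class `chrom_profile`:
#'   * `chromosomes`: `chromosome`, `length`, `satellite_bp`,
#'     `satellite_percent`;
#'   * `families`: `family`, `chromosome`, `bp`, `percent_of_chromosome`;
#'   * `specific`: `family`, `chromosome`, `fraction_on_chromosome`,
#'     `chromosome_specific`.
#' @export
chromosome_abundance <- function(mask, specific_threshold = 0.9) {
  stopifnot(inherits(mask, "assembly_mask"))
  atoms <- mask$atoms
  cl <- mask$chrom_lengths
  if (nrow(atoms)) {
    if (any(atoms$end > cl[atoms$chrom])) {
      stop("hit beyond chromosome end", call. = FALSE)
    }
  }
  bp <- atoms$end - atoms$start
  sat_bp <- tapply(bp, factor(atoms$chrom, levels = names(cl)), sum)
  sat_bp[is.na(sat_bp)] <- 0
  chroms <- data.frame(chromosome = names(cl), length = as.numeric(cl),
                       satellite_bp = as.numeric(sat_bp),
                       satellite_percent = 100 * as.numeric(sat_bp) / as.numeric(cl),
                       stringsAsFactors = FALSE)
  if (nrow(atoms)) {
    fc <- aggregate(list(bp = bp),
                    by = list(family = atoms$family, chromosome = atoms$chrom),
                    sum)
    fc$percent_of_chromosome <- 100 * fc$bp / as.numeric(cl[fc$chromosome])
    fam_tot <- tapply(fc$bp, fc$family, sum)
    best <- do.call(rbind, lapply(split(fc, fc$family), function(d) {
      i <- which.max(d$bp)
      data.frame(family = d$family[i], chromosome = d$chromosome[i],
                 fraction_on_chromosome = d$bp[i] / fam_tot[[d$family[i]]],
                 stringsAsFactors = FALSE)
    }))
    best$chromosome_specific <- best$fraction_on_chromosome >= specific_threshold
    rownames(best) <- NULL
  } else {
    fc <- data.frame(family = character(), chromosome = character(),
                     bp = numeric(), percent_of_chromosome = numeric())
    best <- data.frame(family = character(), chromosome = character(),
                       fraction_on_chromosome = numeric(),
                       chromosome_specific = logical())
  }
  structure(list(chromosomes = chroms, families = fc, specific = best),
            class = "chrom_profile")
}

#' Repeat landscape of one chromosome
#'
#' Builds a [build_landscape()] table from the assembly mask restricted to
#' one chromosome, with the chromosome length as denominator.
#'
#' @param mask An `assembly_mask`.
#' @param chromosome Chromosome name.
#' @param min_abundance Family abundance filter in percent of chromosome.
#' @return A `landscape` data frame.
#' @export
chromosome_landscape <- function(mask, chromosome, min_abundance = 0) {
  stopifnot(inherits(mask, "assembly_mask"))
  if (!chromosome %in% names(mask$chrom_lengths)) {
    stop(sprintf("unknown chromosome '%s'", chromosome), call. = FALSE)
  }
  atoms <- mask$atoms[mask$atoms$chrom == chromosome, , drop = FALSE]
  total <- as.numeric(mask$chrom_lengths[chromosome])
  if (nrow(atoms) == 0L) {
    dv <- structure(data.frame(family = character(), bin = integer(),
                               bp = numeric()),
                    class = c("divsum", "data.frame"), total_query_bp = total)
    return(build_landscape(dv, min_abundance))
  }
  bin <- pmin(floor(atoms$kimura_divergence), 69)
  agg <- aggregate(list(bp = atoms$end - atoms$start),
                   by = list(family = atoms$family, bin = as.integer(bin)), sum)
  dv <- structure(agg[order(agg$family, agg$bin), ],
                  class = c("divsum", "data.frame"), total_query_bp = total)
  build_landscape(dv, min_abundance)
}

#' Write merged satellite intervals as BED
#'
#' Per-family merged (abutting/overlapping) atom intervals.
#'
#' @param mask An `assembly_mask`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_assembly_bed <- function(mask, path) {
  atoms <- mask$atoms
  rows <- list()
  for (cn in unique(atoms$chrom)) {
    for (fam in unique(atoms$family[atoms$chrom == cn])) {
      a <- atoms[atoms$chrom == cn & atoms$family == fam, ]
      r <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, start = IRanges::start(r) - 1L, end = IRanges::end(r),
        name = fam, stringsAsFactors = FALSE)
    }
  }
  bed <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(), start = integer(),
                         end = integer(), name = character())
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
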