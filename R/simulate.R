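# Synthetic tandem-repeat genomes and paired-end reads with full ground truth.
#
# The simulator emulates the data regime of low-coverage satellitome surveys:
# a background genome carrying head-to-tail monomer arrays of known families,
# each copy independently diverged from its consensus (star phylogeny), and
# 150 bp paired-end reads at 0.01-0.5x coverage.

#' Simulation configuration for a synthetic satellite genome
#'
#' Bundles and validates everything [build_genome()] and [simulate_reads()]
#' need. Per-family parameters are given as a data frame with one row per
#' satellite family.
#'
#' @param genome_length Total genome length in bp (background + arrays).
#' @param families Data frame with columns `monomer_length` (bp) and
#'   `target_occupancy` (fraction of the genome), plus optional columns
#'   `name`, `consensus` (monomer sequence; generated when absent),
#'   `divergence_rate` (expected substitutions/site vs consensus, default
#'   0.05), `indel_rate` (indel events/site, default 0.001), `ts_tv_ratio`
#'   (transition:transversion odds, default 2), `gc` (consensus GC, defaults
#'   to `background_gc`) and `n_arrays` (number of tandem arrays; random
#'   1-10 when `NA`). A zero-row data frame simulates a satellite-free genome.
#' @param n_chromosomes Number of chromosomes the genome is split into.
#' @param background_gc GC fraction of the non-repetitive background.
#' @param coverage Sequencing depth in fold coverage (typical 0.01-0.5).
#' @param read_length Read length in bp (default 150).
#' @param insert_size Fragment length in bp (default 350).
#' @param seq_error_rate Per-base sequencing substitution error rate.
#' @param seed Integer seed; the whole simulation is reproducible from
#'   `(config, seed)`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [build_genome()], [simulate_reads()]
#' @export
#' @examples
#' cfg <- sim_config(
#'   genome_length = 2e5,
#'   families = data.frame(monomer_length = 170, target_occupancy = 0.05),
#'   seed = 1
#' )
sim_config <- function(genome_length,
                       families = data.frame(monomer_length = integer(),
                                             target_occupancy = numeric()),
                       n_chromosomes = 1L,
                       background_gc = 0.5,
                       coverage = 0.1,
                       read_length = 150L,
                       insert_size = 350L,
                       seq_error_rate = 0.001,
                       seed = 1L) {
  stopifnot(is.data.frame(families))
  if (!all(c("monomer_length", "target_occupancy") %in% names(families))) {
    stop("`families` needs columns `monomer_length` and `target_occupancy`",
         call. = FALSE)
  }
  n <- nrow(families)
  fill <- function(col, default) {
    if (col %in% names(families)) families[[col]] else rep(default, n)
  }
  fam <- data.frame(
    name = if ("name" %in% names(families)) as.character(families$name)
           else sprintf("Fam%02d", seq_len(n)),
    monomer_length = as.integer(families$monomer_length),
    target_occupancy = as.numeric(families$target_occupancy),
    divergence_rate = as.numeric(fill("divergence_rate", 0.05)),
    indel_rate = as.numeric(fill("indel_rate", 0.001)),
    ts_tv_ratio = as.numeric(fill("ts_tv_ratio", 2)),
    gc = as.numeric(fill("gc", background_gc)),
    n_arrays = as.integer(fill("n_arrays", NA_integer_)),
    stringsAsFactors = FALSE
  )
  if ("consensus" %in% names(families)) {
    fam$consensus <- toupper(as.character(families$consensus))
    bad <- !is.na(fam$consensus) & !is_acgt(fam$consensus)
    if (any(bad)) stop("family consensus sequences must be A/C/G/T only", call. = FALSE)
  } else {
    fam$consensus <- rep(NA_character_, n)
  }
  if (anyDuplicated(fam$name)) stop("duplicate family names in `families`", call. = FALSE)

  genome_length <- as.integer(genome_length)
  if (is.na(genome_length) || genome_length < 1000L) {
    stop("`genome_length` must be at least 1000 bp", call. = FALSE)
  }
  if (n > 0L) {
    if (any(fam$monomer_length < 10L)) stop("monomer_length must be >= 10 bp", call. = FALSE)
    if (any(fam$target_occupancy < 0)) stop("target_occupancy must be >= 0", call. = FALSE)
    for (i in seq_len(n)) {
      check_rate(fam$divergence_rate[i], "divergence_rate")
      check_rate(fam$indel_rate[i], "indel_rate")
      check_rate(fam$gc[i], "gc")
    }
    if (any(fam$ts_tv_ratio <= 0)) stop("ts_tv_ratio must be > 0", call. = FALSE)
  }
  if (sum(fam$target_occupancy) >= 1) {
    stop("sum of target_occupancy must be < 1", call. = FALSE)
  }
  check_rate(background_gc, "background_gc")
  check_rate(seq_error_rate, "seq_error_rate")
  if (!is.numeric(coverage) || coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  read_length <- as.integer(read_length); insert_size <- as.integer(insert_size)
  if (read_length < 20L) stop("read_length must be >= 20 bp", call. = FALSE)
  if (read_length > insert_size) stop("read_length must be <= insert_size", call. = FALSE)
  n_chromosomes <- as.integer(n_chromosomes)
  if (n_chromosomes < 1L) stop("n_chromosomes must be >= 1", call. = FALSE)

  structure(list(
    genome_length = genome_length, families = fam,
    n_chromosomes = n_chromosomes, background_gc = background_gc,
    coverage = coverage, read_length = read_length, insert_size = insert_size,
    seq_error_rate = seq_error_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a random monomer consensus sequence
#'
#' @param length Monomer length in bp (>= 10).
#' @param gc GC fraction; bases are drawn i.i.d. with
#'   `P(G) = P(C) = gc/2`.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return A single uppercase A/C/G/T character string of length `length`.
#' @export
#' @examples
#' make_consensus(170, gc = 0.4, seed = 7)
make_consensus <- function(length, gc = 0.5, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 10L) {
    stop("`length` must be an integer >= 10", call. = FALSE)
  }
  check_rate(gc, "gc")
  with_seed(seed, random_dna(length, gc))
}

#' @noRd
random_dna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a monomer copy away from its consensus
#'
#' Each site is substituted independently with probability `sub_rate`; a
#' substitution is a transition with odds `ts_tv_ratio` : 1 against each of
#' the two transversion targets. Indel events occur at `indel_rate` per site,
#' insertion or deletion with equal probability, lengths uniform on 1-5 bp.
#'
#' @param consensus Consensus sequence (character or `DNAString`).
#' @param sub_rate Substitution probability per site, in `[0, 1)`.
#' @param indel_rate Indel event probability per site, in `[0, 1)`.
#' @param ts_tv_ratio Transition/transversion odds ratio (> 0).
#' @param seed Optional seed.
#' @return The mutated copy as a character string.
#' @export
#' @examples
#' mutate_copy("ACGTACGTACGT", sub_rate = 0.1, indel_rate = 0, seed = 1)
mutate_copy <- function(consensus, sub_rate, indel_rate = 0, ts_tv_ratio = 2,
                        seed = NULL) {
  with_seed(seed, mutate_copy_stats(as_seq_chr(consensus, "consensus"),
                                    sub_rate, indel_rate, ts_tv_ratio)$seq)
}

# Internal workhorse: also reports realized substitution events so the
# simulator's truth table can record per-family divergence exactly.
#' @noRd
mutate_copy_stats <- function(consensus, sub_rate, indel_rate, ts_tv_ratio) {
  check_rate(sub_rate, "sub_rate")
  check_rate(indel_rate, "indel_rate")
  if (!is.numeric(ts_tv_ratio) || ts_tv_ratio <= 0) {
    stop("ts_tv_ratio must be > 0", call. = FALSE)
  }
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  n <- length(chars)
  n_ts <- 0L; n_tv <- 0L
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit)) {
      is_ts <- runif(length(hit)) < ts_tv_ratio / (ts_tv_ratio + 2)
      ts_map <- c(A = "G", G = "A", C = "T", T = "C")
      tv_map <- list(A = c("C", "T"), C = c("A", "G"),
                     G = c("C", "T"), T = c("A", "G"))
      orig <- chars[hit]
      new <- character(length(hit))
      new[is_ts] <- ts_map[orig[is_ts]]
      if (any(!is_ts)) {
        pick <- 1L + (runif(sum(!is_ts)) < 0.5)
        new[!is_ts] <- mapply(function(b, k) tv_map[[b]][k], orig[!is_ts], pick)
      }
      chars[hit] <- new
      n_ts <- sum(is_ts); n_tv <- sum(!is_ts)
    }
  }
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate)
    if (length(ev)) {
      is_ins <- runif(length(ev)) < 0.5
      len <- sample.int(5L, length(ev), replace = TRUE)
      ins_seq <- lapply(seq_along(ev), function(i) {
        if (is_ins[i]) sample(BASES, len[i], replace = TRUE) else NULL
      })
      # splice right-to-left so earlier event positions stay valid
      for (i in rev(seq_along(ev))) {
        p <- ev[i]
        if (is_ins[i]) {
          chars <- append(chars, ins_seq[[i]], after = p)
        } else {
          chars <- chars[-(p:min(p + len[i] - 1L, length(chars)))]
        }
      }
    }
  }
  list(seq = paste(chars, collapse = ""), n_sites = n, n_ts = n_ts, n_tv = n_tv)
}

#' Build a synthetic genome with planted tandem satellite arrays
#'
#' The genome is a random background of `genome_length` minus the planted
#' array bp, split across chromosomes, with each family's bp budget
#' (`target_occupancy * genome_length`) laid down as 1-10 head-to-tail
#' arrays of independently mutated monomer copies. Array loci are disjoint
#' by construction (arrays are spliced into the background), and the truth
#' table records every planted interval and the realized per-family
#' divergence.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sat_sim`: a list with
#'   * `genome`: named `DNAStringSet` of chromosomes;
#'   * `truth`: list of `families` (name, consensus, planted_bp,
#'     realized_occupancy, mean_realized_divergence in %, realized transition
#'     and transversion percentages) and `arrays`
#'     (family, chrom, start, end, strand; 0-based half-open);
#'   * `config`: the input configuration.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, build_genome_impl(config))
}

#' @noRd
build_genome_impl <- function(config) {
  G <- config$genome_length
  fam <- config$families
  nfam <- nrow(fam)

  arrays <- list()   # per-array: family, seq, strand, n_copies
  fam_stats <- data.frame(name = fam$name,
                          consensus = rep(NA_character_, nfam),
                          monomer_length = fam$monomer_length,
                          planted_bp = numeric(nfam),
                          copy_sites = numeric(nfam),
                          n_ts = numeric(nfam), n_tv = numeric(nfam),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nfam)) {
    mono <- fam$monomer_length[i]
    cons <- fam$consensus[i]
    if (is.na(cons)) cons <- random_dna(mono, fam$gc[i])
    fam_stats$consensus[i] <- cons
    budget <- round(fam$target_occupancy[i] * G)
    if (budget < mono) next
    n_arr <- fam$n_arrays[i]
    max_arr <- max(1L, min(10L, budget %/% (2L * mono)))
    if (is.na(n_arr)) n_arr <- sample.int(max_arr, 1L)
    n_arr <- min(n_arr, max_arr)
    w <- rgamma(n_arr, shape = 1)
    alloc <- pmax(budget * w / sum(w), 2 * mono)
    for (j in seq_len(n_arr)) {
      copies <- character(0); total <- 0L
      while (total < alloc[j]) {
        m <- mutate_copy_stats(cons, fam$divergence_rate[i],
                               fam$indel_rate[i], fam$ts_tv_ratio[i])
        copies <- c(copies, m$seq)
        total <- total + nchar(m$seq)
        fam_stats$copy_sites[i] <- fam_stats$copy_sites[i] + m$n_sites
        fam_stats$n_ts[i] <- fam_stats$n_ts[i] + m$n_ts
        fam_stats$n_tv[i] <- fam_stats$n_tv[i] + m$n_tv
      }
      arr <- paste(copies, collapse = "")
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") arr <- revcomp_chr(arr)
      arrays[[length(arrays) + 1L]] <- list(family = fam$name[i], seq = arr,
                                            strand = strand,
                                            n_copies = length(copies))
      fam_stats$planted_bp[i] <- fam_stats$planted_bp[i] + nchar(arr)
    }
  }

  total_planted <- sum(vapply(arrays, function(a) nchar(a$seq), numeric(1)))
  chrom_target <- rep(G %/% config$n_chromosomes, config$n_chromosomes)
  chrom_target[1L] <- chrom_target[1L] + G %% config$n_chromosomes
  if (total_planted >= sum(chrom_target)) {
    stop("placement error: planted arrays exceed genome length", call. = FALSE)
  }

  # assign arrays to chromosomes; retry if a chromosome overflows
  n_arr_tot <- length(arrays)
  assign_ok <- FALSE
  for (try in seq_len(50L)) {
    chrom_of <- if (n_arr_tot) sample.int(config$n_chromosomes, n_arr_tot,
                                          replace = TRUE, prob = chrom_target)
                else integer(0)
    load <- vapply(seq_len(config$n_chromosomes), function(c) {
      sum(vapply(arrays[chrom_of == c], function(a) nchar(a$seq), numeric(1)))
    }, numeric(1))
    if (all(load < chrom_target)) { assign_ok <- TRUE; break }
  }
  if (!assign_ok) {
    stop("placement error: could not place arrays without overflowing a chromosome",
         call. = FALSE)
  }

  chroms <- character(config$n_chromosomes)
  truth_arrays <- list()
  for (c in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == c)
    arr_len <- vapply(arrays[idx], function(a) nchar(a$seq), integer(1))
    bg_len <- chrom_target[c] - sum(arr_len)
    bg <- random_dna(bg_len, config$background_gc)
    if (length(idx)) {
      off <- sort(floor(runif(length(idx)) * (bg_len + 1L)))  # 0-based offsets
      ord <- order(off)
      off <- off[ord]; idx <- idx[ord]; arr_len <- arr_len[ord]
      pieces <- character(0)
      pos <- 0L          # consumed background
      shift <- 0L        # array bp already inserted
      for (k in seq_along(idx)) {
        pieces <- c(pieces, substr(bg, pos + 1L, off[k]))
        start <- off[k] + shift
        pieces <- c(pieces, arrays[[idx[k]]]$seq)
        truth_arrays[[length(truth_arrays) + 1L]] <- data.frame(
          family = arrays[[idx[k]]]$family, chrom = sprintf("chr%d", c),
          start = start, end = start + arr_len[k],
          strand = arrays[[idx[k]]]$strand,
          n_copies = arrays[[idx[k]]]$n_copies, stringsAsFactors = FALSE)
        pos <- off[k]
        shift <- shift + arr_len[k]
      }
      pieces <- c(pieces, substr(bg, pos + 1L, bg_len))
      chroms[c] <- paste(pieces, collapse = "")
    } else {
      chroms[c] <- bg
    }
  }
  genome <- Biostrings::DNAStringSet(chroms)
  names(genome) <- sprintf("chr%d", seq_len(config$n_chromosomes))
  stopifnot(sum(Biostrings::width(genome)) == G)

  truth_fam <- data.frame(
    name = fam_stats$name,
    consensus = fam_stats$consensus,
    monomer_length = fam_stats$monomer_length,
    planted_bp = fam_stats$planted_bp,
    realized_occupancy = fam_stats$planted_bp / G,
    mean_realized_divergence =
      ifelse(fam_stats$copy_sites > 0,
             100 * (fam_stats$n_ts + fam_stats$n_tv) / fam_stats$copy_sites, 0),
    realized_p = ifelse(fam_stats$copy_sites > 0,
                        100 * fam_stats$n_ts / fam_stats$copy_sites, 0),
    realized_q = ifelse(fam_stats$copy_sites > 0,
                        100 * fam_stats$n_tv / fam_stats$copy_sites, 0),
    stringsAsFactors = FALSE
  )
  truth_arr <- if (length(truth_arrays)) do.call(rbind, truth_arrays)
               else data.frame(family = character(), chrom = character(),
                               start = integer(), end = integer(),
                               strand = character(), n_copies = integer())

  structure(list(genome = genome,
                 truth = list(families = truth_fam, arrays = truth_arr),
                 config = config),
            class = "sat_sim")
}

#' Simulate paired-end reads from a genome
#'
#' Fragments of `insert_size` bp are drawn uniformly over the genome; read 1
#' is the fragment 5' end, read 2 the reverse complement of the fragment 3'
#' end. The number of pairs is `floor(coverage * genome_bp /
#' (2 * read_length))`. Per-base substitution errors are applied at
#' `seq_error_rate`; quality strings are constant `"I"` (the pipeline never
#' uses qualities).
#'
#' @param genome A `sat_sim` object from [build_genome()] or a
#'   `DNAStringSet`.
#' @param coverage,read_length,insert_size,seq_error_rate Override the
#'   values stored in the simulation's config (required when `genome` is a
#'   plain `DNAStringSet`).
#' @param seed Optional seed; for a `sat_sim` input the config seed + 1 is
#'   used by default so genome and reads come from distinct streams.
#' @return An object of class `sim_reads`: list with `read1`/`read2`
#'   (`DNAStringSet`), plus the simulation parameters.
#' @export
simulate_reads <- function(genome, coverage = NULL, read_length = NULL,
                           insert_size = NULL, seq_error_rate = NULL,
                           seed = NULL) {
  if (inherits(genome, "sat_sim")) {
    cfg <- genome$config
    coverage <- coverage %||% cfg$coverage
    read_length <- read_length %||% cfg$read_length
    insert_size <- insert_size %||% cfg$insert_size
    seq_error_rate <- seq_error_rate %||% cfg$seq_error_rate
    seed <- seed %||% (cfg$seed + 1L)
    genome <- genome$genome
  }
  genome <- as_dss(genome, "chr")
  if (is.null(coverage) || is.null(read_length) || is.null(insert_size)) {
    stop("coverage, read_length and insert_size are required", call. = FALSE)
  }
  read_length <- as.integer(read_length); insert_size <- as.integer(insert_size)
  if (insert_size < read_length) stop("insert_size must be >= read_length", call. = FALSE)
  check_rate(seq_error_rate %||% 0, "seq_error_rate")
  seq_error_rate <- seq_error_rate %||% 0
  w <- Biostrings::width(genome)
  if (any(w < insert_size)) {
    stop("genome sequence shorter than insert_size", call. = FALSE)
  }
  total_bp <- sum(w)
  n_pairs <- floor(coverage * total_bp / (2 * read_length))
  if (n_pairs < 1) stop("coverage too low: zero read pairs", call. = FALSE)

  with_seed(seed, {
    valid <- w - insert_size + 1L
    chrom <- sample.int(length(genome), n_pairs, replace = TRUE,
                        prob = valid / sum(valid))
    start <- floor(runif(n_pairs) * valid[chrom]) + 1L
    chars <- as.character(genome)
    frag <- substring(chars[chrom], start, start + insert_size - 1L)
    r1 <- substr(frag, 1L, read_length)
    r2 <- revcomp_chr(substring(frag, insert_size - read_length + 1L, insert_size))
    if (seq_error_rate > 0) {
      r1 <- inject_errors(r1, seq_error_rate)
      r2 <- inject_errors(r2, seq_error_rate)
    }
    ids <- sprintf("read%06d", seq_len(n_pairs))
    read1 <- Biostrings::DNAStringSet(r1); names(read1) <- ids
    read2 <- Biostrings::DNAStringSet(r2); names(read2) <- ids
    structure(list(read1 = read1, read2 = read2, n_pairs = n_pairs,
                   read_length = read_length, insert_size = insert_size,
                   coverage = coverage, seq_error_rate = seq_error_rate),
              class = "sim_reads")
  })
}

#' @noRd
inject_errors <- function(reads, rate) {
  nc <- nchar(reads[1L])
  n <- length(reads)
  hits <- which(runif(n * nc) < rate)
  if (!length(hits)) return(reads)
  ri <- ((hits - 1L) %/% nc) + 1L
  pos <- ((hits - 1L) %% nc) + 1L
  for (k in seq_along(hits)) {
    old <- substr(reads[ri[k]], pos[k], pos[k])
    new <- sample(setdiff(BASES, old), 1L)
    substr(reads[ri[k]], pos[k], pos[k]) <- new
  }
  reads
}

#' Write simulated paired reads as a gzip FASTQ pair
#'
#' @param reads A `sim_reads` object.
#' @param prefix Output path prefix; files `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz` are written (uncompressed `.fastq` when
#'   `compress = FALSE`).
#' @param compress Write gzip-compressed output.
#' @return Invisibly, the two file paths.
#' @export
write_reads <- function(reads, prefix, compress = TRUE) {
  stopifnot(inherits(reads, "sim_reads"))
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (i in 1:2) {
    x <- if (i == 1) reads$read1 else reads$read2
    qs <- Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(strrep("I", Biostrings::width(x))))
    Biostrings::writeQualityScaledXStringSet(qs, paths[i], compress = compress)
  }
  invisible(paths)
}

#' Write a simulated genome and its truth table to disk
#'
#' Writes `genome.fasta`, `truth_arrays.tsv` (family, chrom, start, end,
#' strand; 0-based half-open) and `truth_families.tsv` into `dir`.
#'
#' @param sim A `sat_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sat_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(sim$genome, fa)
  p1 <- write_tsv(sim$truth$arrays, file.path(dir, "truth_arrays.tsv"))
  p2 <- write_tsv(sim$truth$families, file.path(dir, "truth_families.tsv"))
  invisible(c(fa, p1, p2))
}

#' Simulate per-family abundance/divergence summary statistics
#'
#' Generates a `FamilyStat`-style table without sequence simulation: a set of
#' exchangeable background families plus a subset of amplified, recently
#' homogenized families (higher abundance, lower divergence). Used to study
#' the behaviour of the z-score gain/loss classifier.
#'
#' @param n_families Total number of families.
#' @param n_amplified Number of amplified low-divergence families.
#' @param base_abundance Range (%, uniform) of background family abundances.
#' @param amplified_abundance Mean abundance (%) of amplified families
#'   (jittered by +/-20%).
#' @param base_divergence,amplified_divergence Mean and sd (length-2 vectors)
#'   of background and amplified mean Kimura divergences (%).
#' @param seed Optional seed.
#' @return Data frame with columns `family`, `abundance` (fraction of
#'   genome), `mean_divergence` (%) and `amplified` (logical truth flag).
#' @export
simulate_family_stats <- function(n_families = 20L, n_amplified = 5L,
                                  base_abundance = c(0.1, 0.3),
                                  amplified_abundance = 3,
                                  base_divergence = c(15, 2),
                                  amplified_divergence = c(4, 1),
                                  seed = NULL) {
  stopifnot(n_amplified < n_families)
  with_seed(seed, {
    n_bg <- n_families - n_amplified
    ab <- c(runif(n_bg, base_abundance[1], base_abundance[2]),
            amplified_abundance * runif(n_amplified, 0.8, 1.2))
    dv <- c(stats::rnorm(n_bg, base_divergence[1], base_divergence[2]),
            stats::rnorm(n_amplified, amplified_divergence[1], amplified_divergence[2]))
    dv <- pmin(pmax(dv, 0.1), 69)
    data.frame(family = sprintf("Fam%02d", seq_len(n_families)),
               abundance = ab / 100,
               mean_divergence = dv,
               amplified = rep(c(FALSE, TRUE), c(n_bg, n_amplified)),
               stringsAsFactors = FALSE)
  })
}
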