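# End-to-end orchestration: simulate/load reads -> subsample -> mask ->
# landscape -> z-scores -> optional chromosome distribution, with a run
# manifest and per-family summary table.

#' Subsample a paired FASTQ file pair
#'
#' Uniform sample of read pairs without replacement, mates kept together and
#' input order preserved. When `n_pairs` is at least the number of pairs the
#' input passes through unchanged.
#'
#' @param in1,in2 Input FASTQ paths (gzip allowed).
#' @param out1,out2 Output FASTQ paths (gzip chosen by extension).
#' @param n_pairs Number of pairs to keep.
#' @param seed Seed for the random sample.
#' @return Invisibly, `c(out1, out2)`.
#' @export
subsample_reads <- function(in1, in2, out1, out2, n_pairs, seed = 1L) {
  r1 <- read_fastq_qs(in1)
  r2 <- read_fastq_qs(in2)
  if (length(r1) != length(r2)) {
    stop(sprintf("mismatched pair counts: %d vs %d", length(r1), length(r2)),
         call. = FALSE)
  }
  keep <- subsample_index(length(r1), n_pairs, seed)
  for (io in list(list(r1, out1), list(r2, out2))) {
    Biostrings::writeQualityScaledXStringSet(
      io[[1]][keep], io[[2]], compress = grepl("\\.gz$", io[[2]]))
  }
  invisible(c(out1, out2))
}

# readQualityScaledDNAStringSet warns about dropping (empty) metadata
# columns on every call; that note is irrelevant here.
#' @noRd
read_fastq_qs <- function(path) {
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' @noRd
subsample_index <- function(total, n_pairs, seed) {
  if (n_pairs >= total) return(seq_len(total))
  with_seed(seed, sort(sample.int(total, n_pairs)))
}

#' Read a pipeline configuration file
#'
#' Plain-text YAML-compatible key/value file; see [run_pipeline()] for the
#' recognised keys.
#'
#' @param path Config file path.
#' @return The configuration as a named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}

#' @noRd
config_sim <- function(sc) {
  fam <- do.call(rbind, lapply(sc$families, function(f) as.data.frame(f)))
  args <- sc[setdiff(names(sc), "families")]
  do.call(sim_config, c(list(families = fam), args))
}

#' Run the satellitome pipeline end to end
#'
#' Stages: (optional) simulate genome and reads -> subsample read pairs ->
#' mask against the satellite library -> divsum summary -> landscape ->
#' z-score gain/loss classification -> (optional) chromosome-level
#' distribution. All stage outputs, a per-family summary TSV and a
#' machine-readable JSON manifest (parameters, seed, output checksums,
#' warning counts) are written to `outdir`. Any stage failure aborts with
#' an error naming the stage; outputs of completed stages are retained.
#'
#' @param config A configuration list or path to a YAML file. Keys:
#'   * `outdir` (required): output directory;
#'   * `seed`: integer seed (default 1);
#'   * either `simulate:` (arguments of [sim_config()], with `families` a
#'     list of per-family maps) or `reads: [R1, R2]` FASTQ paths;
#'   * `library`: FASTA of family consensuses (defaults to the simulation
#'     truth when simulating);
#'   * `assembly`: optional chromosome-level FASTA to profile;
#'   * `subsample_n`: read pairs to keep (default 3000000);
#'   * `scoring`: overrides for [scoring_scheme()] fields;
#'   * `thresholds`: `min_abundance` (landscape filter, % of genome,
#'     default 0.2), `recent_bin` (default 5), `superfamily_identity` /
#'     `superfamily_coverage` (defaults 0.7 / 0.5).
#' @param outdir Overrides `config$outdir`.
#' @return Invisibly, a list with the per-stage results (`family_summary`,
#'   `landscape`, `zscores`, `superfamilies`, optional `chromdist`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("config error: `outdir` is required", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  n_warn <- 0L
  stage <- function(name, code) {
    withCallingHandlers(
      tryCatch(code, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
  }
  scoring <- do.call(scoring_scheme, config$scoring %||% list())
  thr <- config$thresholds %||% list()
  min_abundance <- thr$min_abundance %||% 0.2
  recent_bin <- thr$recent_bin %||% 5
  outputs <- character(0)
  note <- function(path) { outputs <<- c(outputs, path); path }

  sim <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- config$simulate
      sc$seed <- sc$seed %||% seed
      s <- build_genome(config_sim(sc))
      write_simulation(s, file.path(outdir, "simulation"))
      s
    })
    reads <- stage("simulate", simulate_reads(sim))
    lib <- as_satlib_df(sim)
  } else {
    if (is.null(config$reads) || length(config$reads) != 2L) {
      stop("config error: `reads` must list exactly two FASTQ paths (or use `simulate`)",
           call. = FALSE)
    }
    if (is.null(config$library)) {
      stop("config error: `library` FASTA is required when masking real reads",
           call. = FALSE)
    }
    for (p in c(config$reads, config$library)) {
      if (!file.exists(p)) stop(sprintf("config error: path not found: %s", p), call. = FALSE)
    }
    lib <- stage("library", read_satlib(config$library))
    reads <- stage("load_reads", {
      r1 <- read_fastq_qs(config$reads[[1]])
      r2 <- read_fastq_qs(config$reads[[2]])
      if (length(r1) != length(r2)) stop("mismatched pair counts")
      structure(list(read1 = Biostrings::DNAStringSet(r1),
                     read2 = Biostrings::DNAStringSet(r2),
                     n_pairs = length(r1)), class = "sim_reads")
    })
  }

  reads <- stage("subsample", {
    n_keep <- as.integer(config$subsample_n %||% 3000000L)
    keep <- subsample_index(reads$n_pairs, n_keep, seed + 2L)
    structure(list(read1 = reads$read1[keep], read2 = reads$read2[keep],
                   n_pairs = length(keep)), class = "sim_reads")
  })

  hits <- stage("mask", mask_sequences(reads, lib, scoring))
  note(write_tsv(as.data.frame(hits), file.path(outdir, "hits.tsv")))
  note(write_hits_bed(hits, file.path(outdir, "hits.bed")))

  divsum <- stage("divsum", summarize_divsum(hits))
  note(write_tsv(as.data.frame(divsum), file.path(outdir, "divsum.tsv")))
  fstats <- stage("divsum", family_stats(hits))
  note(write_tsv(as.data.frame(fstats), file.path(outdir, "family_stats.tsv")))

  lsc <- stage("landscape", build_landscape(divsum, min_abundance))
  utils::write.csv(as.data.frame(lsc), note(file.path(outdir, "landscape.csv")),
                   row.names = FALSE)
  peaks <- if (nrow(lsc)) stage("landscape", peak_ages(lsc, recent_bin)) else NULL

  zsc <- stage("gainloss", compute_zscores(fstats))
  note(write_tsv(as.data.frame(zsc)[, c("family", "abundance", "mean_divergence",
                                        "z_abundance", "z_divergence", "class",
                                        "highly_abundant_homogenized")],
                 file.path(outdir, "zscores.tsv")))
  gl <- gainloss_summary(zsc)

  sf <- stage("superfamilies", group_superfamilies(
    lib, thr$superfamily_identity %||% 0.7, thr$superfamily_coverage %||% 0.5,
    scoring))
  note(write_tsv(sf$membership, file.path(outdir, "superfamilies.tsv")))

  chromdist <- NULL
  asm <- config$assembly
  if (!is.null(asm) || !is.null(sim)) {
    chromdist <- stage("chromdist", {
      assembly <- if (!is.null(asm)) {
        if (!file.exists(asm)) stop(sprintf("path not found: %s", asm))
        Biostrings::readDNAStringSet(asm)
      } else if (isTRUE(config$profile_simulated_assembly)) {
        sim$genome
      } else NULL
      if (is.null(assembly)) NULL else {
        m <- mask_assembly_windows(assembly, lib, scoring)
        prof <- chromosome_abundance(m)
        write_tsv(prof$chromosomes, note(file.path(outdir, "chromosomes.tsv")))
        write_tsv(prof$families, note(file.path(outdir, "chrom_families.tsv")))
        write_assembly_bed(m, note(file.path(outdir, "satellites.bed")))
        list(mask = m, profile = prof)
      }
    })
  }

  summary_df <- merge(as.data.frame(zsc),
                      if (!is.null(peaks)) peaks else
                        data.frame(family = character(), mode_bin = integer(),
                                   mode_percent = numeric(), is_recent = logical()),
                      by = "family", all.x = TRUE)
  summary_df$abundance_percent <- 100 * summary_df$abundance
  summary_df <- summary_df[order(-summary_df$abundance),
                           c("family", "abundance_percent", "mean_divergence",
                             "n_hits", "z_abundance", "z_divergence", "class",
                             "highly_abundant_homogenized", "mode_bin",
                             "is_recent")]
  note(write_tsv(summary_df, file.path(outdir, "summary.tsv")))

  manifest <- list(
    package = "satdyn",
    version = as.character(utils::packageVersion("satdyn")),
    seed = seed,
    parameters = list(scoring = unclass(scoring),
                      min_abundance = min_abundance, recent_bin = recent_bin,
                      subsample_n = config$subsample_n %||% 3000000L),
    inputs = config[intersect(names(config), c("reads", "library", "assembly",
                                               "simulate"))],
    n_read_pairs = reads$n_pairs,
    total_query_bp = attr(hits, "total_query_bp"),
    n_warnings = n_warn,
    n_saturated_hits = attr(hits, "n_saturated"),
    species_summary = gl,
    checksums = as.list(tools::md5sum(sort(unique(outputs))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(family_summary = summary_df, landscape = lsc, zscores = zsc,
                 gainloss = gl, superfamilies = sf, chromdist = chromdist,
                 hits = hits, manifest = manifest))
}
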