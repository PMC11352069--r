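# Reference study conditions for the parameter-recovery benchmark.

#' Simulation config for the abundance/divergence recovery benchmark
#'
#' A 10 Mb genome with ten satellite families whose occupancies follow the
#' two-tier structure typical of real satellitomes — a rare tier
#' (0.2-0.4% of the genome, below or near the landscape reporting filter)
#' and a dominant tier (2-5%) — with planted divergences interleaved over
#' 2-20% across the tiers so that accuracy is probed over the whole
#' divergence range. Monomer lengths span 57-350 bp; transitions are
#' favoured 2:1; indels at 0.001/site; reads are 150 bp pairs at 0.1x
#' coverage with a 0.001/base error rate.
#'
#' @param seed Integer seed for the simulation.
#' @param genome_length Genome size in bp.
#' @param coverage Sequencing coverage.
#' @return A [sim_config()] object.
#' @export
benchmark_config <- function(seed = 42L, genome_length = 1e7, coverage = 0.1) {
  fams <- data.frame(
    name = sprintf("BchSat%02d", 1:10),
    monomer_length = c(170L, 150L, 300L, 57L, 120L, 210L, 90L, 350L, 140L, 250L),
    target_occupancy = c(0.002, 0.0025, 0.003, 0.0035, 0.004,
                         0.02, 0.025, 0.03, 0.04, 0.05),
    divergence_rate = c(0.04, 0.08, 0.12, 0.16, 0.20,
                        0.02, 0.06, 0.10, 0.14, 0.18),
    indel_rate = 0.001,
    ts_tv_ratio = 2
  )
  sim_config(genome_length = genome_length, families = fams,
             n_chromosomes = 1L, background_gc = 0.5, coverage = coverage,
             read_length = 150L, insert_size = 350L, seq_error_rate = 0.001,
             seed = as.integer(seed))
}

#' Run the recovery benchmark and compare estimates to the planted truth
#'
#' Builds the [benchmark_config()] genome, simulates reads, masks them
#' against the true consensus library and contrasts estimated per-family
#' abundance and mean divergence with the simulator's truth table.
#'
#' @param config A [sim_config()], typically [benchmark_config()].
#' @return List with `comparison` (per-family data frame: truth, estimates,
#'   relative abundance error, divergence error in pp, hit counts),
#'   `spearman_rho` (estimated vs true abundance), and the `hits` /
#'   `family_stats` objects.
#' @export
run_recovery_benchmark <- function(config = benchmark_config()) {
  sim <- build_genome(config)
  reads <- simulate_reads(sim)
  hits <- mask_sequences(reads, sim)
  fs <- family_stats(hits)
  tf <- sim$truth$families
  cmp <- merge(tf[, c("name", "realized_occupancy", "mean_realized_divergence")],
               as.data.frame(fs)[, c("family", "abundance", "mean_divergence",
                                     "n_hits")],
               by.x = "name", by.y = "family", all.x = TRUE)
  cmp$abundance[is.na(cmp$abundance)] <- 0
  cmp$n_hits[is.na(cmp$n_hits)] <- 0L
  cmp$rel_abundance_error <- abs(cmp$abundance - cmp$realized_occupancy) /
    cmp$realized_occupancy
  cmp$divergence_error_pp <- cmp$mean_divergence - cmp$mean_realized_divergence
  rho <- spearman_test(cmp$abundance, cmp$realized_occupancy)$rho
  list(comparison = cmp[order(-cmp$realized_occupancy), ],
       spearman_rho = rho, hits = hits, family_stats = fs, sim = sim)
}
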