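# Z-score classification of satellite family gain, loss and homogenization.
#
# Within one species, per-family abundance and mean divergence are
# standardized across families. Families with positive abundance z-scores
# are classified as net gains (regardless of the divergence sign), negative
# as losses; families with z-abundance > 1 and negative z-divergence are
# flagged as highly abundant and homogenized (recent amplification).

#' Standardize family abundance and divergence into z-scores
#'
#' @param stats A `family_stats`-like data frame with columns `family`,
#'   `abundance` and `mean_divergence` (any additional columns are
#'   retained).
#' @param flag_threshold z-abundance above which a family with negative
#'   z-divergence is flagged highly abundant + homogenized.
#' @return Data frame of class `zscore_records`: input columns plus
#'   `z_abundance`, `z_divergence`, `class` (`"gain"`/`"loss"`) and
#'   `highly_abundant_homogenized`.
#' @details Standardization uses the sample (n-1) standard deviation across
#'   the families of one species. Classification follows
#'   [classify_gainloss()].
#' @export
compute_zscores <- function(stats, flag_threshold = 1) {
  need <- c("family", "abundance", "mean_divergence")
  if (!all(need %in% names(stats))) {
    stop("stats needs columns family, abundance, mean_divergence", call. = FALSE)
  }
  n <- nrow(stats)
  if (n < 2L) stop("need at least 2 families to standardize", call. = FALSE)
  for (v in c("abundance", "mean_divergence")) {
    if (sd(stats[[v]]) == 0) {
      stop(sprintf("zero variance in %s: z-scores undefined", v), call. = FALSE)
    }
  }
  out <- stats
  out$z_abundance <- as.numeric(scale(stats$abundance))
  out$z_divergence <- as.numeric(scale(stats$mean_divergence))
  cls <- classify_gainloss(out$z_abundance, out$z_divergence, flag_threshold)
  out$class <- cls$class
  out$highly_abundant_homogenized <- cls$highly_abundant_homogenized
  structure(out, class = c("zscore_records", "data.frame"))
}

#' Gain/loss classification rule
#'
#' * `z_abundance > 0` -> `"gain"`, whatever the divergence sign;
#' * `z_abundance < 0` -> `"loss"`, irrespective of divergence;
#' * `z_abundance == 0` -> `"loss"` (gain requires strictly positive
#'   standardized abundance; the boundary has measure zero in practice);
#' * flagged highly abundant + homogenized iff `z_abundance >
#'   flag_threshold` (default 1) and `z_divergence < 0`.
#'
#' @param z_abundance,z_divergence Numeric vectors of equal length.
#' @param flag_threshold Abundance z-score the flag requires (exclusive).
#' @return List with `class` (character) and `highly_abundant_homogenized`
#'   (logical).
#' @export
#' @examples
#' classify_gainloss(c(0.5, -0.3, 1.5, 0), c(-1.2, -2, -0.2, 0.7))
classify_gainloss <- function(z_abundance, z_divergence, flag_threshold = 1) {
  if (length(z_abundance) != length(z_divergence)) {
    stop("z_abundance and z_divergence must have equal length", call. = FALSE)
  }
  if (any(!is.finite(z_abundance)) || any(!is.finite(z_divergence))) {
    stop("z-scores must be finite", call. = FALSE)
  }
  list(class = ifelse(z_abundance > 0, "gain", "loss"),
       highly_abundant_homogenized = z_abundance > flag_threshold &
         z_divergence < 0)
}

#' Per-species summary of gain/loss counts
#'
#' @param records A single `zscore_records` data frame, or a named list of
#'   them (one per species), or a data frame with a `species` column.
#' @return Data frame: `species`, `n_families`, `n_gain`, `n_loss`,
#'   `n_flagged`. `n_gain + n_loss == n_families` always.
#' @export
gainloss_summary <- function(records) {
  if (is.data.frame(records)) {
    if ("species" %in% names(records)) {
      records <- split(records, records$species)
    } else {
      records <- list(all = records)
    }
  }
  if (is.null(names(records))) {
    names(records) <- sprintf("species%d", seq_along(records))
  }
  res <- lapply(names(records), function(sp) {
    r <- records[[sp]]
    data.frame(species = sp, n_families = nrow(r),
               n_gain = sum(r$class == "gain"),
               n_loss = sum(r$class == "loss"),
               n_flagged = sum(r$highly_abundant_homogenized),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
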