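# Satellitome landscapes: per-family genome fraction per 1% divergence bin.

#' Build a repeat landscape from a divsum table
#'
#' Converts aligned bp per (family, divergence bin) into percent of genome
#' per bin, dropping families whose total abundance does not exceed
#' `min_abundance` percent (comparative satellitome descriptions typically
#' restrict attention to families above 0.2% of the genome).
#'
#' @param divsum A [summarize_divsum()] table.
#' @param min_abundance Abundance threshold in percent of genome; families
#'   with total abundance `<= min_abundance` are dropped. Use 0 to keep all.
#' @param total_bp Denominator bp (defaults to the divsum attribute).
#' @return Data frame of class `landscape` with columns `family`, `bin`,
#'   `percent`; attributes `total_bp` and `min_abundance`.
#' @export
build_landscape <- function(divsum, min_abundance = 0.2,
                            total_bp = attr(divsum, "total_query_bp")) {
  if (is.null(total_bp) || total_bp <= 0) {
    stop("total_bp must be a positive number", call. = FALSE)
  }
  if (nrow(divsum) == 0L) {
    return(structure(data.frame(family = character(), bin = integer(),
                                percent = numeric()),
                     class = c("landscape", "data.frame"),
                     total_bp = total_bp, min_abundance = min_abundance))
  }
  percent <- 100 * divsum$bp / total_bp
  fam_total <- tapply(percent, divsum$family, sum)
  keep_fams <- names(fam_total)[fam_total > min_abundance]
  out <- data.frame(family = divsum$family, bin = divsum$bin,
                    percent = percent, stringsAsFactors = FALSE)
  out <- out[out$family %in% keep_fams, , drop = FALSE]
  out <- out[order(out$family, out$bin), ]
  rownames(out) <- NULL
  structure(out, class = c("landscape", "data.frame"),
            total_bp = total_bp, min_abundance = min_abundance)
}

#' Landscape peak ages per family
#'
#' The age proxy of a family's amplification is the divergence bin holding
#' most of its genome fraction (the landscape mode; ties resolved to the
#' lowest bin). Families whose mode falls at or below `recent_max_bin` are
#' flagged as recently amplified ("recent burst").
#'
#' @param landscape A [build_landscape()] table.
#' @param recent_max_bin Highest divergence bin still considered recent (%).
#' @return Data frame: `family`, `mode_bin`, `mode_percent`, `is_recent`.
#' @export
peak_ages <- function(landscape, recent_max_bin = 5) {
  if (nrow(landscape) == 0L) {
    stop("landscape is empty", call. = FALSE)
  }
  res <- lapply(split(landscape, landscape$family), function(d) {
    best <- which(d$percent == max(d$percent))
    b <- d$bin[best]
    m <- min(b)  # tie -> lowest bin
    data.frame(family = d$family[1L], mode_bin = m,
               mode_percent = d$percent[d$bin == m][1L],
               is_recent = m <= recent_max_bin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect local modes of a family's landscape
#'
#' Returns all divergence bins that are local maxima of the (zero-filled)
#' per-bin profile and carry at least `min_fraction` of the family's total
#' landscape mass. Two such modes at well-separated divergences indicate
#' repeated amplification bursts of one family.
#'
#' @param landscape A [build_landscape()] table.
#' @param family Family name.
#' @param min_fraction Minimum fraction of the family's mass a mode must hold.
#' @return Integer vector of mode bins (ascending).
#' @export
landscape_modes <- function(landscape, family, min_fraction = 0.05) {
  d <- landscape[landscape$family == family, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("family '%s' not in landscape", family), call. = FALSE)
  bins <- 0:69
  y <- numeric(length(bins))
  y[d$bin + 1L] <- d$percent
  tot <- sum(y)
  up <- c(TRUE, diff(y) >= 0)
  down <- c(diff(y) <= 0, TRUE)
  is_mode <- up & down & y >= min_fraction * tot & y > 0
  # collapse plateaus to their first bin
  modes <- bins[is_mode]
  if (length(modes) > 1L) {
    keep <- c(TRUE, diff(modes) > 1L | y[modes[-length(modes)] + 1L] != y[modes[-1L] + 1L])
    modes <- modes[keep]
  }
  modes
}
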