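# Satellite family library: nomenclature, FASTA I/O, superfamily grouping.

#' Construct a satellite family library
#'
#' @param name Family names (e.g. `"MthSat01"`).
#' @param consensus Monomer consensus sequences (A/C/G/T).
#' @param confidence `"high"` or `"low"` per family; low-confidence families
#'   are kept and flagged, not dropped.
#' @return Data frame of class `sat_library` with columns `name`,
#'   `consensus`, `monomer_length`, `confidence`.
#' @export
sat_library <- function(name, consensus, confidence = "high") {
  consensus <- toupper(as.character(consensus))
  name <- as.character(name)
  if (length(name) != length(consensus)) {
    stop("name and consensus must have equal length", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop(sprintf("duplicate family name: %s",
                 paste(unique(name[duplicated(name)]), collapse = ", ")),
         call. = FALSE)
  }
  bad <- !is_acgt(consensus)
  if (any(bad)) {
    stop(sprintf("non-ACGT characters in consensus of: %s",
                 paste(name[bad], collapse = ", ")), call. = FALSE)
  }
  confidence <- rep_len(as.character(confidence), length(name))
  if (!all(confidence %in% c("high", "low"))) {
    stop("confidence must be 'high' or 'low'", call. = FALSE)
  }
  structure(data.frame(name = name, consensus = consensus,
                       monomer_length = nchar(consensus),
                       confidence = confidence, stringsAsFactors = FALSE),
            class = c("sat_library", "data.frame"))
}

#' @noRd
as_satlib_df <- function(x) {
  if (inherits(x, "sat_library")) return(x)
  if (inherits(x, "sat_sim")) {
    return(sat_library(x$truth$families$name, x$truth$families$consensus))
  }
  if (methods::is(x, "DNAStringSet")) {
    return(sat_library(names(x) %||% sprintf("Fam%02d", seq_along(x)),
                       as.character(x)))
  }
  if (is.data.frame(x) && all(c("name", "consensus") %in% names(x))) {
    return(sat_library(x$name, x$consensus,
                       x$confidence %||% "high"))
  }
  stop("cannot interpret `library`: expected sat_library, data frame with ",
       "name/consensus, DNAStringSet or sat_sim", call. = FALSE)
}

#' Read a satellite library from FASTA
#'
#' Headers are `>NAME`, optionally followed by ` confidence=low`. Duplicate
#' names and non-ACGT residues are rejected.
#'
#' @param path FASTA file.
#' @return A [sat_library()] data frame.
#' @export
read_satlib <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  name <- sub("\\s.*$", "", hdr)
  conf <- ifelse(grepl("confidence=low", hdr, fixed = TRUE), "low", "high")
  sat_library(name, as.character(x), conf)
}

#' Write a satellite library to FASTA
#'
#' @param lib A [sat_library()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_satlib <- function(lib, path) {
  lib <- as_satlib_df(lib)
  x <- Biostrings::DNAStringSet(lib$consensus)
  names(x) <- ifelse(lib$confidence == "low",
                     paste0(lib$name, " confidence=low"), lib$name)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Name satellite families by decreasing abundance
#'
#' Families are ranked by decreasing abundance (ties broken by longer
#' monomer, then input order) and named `<Spc>Sat01`, `<Spc>Sat02`, ...;
#' two digits up to 99, plain integers from 100 on (`<Spc>Sat100`).
#'
#' @param abundance Numeric vector of per-family abundances (>= 0).
#' @param monomer_length Monomer lengths (bp), used for tie-breaking.
#' @param species_code Three-letter species code, first letter capitalized
#'   (e.g. `"Mth"`).
#' @return Data frame with `name`, `rank`, `abundance`, `monomer_length`
#'   and `input_index`, ordered by rank.
#' @export
#' @examples
#' assign_names(c(0.03, 0.05), c(170, 300), "Mth")
assign_names <- function(abundance, monomer_length, species_code) {
  if (!grepl("^[A-Z][a-z]{2}$", species_code)) {
    stop("species_code must be 3 letters, capitalized (e.g. 'Mth')", call. = FALSE)
  }
  if (length(abundance) != length(monomer_length)) {
    stop("abundance and monomer_length must have equal length", call. = FALSE)
  }
  if (any(abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  n <- length(abundance)
  if (n == 0L) {
    return(data.frame(name = character(), rank = integer(),
                      abundance = numeric(), monomer_length = integer(),
                      input_index = integer()))
  }
  ord <- order(-abundance, -monomer_length, seq_len(n))
  num <- ifelse(seq_len(n) < 100, sprintf("%02d", seq_len(n)),
                as.character(seq_len(n)))
  data.frame(name = paste0(species_code, "Sat", num),
             rank = seq_len(n),
             abundance = abundance[ord],
             monomer_length = monomer_length[ord],
             input_index = ord, stringsAsFactors = FALSE)
}

#' Group satellite families into superfamilies by all-to-all homology
#'
#' For every family pair the best local alignment between the longer
#' consensus and the doubled shorter consensus (covering all circular
#' rotations) is computed on both strands. An edge is drawn when identity
#' (matches / alignment columns, gaps counted) is at least `min_identity`
#' over at least `min_coverage` of the shorter monomer; superfamilies are
#' the connected components. The partition is independent of input order
#' and invariant under rotation or reverse-complementation of any
#' consensus.
#'
#' @param lib A [sat_library()] (or coercible input).
#' @param min_identity Minimum alignment identity (fraction).
#' @param min_coverage Minimum aligned fraction of the shorter monomer.
#' @param scoring A [scoring_scheme()] providing the alignment parameters
#'   (filters are not applied).
#' @return List of class `superfamilies`: `membership` (data frame `family`,
#'   `superfamily`, ids contiguous 1..K in order of first appearance) and
#'   `edges` (data frame `family1`, `family2`, `identity`, `coverage`,
#'   `strand`).
#' @export
group_superfamilies <- function(lib, min_identity = 0.70, min_coverage = 0.50,
                                scoring = scoring_scheme()) {
  lib <- as_satlib_df(lib)
  n <- nrow(lib)
  if (n < 1L) stop("library must contain at least one family", call. = FALSE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        shorter <- if (lib$monomer_length[i] <= lib$monomer_length[j]) i else j
        longer <- if (shorter == i) j else i
        slen <- lib$monomer_length[shorter]
        doubled <- strrep(lib$consensus[shorter], 2L)
        best <- NULL
        for (strand in c("+", "-")) {
          subj <- if (strand == "+") doubled else revcomp_chr(doubled)
          a <- align_batch(Biostrings::DNAStringSet(lib$consensus[longer]),
                           subj, scoring)[1L, ]
          cols <- a$matches + a$mismatches + a$gap_columns
          ident <- if (cols > 0) a$matches / cols else 0
          cov <- min(a$target_end - a$target_start, slen) / slen
          if (is.null(best) || ident * cov > best$identity * best$coverage) {
            best <- list(identity = ident, coverage = cov, strand = strand)
          }
          if (ident >= min_identity && cov >= min_coverage) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
            edges[[length(edges) + 1L]] <- data.frame(
              family1 = lib$name[i], family2 = lib$name[j],
              identity = ident, coverage = cov, strand = strand,
              stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  ids <- match(root, unique(root))
  structure(list(
    membership = data.frame(family = lib$name, superfamily = ids,
                            stringsAsFactors = FALSE),
    edges = if (length(edges)) do.call(rbind, edges)
            else data.frame(family1 = character(), family2 = character(),
                            identity = numeric(), coverage = numeric(),
                            strand = character(), stringsAsFactors = FALSE)
  ), class = "superfamilies")
}
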