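# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a character vector of DNA sequences
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
is_acgt <- function(x) grepl("^[ACGT]+$", x)

#' Assert a scalar probability-like rate in [0, 1)
#' @noRd
check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1) {
    stop(sprintf("`%s` must be a single rate in [0, 1), got %s", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Coerce sequence input (character / DNAString / DNAStringSet of 1) to
#' a single uppercase character string
#' @noRd
as_seq_chr <- function(x, name = "sequence") {
  if (methods::is(x, "DNAString")) x <- as.character(x)
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) stop(sprintf("`%s` must be a single sequence", name), call. = FALSE)
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop(sprintf("`%s` must be a single non-empty sequence", name), call. = FALSE)
  }
  toupper(unname(x))
}

#' Coerce to a named DNAStringSet
#' @noRd
as_dss <- function(x, prefix = "seq") {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  if (!methods::is(x, "DNAStringSet")) {
    stop("expected a DNAStringSet or character vector of sequences", call. = FALSE)
  }
  if (is.null(names(x))) {
    names(x) <- sprintf("%s%0*d", prefix, max(3L, nchar(length(x))), seq_along(x))
  }
  x
}

#' Write a data.frame as TSV (no quoting, no row names)
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
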