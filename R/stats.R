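# Rank correlation and descriptive statistics for small cross-species
# comparisons (typically 8-9 species), where printed p-values are only
# meaningful under an explicit exact null.

#' Spearman rank correlation with exact small-n permutation p-value
#'
#' Rank correlation from average (mid) ranks. The two-sided p-value is
#' computed by full enumeration of all `n!` permutations whenever `n <= 9`
#' (and whenever ties are present at such n), counting permutations with
#' `|rho| >= |rho_observed|`; for larger n a t-approximation
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` df) is used.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @param method `"auto"` (exact for `n <= 9`), `"exact"` or
#'   `"approximate"`.
#' @return List of class `spearman_test`: `rho`, `p_value`, `n`, `method`
#'   (`"exact_permutation"` or `"t_approximation"`).
#' @export
#' @examples
#' spearman_test(1:5, c(2, 4, 5, 8, 9))  # rho = 1, p = 2/120
spearman_test <- function(x, y, method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: rho undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  exact <- switch(method, auto = n <= 9L, exact = TRUE, approximate = FALSE)
  if (exact && n > 9L) {
    stop("exact permutation p-value limited to n <= 9", call. = FALSE)
  }
  if (exact) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    # rho is a linear function of the permuted cross-product
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.numeric(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    meth <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    meth <- "t_approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = meth),
            class = "spearman_test")
}

#' @export
print.spearman_test <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

# All permutations of 1..n as an (n! x n) integer matrix.
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  p <- nrow(sub)
  out <- matrix(0L, n * p, n)
  for (i in seq_len(n)) {
    out[(i - 1L) * p + seq_len(p), ] <- cbind(i, sub + (sub >= i))
  }
  out
}

#' Pearson or Spearman correlation (convenience wrapper)
#'
#' @param x,y Numeric vectors.
#' @param method `"spearman"` (default, see [spearman_test()]) or
#'   `"pearson"` (delegates to [stats::cor.test()]).
#' @return A `spearman_test`-shaped list (`rho` holds r for Pearson).
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (method == "spearman") return(spearman_test(x, y))
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = "pearson"),
            class = "spearman_test")
}

#' Descriptive summary of a numeric vector
#'
#' @param values Numeric vector, length >= 1 (NAs dropped).
#' @return List: `n`, `min`, `max`, `mean`, `median` (midpoint average for
#'   even n).
#' @export
#' @examples
#' describe_values(c(1, 2, 3, 4))$median  # 2.5
describe_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  list(n = length(values), min = min(values), max = max(values),
       mean = mean(values), median = median(values))
}

#' Published satellitome survey summary for nine katydid species
#'
#' Literature-reported per-species summary values for eight Tettigoniidae
#' species and a gryllacridid outgroup: satellite DNA family counts,
#' repeatome percent of genome, and satellitome percent of genome. The
#' satellitome percent of *E. pallidus* was not reported and is `NA`.
#'
#' @return Data frame: `species`, `group` (`"tettigoniidae"` /
#'   `"outgroup"`), `n_sat_families`, `repeatome_percent`,
#'   `satellite_percent`.
#' @export
tettigoniidae_summary <- function() {
  path <- system.file("extdata", "tettigoniidae_summary.tsv",
                      package = "satdyn", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
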