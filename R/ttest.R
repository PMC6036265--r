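#' One-sided one-sample t-test from paired differences
#'
#' Computes the t statistic for the directional hypothesis that the mean of
#' the paired differences (real minus sham) is greater than zero:
#' `t = mean(x) / (sd(x) / sqrt(n))` with the usual n-1-denominator sample
#' standard deviation, and the upper-tail p-value of the central t
#' distribution with n-1 degrees of freedom.
#'
#' @param differences numeric vector of paired differences, length >= 2.
#' @return an object of class `t_test_summary` with fields `n`, `t`, `df`,
#'   `p_one_sided`.
#' @examples
#' t_statistic(c(-1, 1)) # t = 0, p = 0.5
#' t_statistic(c(1, 2, 3)) # t = 2*sqrt(3)
#' @export
t_statistic <- function(differences) {
  if (!is.numeric(differences) || length(differences) < 2L) {
    .stop_invalid("`differences` must be a numeric vector with at least 2 values")
  }
  if (anyNA(differences) || any(!is.finite(differences))) {
    .stop_invalid("`differences` must be finite and non-missing")
  }
  n <- length(differences)
  s <- sd(differences)
  if (s <= 0) {
    .stop_degenerate(
      "sample standard deviation is zero: the t statistic is undefined")
  }
  tval <- mean(differences) / (s / sqrt(n))
  structure(
    list(n = n, t = tval, df = n - 1L,
         p_one_sided = one_sided_p(tval, n - 1L)),
    class = "t_test_summary")
}

#' @export
print.t_test_summary <- function(x, ...) {
  cat(sprintf("One-sided one-sample t-test: t(%d) = %.4f, p = %.4f (n = %d)\n",
              x$df, x$t, x$p_one_sided, x$n))
  invisible(x)
}

#' Upper-tail p-value of the central t distribution
#'
#' @param t numeric vector of t statistics.
#' @param df degrees of freedom (single number >= 1).
#' @return `P(T_df > t)`, strictly decreasing in `t`.
#' @examples
#' one_sided_p(0, 9) # 0.5
#' @export
one_sided_p <- function(t, df) {
  if (length(df) != 1L || !is.numeric(df) || !is.finite(df) || df < 1) {
    .stop_invalid("`df` must be a single number >= 1")
  }
  if (!is.numeric(t)) {
    .stop_invalid("`t` must be numeric")
  }
  pt(t, df, lower.tail = FALSE)
}

#' Read paired differences from a text file
#'
#' Accepts a single-column CSV or whitespace-delimited file of paired
#' (real minus sham) differences.  A single non-numeric first row is
#' treated as a header; any other non-numeric row is an error that names
#' the offending line.
#'
#' @param path path to the file.
#' @return numeric vector of differences.
#' @examples
#' # synthetic example data shipped with the package
#' path <- system.file("extdata", "synthetic_differences.csv",
#'                     package = "bfcrit")
#' bf_test(read_differences(path))
#' @export
read_differences <- function(path) {
  if (!file.exists(path)) {
    .stop_invalid(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    .stop_invalid(sprintf("no data in %s", path))
  }
  tokens <- trimws(sub("[,;].*$", "", trimws(lines[keep])))
  vals <- suppressWarnings(as.numeric(tokens))
  if (is.na(vals[1L])) { # header row
    tokens <- tokens[-1L]
    vals <- vals[-1L]
    keep <- keep[-1L]
  }
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    .stop_invalid(sprintf("non-numeric value %s on line %d of %s",
                          shQuote(tokens[bad[1L]]), keep[bad[1L]], path))
  }
  vals
}
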