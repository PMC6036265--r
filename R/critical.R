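# The deterministic p -> BF10 curve and its critical crossings.
#
# Given the sample size and the prior, the Bayes factor is a function of
# the t statistic alone, hence of the one-sided p-value alone.  The
# critical p-value -- beyond which a non-significant result yields at
# least moderate evidence for the null (BF10 below the cutoff) -- is the
# root of BF10(t) = cutoff on that curve, found noise-free by bracketed
# root finding rather than read off simulated scatter.

#' Bayes factor implied by a one-sided p-value
#'
#' Inverts `p` to the t statistic through the central-t quantile at
#' `df = n - 1`, then evaluates [jzs_bf10()].  For the one-sided prior the
#' result is strictly decreasing in `p`.
#'
#' @param p one-sided p-value(s), strictly inside (0, 1).
#' @param n sample size (integer >= 2).
#' @param prior a [prior_spec()].
#' @return numeric vector of BF10 values.
#' @examples
#' bf_given_p(0.05, 20)
#' bf_given_p(0.5, 20) # equals jzs_bf10(0, 20)
#' @export
bf_given_p <- function(p, n, prior = prior_spec()) {
  n <- .check_count(n, "n", min = 2L)
  if (!is.numeric(p) || length(p) == 0L ||
      any(!is.finite(p) | p <= 0 | p >= 1)) {
    .stop_invalid("`p` must lie strictly inside (0, 1)")
  }
  tvals <- qt(p, df = n - 1, lower.tail = FALSE)
  vapply(tvals, jzs_bf10, numeric(1L), n = n, prior = prior)
}

#' Critical p-value where the Bayes factor crosses a cutoff
#'
#' Finds the t statistic at which BF10 equals `cutoff` for the given
#' sample size and prior, by bracketed root finding on `t` in
#' `bracket`, and returns it with the corresponding one-sided p-value.
#' With the default cutoff 1/3, p-values above `critical_p` correspond to
#' at least moderate evidence for H0; smaller non-significant p-values are
#' merely inconclusive.
#'
#' @param n sample size (integer >= 2).
#' @param prior a [prior_spec()].
#' @param cutoff positive BF10 threshold to cross (default 1/3).
#' @param bracket length-2 search interval for the t statistic.
#' @return an object of class `critical_point`: a list with `n`, `cutoff`,
#'   `critical_t`, `critical_p`.
#' @examples
#' critical_p(10) # about 0.46
#' critical_p(80) # about 0.16
#' @export
critical_p <- function(n, prior = prior_spec(), cutoff = 1 / 3,
                       bracket = c(-10, 10)) {
  n <- .check_count(n, "n", min = 2L)
  .check_prior(prior)
  if (length(cutoff) != 1L || !is.numeric(cutoff) || !is.finite(cutoff) ||
      cutoff <= 0) {
    .stop_invalid("`cutoff` must be a single positive number")
  }
  if (length(bracket) != 2L || !all(is.finite(bracket)) ||
      bracket[1L] >= bracket[2L]) {
    .stop_invalid("`bracket` must be an increasing pair of finite numbers")
  }
  f <- function(t) log(jzs_bf10(t, n, prior)) - log(cutoff)
  flo <- f(bracket[1L])
  fhi <- f(bracket[2L])
  if (sign(flo) == sign(fhi)) {
    .stop_unattainable(sprintf(
      "BF10 does not cross %.4g for n = %d on t in [%g, %g]",
      cutoff, n, bracket[1L], bracket[2L]))
  }
  root <- uniroot(f, bracket, f.lower = flo, f.upper = fhi,
                  tol = 1e-12)$root
  structure(
    list(n = n, cutoff = cutoff, critical_t = root,
         critical_p = one_sided_p(root, n - 1)),
    class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf(
    "Critical point (n = %d): BF10 = %.4g at t = %.4f, one-sided p = %.4f\n",
    x$n, x$cutoff, x$critical_t, x$critical_p))
  invisible(x)
}

#' Critical p-value table over a range of sample sizes
#'
#' One [critical_p()] row per sample size.  For the default cutoff 1/3 the
#' critical p-value decreases strictly as the sample size grows: small
#' samples need much larger p-values before the data favor the null.  The
#' table depends only on the sample sizes and the prior, never on the true
#' population effect size.  A sample size for which the cutoff is not
#' attainable inside the bracket yields an `NA` row and a warning instead
#' of aborting the table.
#'
#' @param n_grid integer vector of sample sizes.
#' @inheritParams critical_p
#' @return data frame with columns `n`, `cutoff`, `critical_t`,
#'   `critical_p`.
#' @examples
#' critical_p_table(seq(10, 80, by = 10))
#' @export
critical_p_table <- function(n_grid = seq(10L, 80L, by = 10L),
                             prior = prior_spec(), cutoff = 1 / 3,
                             bracket = c(-10, 10)) {
  if (length(n_grid) == 0L) {
    .stop_invalid("`n_grid` must be non-empty")
  }
  rows <- lapply(n_grid, function(n) {
    cp <- tryCatch(critical_p(n, prior, cutoff, bracket),
                   bfcrit_unattainable = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(cp)) {
      data.frame(n = as.integer(n), cutoff = cutoff,
                 critical_t = NA_real_, critical_p = NA_real_)
    } else {
      data.frame(n = cp$n, cutoff = cp$cutoff, critical_t = cp$critical_t,
                 critical_p = cp$critical_p)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
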