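# Default Bayes factor for the one-sample t-test.
#
# BF10 = m1 / m0 where m0 is the central-t density of the observed t and
# m1 marginalizes the noncentral-t density over the Cauchy effect-size
# prior (truncated and doubled on dz >= 0 for the directional hypothesis):
#
#   m1 = int f_nct(t; df = n-1, ncp = dz * sqrt(n)) pi(dz) d dz.
#
# We integrate the density *ratio* exp(log f_nct - log f_t), so the result
# stays well scaled even where both densities underflow, and substitute
# dz = scale * tan(u), under which the Cauchy prior measure becomes the
# uniform measure du/pi on (-pi/2, pi/2) -- the integrand is then a smooth
# bounded function on a finite interval, handled by adaptive quadrature.

.bf10_one <- function(t, n, prior, rel_tol = 1e-8, abs_tol = 1e-10) {
  df <- n - 1
  l0 <- dt(t, df, log = TRUE)
  one_sided <- prior$side == "positive_one_sided"
  mult <- if (one_sided) 2 else 1
  scale <- prior$scale
  g <- function(u) {
    dz <- scale * tan(u)
    exp(dnct_log(t, df, dz * sqrt(n)) - l0) * (mult / pi)
  }
  lo <- if (one_sided) 0 else -pi / 2
  # split at the prior value matching the observed effect, where the
  # integrand peaks, so the adaptive scheme converges quickly
  brk <- c(lo, pi / 2)
  tpk <- abs(t) / (sqrt(n) * scale)
  upk <- atan(tpk)
  if (one_sided) {
    if (t > 0) brk <- c(0, upk, pi / 2)
  } else {
    brk <- sort(unique(c(-pi / 2, -upk, upk, pi / 2)))
  }
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    piece <- tryCatch(
      integrate(g, brk[i], brk[i + 1L], rel.tol = rel_tol,
                abs.tol = abs_tol, subdivisions = 500L),
      error = function(e) .stop_invalid(sprintf(
        "Bayes-factor quadrature failed on (%.4f, %.4f) for t = %g, n = %d: %s",
        brk[i], brk[i + 1L], t, n, conditionMessage(e))))
    total <- total + piece$value
  }
  max(total, 1e-300)
}

#' Default (JZS) Bayes factor for the one-sample t-test
#'
#' Computes BF10, the marginal likelihood of the data under H1 (Cauchy
#' prior on the standardized effect size) relative to H0 (point null at
#' zero), from the t statistic and the sample size.  With the default
#' one-sided prior, BF10 is strictly increasing in `t` for fixed `n`.
#'
#' `|t| > 50` is far beyond the regime in which the central-t marginal is
#' representable; such values are clamped to +/-50 with a warning and the
#' Bayes factor of the clamped statistic returned.
#'
#' @param t observed t statistic (single finite number).
#' @param n sample size (single integer >= 2); degrees of freedom `n - 1`.
#' @param prior a [prior_spec()].
#' @param rel_tol,abs_tol quadrature tolerances for the marginal integral.
#' @return BF10, a single positive number.
#' @examples
#' jzs_bf10(2.5, 20)
#' jzs_bf10(0.5, 20, prior_spec(side = "two_sided"))
#' @export
jzs_bf10 <- function(t, n, prior = prior_spec(), rel_tol = 1e-8,
                     abs_tol = 1e-10) {
  if (length(t) != 1L || !is.numeric(t) || !is.finite(t)) {
    .stop_invalid("`t` must be a single finite number")
  }
  n <- .check_count(n, "n", min = 2L)
  .check_prior(prior)
  if (abs(t) > 50) {
    warning(sprintf(
      "|t| = %.3g exceeds 50; returning the Bayes factor at t = %s50 (asymptotic regime)",
      abs(t), if (t > 0) "+" else "-"), call. = FALSE)
    t <- sign(t) * 50
  }
  .bf10_one(t, n, prior, rel_tol = rel_tol, abs_tol = abs_tol)
}

#' Categorize a Bayes factor against evidence thresholds
#'
#' @param bf10 positive numeric vector of Bayes factors BF10.
#' @param thresholds an [evidence_thresholds()].
#' @return character vector with values `"supports_H1"` (BF10 > upper),
#'   `"supports_H0"` (BF10 < lower) or `"inconclusive"`.
#' @examples
#' classify_evidence(c(4, 1, 0.2))
#' @export
classify_evidence <- function(bf10, thresholds = evidence_thresholds()) {
  .check_thresholds(thresholds)
  if (!is.numeric(bf10) || length(bf10) == 0L ||
      any(!is.finite(bf10) | bf10 <= 0)) {
    .stop_invalid("`bf10` must be positive and finite")
  }
  out <- rep("inconclusive", length(bf10))
  out[bf10 > thresholds$upper] <- "supports_H1"
  out[bf10 < thresholds$lower] <- "supports_H0"
  out
}

#' t-test and Bayes factor for one set of paired differences
#'
#' End-to-end analysis of a single experiment: one-sided one-sample
#' t-test, default Bayes factor, and evidence category.
#'
#' @param differences numeric vector of paired (real minus sham)
#'   differences, length >= 2.
#' @inheritParams jzs_bf10
#' @param thresholds an [evidence_thresholds()].
#' @return an object of class `bf_test`: a list with `n`, `t`, `df`,
#'   `p_one_sided`, `bf10`, `category`, `significant`.
#' @examples
#' set.seed(7)
#' bf_test(rnorm(12, mean = 0.2))
#' @export
bf_test <- function(differences, prior = prior_spec(),
                    thresholds = evidence_thresholds()) {
  ts <- t_statistic(differences)
  bf <- jzs_bf10(ts$t, ts$n, prior)
  structure(
    list(n = ts$n, t = ts$t, df = ts$df, p_one_sided = ts$p_one_sided,
         bf10 = bf, category = classify_evidence(bf, thresholds),
         significant = ts$p_one_sided < thresholds$alpha,
         prior = prior, thresholds = thresholds),
    class = "bf_test")
}

#' @export
print.bf_test <- function(x, ...) {
  cat(sprintf("One-sided one-sample t-test with default Bayes factor (n = %d)\n",
              x$n))
  cat(sprintf("  t(%d) = %.4f, p = %.4f (%ssignificant at alpha = %g)\n",
              x$df, x$t, x$p_one_sided,
              if (x$significant) "" else "not ", x$thresholds$alpha))
  cat(sprintf("  BF10 = %.4g  [Cauchy scale %.4g, %s]\n", x$bf10,
              x$prior$scale,
              if (x$prior$side == "positive_one_sided") "one-sided" else "two-sided"))
  cat(sprintf("  evidence: %s\n", x$category))
  invisible(x)
}

#' @export
as.data.frame.bf_test <- function(x, ...) {
  data.frame(n = x$n, t = x$t, df = x$df, p = x$p_one_sided, bf10 = x$bf10,
             category = x$category, significant = x$significant,
             stringsAsFactors = FALSE)
}
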