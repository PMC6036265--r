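# Monte-Carlo oracle for the H1 marginal likelihood.
#
# Deliberately simple and fully independent of the quadrature path in
# jzs_bf10(): it draws effect sizes from the (possibly truncated) Cauchy
# prior by inverse-CDF sampling and averages stats::dt(..., ncp = ) --
# plain prior sampling, no importance weighting, no shared density code.
# Its only consumer is the test suite, where the quadrature marginal must
# agree with the estimate within a few Monte-Carlo standard errors.

#' Monte-Carlo estimate of the H1 marginal likelihood
#'
#' Estimates `m1 = E_pi[f_nct(t; n - 1, dz * sqrt(n))]`, the average of the
#' noncentral-t density of the observed statistic over the Cauchy
#' effect-size prior, by plain prior sampling.  The quadrature equivalent
#' is `jzs_bf10(t, n, prior) * dt(t, n - 1)`.
#'
#' `stats::dt(..., ncp = )` is only reliable where the density is not
#' vanishingly small, so the oracle is meant for moderate `t`; that is the
#' regime the validation tests probe.
#'
#' @param t observed t statistic.
#' @param n sample size (integer >= 2).
#' @param prior a [prior_spec()].
#' @param draws number of prior draws (>= 1000).
#' @param seed RNG seed; the estimate is deterministic given it.
#' @return an object of class `mc_estimate`: `estimate`,
#'   `standard_error`, `draws`, `seed`.
#' @examples
#' mc_alt_marginal(1.5, 20, draws = 10000, seed = 1)
#' @export
mc_alt_marginal <- function(t, n, prior = prior_spec(), draws = 1e6,
                            seed = 1L) {
  if (length(t) != 1L || !is.numeric(t) || !is.finite(t)) {
    .stop_invalid("`t` must be a single finite number")
  }
  n <- .check_count(n, "n", min = 2L)
  .check_prior(prior)
  draws <- .check_count(draws, "draws", min = 1000L)
  seed <- .check_count(seed, "seed", min = 0L)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- runif(draws)
  dz <- if (prior$side == "positive_one_sided") {
    prior$scale * tan(pi * u / 2) # inverse CDF of the half-Cauchy
  } else {
    prior$scale * tan(pi * (u - 0.5))
  }
  vals <- suppressWarnings(dt(t, df = n - 1, ncp = dz * sqrt(n)))
  est <- mean(vals)
  se <- sd(vals) / sqrt(draws)
  structure(list(estimate = est, standard_error = se,
                 draws = as.integer(draws), seed = seed),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("MC marginal-likelihood estimate: %.6g (SE %.2g, %d draws)\n",
              x$estimate, x$standard_error, x$draws))
  invisible(x)
}
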