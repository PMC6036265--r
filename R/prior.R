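#' Cauchy effect-size prior for the alternative hypothesis
#'
#' Specifies the H1 model of the default (Jeffreys-Zellner-Siow) Bayes
#' factor: a Cauchy distribution on the standardized effect size (Cohen's
#' dz).  The default scale is the software-default `sqrt(2)/2` (about
#' 0.707, commonly reported rounded as 0.7).  With
#' `side = "positive_one_sided"` the prior is truncated to dz >= 0 and
#' renormalized (a doubled half-Cauchy), encoding the directional
#' hypothesis dz > 0; `side = "two_sided"` keeps the symmetric prior.
#'
#' @param scale positive Cauchy scale in Cohen's dz units.
#' @param side `"positive_one_sided"` (default) or `"two_sided"`.
#' @return an object of class `bf_prior`.
#' @examples
#' prior_spec()
#' prior_spec(scale = 1, side = "two_sided")
#' @export
prior_spec <- function(scale = sqrt(2) / 2,
                       side = c("positive_one_sided", "two_sided")) {
  if (length(scale) != 1L || !is.numeric(scale) || !is.finite(scale) ||
      scale <= 0) {
    .stop_invalid("`scale` must be a single positive number")
  }
  side <- match.arg(side)
  structure(list(scale = as.numeric(scale), side = side),
            class = "bf_prior")
}

#' @export
print.bf_prior <- function(x, ...) {
  cat(sprintf("Cauchy effect-size prior: scale = %.5f, %s\n", x$scale,
              if (x$side == "positive_one_sided") {
                "truncated to dz >= 0 (half-Cauchy)"
              } else {
                "two-sided (symmetric)"
              }))
  invisible(x)
}

.check_prior <- function(prior) {
  if (!inherits(prior, "bf_prior")) {
    .stop_invalid("`prior` must be created with prior_spec()")
  }
  prior
}

#' Evidence thresholds and significance level
#'
#' Conventional cutoffs for categorizing a Bayes factor: BF10 above `upper`
#' counts as noteworthy evidence for H1, below `lower` as noteworthy
#' evidence for H0, anything between as inconclusive (anecdotal).  The
#' defaults are the Jeffreys convention 3 and 1/3 (1/3, not the rounded
#' 0.33, so that the reciprocal symmetry BF01 = 1/BF10 maps the two cutoffs
#' onto each other exactly).  `alpha` is the significance level used to
#' flag conventional t-test decisions.
#'
#' @param upper BF10 cutoff for evidence supporting H1 (> 1).
#' @param lower BF10 cutoff for evidence supporting H0 (in (0, 1)).
#' @param alpha one-sided significance level in (0, 1).
#' @return an object of class `bf_thresholds`.
#' @examples
#' evidence_thresholds()
#' evidence_thresholds(upper = 10, lower = 1 / 10)
#' @export
evidence_thresholds <- function(upper = 3, lower = 1 / 3, alpha = 0.05) {
  for (nm in c("upper", "lower", "alpha")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v <= 0) {
      .stop_invalid(sprintf("`%s` must be a single positive number", nm))
    }
  }
  if (!(lower < 1 && 1 < upper)) {
    .stop_invalid("need 0 < lower < 1 < upper")
  }
  if (alpha >= 1) {
    .stop_invalid("`alpha` must lie in (0, 1)")
  }
  structure(list(upper = as.numeric(upper), lower = as.numeric(lower),
                 alpha = as.numeric(alpha)),
            class = "bf_thresholds")
}

#' @export
print.bf_thresholds <- function(x, ...) {
  cat(sprintf(
    "Evidence thresholds: BF10 > %g supports H1, BF10 < %g supports H0; alpha = %g\n",
    x$upper, x$lower, x$alpha))
  invisible(x)
}

.check_thresholds <- function(thresholds) {
  if (!inherits(thresholds, "bf_thresholds")) {
    .stop_invalid("`thresholds` must be created with evidence_thresholds()")
  }
  thresholds
}
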