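---
title: "Critical p-values: when does a non-significant result support the null?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical p-values: when does a non-significant result support the null?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfcrit)
```

## The problem

Sham-controlled within-subject stimulation experiments often end in a
non-significant t-test, and the temptation is to read that as "the
protocol has no effect". Significance testing cannot license that
reading: a non-significant p-value is compatible both with a true null
and with data too weak to decide. A Bayes factor makes the distinction.
`bfcrit` implements the default Bayes factor for this design, simulates
the design at scale, and computes the *critical p-value* — the point on
the p-axis beyond which the Bayes factor actually favors the null.

## Model and Bayes factor

Each participant contributes one real-minus-sham performance difference,
modelled as normal with standardized mean `dz` and unit standard
deviation (so `dz` is Cohen's dz for the one-sample design). The null
hypothesis is the point `dz = 0`; the alternative places a Cauchy prior
with scale `r` on `dz`, truncated to `dz >= 0` and renormalized — a
doubled half-Cauchy — because the research hypothesis is directional
(real stimulation improves performance). The default scale is
`sqrt(2)/2`, the common software default, often quoted rounded as 0.7;
`prior_spec()` exposes both the scale and the sidedness
(`"two_sided"` keeps the symmetric prior).

Since the t statistic is sufficient, both marginal likelihoods are
densities of `t`: the central t under H0, and the noncentral t with
noncentrality `dz * sqrt(N)` averaged over the prior under H1:

$$
\mathrm{BF}_{10}(t, N)
 = \frac{\int f_{\mathrm{nct}}(t;\, N-1,\, \delta\sqrt{N})\,\pi(\delta)\,d\delta}
        {f_t(t;\, N-1)} .
$$

The truncated-prior construction used here is mathematically equivalent
to restricting the posterior of a symmetric analysis to the positive
half-line, but needs only a single quadrature. Evidence is categorized
by the Jeffreys-style convention: `BF10 > 3` noteworthy for H1,
`BF10 < 1/3` noteworthy for H0, in between inconclusive. The lower
threshold is exactly `1/3` — not the rounded 0.33 — so that the
reciprocal symmetry `BF01 = 1/BF10` maps the two thresholds onto each
other.

## Numerical choices

**Stable noncentral-t density.** `stats::dt(x, df, ncp)` computes the
noncentral density as a difference of distribution functions and is
accurate only to an *absolute* error; once the density falls below about
1e-12 its relative error is total. The Bayes-factor integrand lives
partly in that regime (large `|t|`, noncentralities far from `t`).
`dnct_log()` therefore evaluates the chi-mixture representation
$f(t) = \int_0^\infty w\,\phi(tw-\delta)\,f_W(w)\,dw$ (with
$W = \sqrt{\chi^2_{df}/df}$) by Gauss–Legendre quadrature centred on the
integrand's mode, in log space. The integrand is log-concave in `w`, so
a mode ± 20-standard-deviation window captures it to machine precision;
the package's tests pin `dnct_log()` against `stats::dt` everywhere the
latter is reliable and check symmetry and tail monotonicity beyond that.

**Quadrature.** The marginal ratio is integrated over the prior with the
substitution `dz = r tan(u)`, under which the Cauchy measure becomes the
uniform measure `du/pi` on a finite interval; `stats::integrate` then
works on a smooth bounded integrand (absolute tolerance 1e-10, relative
1e-8), split at the prior value matching the observed effect where the
integrand peaks. Integrating the density *ratio* rather than the two
marginals separately keeps everything well scaled: the Bayes factor is
computable for any `t` in the root-finding bracket. `|t| > 50` is
clamped (with a warning) to ±50 — far beyond any regime of practical
relevance — rather than risking underflow of the null marginal.

**Root finding.** `critical_p()` solves `BF10(t) = cutoff` by bracketed
root finding (`uniroot` on the log scale) over `t in [-10, 10]`, then
maps the root through the central-t upper tail. If the Bayes factor
never crosses the cutoff inside the bracket — possible for extreme
cutoffs — a classed error is raised, and `critical_p_table()` converts
it into an `NA` row with a warning instead of aborting. Critical values
are never rounded in computation; the command-line table rounds to two
decimals for display only.

**Validation oracle.** `mc_alt_marginal()` estimates the H1 marginal by
plain prior sampling: inverse-CDF draws from the (half-)Cauchy prior,
averaging `stats::dt(..., ncp = )`. It deliberately shares no code with
the quadrature path and is only trustworthy at moderate `t`, which is
where the tests compare the two (agreement within three Monte-Carlo
standard errors).

## What the simulator emulates — and what it does not

`simulate_sample(n, dz)` draws the per-participant difference scores
directly from `Normal(dz, 1)`: the sham-vs-real contrast is simulated as
one difference per participant, not as two correlated condition scores.
That matches the one-sample analysis exactly, but it means the simulator
says nothing about unequal variances, non-normal performance
distributions, carry-over effects between conditions, or between-subject
designs — passing tests demonstrate the statistical machinery, not the
robustness of real experiments to those violations.

The default study conditions are a full factorial of
`N in {10, ..., 80}` (step 10) by `dz in {0, 0.1, ..., 0.5}` with 1000
replicates per cell. Replicates are reproducible individually: each
(master seed, n, dz, replicate) tuple is hashed — a chained
multiplicative-congruential step, exact in doubles — to its own RNG
seed, so any cell can be redrawn without rerunning the grid, and the
whole grid is bitwise reproducible. Cells draw independently; nothing is
shared across the grid. A zero-variance sample, a probability-zero event
under a continuous distribution, is flagged in the `degenerate` column
rather than aborting a long run.

## What the analysis shows

```{r curves}
critical_p_table(seq(10, 80, by = 10))
```

The critical p-value where `BF10` drops below 1/3 *decreases* as the
sample size grows: with 10 participants, non-significant p-values all
the way to ≈ 0.46 are merely inconclusive, while with 80 participants
the data favor the null from p ≈ 0.16 upward. The curve is a function of
the sample size and the prior alone — the true effect size moves points
*along* the curve (more or fewer significant replicates) but never moves
the curve itself, which is why the table takes no `dz` argument.

```{r grid, fig.width = 8, fig.height = 5}
grid <- run_grid(n_grid = c(10, 40, 80), dz_grid = c(0.2, 0.5),
                 reps = 150, seed = 1)
plot_p_vs_bf(grid)
```

Every simulated point lies exactly on its per-N curve; with increasing
`N` and `dz` more replicates land in the significant/supports-H1 corner,
and with small `N` a large share of non-significant replicates sits in
the inconclusive band. The replicate counts in this vignette (150 per
cell here, 200 in the heavier test-suite grid) keep the document and the
tests quick; the pipeline default of 1000 replicates per cell reproduces
the full study and takes a few minutes on one core.

The frequentist calibration of the simulator is itself checked in the
tests: under `dz = 0` the one-sided rejection rate at `alpha = 0.05`
is 0.05 within binomial error and the p-values are uniform; under
`dz = 0.5, N = 80` the rejection rate matches the closed-form
noncentral-t power (≈ 0.997).

## Known limitations

* The Bayes factor covers the one-sample (paired-difference), one-sided
  or two-sided default-Cauchy setting only — no two-sample, regression
  or ANOVA designs, and no informed (non-Cauchy) priors.
* `stats::dt`'s noncentral branch limits the Monte-Carlo *oracle* (not
  the quadrature) to moderate `t`.
* The critical p-value is a property of the default prior; with a
  different scale the table shifts, which is why the scale is recorded
  in every run log.
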