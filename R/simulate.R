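# Simulator of sham-controlled within-subject experiments.
#
# Each fictional experiment draws one real-minus-sham performance
# difference per participant from Normal(dz, 1), so dz is directly the
# population effect in Cohen's dz units.  Replicates are reproducible
# individually: every (master seed, n, dz, replicate) tuple is hashed to
# its own RNG seed, so a single cell or a single replicate can be redrawn
# without rerunning the grid.

# Park-Miller multiplicative step on [1, 2^31 - 2]; exact in doubles
.pm_step <- function(x) {
  x <- x %% 2147483647
  if (x <= 0) x <- x + 2147483646
  (16807 * x) %% 2147483647
}

.sub_seed <- function(master, n, dz, rep) {
  h <- .pm_step(master + 1)
  h <- .pm_step(h + n)
  h <- .pm_step(h + round(dz * 1e4) + 20001) # keep negative dz distinct
  h <- .pm_step(h + rep)
  as.integer(h)
}

#' Simulate one sham-controlled experiment
#'
#' Draws `n` per-participant performance differences (real minus sham)
#' from a normal distribution with mean `dz` and standard deviation 1.
#'
#' @param n number of participants (integer >= 2).
#' @param dz true population effect size in Cohen's dz units.
#' @param seed optional integer; when given, the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @return numeric vector of `n` differences.
#' @examples
#' simulate_sample(10, 0.3, seed = 1)
#' @export
simulate_sample <- function(n, dz, seed = NULL) {
  n <- .check_count(n, "n", min = 2L)
  if (length(dz) != 1L || !is.numeric(dz) || !is.finite(dz)) {
    .stop_invalid("`dz` must be a single finite number")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  rnorm(n, mean = dz, sd = 1)
}

#' Run replicated experiments for one (n, dz) condition
#'
#' Repeats the fictional experiment `reps` times; each replicate is tested
#' with the one-sided one-sample t-test and the default Bayes factor.  A
#' zero-variance sample (probability zero under a continuous distribution)
#' is flagged in the `degenerate` column rather than aborting the run.
#'
#' @param n participants per experiment (integer >= 2).
#' @param dz true population effect size.
#' @param reps number of replicates (default 1000).
#' @param seed master RNG seed (integer).
#' @param prior a [prior_spec()].
#' @param thresholds an [evidence_thresholds()].
#' @return data frame with one row per replicate: `n`, `dz`, `rep`, `t`,
#'   `p`, `bf10`, `category`, `significant`, `degenerate`.
#' @examples
#' run_replicates(10, 0, reps = 5, seed = 1)
#' @export
run_replicates <- function(n, dz, reps = 1000L, seed = 1L,
                           prior = prior_spec(),
                           thresholds = evidence_thresholds()) {
  n <- .check_count(n, "n", min = 2L)
  reps <- .check_count(reps, "reps", min = 1L)
  seed <- .check_count(seed, "seed", min = 0L)
  .check_prior(prior)
  .check_thresholds(thresholds)

  t_out <- p_out <- bf_out <- rep(NA_real_, reps)
  cat_out <- rep(NA_character_, reps)
  degen <- logical(reps)
  for (r in seq_len(reps)) {
    x <- simulate_sample(n, dz, seed = .sub_seed(seed, n, dz, r))
    ts <- tryCatch(t_statistic(x), bfcrit_degenerate = function(e) NULL)
    if (is.null(ts)) {
      degen[r] <- TRUE
      next
    }
    t_out[r] <- ts$t
    p_out[r] <- ts$p_one_sided
    bf_out[r] <- jzs_bf10(ts$t, n, prior)
    cat_out[r] <- classify_evidence(bf_out[r], thresholds)
  }
  data.frame(n = n, dz = dz, rep = seq_len(reps), t = t_out, p = p_out,
             bf10 = bf_out, category = cat_out,
             significant = !is.na(p_out) & p_out < thresholds$alpha,
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Run the replicated simulation over a (sample size, effect size) grid
#'
#' Full factorial over `n_grid` x `dz_grid` with `reps` replicates per
#' cell; the defaults reproduce the 8 x 6 x 1000 design (N from 10 to 80,
#' dz from 0 to 0.5).  Per-replicate seeds are derived deterministically
#' from the master seed, so the whole grid is bitwise reproducible.
#'
#' @param n_grid integer vector of sample sizes.
#' @param dz_grid numeric vector of population effect sizes.
#' @param reps replicates per cell (default 1000).
#' @param seed master RNG seed.
#' @inheritParams run_replicates
#' @return a `bf_grid` data frame: one row per (n, dz, replicate) with the
#'   columns of [run_replicates()].
#' @examples
#' g <- run_grid(n_grid = c(10, 20), dz_grid = c(0, 0.5), reps = 3, seed = 1)
#' nrow(g) # 2 * 2 * 3
#' @export
run_grid <- function(n_grid = seq(10L, 80L, by = 10L),
                     dz_grid = seq(0, 0.5, by = 0.1),
                     reps = 1000L, seed = 1L, prior = prior_spec(),
                     thresholds = evidence_thresholds()) {
  if (length(n_grid) == 0L || length(dz_grid) == 0L) {
    .stop_invalid("`n_grid` and `dz_grid` must be non-empty")
  }
  cells <- expand.grid(dz = dz_grid, n = n_grid,
                       KEEP.OUT.ATTRS = FALSE)[, c("n", "dz")]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    out[[i]] <- run_replicates(cells$n[i], cells$dz[i], reps = reps,
                               seed = seed, prior = prior,
                               thresholds = thresholds)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  attr(res, "thresholds") <- thresholds
  attr(res, "seed") <- seed
  class(res) <- c("bf_grid", "data.frame")
  res
}

#' Per-cell summary of a simulation grid
#'
#' For every (n, dz) cell, the fraction of significant t-tests and the
#' fraction of replicates in each evidence category (computed over the
#' non-degenerate replicates; the three category proportions sum to 1).
#'
#' @param grid a `bf_grid` from [run_grid()] (or any data frame with its
#'   columns).
#' @return data frame with columns `n`, `dz`, `reps`, `prop_significant`,
#'   `prop_supports_h1`, `prop_inconclusive`, `prop_supports_h0`.
#' @export
summarize_cells <- function(grid) {
  need <- c("n", "dz", "p", "category", "significant")
  if (!is.data.frame(grid) || !all(need %in% names(grid)) ||
      nrow(grid) == 0L) {
    .stop_invalid(
      "`grid` must be a non-empty data frame with run_grid() columns")
  }
  cells <- split(grid, list(grid$dz, grid$n), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    ok <- !is.na(cell$category)
    if (!any(ok)) {
      .stop_invalid(sprintf("cell (n = %s, dz = %s) has no usable replicates",
                            cell$n[1L], cell$dz[1L]))
    }
    data.frame(
      n = cell$n[1L], dz = cell$dz[1L], reps = nrow(cell),
      prop_significant = mean(cell$significant[ok]),
      prop_supports_h1 = mean(cell$category[ok] == "supports_H1"),
      prop_inconclusive = mean(cell$category[ok] == "inconclusive"),
      prop_supports_h0 = mean(cell$category[ok] == "supports_H0"))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$n, res$dz), ]
  rownames(res) <- NULL
  res
}
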