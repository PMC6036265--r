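# simulator of sham-vs-real paired differences and the replicated grid

test_that("simulate_sample is deterministic given a seed and leaves the RNG alone", {
  a <- simulate_sample(10, 0.3, seed = 1)
  b <- simulate_sample(10, 0.3, seed = 1)
  expect_identical(a, b)
  expect_length(a, 10L)

  set.seed(99)
  ahead <- rnorm(3)
  set.seed(99)
  invisible(simulate_sample(10, 0, seed = 5))
  expect_identical(rnorm(3), ahead)

  expect_error(simulate_sample(1, 0), class = "bfcrit_invalid_input")
})

test_that("simulated differences have the requested mean and unit spread", {
  x0 <- simulate_sample(1e5, 0, seed = 31L)
  expect_lt(abs(mean(x0)), 3 / sqrt(1e5))
  x5 <- simulate_sample(1e5, 0.5, seed = 32L)
  expect_lt(abs(mean(x5) - 0.5), 3 / sqrt(1e5))
  expect_lt(abs(sd(x5) - 1), 3 / sqrt(2 * 1e5))
})

test_that("per-replicate seeds are distinct across replicates and cells", {
  seeds <- c(
    vapply(1:200, function(r) bfcrit:::.sub_seed(1L, 10L, 0.2, r),
           integer(1)),
    vapply(1:200, function(r) bfcrit:::.sub_seed(1L, 20L, 0.2, r),
           integer(1)),
    vapply(1:200, function(r) bfcrit:::.sub_seed(1L, 10L, 0.3, r),
           integer(1)))
  expect_identical(anyDuplicated(seeds), 0L)
  # and they respond to the master seed
  expect_false(bfcrit:::.sub_seed(1L, 10L, 0.2, 1L) ==
                 bfcrit:::.sub_seed(2L, 10L, 0.2, 1L))
})

test_that("run_replicates produces consistent per-replicate records", {
  out <- run_replicates(10, 0.3, reps = 25L, seed = 3L)
  expect_identical(nrow(out), 25L)
  expect_true(all(out$bf10 > 0))
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_identical(out$significant, out$p < 0.05)
  expect_identical(out$category, classify_evidence(out$bf10))
  # p and t agree record by record
  expect_equal(out$p, one_sided_p(out$t, 9), tolerance = 1e-12)
})

test_that("the full grid is reproducible and fully factorial", {
  g1 <- run_grid(n_grid = c(10L, 20L), dz_grid = c(0, 0.5), reps = 4L,
                 seed = 11L)
  g2 <- run_grid(n_grid = c(10L, 20L), dz_grid = c(0, 0.5), reps = 4L,
                 seed = 11L)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_identical(nrow(g1), 2L * 2L * 4L)
  expect_identical(nrow(unique(g1[, c("n", "dz")])), 4L)
  g3 <- run_grid(n_grid = 10L, dz_grid = 0, reps = 1L, seed = 11L)
  expect_identical(nrow(g3), 1L)
  expect_error(run_grid(n_grid = integer(0), seed = 1),
               class = "bfcrit_invalid_input")
})

test_that("under the null the p-values are uniform and alpha is respected", {
  null_cell <- run_replicates(10L, 0, reps = 1000L, seed = 11L)
  # type-I error: binomial 3-sigma band around alpha = 0.05
  expect_lt(abs(mean(null_cell$significant) - 0.05),
            3 * sqrt(0.05 * 0.95 / 1000))
  expect_gt(stats::ks.test(null_cell$p, "punif")$p.value, 0.01)
})

test_that("summarize_cells partitions every cell into the three categories", {
  g <- run_grid(n_grid = c(10L, 40L), dz_grid = c(0, 0.5), reps = 30L,
                seed = 5L)
  cs <- summarize_cells(g)
  expect_identical(nrow(cs), 4L)
  sums <- cs$prop_supports_h1 + cs$prop_inconclusive + cs$prop_supports_h0
  expect_equal(sums, rep(1, 4), tolerance = 1e-12)
  expect_true(all(cs$prop_significant >= 0 & cs$prop_significant <= 1))
  # under the null, noteworthy evidence for H1 needs a large positive t
  # and must stay rare
  expect_lt(cs$prop_supports_h1[cs$n == 10 & cs$dz == 0], 0.5)

  one_cat <- data.frame(n = 5L, dz = 0, p = c(0.4, 0.6),
                        category = "inconclusive",
                        significant = FALSE)
  cs1 <- summarize_cells(one_cat)
  expect_equal(cs1$prop_inconclusive, 1)
  expect_equal(cs1$prop_supports_h1 + cs1$prop_supports_h0, 0)
  expect_error(summarize_cells(data.frame()),
               class = "bfcrit_invalid_input")
})
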