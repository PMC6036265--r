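# one-sided t-test, default Bayes factor, evidence categories

test_that("t_statistic computes t, df and one-sided p from differences", {
  ts <- t_statistic(c(-1, 1))
  expect_equal(ts$t, 0)
  expect_equal(ts$df, 1L)
  expect_equal(ts$p_one_sided, 0.5)

  ts <- t_statistic(c(1, 2, 3)) # mean 2, sd 1 => t = 2*sqrt(3)
  expect_equal(ts$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(ts$df, 2L)

  expect_error(t_statistic(c(5, 5, 5)), class = "bfcrit_degenerate")
  expect_error(t_statistic(3), class = "bfcrit_invalid_input")
  expect_error(t_statistic(c(1, NA)), class = "bfcrit_invalid_input")
})

test_that("one_sided_p is the upper tail of the central t", {
  expect_equal(one_sided_p(0, 9), 0.5)
  expect_equal(one_sided_p(1.833113, 9), 0.05, tolerance = 1e-4)
  expect_lt(one_sided_p(60, 9), 1e-10)
  tt <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(one_sided_p(tt, 9)) < 0))
  expect_error(one_sided_p(1, 0), class = "bfcrit_invalid_input")
})

test_that("one-sided and two-sided Bayes factors coincide at t = 0", {
  for (n in c(2L, 10L, 80L)) {
    expect_equal(jzs_bf10(0, n, default_prior),
                 jzs_bf10(0, n, two_sided_prior),
                 tolerance = 1e-8, label = sprintf("n=%d", n))
  }
})

test_that("the one-sided Bayes factor is strictly increasing in t", {
  for (n in c(10L, 30L)) {
    tt <- seq(-3, 6, by = 0.5)
    bf <- vapply(tt, jzs_bf10, numeric(1), n = n)
    expect_true(all(diff(bf) > 0), label = sprintf("n=%d", n))
  }
})

test_that("Bayes factor anchors: inconclusive at p = 0.45 (N = 10), decisive at t = 5", {
  # the t with one-sided p = 0.45 at df = 9 sits essentially on the
  # moderate-evidence-for-H0 boundary
  t45 <- qt(0.45, 9, lower.tail = FALSE)
  expect_equal(jzs_bf10(t45, 10), 1 / 3, tolerance = 0.05)
  expect_gt(jzs_bf10(5, 20), 100)
})

test_that("the Bayes factor collapses to 1 as the prior scale vanishes", {
  expect_equal(jzs_bf10(2, 20, prior_spec(scale = 1e-4)), 1,
               tolerance = 1e-2)
})

test_that("extreme t statistics are clamped with a warning", {
  expect_warning(bf_hi <- jzs_bf10(120, 20), "asymptotic")
  expect_equal(bf_hi, jzs_bf10(50, 20))
  expect_error(jzs_bf10(Inf, 20), class = "bfcrit_invalid_input")
  expect_error(jzs_bf10(1, 1), class = "bfcrit_invalid_input")
})

test_that("evidence categories follow the 3 / 1-3 / 1/3 convention", {
  expect_identical(classify_evidence(4), "supports_H1")
  expect_identical(classify_evidence(0.2), "supports_H0")
  expect_identical(classify_evidence(1), "inconclusive")
  # the boundaries themselves are inconclusive (strict inequalities)
  expect_identical(classify_evidence(c(3, 1 / 3)),
                   c("inconclusive", "inconclusive"))
  expect_error(classify_evidence(-1), class = "bfcrit_invalid_input")
})

test_that("median Bayes factor diverges under a real effect and shrinks under the null", {
  med_bf <- function(dz, n) {
    median(run_replicates(n, dz, reps = 60L, seed = 7L)$bf10, na.rm = TRUE)
  }
  under_h1 <- vapply(c(10L, 80L, 320L), med_bf, numeric(1), dz = 0.5)
  expect_true(all(diff(under_h1) > 0))
  under_h0 <- vapply(c(10L, 80L, 320L), med_bf, numeric(1), dz = 0)
  expect_true(all(diff(under_h0) < 0))
  expect_lt(under_h0[3], 1 / 3)
})

test_that("bf_test and read_differences analyze a file of differences end to end", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("difference", "0.31", "-0.12", "0.55", "0.90", "0.02",
               "0.44", "-0.25", "0.67"), path)
  x <- read_differences(path)
  expect_length(x, 8L)
  res <- bf_test(x)
  expect_equal(res$t, t_statistic(x)$t)
  expect_equal(res$bf10, jzs_bf10(res$t, 8L))
  expect_identical(res$category, classify_evidence(res$bf10))
  rec <- as.data.frame(res)
  expect_identical(names(rec),
                   c("n", "t", "df", "p", "bf10", "category", "significant"))

  writeLines(c("0.1", "oops", "0.2"), path)
  expect_error(read_differences(path), "line 2",
               class = "bfcrit_invalid_input")
})
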