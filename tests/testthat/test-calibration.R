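exact_cubic_samples <- function(replicates = 1) {
  g <- rep(seq(0.1, 1, by = 0.1), each = replicates)
  calibration_samples(g, ink_weight_mg = 0.1 + 2 * g + 0.5 * g^3)
}

test_that("exact cubic data is recovered to 1e-9 with R^2 = 1", {
  fit <- fit_grey_to_ink(exact_cubic_samples())
  expect_equal(fit$kind, "cubic")
  expect_lt(max(abs(fit$coefficients - c(0.1, 2, 0, 0.5))), 1e-9)
  expect_equal(fit$r_squared, 1)
})

test_that("1% noise at ten levels x five replicates still fits with R^2 > 0.99", {
  s <- exact_cubic_samples(replicates = 5)
  s$ink_weight_mg <- withr::with_seed(42, {
    s$ink_weight_mg * (1 + stats::rnorm(nrow(s), sd = 0.01))
  })
  fit <- fit_grey_to_ink(s)
  expect_gt(fit$r_squared, 0.99)
})

test_that("degenerate or non-monotone designs are refused", {
  same <- calibration_samples(rep(0.5, 10), ink_weight_mg = runif(10))
  expect_error(fit_grey_to_ink(same), "distinct grey levels")
  g <- seq(0.1, 1, by = 0.1)
  wiggly <- calibration_samples(g, ink_weight_mg = sin(12 * g))
  expect_error(fit_grey_to_ink(wiggly), "monotone")
})

test_that("exact linear ink-to-counts data is recovered to 1e-9", {
  ink <- seq(0.5, 5, by = 0.5)
  s <- calibration_samples(seq(0.1, 1, 0.1), ink_weight_mg = ink,
                           counts = 40 + 300 * ink, activity_rel = 1)
  fit <- fit_ink_to_counts(s)
  expect_lt(max(abs(fit$coefficients - c(40, 300))), 1e-9)
})

test_that("pooled Poisson-noise data across 3 activities fits with R^2 > 0.98", {
  g <- rep(seq(0.05, 1, length.out = 20), 3)
  ink <- 0.1 + 2 * g + 0.5 * g^3
  act <- rep(c(0.5, 1, 2), each = 20)
  mu <- 4000 * ink * act
  counts <- withr::with_seed(7, stats::rpois(length(mu), mu))
  fit <- fit_ink_to_counts(calibration_samples(g, ink, counts, act))
  expect_gt(fit$r_squared, 0.98)
})

test_that("zero-activity samples give a flat line; tiny designs error", {
  s0 <- calibration_samples(seq(0.1, 0.3, 0.1), ink_weight_mg = 1:3,
                            counts = c(0, 0, 0), activity_rel = 0)
  expect_equal(fit_ink_to_counts(s0)$coefficients[2], 0)
  expect_error(fit_ink_to_counts(s0[1:2, ]), "3 points")
})

test_that("decay correction is analytic and invertible", {
  expect_equal(decay_correct(123, 0), 123)
  expect_equal(decay_correct(100, 109.77), 200)
  expect_equal(decay_correct(100, -109.77), 50)
  expect_equal(decay_correct(decay_correct(77, 31.4), -31.4), 77,
               tolerance = 1e-12)
  expect_error(decay_correct(-1, 10), ">= 0")
})

test_that("bisection inversion round-trips within 1e-5 and matches brute force", {
  cub <- fit_grey_to_ink(exact_cubic_samples())
  ink <- seq(0.5, 5, by = 0.5)
  lin <- fit_ink_to_counts(calibration_samples(
    seq(0.1, 1, 0.1), ink_weight_mg = ink, counts = 40 + 300 * ink))
  f <- function(gr) eval_curve(lin, eval_curve(cub, gr))
  c0 <- f(cub$domain[1]); c1 <- f(cub$domain[2])
  for (target in c(0, 0.2, 0.5, 0.77, 1)) {
    gr <- grey_for_target_activity(target, cub, lin)
    expect_lt(abs((f(gr) - c0) / (c1 - c0) - target), 1e-5)
    # brute-force grid oracle at 1e-4 resolution
    grid <- seq(cub$domain[1], cub$domain[2], by = 1e-4)
    oracle <- grid[which.min(abs((f(grid) - c0) / (c1 - c0) - target))]
    expect_lt(abs(gr - oracle), 2e-4)
  }
  expect_equal(grey_for_target_activity(1, cub, lin), 1, tolerance = 1e-5)
  expect_error(grey_for_target_activity(1.2, cub, lin), "achievable")
})

test_that("identity-like curves return the target itself", {
  cub <- calibration_curve("cubic", c(0, 1, 0, 0), domain = c(0, 1))
  lin <- calibration_curve("linear", c(0, 1), domain = c(0, 1))
  expect_equal(grey_for_target_activity(0.42, cub, lin), 0.42,
               tolerance = 1e-5)
})

test_that("CSV and JSON interfaces round-trip calibration objects", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(grey_level = seq(0.1, 1, 0.1),
                              ink_weight_mg = 0.1 + 2 * seq(0.1, 1, 0.1),
                              counts = 100 * seq(0.1, 1, 0.1),
                              activity_rel = 1,
                              elapsed_min = 109.77),
                   path, row.names = FALSE)
  s <- read_calibration_csv(path)
  expect_equal(s$counts, 200 * seq(0.1, 1, 0.1))   # decay-corrected doubled
  cub <- fit_grey_to_ink(exact_cubic_samples())
  jf <- withr::local_tempfile(fileext = ".json")
  curve_to_json(cub, jf)
  back <- curve_from_json(jf)
  expect_equal(back$coefficients, cub$coefficients)
  expect_equal(back$kind, "cubic")
})
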