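# Worm-like-chain metrology: resampling, contour length, the three
# persistence-length estimators and their combination, diameter sampling.

test_that("resampling is arc-length uniform and length preserving", {
  straight <- cbind(seq(0, 100, length.out = 5), rep(0, 5))
  rs <- resample_contour(straight, 10)
  expect_identical(nrow(rs$points), 11L)
  expect_equal(contour_length(rs), 100, tolerance = 1e-9)
  # gently curved polyline: length preserved to 0.5%
  poly <- generate_wlc_contours(lambda = 300, length = 150, ds = 2,
                                n = 1, seed = 2)[[1]]$points
  rs2 <- resample_contour(poly, 3)
  expect_lt(abs(contour_length(rs2) - contour_length(poly)) /
              contour_length(poly), 0.005)
  # idempotent to tolerance
  rs3 <- resample_contour(rs2$points, 3)
  expect_equal(contour_length(rs3), contour_length(rs2), tolerance = 0.005)
  expect_error(resample_contour(cbind(c(1, 1), c(2, 2)), 1), "degenerate")
})

test_that("contour length matches the cumulative-sum oracle", {
  expect_equal(contour_length(cbind(c(0, 50), c(0, 0))), 50)
  # open traversal of a square visits 3 sides
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)) * 7
  expect_equal(contour_length(sq), 21)
  set.seed(3)
  p <- matrix(rnorm(40), 20, 2)
  oracle <- sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  expect_equal(contour_length(p), oracle, tolerance = 1e-12)
})

test_that("straight contours are flagged rigid", {
  straight <- lapply(1:5, function(i) {
    list(points = cbind(seq(0, 100, by = 5), rep(i, 21)))
  })
  b <- persistence_length_bcf(straight)
  expect_true(b$rigid)
  expect_identical(b$lambda, Inf)
  m <- persistence_length_msmd(straight)
  expect_true(m$rigid)
  expect_error(wlc_fit(straight), "rigid")
})

test_that("generator round-trip recovers the persistence length", {
  cts <- generate_wlc_contours(lambda = 150, length = 600, ds = 6,
                               n = 80, seed = 5)
  b <- persistence_length_bcf(cts)
  expect_lt(abs(b$lambda - 150) / 150, 0.15)
  m <- persistence_length_msed(cts)
  expect_lt(abs(m$lambda - 150) / 150, 0.15)
  u <- persistence_length_msmd(cts)
  expect_lt(abs(u$lambda - 150) / 150, 0.20)
  f <- wlc_fit(cts)
  expect_lt(abs(f$lambda - 150) / 150, 0.15)
  expect_true(all(f$converged))
})

test_that("estimators are scale equivariant", {
  cts <- generate_wlc_contours(lambda = 100, length = 400, ds = 5,
                               n = 40, seed = 8)
  doubled <- lapply(cts, function(ct) list(points = ct$points * 2))
  b1 <- persistence_length_bcf(cts)$lambda
  b2 <- persistence_length_bcf(doubled)$lambda
  expect_equal(b2 / b1, 2, tolerance = 1e-6)
  m1 <- persistence_length_msed(cts)$lambda
  m2 <- persistence_length_msed(doubled)$lambda
  expect_equal(m2 / m1, 2, tolerance = 1e-3)
})

test_that("estimators are rotation and translation invariant", {
  cts <- generate_wlc_contours(lambda = 100, length = 400, ds = 5,
                               n = 20, seed = 9)
  ang <- 0.83
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  moved <- lapply(cts, function(ct) {
    list(points = sweep(ct$points %*% R, 2, c(31, -17), "+"))
  })
  expect_equal(persistence_length_bcf(moved)$lambda,
               persistence_length_bcf(cts)$lambda, tolerance = 1e-9)
  expect_equal(persistence_length_msmd(moved)$lambda,
               persistence_length_msmd(cts)$lambda, tolerance = 1e-9)
})

test_that("lambda ordering is preserved across ensembles", {
  lo <- generate_wlc_contours(lambda = 80, length = 320, ds = 4,
                              n = 60, seed = 10)
  hi <- generate_wlc_contours(lambda = 400, length = 1600, ds = 20,
                              n = 60, seed = 10)
  expect_lt(persistence_length_bcf(lo)$lambda,
            persistence_length_bcf(hi)$lambda)
  expect_lt(wlc_fit(lo)$lambda, wlc_fit(hi)$lambda)
})

test_that("the MSED curve increases monotonically in s", {
  for (sd in 1:3) {
    cts <- generate_wlc_contours(lambda = 120, length = 480, ds = 6,
                                 n = 40, seed = sd)
    m <- persistence_length_msed(cts)
    expect_true(all(diff(m$curve$r2) > 0))
  }
})

test_that("the MSMD curve is non-negative everywhere", {
  cts <- generate_wlc_contours(lambda = 120, length = 480, ds = 6,
                               n = 30, seed = 12)
  u <- persistence_length_msmd(cts)
  expect_true(all(u$curve$u2 >= 0))
})

test_that("combined estimate averages the converged estimators", {
  cts <- generate_wlc_contours(lambda = 150, length = 600, ds = 6,
                               n = 60, seed = 13)
  f <- wlc_fit(cts)
  expect_equal(f$lambda,
               mean(c(f$lambda_bcf, f$lambda_msed, f$lambda_msmd)),
               tolerance = 1e-12)
  expect_named(coef(f), c("lambda", "lambda_bcf", "lambda_msed",
                          "lambda_msmd", "contour_length"))
})

test_that("diameter statistics recover the generating width model", {
  cts <- generate_wlc_contours(lambda = 200, length = 800, ds = 8,
                               n = 50, seed = 14,
                               width_mean = 8.9, width_sd = 1.1)
  ds1 <- diameter_stats(cts, n_samples = 100, seed = 21)
  ds2 <- diameter_stats(cts, n_samples = 100, seed = 21)
  expect_identical(ds1$widths, ds2$widths)   # seeded determinism
  # fitted mean within 3 standard errors of the generating value
  se <- ds1$fit$sd_error["mean"]
  expect_lt(abs(ds1$fit$estimate["mean"] - 8.9), 3 * se + 0.5)
  # constant width: zero spread
  flat <- lapply(cts[1:3], function(ct) {
    ct$width <- rep(12, nrow(ct$points)); ct
  })
  dflat <- diameter_stats(flat, n_samples = 50, seed = 22)
  expect_equal(dflat$mean, 12)
  expect_equal(dflat$sd, 0)
  expect_error(diameter_stats(list(list(points = cbind(0:1, 0:1)))),
               "width")
})

test_that("wlc_fit methods print and plot without error", {
  cts <- generate_wlc_contours(lambda = 100, length = 400, ds = 5,
                               n = 20, seed = 15)
  f <- wlc_fit(cts)
  expect_output(print(f), "persistence length")
  expect_output(summary(f), "2D convention")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(f))
})
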