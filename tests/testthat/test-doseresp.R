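PRINTED_SERIES <- c(0.01, 0.1, 1, 10, 50, 100, 200, 500, 1000)

test_that("solvent controls are placed at the log10 of the lowest dose", {
  x <- logTransformConcentrations(c(0, PRINTED_SERIES))
  expect_equal(x[1], -2)  # 0 -> log10(0.01)
  expect_equal(logTransformConcentrations(100), 2)
  expect_equal(logTransformConcentrations(1), 0)
  expect_error(logTransformConcentrations(c(0, 0)), "all-zero")
  # several solvent replicates all land on the same x
  x2 <- logTransformConcentrations(c(0, 0, 0, 1, 10))
  expect_true(all(x2[1:3] == 0))
})

test_that("4PL prediction: midpoint, plateaus, independent formula grid", {
  curve <- list(bottom = 0, top = 100, logIC50 = 2, hill = 1)
  expect_equal(predictFourPL(curve, 2), 50)
  expect_equal(predictFourPL(curve, -30), 100, tolerance = 1e-10)
  expect_equal(predictFourPL(curve, 30), 0, tolerance = 1e-10)
  xs <- seq(-3, 4, length.out = 50)
  expect_equal(predictFourPL(list(bottom = 10, top = 90, logIC50 = 0.5,
                                  hill = 2.2), xs),
               brute4PL(10, 90, 0.5, 2.2, xs), tolerance = 1e-12)
})

test_that("noise-free 4PL data are recovered to high precision", {
  xs <- logTransformConcentrations(c(0, PRINTED_SERIES))
  y <- brute4PL(0, 100, 1, 1.5, xs)
  f <- fitFourPL(xs, y)
  expect_true(isConverged(f))
  expect_lt(abs(f@bottom - 0) / 100, 1e-6)
  expect_lt(abs(f@top - 100) / 100, 1e-6)
  expect_lt(abs(f@logIC50 - 1), 1e-6)
  expect_lt(abs(f@hill - 1.5) / 1.5, 1e-6)
  expect_equal(ic50(f), 10, tolerance = 1e-6)
})

test_that("constant responses are flagged unidentifiable, with no IC50", {
  f <- fitFourPL(seq(-2, 3, length.out = 8), rep(100, 8))
  expect_false(isConverged(f))
  expect_error(ic50(f), "did not converge")
})

test_that("IC50 is 10^logIC50", {
  f <- new("DoseResponseFit", bottom = 0, top = 100, logIC50 = 2, hill = 1,
           rss = 0, converged = TRUE, n = 10L, message = "converged")
  expect_equal(ic50(f), 100)
  f@logIC50 <- -1
  expect_equal(ic50(f), 0.1)
})

test_that("noisy fits recover the IC50 (Monte-Carlo, reduced here)", {
  xs <- rep(logTransformConcentrations(c(0, PRINTED_SERIES)), each = 8)
  set.seed(20)
  errs <- replicate(40, {
    y <- brute4PL(0, 100, 1, 1.5, xs) * (1 + rnorm(length(xs), 0, 0.05))
    f <- fitFourPL(xs, y)
    c(abs(f@logIC50 - 1), abs(10^f@logIC50 / 10 - 1))
  })
  expect_lt(median(errs[1, ]), 0.15)
  expect_gte(mean(errs[2, ] < 0.2), 0.8)
})

test_that("RSS at the optimum is no worse than at the generator parameters", {
  xs <- rep(seq(-2, 3, length.out = 10), each = 4)
  set.seed(9)
  y <- brute4PL(5, 95, 0.8, 1.2, xs) + rnorm(length(xs), 0, 4)
  f <- fitFourPL(xs, y)
  rssGen <- sum((y - brute4PL(5, 95, 0.8, 1.2, xs))^2)
  expect_lte(f@rss, rssGen)
})

test_that("rescaling concentrations shifts logIC50 by exactly the scale", {
  xs <- rep(seq(-2, 3, length.out = 10), each = 3)
  set.seed(10)
  y <- brute4PL(0, 100, 1, 1.5, xs) * (1 + rnorm(length(xs), 0, 0.03))
  f1 <- fitFourPL(xs, y)
  f2 <- fitFourPL(xs + 3, y)  # concentrations in nM
  expect_equal(f2@logIC50 - f1@logIC50, 3, tolerance = 1e-6)
  # remaining parameters agree to the optimizer's convergence precision
  expect_equal(f2@hill, f1@hill, tolerance = 1e-4)
  expect_equal(f2@top, f1@top, tolerance = 1e-4)
  expect_equal(f2@bottom, f1@bottom, tolerance = 1e-4)
})

test_that("including the solvent point changes the top plateau boundedly", {
  set.seed(14)
  conc <- rep(c(0, PRINTED_SERIES), each = 4)
  y <- brute4PL(0, 100, 1.2, 1.3, logTransformConcentrations(conc)) *
    (1 + rnorm(length(conc), 0, 0.04))
  fAll <- fitDoseResponse(conc, y)
  keep <- conc > 0
  fNoCtrl <- fitDoseResponse(conc[keep], y[keep])
  expect_true(isConverged(fAll) && isConverged(fNoCtrl))
  expect_lt(abs(fAll@top - fNoCtrl@top), 5)  # regression bound, in percent
})
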