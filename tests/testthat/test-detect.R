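constMatrix <- function(value, F = 2, L = 50) {
  new("TimeSeriesMatrix", kind = "rna", values = matrix(value, F, L),
      sampleInterval = 1, burnin = 0, label = "const", seeds = seq_len(F))
}

noiseMatrix <- function(seed, F = 2, L = 2000, shift = 0, label = "noise") {
  new("TimeSeriesMatrix", kind = "rna",
      values = matrix(withr::with_seed(seed, rpois(F * L, 5)) + shift, F, L),
      sampleInterval = 1, burnin = 0, label = label, seeds = seq_len(F))
}

test_that("window means cover deltaL + 1 samples", {
  m <- new("TimeSeriesMatrix", kind = "rna",
           values = matrix(c(1, 2, 3), 1), sampleInterval = 1, burnin = 0,
           label = "x", seeds = 1)
  # with L = 3 and deltaL = 2 the only admissible start is 1
  p <- sampleMeanProfile(m, deltaL = 2, S = 4, seed = 1)
  expect_true(all(p == 2))
  expect_equal(unname(p[1]), naiveWindowMean(c(1, 2, 3), 1, 2))
  expect_error(sampleMeanProfile(m, deltaL = 3, S = 1), "smaller")
})

test_that("profiles of a constant matrix are constant", {
  p <- sampleMeanProfile(constMatrix(4), deltaL = 10, S = 20, seed = 2)
  expect_true(all(p == 4))
})

test_that("profile means obey the law of large numbers", {
  m <- noiseMatrix(3, F = 3, L = 5000)
  p <- sampleMeanProfile(m, deltaL = 50, S = 1000, seed = 4)
  grand <- mean(tsValues(m))
  se <- stats::sd(tsValues(m)) / sqrt(51) / sqrt(1000) * 2 # conservative
  expect_lt(abs(mean(p) - grand), max(3 * se, 0.05))
})

test_that("null comparisons give uniform-ish p-values", {
  mA <- noiseMatrix(5)
  mB <- noiseMatrix(6)
  pv <- compareModels(mA, mB, deltaL = 50, S = 10, N = 200, seed = 7)
  expect_gt(stats::median(pv@pvalues), 0.25)
  expect_lt(stats::median(pv@pvalues), 0.75)
  expect_lt(mean(pv@pvalues < 0.05), 0.12)
})

test_that("a large mean offset is always detected", {
  mA <- noiseMatrix(8)
  mB <- noiseMatrix(9, shift = 100, label = "shifted")
  pv <- compareModels(mA, mB, deltaL = 50, S = 10, N = 50, seed = 10)
  expect_true(all(pv@pvalues < 1e-6))
})

test_that("degenerate zero-variance comparisons are excluded, not coerced", {
  pv <- compareModels(constMatrix(1), constMatrix(1), deltaL = 5, S = 10,
                      N = 20, seed = 11)
  expect_equal(pv@nIndeterminate, 20)
  expect_length(pv@pvalues, 0)
})

test_that("mismatched kinds or intervals are rejected", {
  mA <- noiseMatrix(12)
  mP <- mA
  mP@kind <- "protein"
  expect_error(compareModels(mA, mP, 10, 5, 5), "same kind")
})
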