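fakeTrajectory <- function(rna, protein, total, seed = 1) {
  df <- data.frame(time = seq_along(rna) - 1, rna = rna, protein = protein,
                   proteinTotal = total)
  attr(df, "seed") <- seed
  attr(df, "label") <- "fake"
  attr(df, "sampleInterval") <- 1
  df
}

test_that("assembly stacks replicates and keeps production bookkeeping", {
  t1 <- fakeTrajectory(c(0, 1, 1, 0, 2), c(0, 1, 1, 0, 2), c(0, 1, 1, 1, 3))
  t2 <- fakeTrajectory(c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 1), c(0, 0, 1, 1, 1))
  m <- assembleMatrix(list(t1, t2), "cumulative")
  expect_equal(dim(tsValues(m)), c(2, 5))
  expect_equal(tsValues(m)[1, ], c(0, 1, 1, 1, 3))

  single <- assembleMatrix(list(t1), "rna")
  expect_equal(nrow(tsValues(single)), 1)

  short <- fakeTrajectory(c(0, 1), c(0, 0), c(0, 0))
  expect_error(assembleMatrix(list(t1, short), "rna"), "ragged")
})

test_that("cumulative production from the simulator is non-decreasing and
           dominates the instantaneous count net of degradation", {
  fx <- tinyFixture()
  cum <- tsValues(fx$A$cumulative)
  expect_true(all(apply(cum, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(cum >= tsValues(fx$A$protein)))
})

test_that("burn-in truncation drops exactly the leading columns", {
  t1 <- fakeTrajectory(1:100, 1:100, cumsum(rep(1, 100)))
  m <- assembleMatrix(list(t1), "rna")
  tr <- truncateBurnin(m, t0 = 50)
  expect_equal(ncol(tsValues(tr)), 50)
  expect_equal(tsValues(tr)[1, ], 51:100)
  expect_equal(tr@burnin, 50)

  expect_identical(truncateBurnin(m, 0), m)
  expect_error(truncateBurnin(m, 100), "smaller than the duration")
})

test_that("assembly and truncation commute", {
  fx <- tinyFixture()
  full <- fx$A$rna # burn-in already removed by runExperiment
  again <- truncateBurnin(full, 1000)
  pre <- tsValues(full)[, -(1:1000), drop = FALSE]
  expect_identical(tsValues(again), pre)
})

test_that("stationarity check passes i.i.d. noise at roughly 1 - alpha", {
  outcomes <- vapply(1:200, function(i) {
    m <- new("TimeSeriesMatrix", kind = "rna",
             values = matrix(withr::with_seed(i, rpois(5 * 300, 10)), 5),
             sampleInterval = 1, burnin = 0, label = "noise", seeds = 1:5)
    stationarityCheck(m, seed = 1000 + i)$status
  }, character(1))
  expect_gt(mean(outcomes == "pass"), 0.85)

  trended <- vapply(1:50, function(i) {
    base <- withr::with_seed(300 + i, rpois(5 * 300, 10))
    m <- new("TimeSeriesMatrix", kind = "rna",
             values = matrix(base, 5) +
               matrix(rep(seq(0, 15, length.out = 300), each = 5), 5),
             sampleInterval = 1, burnin = 0, label = "trend", seeds = 1:5)
    stationarityCheck(m, seed = 2000 + i)$status
  }, character(1))
  expect_gt(mean(trended == "fail"), 0.9)

  const <- new("TimeSeriesMatrix", kind = "rna",
               values = matrix(3, 4, 100), sampleInterval = 1, burnin = 0,
               label = "const", seeds = 1:4)
  expect_equal(stationarityCheck(const, seed = 5)$status, "indeterminate")
})

test_that("simulated model time series are weakly stationary after burn-in", {
  fx <- calibrationFixture()
  chk <- stationarityCheck(fx$A$rna, seed = 9)
  expect_equal(chk$status, "pass")
})
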