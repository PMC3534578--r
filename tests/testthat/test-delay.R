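test_that("point-mass delays are exact and zero behaves instantaneously", {
  expect_identical(drawDelay(delayPoint(5), 10, seed = 1), rep(5, 10))
  expect_identical(drawDelay(delayPoint(0), 3, seed = 1), rep(0, 3))
})

test_that("exponential and truncated-normal samplers hit their means", {
  ex <- drawDelay(delayExponential(47), 1e5, seed = 11)
  expect_lt(abs(mean(ex) - 47), 0.5)
  expect_true(all(ex >= 0))

  no <- drawDelay(delayNormal(40, 4), 1e5, seed = 12)
  expect_lt(abs(mean(no) - 40), 0.05)
  expect_true(all(no >= 0))
  # rejection resampling leaves no atom at zero
  expect_gt(min(no), 0)
})

test_that("invalid delay parameters are configuration errors", {
  expect_error(delayPoint(-1), "non-negative")
  expect_error(delayNormal(40, -1), "standard deviation")
  expect_error(delayExponential(-2), "non-negative")
})

test_that("delay draws are reproducible under a seed", {
  expect_identical(drawDelay(delayNormal(40, 4), 100, seed = 5),
                   drawDelay(delayNormal(40, 4), 100, seed = 5))
  expect_false(identical(drawDelay(delayNormal(40, 4), 100, seed = 5),
                         drawDelay(delayNormal(40, 4), 100, seed = 6)))
})
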