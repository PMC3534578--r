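gaussFeatures <- function(n, centre, seed, V = 3) {
  withr::with_seed(seed,
    matrix(stats::rnorm(n * V, mean = centre), n, V,
           dimnames = list(NULL, paste0("f", seq_len(V)))))
}

test_that("overlap is 1 for identical samples and 0 for disjoint supports", {
  x <- withr::with_seed(1, stats::rnorm(500))
  expect_lt(abs(densityOverlap(x, x) - 1), 1e-3)
  expect_lt(densityOverlap(x, x + 1000), 1e-6)
  expect_error(densityOverlap(rep(1, 10), x), "zero-spread")
  expect_error(densityOverlap(x[1:3], x), "5")
})

test_that("two large samples from the same density overlap almost fully", {
  f <- withr::with_seed(2, stats::rnorm(1e4))
  g <- withr::with_seed(3, stats::rnorm(1e4))
  expect_gte(densityOverlap(f, g), 0.95)
})

test_that("overlap is symmetric and matches the dense-grid oracle", {
  withr::with_seed(4, {
    for (rep in 1:5) {
      f <- stats::rnorm(30, sd = stats::runif(1, 0.5, 2))
      g <- stats::rnorm(40, mean = stats::runif(1, -1, 1))
      o <- densityOverlap(f, g)
      expect_lt(abs(o - densityOverlap(g, f)), 1e-6)
      expect_lt(abs(o - naiveOverlap(f, g)), 1e-3)
      expect_gte(o, 0)
      expect_lte(o, 1)
    }
  })
})

test_that("the log-likelihood reduces to S log(overlap) for V = 1", {
  obs <- gaussFeatures(20, 0, seed = 5, V = 1)
  sim <- gaussFeatures(25, 0.2, seed = 6, V = 1)
  ll <- approximateLogLikelihood(obs, sim)
  expect_equal(as.numeric(ll), 20 * log(densityOverlap(obs[, 1], sim[, 1])))
})

test_that("disjoint supports floor to -Inf bookkeeping", {
  obs <- gaussFeatures(20, 0, seed = 7)
  sim <- gaussFeatures(20, 1000, seed = 8)
  ll <- approximateLogLikelihood(obs, sim)
  expect_equal(attr(ll, "zeroFeatures"), paste0("f", 1:3))
  expect_equal(as.numeric(ll), 20 * 3 * log(1e-12))
})

test_that("profiles are normalised with the maximum at zero", {
  obs <- gaussFeatures(20, 1, seed = 9)
  refs <- list(`100` = gaussFeatures(30, 0, seed = 10),
               `200` = gaussFeatures(30, 1, seed = 11),
               `300` = gaussFeatures(30, 2.5, seed = 12))
  prof <- profileLikelihood(obs, refs)
  expect_equal(prof@thetaHat, 200)
  expect_equal(max(prof@lrl), 0)
  expect_true(all(prof@lrl <= 0))
  expect_equal(prof@lrl[prof@theta == 200], 0)
})

test_that("bootstrap positions stay on the grid; a single row gives SD 0", {
  obs <- gaussFeatures(15, 1, seed = 13)
  refs <- list(`100` = gaussFeatures(30, 0, seed = 14),
               `200` = gaussFeatures(30, 1, seed = 15),
               `300` = gaussFeatures(30, 3, seed = 16))
  bs <- suppressWarnings(bootstrapCI(obs, refs, B = 200, seed = 17))
  expect_true(all(bs$thetaHats %in% c(100, 200, 300)))
  expect_true(bs$ci[1] >= 100 && bs$ci[2] <= 300)

  one <- obs[1, , drop = FALSE]
  bs1 <- suppressWarnings(bootstrapCI(one, refs, B = 50, seed = 18))
  expect_equal(bs1$sd, 0)
  expect_equal(bs1$ci[1], bs1$ci[2])
  expect_warning(bootstrapCI(obs, refs, B = 50, seed = 19), "unstable")
})

test_that("likelihood depends on theta only through the simulated samples", {
  obs <- gaussFeatures(20, 1, seed = 20)
  refs <- list(`100` = gaussFeatures(30, 0, seed = 21),
               `200` = gaussFeatures(30, 1, seed = 22))
  relabeled <- refs
  names(relabeled) <- c("1000", "2000") # monotone relabelling of the grid
  p1 <- profileLikelihood(obs, refs)
  p2 <- profileLikelihood(obs, relabeled)
  expect_equal(p1@logLik, p2@logLik)
  expect_equal(which.max(p1@lrl), which.max(p2@lrl))
})
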