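test_that("autocorrelation matches its definition and the naive oracle", {
  expect_equal(autocorrLag(c(1, 2, 3, 4, 5), 1), 0.4)
  expect_equal(autocorrLag(stats::rnorm(50), 0), 1)
  withr::with_seed(1, {
    for (rep in 1:5) {
      x <- stats::rpois(sample(50:200, 1), 5)
      l <- sample(1:10, 1)
      expect_equal(autocorrLag(x, l), naiveAutocorr(x, l), tolerance = 1e-12)
    }
  })
  expect_error(autocorrLag(rep(2, 10), 1), "degenerate")
  wn <- withr::with_seed(2, stats::rnorm(1e4))
  expect_lt(abs(autocorrLag(wn, 1)), 0.03)
})

test_that("cross-correlation matches its definition and the naive oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(crossCorrLag(x, x, 0), 1)
  expect_equal(crossCorrLag(x, -x, 0), -1)
  expect_equal(crossCorrLag(x, c(4, 3, 2, 1), 1),
               naiveCrosscorr(x, c(4, 3, 2, 1), 1), tolerance = 1e-12)
  withr::with_seed(3, {
    for (rep in 1:5) {
      n <- sample(50:200, 1)
      a <- stats::rnorm(n)
      b <- stats::rnorm(n)
      l <- sample(0:10, 1)
      expect_equal(crossCorrLag(a, b, l), naiveCrosscorr(a, b, l),
                   tolerance = 1e-12)
    }
  })
})

test_that("the lag-weighted summary follows the printed form", {
  expect_equal(unname(corrSummary(c(0.5, 0.25, 0.125))["m"]),
               (0.5 + 0.5 + 0.375) / 3)
  K <- 10
  expect_equal(unname(corrSummary(rep(0.2, K))["m"]), 0.2 * (K + 1) / 2)
  expect_equal(unname(corrSummary(rep(0, K))), c(0, 0))
  withr::with_seed(4, {
    r <- stats::runif(300, -1, 1)
    expect_equal(corrSummary(r), naiveCorrSummary(r), tolerance = 1e-12)
  })
  expect_error(corrSummary(0.5), "at least")
})

test_that("decay times are maximal non-increasing runs", {
  expect_equal(decayTimes(c(5, 4, 4, 3, 6, 6, 5)), c(3, 2))
  expect_equal(mean(decayTimes(c(5, 4, 4, 3, 6, 6, 5))), 2.5)
  expect_length(decayTimes(1:10), 0)
  expect_equal(decayTimes(rep(2, 8)), 7)
  withr::with_seed(5, {
    for (rep in 1:10) {
      x <- stats::rpois(100, 3)
      expect_identical(decayTimes(x), naiveDecayTimes(x))
    }
  })
})

test_that("feature vectors compose the primitive statistics", {
  withr::with_seed(6, {
    R <- stats::rpois(500, 4)
    P <- stats::rpois(500, 40)
    E <- cumsum(stats::rpois(500, 1))
  })
  v <- featureVector(R, P, E, K = 100)
  expect_length(v, 10)
  expect_named(v, featureNames())
  expect_equal(unname(v["m_decay_rna"]), mean(decayTimes(R)))
  acf100 <- vapply(1:100, function(l) autocorrLag(R, l), numeric(1))
  expect_equal(unname(v[c("m_acf_rna", "s_acf_rna")]),
               unname(corrSummary(acf100)), tolerance = 1e-12)
  # determinism: identical rows give identical vectors
  expect_identical(v, featureVector(R, P, E, K = 100))
  expect_error(featureVector(rep(1, 500), P, E, K = 100), "rna")
})

test_that("correlation features are affine-invariant; decay features are
           monotone-invariant", {
  withr::with_seed(7, {
    R <- stats::rpois(500, 4)
    P <- stats::rpois(500, 40)
    E <- cumsum(stats::rpois(500, 1))
  })
  v1 <- featureVector(R, P, E, K = 100)
  v2 <- featureVector(3 * R + 2, 0.5 * P + 1, 10 * E + 5, K = 100)
  expect_equal(v1[1:8], v2[1:8], tolerance = 1e-9)
  v3 <- featureVector(R^3, P, E, K = 100)
  expect_equal(v1[9:10], v3[9:10])
})

test_that("the z-transform standardises every component", {
  df <- data.frame(model = "A", replicate = 1:20)
  withr::with_seed(8,
    df[featureNames()] <- matrix(stats::rnorm(200, 5, 3), 20))
  z <- zTransform(df)
  zm <- as.matrix(z[featureNames()])
  expect_true(all(abs(colMeans(zm)) < 1e-12))
  expect_equal(unname(apply(zm, 2, stats::var)), rep(1, 10))

  two <- data.frame(f = c(0, 2))
  zz <- zTransform(two)
  expect_equal(zz$f, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  df$m_acf_rna <- 1
  expect_error(zTransform(df), "constant")
})
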