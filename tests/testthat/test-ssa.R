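# Generic delayed-SSA engine

test_that("delayed products fire instantaneously and release after tau", {
  rx <- list(delayedReaction(1, c(A = 1), c(B = 1),
                             delayed = list(delayedProduct("C", 1,
                                                           delayPoint(5))),
                             name = "fire"))
  s0 <- simState(c(A = 1, B = 0, C = 0))
  s1 <- ssaStep(s0, rx, seed = 3)
  expect_equal(unname(s1@counts[c("A", "B", "C")]), c(0, 1, 0))
  expect_equal(nrow(s1@waiting), 1)
  expect_equal(s1@waiting$time, s1@time + 5)

  s2 <- ssaStep(s1, rx, seed = 4)
  expect_equal(unname(s2@counts[c("A", "B", "C")]), c(0, 1, 1))
  expect_equal(s2@time, s1@time + 5)
  expect_equal(nrow(s2@waiting), 0)
})

test_that("zero propensity with an empty waiting list signals exhaustion", {
  rx <- list(delayedReaction(1, c(A = 1), c(B = 1)))
  s0 <- simState(c(A = 0, B = 0))
  s1 <- ssaStep(s0, rx, seed = 1)
  expect_equal(s1@status, "exhausted")
  expect_equal(s1@counts, s0@counts)
  expect_equal(s1@time, 0)
})

test_that("an empty reaction set leaves all samples at the initial counts", {
  tr <- simulateReactions(list(), c(X = 7), tEnd = 10, seed = 1)
  expect_equal(nrow(tr), 11)
  expect_true(all(tr[, "X"] == 7))
})

test_that("sampling grid arithmetic and determinism hold", {
  bd <- list(delayedReaction(5, products = c(X = 1)),
             delayedReaction(0.1, reactants = c(X = 1)))
  t1 <- simulateReactions(bd, c(X = 0), tEnd = 10, seed = 9)
  expect_equal(nrow(t1), 11)
  expect_equal(t1[, "time"], 0:10)
  t2 <- simulateReactions(bd, c(X = 0), tEnd = 10, seed = 9)
  expect_identical(t1[, ], t2[, ])
  expect_true(all(t1[, "X"] >= 0))
})

test_that("pure-decay dynamics match the exponential-decay law", {
  n0 <- 30
  d <- 0.1
  rx <- list(delayedReaction(d, c(X = 1)))
  runs <- vapply(1:4000, function(i) {
    tr <- simulateReactions(rx, c(X = n0), tEnd = 10, sampleInterval = 5,
                            seed = 10000 + i)
    tr[, "X"]
  }, numeric(3))
  for (k in 2:3) {
    t <- (k - 1) * 5
    expected <- n0 * exp(-d * t)
    p <- exp(-d * t)
    se <- sqrt(n0 * p * (1 - p) / ncol(runs))
    expect_lt(abs(mean(runs[k, ]) - expected), 3 * se)
  }
})

test_that("birth-death stationary mean matches k/d", {
  k <- 5
  d <- 0.1
  tr <- simulateReactions(list(delayedReaction(k, products = c(X = 1)),
                               delayedReaction(d, reactants = c(X = 1))),
                          c(X = 0), tEnd = 20000, seed = 77)
  x <- tr[tr[, "time"] > 200, "X"]
  # stationary variance k/d, autocorrelation time 1/d
  se <- sqrt((k / d) * (2 / d) / length(x))
  expect_lt(abs(mean(x) - k / d), 3 * se)
})

test_that("delay-free event times agree with a reference direct-method SSA", {
  # 3-species toy network: A + B -> C (0.5), A -> 0 (1), C -> 0 (2)
  rx <- list(
    delayedReaction(0.5, c(A = 1, B = 1), c(C = 1)),
    delayedReaction(1, c(A = 1)),
    delayedReaction(2, c(C = 1))
  )
  init <- c(A = 3, B = 2, C = 0)
  nRuns <- 4000
  mineTimes <- vapply(seq_len(nRuns), function(i) {
    s <- simState(init)
    repeat {
      s2 <- ssaStep(s, rx, nEvents = 100, seed = 20000 + i)
      if (s2@status == "exhausted") return(s2@time)
      s <- s2
    }
  }, numeric(1))
  reactMat <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1))
  prodMat <- rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0))
  withr::with_seed(99, {
    refTimes <- vapply(seq_len(nRuns), function(i) {
      referenceSsaAbsorptionTime(init, reactMat, prodMat, c(0.5, 1, 2))
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(mineTimes, refTimes))
  expect_gt(ks$p.value, 0.01)
})

test_that("every enqueued delayed product is eventually released, none early", {
  rx <- list(delayedReaction(10, c(A = 1),
                             delayed = list(delayedProduct("C", 1,
                                            delayExponential(2)))))
  tr <- simulateReactions(rx, c(A = 5, C = 0), tEnd = 200, seed = 3)
  expect_equal(unname(tr[nrow(tr), "C"]), 5)
  # release cannot precede firing: C never exceeds consumed A
  expect_true(all(tr[, "C"] <= 5 - tr[, "A"]))
})

test_that("guarded reactions fire only inside their count bounds", {
  # production of Y only while X == 0
  rx <- list(delayedReaction(100, products = c(Y = 1),
                             guards = data.frame(species = "X", min = 0,
                                                 max = 0)))
  tr1 <- simulateReactions(rx, c(X = 1, Y = 0), tEnd = 5, seed = 1)
  expect_true(all(tr1[, "Y"] == 0))
  tr2 <- simulateReactions(rx, c(X = 0, Y = 0), tEnd = 5, seed = 1)
  expect_gt(tr2[nrow(tr2), "Y"], 0)
})
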