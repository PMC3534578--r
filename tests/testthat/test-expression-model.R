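# Gene template construction and the transcription/translation kernel

test_that("codon sequences follow the frequency table", {
  one <- data.frame(codon = "AAA", freq = 1)
  expect_identical(generateCodonSequence(5, one, seed = 1), rep("AAA", 5))
  expect_identical(generateCodonSequence(0, one, seed = 1), character())
  expect_error(generateCodonSequence(5, data.frame(codon = "AAA", freq = 0)),
               "all-zero")

  tab <- codonFrequencies()
  seqs <- generateCodonSequence(1e5, tab, seed = 2)
  obs <- table(factor(seqs, levels = tab$codon))
  chi <- suppressWarnings(stats::chisq.test(obs, p = tab$freq))
  expect_gt(chi$p.value, 0.001)
})

test_that("pause efficiency maps to the entry rate and back", {
  expect_equal(pauseRate(150, 0.8), 600)
  expect_equal(pauseRate(150, 0.5), 150)
  expect_equal(pauseRate(150, 0), 0)
  expect_error(pauseRate(150, 1), "infinite")
  # competition recovers the efficiency
  k <- pauseRate(150, 0.8)
  expect_equal(k / (k + 150), 0.8)
})

test_that("the six reference models carry the stated pause sites", {
  b <- makeModel("B", seed = 1)
  expect_length(b@template@pauseSites, 1)
  expect_equal(b@template@pauseSites[[1]]@position, 500)
  expect_equal(b@template@pauseSites[[1]]@meanDuration, 47)
  expect_equal(b@template@pauseSites[[1]]@efficiency, 0.8)

  expect_length(makeModel("A", seed = 1)@template@pauseSites, 0)
  expect_equal(makeModel("C", seed = 1)@template@pauseSites[[1]]@position, 250)
  expect_equal(makeModel("D", seed = 1)@template@pauseSites[[1]]@position, 750)
  expect_equal(makeModel("E", seed = 1)@template@pauseSites[[1]]@meanDuration,
               23.5)
  expect_equal(makeModel("F", seed = 1)@template@pauseSites[[1]]@meanDuration,
               94)
  expect_error(makeModel("G"), "unknown model label")
})

test_that("the reaction system substitutes site rates at pause nucleotides", {
  b <- makeModel("B", seed = 1)
  sys <- buildReactionSystem(b@template, b@params)
  expect_equal(sys@pauseEntry[500], 600)
  expect_equal(sys@pauseMean[500], 47)
  expect_equal(sys@pauseEntry[499], b@params@kp)
  expect_equal(sys@pauseMean[499], b@params@taup)
  expect_equal(sys@activation[10], b@params@kaSlow)
  expect_equal(sys@activation[11], b@params@kaFast)

  bad <- b@template
  expect_error(geneTemplate(length = 300,
                            pauseSites = list(pauseSite(500))),
               "outside")
})

test_that("one elongating RNAP renders exactly 25 template positions unavailable", {
  fp <- rnapFootprint(500, modelParameters(), 1000)
  expect_length(fp, 25)
  expect_identical(fp, 488:512)
  # clipped at the template edge
  expect_length(rnapFootprint(5, modelParameters(), 1000), 17)
})

test_that("passage time matches the sum of exponential stage means", {
  # no pausing/arrest/editing/backstepping and no translation load
  p <- modelParameters(kp = 0, kar = 0, ked = 0, kpre = 0, kpyr = 0,
                       ktl = 0, nRnap = 1)
  tpl <- geneTemplate(seed = 5)
  tr <- simulateGene(geneModel(tpl, params = p, label = "bare"),
                     tEnd = 30000, seed = 6, recordPassages = TRUE)
  pa <- attr(tr, "passages")
  expect_gt(nrow(pa), 100)
  durations <- pa$end - pa$start
  expected <- sum(1 / ifelse(1:1000 <= 10, 30, 150)) + 999 / 150 + 1 / 2
  se <- stats::sd(durations) / sqrt(length(durations))
  expect_lt(abs(mean(durations) - expected), 3 * se + 0.05)
})

test_that("a pause site delays passages by the geometric pause load", {
  # with entry rate k = ka (1/eps - 1)^-1 the reversible pause channel is
  # re-entered until activation wins, so an unobstructed polymerase incurs
  # eps/(1-eps) pause episodes of mean tau on average: 4 x 47 s here
  base <- modelParameters(kp = 0, kar = 0, ked = 0, kpre = 0, kpyr = 0,
                          ktl = 0, nRnap = 1)
  tplA <- geneTemplate(seed = 7)
  tplB <- geneTemplate(pauseSites = list(pauseSite(500, 0.8, 47)), seed = 7)
  trA <- simulateGene(geneModel(tplA, params = base), tEnd = 30000,
                      seed = 8, recordPassages = TRUE)
  trB <- simulateGene(geneModel(tplB, params = base), tEnd = 80000,
                      seed = 9, recordPassages = TRUE)
  dA <- with(attr(trA, "passages"), end - start)
  dB <- with(attr(trB, "passages"), end - start)
  added <- mean(dB) - mean(dA)
  se <- sqrt(stats::var(dB) / length(dB) + stats::var(dA) / length(dA))
  expect_lt(abs(added - (0.8 / 0.2) * 47), 3 * se)
})

test_that("pause-entry fraction over the site recovers the efficiency", {
  b <- makeModel("B", seed = 1)
  res <- simulatePassages(b, n = 10000, seed = 3)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(res$fractionPaused - 0.8), 3 * se + 0.005)
})

test_that("molecule pools are conserved through a simulation", {
  m <- makeModel("B", seed = 21)
  tr <- simulateGene(m, tEnd = 5000, seed = 22)
  expect_true(all(tr$rna >= 0))
  expect_true(all(tr$protein >= 0))
  expect_true(all(diff(tr$proteinTotal) >= 0))
  # proteins produced minus degraded equals the current count
  expect_gte(tr$proteinTotal[nrow(tr)], tr$protein[nrow(tr)])
})

test_that("identical seed and model give identical trajectories", {
  m <- makeModel("B", codons = rep("AAA", 333), seed = 1)
  t1 <- simulateGene(m, tEnd = 2000, seed = 5)
  t2 <- simulateGene(m, tEnd = 2000, seed = 5)
  expect_identical(t1$rna, t2$rna)
  expect_identical(t1$proteinTotal, t2$proteinTotal)
})
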