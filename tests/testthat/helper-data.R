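# Shared simulated data sets, generated once per test run and reused across
# test files.  Scales are reduced relative to the full study (the full runs
# are 10 x 1,000,000 s); the methods vignette documents the reduced sizes.

.dataCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .dataCache)) {
    assign(name, force(expr), envir = .dataCache)
  }
  get(name, envir = .dataCache)
}

# model A and B at the detection scale: 2 replicates x 200,000 s, 1 Hz,
# burn-in 50,000 s
detectionData <- function() {
  cached("detection", {
    list(
      A = runExperiment(runConfig("A", replicates = 2, tEnd = 2e5,
                                  burnin = 5e4, seed = 41)),
      B = runExperiment(runConfig("B", replicates = 2, tEnd = 2e5,
                                  burnin = 5e4, seed = 42))
    )
  })
}

# six models x 4 replicates x 105,000 s (burn-in 5,000 s) plus feature
# tables: one per-replicate full-row table for clustering, one windowed
# table for the random-forest error
classificationData <- function() {
  cached("classification", {
    labs <- c("A", "B", "C", "D", "E", "F")
    sims <- lapply(seq_along(labs), function(i) {
      runExperiment(runConfig(labs[i], replicates = 4, tEnd = 105000,
                              burnin = 5000, seed = 3000 + i))
    })
    names(sims) <- labs
    fullRow <- do.call(rbind, lapply(labs, function(l) {
      v <- tsValues(sims[[l]]$rna)
      rows <- lapply(seq_len(nrow(v)), function(i) {
        featureVector(v[i, ], tsValues(sims[[l]]$protein)[i, ],
                      tsValues(sims[[l]]$cumulative)[i, ])
      })
      out <- data.frame(model = l, replicate = seq_len(nrow(v)))
      out[featureNames()] <- do.call(rbind, rows)
      out
    }))
    windowed <- do.call(rbind, lapply(seq_along(labs), function(i) {
      featureTable(sims[[labs[i]]]$rna, sims[[labs[i]]]$protein,
                   sims[[labs[i]]]$cumulative, nVectors = 16,
                   window = 50000, seed = 7000 + i)
    }))
    list(fullRow = fullRow, windowed = windowed)
  })
}

# cached reference feature sets over the locate grid, plus a generator for
# observed data sets with the pause at theta* = 500
locateGrid <- c(200, 350, 500, 650, 800)

locateReferenceSets <- function() {
  cached("locateRefs", {
    simulateReferenceSets(locateGrid, nRuns = 3, tEnd = 105000,
                          burnin = 5000, nVectors = 24, window = 25000,
                          seed = 501)
  })
}

locateObserved <- function(rep, position = 500, meanDuration = 47) {
  tpl <- geneTemplate(pauseSites = list(pauseSite(position, 0.8,
                                                  meanDuration)),
                      seed = 600 + rep + position)
  tr <- simulateGene(geneModel(tpl, label = "obs"), tEnd = 105000,
                     seed = 700 + rep + position)
  mats <- lapply(c("rna", "protein", "cumulative"), function(k) {
    truncateBurnin(assembleMatrix(list(tr), k, label = "obs"), 5000)
  })
  featureTable(mats[[1]], mats[[2]], mats[[3]], nVectors = 12,
               window = 25000, seed = 800 + rep + position)
}

# small fixtures
tinyFixture <- function() cached("tiny", makeFixture("tiny-AB", seed = 1))

calibrationFixture <- function() {
  cached("calibration", makeFixture("calibration", seed = 11))
}

splitRows <- function(m, rows, label) {
  new("TimeSeriesMatrix", kind = m@kind,
      values = tsValues(m)[rows, , drop = FALSE],
      sampleInterval = m@sampleInterval, burnin = m@burnin, label = label,
      seeds = m@seeds[rows])
}
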