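blobData <- function(n = 20, offset = 10, seed = 1) {
  withr::with_seed(seed, {
    m <- rbind(matrix(stats::rnorm(n * 2), ncol = 2),
               matrix(stats::rnorm(n * 2, mean = offset), ncol = 2))
  })
  data.frame(model = rep(c("one", "two"), each = n), f1 = m[, 1],
             f2 = m[, 2])
}

test_that("well-separated blobs are recovered exactly by the clustering", {
  d <- blobData()
  hc <- clusterFeatures(d)
  cl <- stats::cutree(hc, 2)
  expect_equal(length(unique(cl[d$model == "one"])), 1)
  expect_equal(length(unique(cl[d$model == "two"])), 1)
  expect_false(cl[1] == cl[nrow(d)])
})

test_that("duplicate points merge first at height zero", {
  d <- data.frame(f1 = c(1, 1, 5, 9), f2 = c(2, 2, 5, 9))
  hc <- clusterFeatures(d)
  expect_equal(hc$height[1], 0)
  expect_setequal(-hc$merge[1, ], c(1, 2))
})

test_that("McQuitty linkage averages the merged clusters' distances", {
  # points on a line: 0, 1, 10 (Manhattan); first merge {0,1} at height 1,
  # then d(C, {A,B}) = (10 + 9) / 2 = 9.5
  d <- data.frame(f1 = c(0, 1, 10))
  hc <- clusterFeatures(d)
  expect_setequal(-hc$merge[1, ], c(1, 2))
  expect_equal(hc$height, c(1, 9.5))
  expect_error(clusterFeatures(d[1, , drop = FALSE]), "at least two")
})

test_that("random forest error is near zero for separated classes and near
           chance for permuted labels", {
  d <- blobData(n = 30)
  r <- rfClassify(d, nTrees = 200, nBootstrap = 10, seed = 2)
  expect_lt(r@errorMean, 0.05)
  expect_gte(r@errorMean, 0)
  expect_gte(r@errorSd, 0)

  permuted <- d
  permuted$model <- withr::with_seed(3, sample(d$model))
  rp <- rfClassify(permuted, nTrees = 200, nBootstrap = 10, seed = 4)
  expect_gt(rp@errorMean, 0.3) # chance is 0.5 for two balanced classes
})

test_that("correlation p-value matrices are symmetric with an NA diagonal", {
  withr::with_seed(5, {
    m <- matrix(stats::rnorm(1000), 100)
  })
  colnames(m) <- paste0("f", 1:10)
  pm <- featureCorrelationPvalues(m)
  expect_true(all(is.na(diag(pm))))
  expect_equal(pm, t(pm))
  off <- pm[upper.tri(pm)]
  expect_lt(mean(off < 0.05), 0.15) # null uniformity

  m2 <- cbind(m, dup = m[, 1])
  expect_lt(featureCorrelationPvalues(m2)["f1", "dup"], 1e-20)
})
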