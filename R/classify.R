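featureMatrix <- function(features) {
  df <- as.data.frame(features)
  cols <- intersect(featureNames(), names(df))
  if (length(cols) == 0) {
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  as.matrix(df[cols])
}

#' Hierarchical clustering of feature vectors
#'
#' Agglomerative clustering with a Manhattan distance and McQuitty (WPGMA)
#' linkage, in which the distance from a new cluster to any other is the
#' unweighted mean of the two merged clusters' distances.  Inversions
#' (non-monotone merge heights) are possible under WPGMA and are not an
#' error.
#'
#' @param features data.frame from [featureTable()] (z-transform first) or
#'   a numeric matrix
#' @param metric distance metric (default "manhattan")
#' @param linkage linkage method (default "mcquitty")
#' @return an \code{\link[stats]{hclust}} tree; leaf labels are the model
#'   labels when present
#' @export
clusterFeatures <- function(features, metric = "manhattan",
                            linkage = "mcquitty") {
  m <- featureMatrix(features)
  if (nrow(m) < 2) stop("need at least two feature vectors to cluster")
  df <- as.data.frame(features)
  if ("model" %in% names(df)) {
    rownames(m) <- make.unique(as.character(df$model))
  }
  stats::hclust(stats::dist(m, method = metric), method = linkage)
}

#' Random-forest classification error
#'
#' Result of [rfClassify()]: the misclassification rate of feature vectors
#' into model classes, averaged over bootstrap data sets.
#'
#' @slot errorMean,errorSd mean and SD of the per-bootstrap error rate
#' @slot errors the individual bootstrap error rates
#' @slot nTrees,nBootstrap forest size and number of bootstrap data sets
#' @slot confusion aggregated confusion matrix over held-out predictions
#' @slot nRedraws bootstrap resamples redrawn because a class was missing
#' @export
setClass("ClassificationResult",
  representation(errorMean = "numeric", errorSd = "numeric",
                 errors = "numeric", nTrees = "numeric",
                 nBootstrap = "numeric", confusion = "table",
                 nRedraws = "numeric"),
  validity = function(object) {
    if (object@errorMean < 0 || object@errorMean > 1) {
      return("error rate must lie in [0, 1]")
    }
    if (object@errorSd < 0) return("error SD must be non-negative")
    TRUE
  }
)

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf(
    "Random-forest classification: error %.2f%% (+/- %.2f%% SD)\n",
    100 * object@errorMean, 100 * object@errorSd))
  cat(sprintf("  %d trees, %d bootstrap data sets",
              as.integer(object@nTrees), as.integer(object@nBootstrap)))
  if (object@nRedraws > 0) {
    cat(sprintf(", %d resample(s) redrawn", as.integer(object@nRedraws)))
  }
  cat("\n")
  invisible(object)
})

#' Random-forest classification of model feature vectors
#'
#' For each of \code{nBootstrap} bootstrap resamples of the feature table, a
#' random forest is trained on the resample and evaluated on the held-out
#' items (those not drawn into the resample); the misclassification rates
#' are averaged.  Resamples missing a class entirely are redrawn (and
#' counted).  Forest defaults beyond the tree count are the standard ones
#' (sqrt(V) variables tried per split, unlimited depth).
#'
#' @param features data.frame from [featureTable()] or numeric matrix
#' @param labels class label per row (default: the \code{model} column)
#' @param nTrees trees per forest (default 5,000)
#' @param nBootstrap bootstrap data sets (default 100)
#' @param seed integer seed
#' @return a [ClassificationResult-class]
#' @export
rfClassify <- function(features, labels = NULL, nTrees = 5000,
                       nBootstrap = 100, seed = randomSeed()) {
  m <- featureMatrix(features)
  if (is.null(labels)) {
    df <- as.data.frame(features)
    if (!"model" %in% names(df)) stop("no labels given and no model column")
    labels <- df$model
  }
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (any(table(y) < 2)) stop("need at least two vectors per class")
  n <- nrow(m)
  errors <- numeric(nBootstrap)
  nRedraws <- 0
  confusion <- table(factor(levels(y), levels = levels(y)),
                     factor(levels(y), levels = levels(y)))
  confusion[] <- 0
  withr::with_seed(seed, {
    for (b in seq_len(nBootstrap)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        held <- setdiff(seq_len(n), idx)
        if (nlevels(droplevels(y[idx])) == nlevels(y) && length(held) > 0) {
          break
        }
        nRedraws <- nRedraws + 1
      }
      fit <- randomForest::randomForest(m[idx, , drop = FALSE], y[idx],
                                        ntree = nTrees)
      pred <- stats::predict(fit, m[held, , drop = FALSE])
      errors[b] <- mean(pred != y[held])
      confusion <- confusion + table(y[held], pred)
    }
  })
  new("ClassificationResult", errorMean = mean(errors),
      errorSd = stats::sd(errors), errors = errors, nTrees = nTrees,
      nBootstrap = nBootstrap, confusion = confusion, nRedraws = nRedraws)
}

#' P-values of pairwise feature correlations
#'
#' Tests, for every pair of the 10 features, the null hypothesis of zero
#' Pearson correlation (two-sided t-transform test).  Predominantly
#' non-significant p-values indicate that the features carry complementary
#' information.  The diagonal is NA (self-correlation is not of interest);
#' constant features yield NA rows/columns and are reported in the
#' \code{constant} attribute.
#'
#' @param features data.frame from [featureTable()] or numeric matrix with
#'   at least 3 rows
#' @return symmetric matrix of p-values with NA diagonal
#' @export
featureCorrelationPvalues <- function(features) {
  m <- featureMatrix(features)
  if (nrow(m) < 3) stop("need at least three feature vectors")
  V <- ncol(m)
  out <- matrix(NA_real_, V, V, dimnames = list(colnames(m), colnames(m)))
  constant <- colnames(m)[apply(m, 2, stats::sd) == 0]
  for (i in seq_len(V - 1)) {
    for (j in (i + 1):V) {
      if (colnames(m)[i] %in% constant || colnames(m)[j] %in% constant) next
      p <- stats::cor.test(m[, i], m[, j])$p.value
      out[i, j] <- p
      out[j, i] <- p
    }
  }
  attr(out, "constant") <- constant
  out
}
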