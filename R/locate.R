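#' Overlap probability of two feature samples
#'
#' Estimates the densities of two univariate samples with Gaussian kernel
#' density estimators (Silverman's rule-of-thumb bandwidth per sample) and
#' integrates the pointwise minimum of the two estimates over a grid
#' spanning both samples plus three bandwidths (trapezoidal rule).  The
#' overlap is 1 for identical densities and approaches 0 for disjoint
#' supports; the result is clipped to [0, 1].
#'
#' @param f,g numeric samples with at least 5 points and positive spread
#' @param nGrid integration grid size (default 512)
#' @return overlap probability in [0, 1]
#' @examples
#' x <- rnorm(500)
#' densityOverlap(x, x) # ~1
#' @export
densityOverlap <- function(f, g, nGrid = 512) {
  stopifnot(length(f) >= 5, length(g) >= 5)
  if (stats::sd(f) == 0 || stats::sd(g) == 0) {
    stop("degenerate input: zero-spread sample")
  }
  .cpp_density_overlap(as.double(f), as.double(g), as.integer(nGrid))
}

#' Approximate log-likelihood of a candidate pause position
#'
#' The approximate likelihood of a candidate model M_theta given an observed
#' S x V feature table treats the V features as independent and identically
#' informative across the S samples: each feature contributes the overlap
#' probability between the observed feature density and the density of the
#' same feature under data simulated from M_theta, so that
#' \deqn{\log L(\theta | y) = S \sum_{j=1}^{V} \log p_j(\theta).}
#' Overlaps below \code{floorP} are floored before taking logs to keep
#' profiles comparable; features with zero raw overlap are reported in the
#' \code{zeroFeatures} attribute (the unfloored value would be -Inf).
#'
#' @param observed S x V matrix (or [featureTable()] data.frame) of observed
#'   feature values
#' @param simulated S' x V matrix (or data.frame) of feature values
#'   simulated under the candidate model
#' @param floorP overlap floor (default 1e-12)
#' @param nGrid integration grid size per overlap
#' @return the log-likelihood, with attributes \code{overlaps} (raw per-
#'   feature overlaps) and \code{zeroFeatures}
#' @export
approximateLogLikelihood <- function(observed, simulated, floorP = 1e-12,
                                     nGrid = 512) {
  obs <- featureMatrix(observed)
  sim <- featureMatrix(simulated)
  if (ncol(obs) != ncol(sim)) stop("feature dimensions differ")
  S <- nrow(obs)
  p <- vapply(seq_len(ncol(obs)), function(j) {
    densityOverlap(obs[, j], sim[, j], nGrid = nGrid)
  }, numeric(1))
  ll <- S * sum(log(pmax(p, floorP)))
  attr(ll, "overlaps") <- stats::setNames(p, colnames(obs))
  attr(ll, "zeroFeatures") <- colnames(obs)[p < floorP]
  ll
}

#' Likelihood profile over candidate pause positions
#'
#' @slot theta candidate pause positions (nucleotides)
#' @slot logLik per-position approximate log-likelihood
#' @slot lrl logarithmic relative likelihood, log L(theta) - log L(thetaHat)
#'   (0 at the maximum, negative elsewhere)
#' @slot thetaHat maximum-likelihood position (ties: smallest theta)
#' @slot bootSd bootstrap SD of the position estimate (NA until
#'   [bootstrapCI()] is run)
#' @slot ciLower,ciUpper bootstrap percentile confidence bounds
#' @slot level confidence level
#' @slot B bootstrap samples used
#' @export
setClass("LikelihoodProfile",
  representation(theta = "numeric", logLik = "numeric", lrl = "numeric",
                 thetaHat = "numeric", bootSd = "numeric",
                 ciLower = "numeric", ciUpper = "numeric", level = "numeric",
                 B = "numeric"),
  validity = function(object) {
    if (length(object@theta) != length(object@logLik)) {
      return("theta and logLik lengths differ")
    }
    if (length(object@lrl) && any(object@lrl > 1e-9)) {
      return("LRL must be <= 0 everywhere")
    }
    TRUE
  }
)

setMethod("show", "LikelihoodProfile", function(object) {
  cat(sprintf(
    "LikelihoodProfile over %d candidate positions [%g, %g]\n",
    length(object@theta), min(object@theta), max(object@theta)))
  cat(sprintf("  ML position estimate: %g nt\n", object@thetaHat))
  if (is.finite(object@bootSd)) {
    cat(sprintf("  bootstrap SD %.1f nt; %g%% CI [%g, %g] (B = %d)\n",
                object@bootSd, 100 * object@level, object@ciLower,
                object@ciUpper, as.integer(object@B)))
  }
  invisible(object)
})

#' Profile the approximate likelihood over a position grid
#'
#' Computes the approximate log-likelihood of the observed feature table
#' against cached simulated feature sets for each candidate pause position
#' and normalises to the logarithmic relative likelihood
#' LRL(theta) = log L(theta) - log L(thetaHat), which is 0 at the maximum.
#'
#' @param observed S x V observed feature table
#' @param referenceSets named list: candidate position -> simulated feature
#'   table (see [simulateReferenceSets()])
#' @param floorP overlap floor passed to [approximateLogLikelihood()]
#' @return a [LikelihoodProfile-class]
#' @export
profileLikelihood <- function(observed, referenceSets, floorP = 1e-12) {
  if (length(referenceSets) == 0) stop("empty candidate grid")
  theta <- as.numeric(names(referenceSets))
  if (anyNA(theta)) stop("referenceSets must be named by position")
  ord <- order(theta)
  theta <- theta[ord]
  referenceSets <- referenceSets[ord]
  ll <- vapply(referenceSets, function(sim) {
    as.numeric(approximateLogLikelihood(observed, sim, floorP = floorP))
  }, numeric(1))
  if (all(!is.finite(ll))) stop("estimation failed: all positions at -Inf")
  best <- which.max(ll) # ties resolve to the smallest theta
  new("LikelihoodProfile", theta = theta, logLik = unname(ll),
      lrl = unname(ll - ll[best]), thetaHat = theta[best],
      bootSd = NA_real_, ciLower = NA_real_, ciUpper = NA_real_,
      level = NA_real_, B = 0)
}

#' Bootstrap uncertainty of the pause-position estimate
#'
#' Resamples the observed feature rows with replacement \code{B} times and
#' recomputes the maximum-likelihood position against the cached simulated
#' feature sets (which are fixed, not re-simulated).  Returns the SD of the
#' bootstrap position distribution and the percentile confidence interval.
#'
#' @param observed S x V observed feature table
#' @param referenceSets named list of cached simulated feature sets per
#'   candidate position
#' @param B bootstrap samples (default 50,000)
#' @param level confidence level (default 0.95)
#' @param floorP overlap floor
#' @param nGrid integration grid size per overlap
#' @param seed integer seed
#' @return list with \code{sd}, \code{ci} (length-2 vector), \code{level},
#'   \code{B} and \code{thetaHats} (the bootstrap position draws)
#' @export
bootstrapCI <- function(observed, referenceSets, B = 50000, level = 0.95,
                        floorP = 1e-12, nGrid = 512, seed = randomSeed()) {
  if (length(referenceSets) == 0) stop("cache missing: no reference sets")
  if (B < 100) warning("B < 100 bootstrap samples gives unstable intervals")
  theta <- as.numeric(names(referenceSets))
  ord <- order(theta)
  theta <- theta[ord]
  referenceSets <- referenceSets[ord]
  obs <- featureMatrix(observed)
  refs <- lapply(referenceSets, featureMatrix)
  idx <- .cpp_overlap_bootstrap(obs, refs, as.integer(B), as.integer(nGrid),
                                floorP, as.double(seed))
  hats <- theta[idx]
  ci <- unname(stats::quantile(hats, c((1 - level) / 2, 1 - (1 - level) / 2)))
  list(sd = stats::sd(hats), ci = ci, level = level, B = B,
       thetaHats = hats)
}

#' Locate a pause site: profile plus bootstrap interval
#'
#' Convenience wrapper running [profileLikelihood()] and [bootstrapCI()]
#' and returning one completed [LikelihoodProfile-class].
#'
#' @inheritParams bootstrapCI
#' @export
locatePauseSite <- function(observed, referenceSets, B = 50000,
                            level = 0.95, floorP = 1e-12,
                            seed = randomSeed()) {
  prof <- profileLikelihood(observed, referenceSets, floorP = floorP)
  bs <- bootstrapCI(observed, referenceSets, B = B, level = level,
                    floorP = floorP, seed = seed)
  prof@bootSd <- bs$sd
  prof@ciLower <- bs$ci[1]
  prof@ciUpper <- bs$ci[2]
  prof@level <- level
  prof@B <- B
  prof
}

#' Simulate reference feature sets over a candidate position grid
#'
#' For each candidate position theta, builds a gene model with a single
#' sequence-dependent pause site at theta (given efficiency and mean
#' duration), simulates replicate expression runs, removes the burn-in, and
#' computes a feature table.  The resulting named list is the cached
#' reference against which observed data are profiled.
#'
#' @param positions candidate pause positions (nucleotides)
#' @param geneLength gene length (nt)
#' @param efficiency,meanDuration pause-site kinetics of the candidate
#'   models (defaults: the his-pause values 0.8 and 47 s)
#' @param params a [ModelParameters-class]
#' @param nRuns replicate runs per candidate position
#' @param tEnd simulated time per run (s)
#' @param burnin burn-in removed (s)
#' @param nVectors feature vectors per candidate position
#' @param window feature window length (samples; NULL = full row)
#' @param K correlation lags
#' @param seed integer seed
#' @return named list: position -> feature data.frame
#' @export
simulateReferenceSets <- function(positions, geneLength = 1000,
                                  efficiency = 0.8, meanDuration = 47,
                                  params = modelParameters(), nRuns = 2,
                                  tEnd = 55000, burnin = 5000,
                                  nVectors = 20, window = NULL, K = 300,
                                  seed = randomSeed()) {
  stopifnot(all(positions >= 1), all(positions <= geneLength))
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max,
                      length(positions) * (2 * nRuns + 1)),
           nrow = length(positions)))
  out <- list()
  for (k in seq_along(positions)) {
    label <- sprintf("theta%g", positions[k])
    # replicate runs differ in their (randomly generated) codon sequences
    runs <- lapply(seq_len(nRuns), function(r) {
      tpl <- geneTemplate(length = geneLength,
                          pauseSites = list(pauseSite(positions[k],
                                                      efficiency,
                                                      meanDuration)),
                          seed = seeds[k, 2 * r - 1])
      simulateGene(geneModel(tpl, params = params, label = label),
                   tEnd = tEnd, seed = seeds[k, 2 * r])
    })
    mats <- lapply(c("rna", "protein", "cumulative"), function(kind) {
      truncateBurnin(assembleMatrix(runs, kind, label = label),
                     t0 = burnin)
    })
    out[[as.character(positions[k])]] <-
      featureTable(mats[[1]], mats[[2]], mats[[3]], nVectors = nVectors,
                   window = window, K = K, seed = seeds[k, 2 * nRuns + 1])
  }
  out
}
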