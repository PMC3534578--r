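#' Windowed-mean profiles of a time-series matrix
#'
#' Draws \code{S} window means from an F x L count matrix: for each draw a
#' replicate row \code{i ~ unif(1:F)} and a window start
#' \code{Ls ~ unif(1:(L - deltaL))} are sampled (both endpoints inclusive),
#' and the mean of the \code{deltaL + 1} consecutive values starting at
#' \code{Ls} is recorded.  These profiles carry the information about the
#' mean molecule number that the pause-detection test compares between
#' models.
#'
#' @param matrix a [TimeSeriesMatrix-class]
#' @param deltaL window length parameter; each window spans
#'   \code{deltaL + 1} samples
#' @param S number of window means to draw
#' @param seed integer seed
#' @return numeric vector of \code{S} window means (a mean profile), with
#'   attributes \code{deltaL} and \code{S}
#' @export
sampleMeanProfile <- function(matrix, deltaL, S, seed = randomSeed()) {
  stopifnot(is(matrix, "TimeSeriesMatrix"), S >= 1)
  v <- matrix@values
  FF <- nrow(v)
  L <- ncol(v)
  if (deltaL >= L) stop("deltaL must be smaller than the series length L")
  out <- withr::with_seed(seed, {
    rows <- sample.int(FF, S, replace = TRUE)
    starts <- sample.int(L - deltaL, S, replace = TRUE)
    vapply(seq_len(S), function(s) {
      mean(v[rows[s], starts[s]:(starts[s] + deltaL)])
    }, numeric(1))
  })
  attr(out, "deltaL") <- deltaL
  attr(out, "S") <- S
  out
}

#' Population of p-values from repeated two-model comparisons
#'
#' @slot pvalues N p-values in [0, 1] (indeterminate tests excluded)
#' @slot nIndeterminate number of repetitions whose t-test was degenerate
#'   (zero variance in both profiles) and was excluded
#' @slot deltaL,S,N the procedure parameters
#' @slot labels the two model labels compared
#' @export
setClass("PValueSet",
  representation(pvalues = "numeric", nIndeterminate = "numeric",
                 deltaL = "numeric", S = "numeric", N = "numeric",
                 labels = "character"),
  validity = function(object) {
    if (length(object@pvalues) &&
        (min(object@pvalues) < 0 || max(object@pvalues) > 1)) {
      return("p-values must lie in [0, 1]")
    }
    TRUE
  }
)

setMethod("show", "PValueSet", function(object) {
  cat(sprintf("PValueSet: %s vs %s (deltaL=%d, S=%d, N=%d)\n",
              object@labels[1], object@labels[2], as.integer(object@deltaL),
              as.integer(object@S), as.integer(object@N)))
  cat(sprintf("  median p = %.4g; fraction below 0.05 = %.3f\n",
              stats::median(object@pvalues),
              mean(object@pvalues < 0.05)))
  if (object@nIndeterminate > 0) {
    cat(sprintf("  %d indeterminate repetition(s) excluded\n",
                as.integer(object@nIndeterminate)))
  }
  invisible(object)
})

#' Test for a difference in mean molecule numbers between two models
#'
#' The pause-presence detection procedure: \code{N} independent repetitions
#' of (i) drawing an \code{S}-long windowed-mean profile from each matrix
#' with [sampleMeanProfile()] and (ii) comparing the two profiles with a
#' Welch two-sample t-test of equal means.  The resulting p-value population
#' reflects how separable the two models are; a median p-value below the
#' significance level indicates a detectable difference (e.g. a
#' sequence-dependent pause site present in one model only).
#'
#' @param matrixM,matrixMprime two [TimeSeriesMatrix-class] objects of the
#'   same kind and sampling interval
#' @param deltaL window length parameter (window = deltaL + 1 samples)
#' @param S profile size (window means per profile)
#' @param N repetitions
#' @param seed integer seed
#' @return a [PValueSet-class]
#' @examples
#' \donttest{
#' pv <- compareModels(rnaA, rnaB, deltaL = 1000, S = 10, N = 50, seed = 7)
#' stats::median(pv@pvalues)
#' }
#' @export
compareModels <- function(matrixM, matrixMprime, deltaL, S, N,
                          seed = randomSeed()) {
  stopifnot(is(matrixM, "TimeSeriesMatrix"),
            is(matrixMprime, "TimeSeriesMatrix"))
  if (matrixM@kind != matrixMprime@kind) {
    stop("matrices must hold the same kind of counts")
  }
  if (matrixM@sampleInterval != matrixMprime@sampleInterval) {
    stop("matrices must share the sampling interval")
  }
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, 2 * N), ncol = 2))
  pvals <- numeric(0)
  nInd <- 0
  for (k in seq_len(N)) {
    pM <- sampleMeanProfile(matrixM, deltaL, S, seed = seeds[k, 1])
    pMp <- sampleMeanProfile(matrixMprime, deltaL, S, seed = seeds[k, 2])
    tt <- tryCatch(stats::t.test(pM, pMp), error = function(e) NULL)
    if (is.null(tt)) {
      nInd <- nInd + 1
    } else {
      pvals <- c(pvals, tt$p.value)
    }
  }
  new("PValueSet", pvalues = pvals, nIndeterminate = nInd, deltaL = deltaL,
      S = S, N = N,
      labels = c(matrixM@label, matrixMprime@label))
}
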