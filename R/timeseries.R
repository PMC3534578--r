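#' Replicate time-series matrices
#'
#' An F-by-L integer matrix of molecule counts: one row per replicate
#' simulation, one column per sample (1 s apart by default).  \code{kind}
#' records whether the matrix holds mRNA numbers, protein numbers, or the
#' cumulative number of proteins produced.
#'
#' @slot kind one of "rna", "protein", "cumulative"
#' @slot values F x L numeric matrix of non-negative counts
#' @slot sampleInterval sampling interval (s)
#' @slot burnin seconds already removed from the front of each row
#' @slot label model label
#' @slot seeds per-row simulation seeds
#' @export
setClass("TimeSeriesMatrix",
  representation(kind = "character", values = "matrix",
                 sampleInterval = "numeric", burnin = "numeric",
                 label = "character", seeds = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("rna", "protein", "cumulative")) {
      return("kind must be 'rna', 'protein' or 'cumulative'")
    }
    if (nrow(object@values) < 1 || ncol(object@values) < 2) {
      return("need at least one row and two columns")
    }
    if (any(object@values < 0)) return("counts must be non-negative")
    if (object@kind == "cumulative") {
      if (any(apply(object@values, 1, function(r) any(diff(r) < 0)))) {
        return("cumulative-protein rows must be non-decreasing")
      }
    }
    TRUE
  }
)

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat(sprintf(
    "TimeSeriesMatrix (%s, model %s): %d replicate(s) x %d samples @ %g s",
    object@kind, object@label, nrow(object@values), ncol(object@values),
    object@sampleInterval))
  cat(sprintf(", burn-in %g s removed\n", object@burnin))
  invisible(object)
})

#' @rdname TimeSeriesMatrix-class
#' @param x a [TimeSeriesMatrix-class]
#' @export
tsValues <- function(x) x@values

#' Assemble replicate trajectories into a matrix
#'
#' Stacks the chosen observable of several [simulateGene()] trajectories
#' into one F x L [TimeSeriesMatrix-class].  The cumulative kind uses the
#' running total of protein production events, not the instantaneous count.
#'
#' @param trajectories list of data.frames from [simulateGene()]
#' @param kind "rna", "protein" or "cumulative"
#' @param label model label recorded on the matrix
#' @return a [TimeSeriesMatrix-class]
#' @export
assembleMatrix <- function(trajectories, kind = c("rna", "protein",
                                                  "cumulative"),
                           label = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(trajectories) >= 1)
  lens <- vapply(trajectories, nrow, integer(1))
  if (length(unique(lens)) != 1) {
    stop("trajectories differ in length (ragged input)")
  }
  ivs <- vapply(trajectories, function(tr) {
    iv <- attr(tr, "sampleInterval")
    if (is.null(iv)) diff(tr$time[1:2]) else iv
  }, numeric(1))
  if (length(unique(ivs)) != 1) {
    stop("trajectories differ in sampling interval")
  }
  col <- switch(kind, rna = "rna", protein = "protein",
                cumulative = "proteinTotal")
  vals <- do.call(rbind, lapply(trajectories, function(tr) tr[[col]]))
  seeds <- vapply(trajectories, function(tr) {
    s <- attr(tr, "seed")
    if (is.null(s)) NA_real_ else as.numeric(s)
  }, numeric(1))
  if (is.null(label)) {
    label <- attr(trajectories[[1]], "label")
    if (is.null(label)) label <- "unknown"
  }
  new("TimeSeriesMatrix", kind = kind, values = vals,
      sampleInterval = ivs[1], burnin = 0, label = label, seeds = seeds)
}

#' Remove the initial transient
#'
#' Drops all columns sampled before \code{t0} seconds, after which the model
#' time series are treated as weakly stationary.
#'
#' @param matrix a [TimeSeriesMatrix-class]
#' @param t0 burn-in to remove (s); default 50,000 s
#' @return the truncated [TimeSeriesMatrix-class] with its burn-in offset
#'   recorded
#' @export
truncateBurnin <- function(matrix, t0 = 50000) {
  stopifnot(is(matrix, "TimeSeriesMatrix"))
  duration <- ncol(matrix@values) * matrix@sampleInterval
  if (t0 >= duration) stop("burn-in t0 must be smaller than the duration")
  if (t0 <= 0) return(matrix)
  drop <- floor(t0 / matrix@sampleInterval)
  matrix@values <- matrix@values[, -seq_len(drop), drop = FALSE]
  matrix@burnin <- matrix@burnin + drop * matrix@sampleInterval
  matrix
}

#' Weak-stationarity check by a two-sample t-test on ensemble means
#'
#' Samples \code{nSample} column (ensemble) means from an early window and
#' \code{nSample} from a late window of the series and compares them with a
#' Welch two-sample t-test.  The windows are the first and last thirds of
#' the span.  A high p-value is consistent with a stable mean; a strong
#' trend yields a small p-value.  Zero-variance windows make the test
#' indeterminate (reported as such, not as a pass).
#'
#' @param matrix a [TimeSeriesMatrix-class]
#' @param nSample ensemble-mean values drawn per window (default 10)
#' @param alpha significance level (default 0.05)
#' @param seed integer seed for the column draws
#' @return list with \code{status} ("pass", "fail" or "indeterminate"),
#'   \code{p.value}, and the sampled window means
#' @export
stationarityCheck <- function(matrix, nSample = 10, alpha = 0.05,
                              seed = randomSeed()) {
  stopifnot(is(matrix, "TimeSeriesMatrix"))
  v <- matrix@values
  L <- ncol(v)
  if (L < 2 * nSample) stop("need at least 2*nSample columns")
  third <- floor(L / 3)
  withr::with_seed(seed, {
    earlyCols <- sample.int(third, nSample, replace = third < nSample)
    lateCols <- L - third + sample.int(third, nSample,
                                       replace = third < nSample)
  })
  early <- colMeans(v[, earlyCols, drop = FALSE])
  late <- colMeans(v[, lateCols, drop = FALSE])
  tt <- tryCatch(stats::t.test(early, late), error = function(e) NULL)
  if (is.null(tt)) {
    return(list(status = "indeterminate", p.value = NA_real_,
                early = early, late = late))
  }
  list(status = if (tt$p.value > alpha) "pass" else "fail",
       p.value = tt$p.value, early = early, late = late)
}
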