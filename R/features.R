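#' Names of the 10 time-series features
#'
#' Order: mean and SD of the lag-weighted autocorrelation summary of the
#' mRNA and of the protein series (1-4), mean and SD of the lag-weighted
#' cross-correlation summary of (mRNA, protein) and of (protein, cumulative
#' protein) (5-8), and mean and SD of the mRNA decay times (9-10).
#'
#' @return character vector of length 10
#' @export
featureNames <- function() {
  c("m_acf_rna", "s_acf_rna", "m_acf_protein", "s_acf_protein",
    "m_ccf_rna_protein", "s_ccf_rna_protein",
    "m_ccf_protein_cumul", "s_ccf_protein_cumul",
    "m_decay_rna", "s_decay_rna")
}

#' Lag-l sample autocorrelation
#'
#' \deqn{r_{xx}(l) = \frac{\sum_{t=l+1}^{T}(x_t-\bar m)(x_{t-l}-\bar m)}
#'                        {\sum_{t=1}^{T}(x_t-\bar m)^2}}
#'
#' @param x numeric series of length T (variance must be positive)
#' @param lag integer lag, 0 <= lag < T-1
#' @return the autocorrelation estimate
#' @examples
#' autocorrLag(c(1, 2, 3, 4, 5), 1) # 0.4
#' @export
autocorrLag <- function(x, lag) {
  T <- length(x)
  if (lag < 0 || lag >= T - 1) stop("lag must satisfy 0 <= lag < T-1")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) stop("degenerate input: constant series has no autocorrelation")
  if (lag == 0) return(1)
  sum(xc[(lag + 1):T] * xc[1:(T - lag)]) / den
}

#' Lag-l sample cross-correlation
#'
#' \deqn{r_{xy}(l) = \frac{\sum_{t=l+1}^{T}(x_t-\bar m_x)(y_{t-l}-\bar m_y)}
#'   {\sqrt{\sum_t (x_t-\bar m_x)^2 \sum_t (y_t-\bar m_y)^2}}}
#'
#' @param x,y numeric series of equal length (both non-constant)
#' @param lag integer lag, 0 <= lag < T-1; \code{y} is the lagged series
#' @return the cross-correlation estimate
#' @export
crossCorrLag <- function(x, y, lag) {
  T <- length(x)
  stopifnot(length(y) == T)
  if (lag < 0 || lag >= T - 1) stop("lag must satisfy 0 <= lag < T-1")
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) stop("degenerate input: constant series has no cross-correlation")
  sum(xc[(lag + 1):T] * yc[1:(T - lag)]) / den
}

# correlation values at lags 1..K, computed in one vectorised pass
corrCurve <- function(x, y = NULL, K) {
  T <- length(x)
  if (T < K + 2) stop("series too short for K = ", K, " lags")
  xc <- x - mean(x)
  if (is.null(y)) {
    den <- sum(xc^2)
    if (den == 0) stop("degenerate input: constant series")
    yc <- xc
  } else {
    yc <- y - mean(y)
    den <- sqrt(sum(xc^2) * sum(yc^2))
    if (den == 0) stop("degenerate input: constant series")
  }
  vapply(seq_len(K), function(l) {
    sum(xc[(l + 1):T] * yc[1:(T - l)]) / den
  }, numeric(1))
}

#' Lag-weighted mean and SD of a correlation function
#'
#' Summarises a correlation function r(1..K) by the mean and standard
#' deviation of the lag-weighted values r(l) * l:
#' \deqn{m = \frac{1}{K}\sum_{l=1}^{K} r(l)\,l, \qquad
#'       s = \sqrt{\frac{1}{K-1}\sum_{l=1}^{K} (r(l)\,l - m)^2}.}
#' The multiplication by the lag emphasises slow correlation decay.
#'
#' @param r correlation values at lags 1..K (K >= 2)
#' @return named vector \code{c(m =, s =)}
#' @examples
#' corrSummary(c(0.5, 0.25, 0.125)) # m = 0.4583...
#' @export
corrSummary <- function(r) {
  K <- length(r)
  if (K < 2) stop("need at least K = 2 correlation values")
  w <- r * seq_len(K)
  c(m = mean(w), s = stats::sd(w))
}

#' Decay times of a count series
#'
#' The lengths of all maximal runs of consecutive time steps t at which
#' \code{x[t-1] >= x[t]} holds, i.e. for how long the count does not
#' increase.  A strictly increasing series has no decay runs (empty vector);
#' a constant series is one single run of length T-1.
#'
#' @param x numeric series of length >= 2
#' @return integer vector of run lengths (possibly empty)
#' @examples
#' decayTimes(c(5, 4, 4, 3, 6, 6, 5)) # 3 2
#' @export
decayTimes <- function(x) {
  stopifnot(length(x) >= 2)
  nonIncreasing <- x[-length(x)] >= x[-1]
  r <- rle(nonIncreasing)
  r$lengths[r$values]
}

#' The 10-feature vector of one replicate
#'
#' Assembles the feature vector from one (mRNA, protein, cumulative-protein)
#' row triple: lag-weighted autocorrelation summaries of the mRNA and
#' protein series, lag-weighted cross-correlation summaries of
#' (mRNA, protein) and (protein, cumulative protein), and the mean and SD of
#' the mRNA decay times.  An empty decay vector yields (0, 0) by convention;
#' the SD of a single decay run is 0.
#'
#' @param rnaRow,proteinRow,cumulativeRow numeric series of equal length
#'   (at least K + 2 samples)
#' @param K number of correlation lags (default 300)
#' @return named numeric vector of length 10, see [featureNames()]
#' @export
featureVector <- function(rnaRow, proteinRow, cumulativeRow, K = 300) {
  T <- length(rnaRow)
  stopifnot(length(proteinRow) == T, length(cumulativeRow) == T)
  if (T < K + 2) stop("rows must have at least K + 2 samples")
  tryFeature <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("degenerate input for feature ", what, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  accR <- tryFeature("autocorrelation(rna)",
                     corrSummary(corrCurve(rnaRow, K = K)))
  accP <- tryFeature("autocorrelation(protein)",
                     corrSummary(corrCurve(proteinRow, K = K)))
  ccRP <- tryFeature("cross-correlation(rna, protein)",
                     corrSummary(corrCurve(rnaRow, proteinRow, K = K)))
  ccPE <- tryFeature("cross-correlation(protein, cumulative)",
                     corrSummary(corrCurve(proteinRow, cumulativeRow, K = K)))
  d <- decayTimes(rnaRow)
  md <- if (length(d) == 0) 0 else mean(d)
  sd_ <- if (length(d) <= 1) 0 else stats::sd(d)
  stats::setNames(c(accR, accP, ccRP, ccPE, md, sd_), featureNames())
}

#' Feature vectors from replicate matrices
#'
#' Computes \code{nVectors} feature vectors from an (mRNA, protein,
#' cumulative-protein) matrix triple by drawing (row, window) pairs
#' uniformly at random: a replicate row and, if \code{window} is smaller
#' than the row, a window start.  With \code{window = NULL} each vector
#' uses a full stationary row.
#'
#' @param rna,protein,cumulative [TimeSeriesMatrix-class] triples of equal
#'   shape
#' @param nVectors number of feature vectors
#' @param window window length in samples (NULL = full row)
#' @param K correlation lags (default 300)
#' @param seed integer seed
#' @return data.frame: \code{model}, \code{replicate}, \code{start}, then
#'   the 10 feature columns
#' @export
featureTable <- function(rna, protein, cumulative, nVectors = 50,
                         window = NULL, K = 300, seed = randomSeed()) {
  stopifnot(is(rna, "TimeSeriesMatrix"), is(protein, "TimeSeriesMatrix"),
            is(cumulative, "TimeSeriesMatrix"))
  v <- rna@values
  stopifnot(all(dim(protein@values) == dim(v)),
            all(dim(cumulative@values) == dim(v)))
  L <- ncol(v)
  if (is.null(window)) window <- L
  if (window > L) stop("window longer than the series")
  if (window < K + 2) stop("window must be at least K + 2 samples")
  draws <- withr::with_seed(seed, {
    data.frame(row = sample.int(nrow(v), nVectors, replace = TRUE),
               start = if (window < L) {
                 sample.int(L - window + 1, nVectors, replace = TRUE)
               } else rep(1L, nVectors))
  })
  feats <- t(vapply(seq_len(nVectors), function(k) {
    i <- draws$row[k]
    cols <- draws$start[k]:(draws$start[k] + window - 1)
    featureVector(v[i, cols], protein@values[i, cols],
                  cumulative@values[i, cols], K = K)
  }, numeric(10)))
  out <- data.frame(model = rna@label, replicate = draws$row,
                    start = draws$start)
  out[featureNames()] <- feats
  out
}

#' Z-transform feature collections
#'
#' Centres and scales each feature column to sample mean 0 and sample
#' variance 1 (n-1 normalisation) across the collection, so that features
#' on different scales become comparable for clustering.
#'
#' @param features data.frame from [featureTable()] (or any data.frame /
#'   matrix whose feature columns are named as in [featureNames()]; absent
#'   that, all numeric columns are transformed)
#' @return the same structure with transformed feature columns
#' @export
zTransform <- function(features) {
  df <- as.data.frame(features)
  cols <- intersect(featureNames(), names(df))
  if (length(cols) == 0) {
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  if (nrow(df) < 2) stop("need at least two feature vectors")
  for (cn in cols) {
    s <- stats::sd(df[[cn]])
    if (!is.finite(s) || s == 0) {
      stop("feature '", cn, "' is constant across the collection")
    }
    df[[cn]] <- (df[[cn]] - mean(df[[cn]])) / s
  }
  df
}
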