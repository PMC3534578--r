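# Brute-force reference implementations, kept deliberately naive (explicit
# loops, no shared code with the package) so they can serve as independent
# oracles.

naiveAutocorr <- function(x, l) {
  T <- length(x)
  m <- sum(x) / T
  num <- 0
  for (t in (l + 1):T) num <- num + (x[t] - m) * (x[t - l] - m)
  den <- 0
  for (t in 1:T) den <- den + (x[t] - m)^2
  num / den
}

naiveCrosscorr <- function(x, y, l) {
  T <- length(x)
  mx <- sum(x) / T
  my <- sum(y) / T
  num <- 0
  for (t in (l + 1):T) num <- num + (x[t] - mx) * (y[t - l] - my)
  dx <- 0
  dy <- 0
  for (t in 1:T) {
    dx <- dx + (x[t] - mx)^2
    dy <- dy + (y[t] - my)^2
  }
  num / sqrt(dx * dy)
}

naiveCorrSummary <- function(r) {
  K <- length(r)
  m <- 0
  for (l in 1:K) m <- m + r[l] * l
  m <- m / K
  s <- 0
  for (l in 1:K) s <- s + (r[l] * l - m)^2
  c(m = m, s = sqrt(s / (K - 1)))
}

naiveDecayTimes <- function(x) {
  d <- integer(0)
  run <- 0L
  for (t in 2:length(x)) {
    if (x[t - 1] >= x[t]) {
      run <- run + 1L
    } else if (run > 0L) {
      d <- c(d, run)
      run <- 0L
    }
  }
  if (run > 0L) d <- c(d, run)
  d
}

naiveWindowMean <- function(row, start, deltaL) {
  s <- 0
  for (t in start:(start + deltaL)) s <- s + row[t]
  s / (deltaL + 1)
}

# Gaussian-KDE overlap on a much denser grid than the package uses, so
# agreement is numerical rather than definitional
naiveOverlap <- function(f, g, nGrid = 8192) {
  bwF <- stats::bw.nrd0(f)
  bwG <- stats::bw.nrd0(g)
  lo <- min(min(f) - 3 * bwF, min(g) - 3 * bwG)
  hi <- max(max(f) + 3 * bwF, max(g) + 3 * bwG)
  xs <- seq(lo, hi, length.out = nGrid)
  kde <- function(s, bw) {
    sapply(xs, function(x) mean(stats::dnorm((x - s) / bw)) / bw)
  }
  m <- pmin(kde(f, bwF), kde(g, bwG))
  sum((m[-1] + m[-nGrid]) / 2 * diff(xs))
}

# Plain direct-method SSA (no delays) for a reaction list given as
# stoichiometry matrices; returns the time of the last possible event.
referenceSsaAbsorptionTime <- function(init, reactMat, prodMat, rates) {
  x <- init
  t <- 0
  repeat {
    a <- rates
    for (i in seq_along(rates)) {
      for (s in seq_along(x)) {
        if (reactMat[i, s] > 0) {
          a[i] <- a[i] * prod(x[s] - seq_len(reactMat[i, s]) + 1)
        }
      }
      if (any(x - reactMat[i, ] < 0)) a[i] <- 0
    }
    a[a < 0] <- 0
    a0 <- sum(a)
    if (a0 <= 0) return(t)
    t <- t + stats::rexp(1, a0)
    i <- sample.int(length(rates), 1, prob = a)
    x <- x - reactMat[i, ] + prodMat[i, ]
  }
}
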