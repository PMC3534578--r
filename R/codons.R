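#' Bundled codon usage frequencies
#'
#' Relative codon usage for \emph{Escherichia coli} K-12 coding sequences
#' (occurrences per 1000 codons), bundled as a stand-in for a fresh GenBank
#' extraction.  Stop codons are present in the table but are excluded when
#' random coding sequences are generated.
#'
#' @param file optional path to a two-column TSV (codon, relative frequency)
#'   to use instead of the bundled table
#' @return data.frame with columns \code{codon} and \code{freq} (normalised
#'   to sum to 1 over sense codons)
#' @export
codonFrequencies <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "ecoli_codon_usage.tsv",
                        package = "pauseTrace", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  names(tab) <- c("codon", "freq")
  stops <- c("TAA", "TAG", "TGA")
  tab <- tab[!tab$codon %in% stops, ]
  if (nrow(tab) == 0 || any(tab$freq < 0) || sum(tab$freq) <= 0) {
    stop("codon table must have non-negative frequencies with positive sum")
  }
  tab$freq <- tab$freq / sum(tab$freq)
  tab
}

#' Generate a random codon sequence
#'
#' Codons are drawn i.i.d. with the probabilities given by the frequency
#' table, emulating a coding sequence with the host's codon usage statistics.
#'
#' @param nCodons number of codons
#' @param freqTable data.frame(codon, freq) as returned by
#'   [codonFrequencies()]
#' @param seed integer seed
#' @return character vector of \code{nCodons} codons
#' @export
generateCodonSequence <- function(nCodons, freqTable = codonFrequencies(),
                                  seed = randomSeed()) {
  stopifnot(nCodons >= 0)
  if (nrow(freqTable) == 0 || sum(freqTable$freq) <= 0) {
    stop("empty or all-zero codon frequency table")
  }
  if (any(freqTable$freq < 0)) stop("codon frequencies must be non-negative")
  if (nCodons == 0) return(character())
  withr::with_seed(seed,
    sample(freqTable$codon, nCodons, replace = TRUE,
           prob = freqTable$freq))
}

#' Codon translation-rate classes
#'
#' Assigns each sense codon to a translation rate class A (fast), B or C
#' (slow) used by the codon-activation step of the translation model.  The
#' default map splits codons into abundance terciles of the frequency table:
#' the most used third of codons translate fastest.  A user map (two-column
#' TSV codon, class) overrides the default.
#'
#' @param freqTable data.frame(codon, freq)
#' @param mapFile optional TSV path with columns codon and class (A/B/C)
#' @return named character vector: codon -> "A", "B" or "C"
#' @export
codonClasses <- function(freqTable = codonFrequencies(), mapFile = NULL) {
  if (!is.null(mapFile)) {
    m <- utils::read.delim(mapFile, stringsAsFactors = FALSE)
    names(m) <- c("codon", "class")
    if (!all(m$class %in% c("A", "B", "C"))) {
      stop("codon classes must be A, B or C")
    }
    return(stats::setNames(m$class, m$codon))
  }
  ord <- order(-freqTable$freq, freqTable$codon)
  n <- nrow(freqTable)
  cls <- character(n)
  third <- ceiling(n / 3)
  idxA <- ord[seq_len(third)]
  idxB <- ord[seq(third + 1, min(2 * third, n))]
  idxC <- setdiff(ord, c(idxA, idxB))
  cls[idxA] <- "A"
  cls[idxB] <- "B"
  cls[idxC] <- "C"
  stats::setNames(cls, freqTable$codon)
}
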