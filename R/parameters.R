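#' Kinetic parameters of the gene expression model
#'
#' Holds every rate constant of the transcription/translation reaction set,
#' the two footprint half-widths, and the free RNA polymerase and ribosome
#' pool sizes.  Defaults are the measured or literature-backed values of the
#' underlying model; see the methods vignette for a discussion of the pool
#' sizes, which set the induction level.
#'
#' Rates are in s^-1; delays in seconds.  Transcription: \code{ktc} promoter
#' binding, open-complex delay N(\code{tocMean}, \code{tocSd}^2), \code{km}
#' promoter clearance / stepwise elongation, nucleotide activation
#' \code{kaFast} (\code{kaSlow} for the first \code{kaBoundary} nucleotides),
#' ubiquitous pausing \code{kp} with mean duration \code{taup}, arrest
#' \code{kar}/\code{tauArrest}, editing \code{ked}/\code{dEdit}, premature
#' termination \code{kpre}, pyrophosphorolysis \code{kpyr}, termination
#' \code{kf}, mRNA degradation \code{kdr}.  Translation: initiation
#' \code{ktl}, codon-class activation \code{ktrA}/\code{ktrB}/\code{ktrC},
#' translocation \code{ktm}, back-translocation \code{kbt}, drop-off
#' \code{kdrop}, trans-translation \code{ktt}, completion \code{ktlf} with
#' folding delay N(\code{foldMean}, \code{foldSd}^2), protein degradation
#' \code{kdp}.  \code{deltaP} and \code{deltaR} are the RNAP and ribosome
#' footprint half-widths (an elongating RNAP occupies 2*deltaP+1 = 25
#' template nucleotides).
#'
#' @export
setClass("ModelParameters",
  representation(
    ktc = "numeric", tocMean = "numeric", tocSd = "numeric", km = "numeric",
    kaFast = "numeric", kaSlow = "numeric", kaBoundary = "numeric",
    kp = "numeric", taup = "numeric", kar = "numeric", tauArrest = "numeric",
    ked = "numeric", dEdit = "numeric", kpre = "numeric", kpyr = "numeric",
    kf = "numeric", kdr = "numeric", ktl = "numeric", ktrA = "numeric",
    ktrB = "numeric", ktrC = "numeric", ktm = "numeric", kbt = "numeric",
    kdrop = "numeric", ktt = "numeric", ktlf = "numeric",
    foldMean = "numeric", foldSd = "numeric", kdp = "numeric",
    deltaP = "numeric", deltaR = "numeric", nRnap = "numeric",
    nRib = "numeric"),
  validity = function(object) {
    for (s in slotNames(object)) {
      v <- slot(object, s)
      if (!is.finite(v) || v < 0) {
        return(sprintf("parameter '%s' must be finite and non-negative", s))
      }
    }
    if (object@nRnap < 1 || object@nRib < 1) {
      return("polymerase and ribosome pools must hold at least one molecule")
    }
    TRUE
  }
)

#' @rdname ModelParameters-class
#' @param ... named parameter overrides; see the class description for the
#'   slot names and meanings
#' @return a validated [ModelParameters-class]
#' @examples
#' p <- modelParameters()            # defaults
#' p2 <- modelParameters(ktt = 0)    # disable trans-translation
#' @export
modelParameters <- function(...) {
  defaults <- list(
    ktc = 0.0245, tocMean = 40, tocSd = 4, km = 150,
    kaFast = 150, kaSlow = 30, kaBoundary = 10,
    kp = 0.55, taup = 3, kar = 2.78e-4, tauArrest = 100,
    ked = 0.009, dEdit = 5, kpre = 1.9e-4, kpyr = 0.75,
    kf = 2, kdr = 0.025, ktl = 0.53, ktrA = 35, ktrB = 8, ktrC = 4.5,
    ktm = 10000, kbt = 1.5, kdrop = 1.14e-4, ktt = 2e-5, ktlf = 2,
    foldMean = 420, foldSd = 100, kdp = 0.0029,
    deltaP = 12, deltaR = 15, nRnap = 2, nRib = 20
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  do.call(new, c(list("ModelParameters"), defaults))
}

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters (gene expression kinetics)\n")
  cat(sprintf("  initiation: ktc=%g /s, open complex N(%g,%g^2) s\n",
              object@ktc, object@tocMean, object@tocSd))
  cat(sprintf("  elongation: km=%g, ka=%g (%g for first %d nt)\n",
              object@km, object@kaFast, object@kaSlow,
              as.integer(object@kaBoundary)))
  cat(sprintf("  ubiquitous pauses: kp=%g /s, mean %g s\n",
              object@kp, object@taup))
  cat(sprintf("  footprints: RNAP %d nt, ribosome half-width %d nt\n",
              as.integer(2 * object@deltaP + 1), as.integer(object@deltaR)))
  cat(sprintf("  pools: %d RNAP, %d ribosomes\n",
              as.integer(object@nRnap), as.integer(object@nRib)))
  invisible(object)
})

#' Sequence-dependent pause sites
#'
#' A pause site at nucleotide \code{position} replaces the ubiquitous pause
#' channel at that nucleotide.  Its entry rate is derived from the pause
#' efficiency \eqn{\epsilon} (the probability that an RNAP at the site
#' pauses rather than activates for elongation) by
#' \deqn{k_p^n = k_a(n) \, (1/\epsilon - 1)^{-1},}
#' so that the competition \eqn{k_p^n / (k_p^n + k_a(n))} equals
#' \eqn{\epsilon}.  The pause duration is exponential with mean
#' \code{meanDuration}.
#'
#' @slot position nucleotide index, 1-based from the transcription start site
#' @slot efficiency pausing probability in [0, 1)
#' @slot meanDuration mean pause duration (s)
#' @export
setClass("PauseSite",
  representation(position = "numeric", efficiency = "numeric",
                 meanDuration = "numeric"),
  validity = function(object) {
    if (object@position < 1 || object@position != round(object@position)) {
      return("position must be a positive integer nucleotide index")
    }
    if (object@efficiency < 0 || object@efficiency >= 1) {
      return("efficiency must lie in [0, 1)")
    }
    if (object@meanDuration <= 0) return("meanDuration must be positive")
    TRUE
  }
)

#' @rdname PauseSite-class
#' @param position nucleotide index (1-based)
#' @param efficiency pausing probability in [0, 1)
#' @param meanDuration mean pause duration in seconds
#' @export
pauseSite <- function(position, efficiency = 0.8, meanDuration = 47) {
  new("PauseSite", position = position, efficiency = efficiency,
      meanDuration = meanDuration)
}

setMethod("show", "PauseSite", function(object) {
  cat(sprintf(
    "PauseSite: nt %d, efficiency %.2f, mean duration %g s (exponential)\n",
    as.integer(object@position), object@efficiency, object@meanDuration))
  invisible(object)
})

#' Pause entry rate from efficiency
#'
#' Converts a pause efficiency into the entry rate that competes with the
#' activation rate at that nucleotide: \code{kA * (1/efficiency - 1)^-1}.
#' Zero efficiency gives rate 0; efficiency 1 would require an infinite rate
#' and is rejected.
#'
#' @param kA activation rate at the nucleotide (s^-1)
#' @param efficiency pausing probability in [0, 1)
#' @return pause entry rate (s^-1)
#' @examples
#' pauseRate(150, 0.8) # 600
#' @export
pauseRate <- function(kA, efficiency) {
  stopifnot(kA >= 0)
  if (efficiency < 0 || efficiency >= 1) {
    stop("efficiency must lie in [0, 1): efficiency 1 implies an infinite rate")
  }
  if (efficiency == 0) return(0)
  kA / (1 / efficiency - 1)
}

#' Per-nucleotide layout of one gene
#'
#' Couples the gene length, the (randomly generated or supplied) codon
#' sequence with its translation-rate classes, and the list of
#' sequence-dependent pause sites.  A gene of length not divisible by three
#' drops the final partial codon (a 1,000-nt gene translates 333 codons).
#'
#' @slot length gene length in nucleotides
#' @slot codons character vector of codons (length \code{floor(length/3)})
#' @slot rateClass character vector, "A"/"B"/"C" per codon
#' @slot pauseSites list of [PauseSite-class]
#' @slot codonFreq the codon frequency table used for generation
#' @export
setClass("GeneTemplate",
  representation(length = "numeric", codons = "character",
                 rateClass = "character", pauseSites = "list",
                 codonFreq = "data.frame"),
  validity = function(object) {
    if (object@length < 3) return("gene must be at least one codon long")
    if (length(object@codons) != floor(object@length / 3)) {
      return("codon sequence length must be floor(length/3)")
    }
    if (length(object@rateClass) != length(object@codons)) {
      return("one rate class per codon required")
    }
    if (!all(object@rateClass %in% c("A", "B", "C"))) {
      return("rate classes must be A, B or C")
    }
    for (ps in object@pauseSites) {
      if (!is(ps, "PauseSite")) return("pauseSites must hold PauseSite objects")
      if (ps@position > object@length) {
        return("pause site position outside the template")
      }
    }
    TRUE
  }
)

#' @rdname GeneTemplate-class
#' @param length gene length in nucleotides (default 1,000)
#' @param pauseSites list of [PauseSite-class] objects
#' @param codons optional fixed codon sequence; by default a fresh random
#'   sequence is generated from \code{freqTable}
#' @param freqTable codon frequency table, see [codonFrequencies()]
#' @param classMap named codon -> class vector, see [codonClasses()]
#' @param seed integer seed for sequence generation
#' @export
geneTemplate <- function(length = 1000, pauseSites = list(), codons = NULL,
                         freqTable = codonFrequencies(),
                         classMap = codonClasses(freqTable),
                         seed = randomSeed()) {
  nCodons <- floor(length / 3)
  if (is.null(codons)) {
    codons <- generateCodonSequence(nCodons, freqTable, seed = seed)
  }
  cls <- unname(classMap[codons])
  if (anyNA(cls)) {
    stop("codon(s) missing from the class map: ",
         paste(unique(codons[is.na(cls)]), collapse = ", "))
  }
  new("GeneTemplate", length = length, codons = codons, rateClass = cls,
      pauseSites = pauseSites, codonFreq = freqTable)
}

setMethod("show", "GeneTemplate", function(object) {
  cat(sprintf("GeneTemplate: %d nt, %d codons, %d pause site(s)\n",
              as.integer(object@length), length(object@codons),
              length(object@pauseSites)))
  for (ps in object@pauseSites) show(ps)
  invisible(object)
})

#' A gene model: template plus kinetic parameters
#'
#' @slot label model label ("A".."F" for the reference configurations, or a
#'   free-form name)
#' @slot template a [GeneTemplate-class]
#' @slot params a [ModelParameters-class]
#' @export
setClass("GeneModel",
  representation(label = "character", template = "GeneTemplate",
                 params = "ModelParameters"))

#' @rdname GeneModel-class
#' @param template a [GeneTemplate-class]
#' @param params a [ModelParameters-class]
#' @param label model label
#' @export
geneModel <- function(template, params = modelParameters(), label = "custom") {
  new("GeneModel", label = label, template = template, params = params)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s'\n", object@label))
  show(object@template)
  invisible(object)
})

#' The six reference models A-F
#'
#' Builds the gene model configurations used throughout the pause-detection
#' study.  All models are 1,000 nt long with ubiquitous pauses (rate 0.55
#' s^-1, mean 3 s) at every nucleotide; they differ in the single
#' sequence-dependent pause site:
#' \describe{
#'   \item{A}{no sequence-dependent pause site (null model)}
#'   \item{B}{site at nucleotide 500, efficiency 0.8, mean duration 47 s}
#'   \item{C}{as B but at nucleotide 250}
#'   \item{D}{as B but at nucleotide 750}
#'   \item{E}{site at 500 with mean duration 23.5 s}
#'   \item{F}{site at 500 with mean duration 94 s}
#' }
#'
#' @param label one of "A".."F"
#' @param length gene length in nucleotides
#' @param params a [ModelParameters-class]
#' @param codons optional fixed codon sequence (by default regenerated per
#'   call, as replicate instances differ in their codon sequences)
#' @param seed integer seed for codon sequence generation
#' @return a [GeneModel-class]
#' @examples
#' b <- makeModel("B", seed = 1)
#' b@template@pauseSites[[1]]
#' @export
makeModel <- function(label, length = 1000, params = modelParameters(),
                      codons = NULL, seed = randomSeed()) {
  sites <- switch(label,
    A = list(),
    B = list(pauseSite(500, 0.8, 47)),
    C = list(pauseSite(250, 0.8, 47)),
    D = list(pauseSite(750, 0.8, 47)),
    E = list(pauseSite(500, 0.8, 23.5)),
    F = list(pauseSite(500, 0.8, 94)),
    stop("unknown model label: ", label)
  )
  sites <- lapply(sites, function(ps) {
    if (ps@position > length) ps@position <- round(ps@position / 1000 * length)
    ps
  })
  tpl <- geneTemplate(length = length, pauseSites = sites, codons = codons,
                      seed = seed)
  geneModel(tpl, params = params, label = label)
}
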