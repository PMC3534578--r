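#' Expand a gene template into its reaction system
#'
#' Lays out the full transcription/translation channel set for one gene:
#' promoter binding with the open-complex delay, clearance, per-nucleotide
#' activation and elongation, pausing (with the efficiency-derived entry
#' rate substituted at sequence-dependent sites), collision-mediated pause
#' release/induction, arrest, editing, premature termination,
#' pyrophosphorolysis, termination, mRNA degradation, and the codon-level
#' translation machinery.  The returned object carries both a summary
#' channel table and the flat per-nucleotide rate vectors consumed by the
#' simulation kernel.
#'
#' @param template a [GeneTemplate-class]
#' @param params a [ModelParameters-class]
#' @return a \code{ReactionSystem} object
#' @export
buildReactionSystem <- function(template, params = modelParameters()) {
  validObject(template)
  validObject(params)
  L <- as.integer(template@length)
  ka <- ifelse(seq_len(L) <= params@kaBoundary, params@kaSlow, params@kaFast)

  pauseEntry <- rep(params@kp, L)
  pauseMean <- rep(params@taup, L)
  for (ps in template@pauseSites) {
    if (ps@position > L) stop("pause site outside the template")
    n <- as.integer(ps@position)
    pauseEntry[n] <- pauseRate(ka[n], ps@efficiency)
    pauseMean[n] <- ps@meanDuration
  }

  ktrCodon <- c(A = params@ktrA, B = params@ktrB,
                C = params@ktrC)[template@rateClass]

  channels <- data.frame(
    reaction = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 19,
                 20, 21, 22, 23),
    description = c(
      "promoter binding + open complex delay", "promoter clearance",
      "nucleotide activation", "stepwise elongation",
      "pause entry/exit (ubiquitous or site)", "collision pause release",
      "collision pause induction", "arrest/unarrest", "editing excursion",
      "premature termination", "pyrophosphorolysis", "termination",
      "mRNA degradation", "translation initiation",
      "ribonucleotide activation (codon class)", "three-stage translocation",
      "back-translocation", "ribosome drop-off", "trans-translation",
      "translation completion + folding delay", "protein degradation"),
    instances = c(1, 1, L, L - 1, L, L, L, L, L, L, L, 1, 1, 1,
                  length(template@codons), length(template@codons),
                  length(template@codons), length(template@codons), 1,
                  1, 1),
    rate = c(params@ktc, params@km, NA, params@km, NA, 0.8 * params@km,
             0.2 * params@km, params@kar, params@ked, params@kpre,
             params@kpyr, params@kf, params@kdr, params@ktl, NA, params@ktm,
             params@kbt, params@kdrop, params@ktt, params@ktlf, params@kdp)
  )

  new("ReactionSystem", geneLength = L, channels = channels,
      activation = ka, pauseEntry = pauseEntry, pauseMean = pauseMean,
      ktrCodon = unname(ktrCodon), template = template, params = params)
}

#' @rdname buildReactionSystem
#' @slot geneLength gene length (nt)
#' @slot channels summary table of reaction families
#' @slot activation per-nucleotide activation rate k_a(n)
#' @slot pauseEntry per-nucleotide pause entry rate (site rates substituted)
#' @slot pauseMean per-nucleotide mean pause duration (s)
#' @slot ktrCodon per-codon activation rate
#' @slot template the source [GeneTemplate-class]
#' @slot params the source [ModelParameters-class]
#' @export
setClass("ReactionSystem",
  representation(geneLength = "integer", channels = "data.frame",
                 activation = "numeric", pauseEntry = "numeric",
                 pauseMean = "numeric", ktrCodon = "numeric",
                 template = "GeneTemplate", params = "ModelParameters"))

setMethod("show", "ReactionSystem", function(object) {
  cat(sprintf("ReactionSystem: gene of %d nt, %d codons\n",
              object@geneLength, length(object@ktrCodon)))
  print(object@channels[, c("reaction", "description", "instances")],
        row.names = FALSE)
  invisible(object)
})

kernelParams <- function(params) {
  list(ktc = params@ktc, tocMean = params@tocMean, tocSd = params@tocSd,
       km = params@km, kaSlow = params@kaSlow, kaFast = params@kaFast,
       kaBoundary = as.integer(params@kaBoundary), kar = params@kar,
       tauArrest = params@tauArrest, ked = params@ked, dEdit = params@dEdit,
       kpre = params@kpre, kpyr = params@kpyr, kf = params@kf,
       kdr = params@kdr, ktl = params@ktl, ktm = params@ktm,
       kbt = params@kbt, kdrop = params@kdrop, ktt = params@ktt,
       ktlf = params@ktlf, foldMean = params@foldMean,
       foldSd = params@foldSd, kdp = params@kdp,
       deltaP = as.integer(params@deltaP), deltaR = as.integer(params@deltaR),
       nRnap = params@nRnap, nRib = params@nRib)
}

#' Simulate gene expression for one gene model
#'
#' Runs the nucleotide/codon-resolution delayed stochastic simulation of the
#' model and samples, at fixed intervals, the number of intact mRNA
#' molecules (nascent transcripts under elongation plus completed
#' transcripts — what a single-molecule RNA tag reports), the protein count,
#' and the cumulative number of proteins produced.
#'
#' @param model a [GeneModel-class] (or a [ReactionSystem-class])
#' @param tEnd simulated time (s)
#' @param sampleInterval sampling interval (s), default 1 s
#' @param seed integer seed; same seed and model give an identical trajectory
#' @param recordPassages if TRUE, also record the initiation and termination
#'   times of every completed transcript
#' @return data.frame with columns \code{time}, \code{rna}, \code{protein},
#'   \code{proteinTotal}; attributes \code{seed}, \code{label},
#'   \code{nEvents}, \code{nCompleted}, \code{nPremature} and (if requested)
#'   \code{passages}
#' @examples
#' \donttest{
#' m <- makeModel("B", seed = 1)
#' tr <- simulateGene(m, tEnd = 2000, seed = 1)
#' }
#' @export
simulateGene <- function(model, tEnd, sampleInterval = 1,
                         seed = randomSeed(), recordPassages = FALSE) {
  sys <- if (is(model, "ReactionSystem")) {
    model
  } else {
    buildReactionSystem(model@template, model@params)
  }
  label <- if (is(model, "GeneModel")) model@label else "custom"
  stopifnot(tEnd > 0, sampleInterval > 0)
  res <- .cpp_gene_sim(sys@geneLength, sys@ktrCodon, sys@pauseEntry,
                       sys@pauseMean, kernelParams(sys@params),
                       tEnd, sampleInterval, as.double(seed), recordPassages)
  out <- as.data.frame(res$samples)
  attr(out, "seed") <- seed
  attr(out, "label") <- label
  attr(out, "nEvents") <- res$nEvents
  attr(out, "nCompleted") <- res$nCompleted
  attr(out, "nPremature") <- res$nPremature
  attr(out, "sampleInterval") <- sampleInterval
  if (recordPassages) {
    attr(out, "passages") <- data.frame(start = res$passageStart,
                                        end = res$passageEnd)
  }
  out
}

#' Template positions occupied by one elongating RNAP
#'
#' Evaluates the kernel's footprint-exclusion rule for a single polymerase:
#' the set of template positions unavailable to any other polymerase.
#'
#' @param position RNAP position (active-site nucleotide)
#' @param params a [ModelParameters-class]
#' @param geneLength template length (nt)
#' @return integer vector of occupied positions
#' @examples
#' length(rnapFootprint(500, modelParameters(), 1000)) # 25
#' @export
rnapFootprint <- function(position, params = modelParameters(),
                          geneLength = 1000) {
  .cpp_rnap_footprint(as.integer(position), as.integer(params@deltaP),
                      as.integer(geneLength))
}

#' Pause duration distribution of a site or model
#'
#' The release delay of a paused polymerase is exponential with the site's
#' mean duration.  For a [GeneModel-class] the first sequence-dependent
#' pause site is used; models without a site have no sequence-dependent
#' distribution and raise an error.
#'
#' @param x a [PauseSite-class] or [GeneModel-class]
#' @return a [DelayDistribution-class] (exponential)
#' @export
pauseDurationDistribution <- function(x) {
  if (is(x, "GeneModel")) {
    if (length(x@template@pauseSites) == 0) {
      stop("model '", x@label, "' has no sequence-dependent pause site")
    }
    x <- x@template@pauseSites[[1]]
  }
  stopifnot(is(x, "PauseSite"))
  delayExponential(x@meanDuration)
}

#' @rdname pauseDurationDistribution
#' @param params a [ModelParameters-class]
#' @export
ubiquitousPauseDistribution <- function(params = modelParameters()) {
  delayExponential(params@taup)
}

#' Single-RNAP passages over a pause site
#'
#' Simulates independent arrivals of a single unobstructed RNAP at the
#' model's sequence-dependent pause nucleotide and records whether it enters
#' the paused state before activating for elongation.  The race at the
#' nucleotide is between pause entry (rate from the site efficiency),
#' activation, pyrophosphorolysis and premature termination; arrest and
#' editing excursions return the polymerase to the same state and therefore
#' leave the race unchanged.
#'
#' @param model a [GeneModel-class] with at least one pause site
#' @param n number of independent passages
#' @param seed integer seed
#' @return list with \code{fractionPaused}, \code{n} and the per-channel
#'   outcome counts
#' @export
simulatePassages <- function(model, n = 10000, seed = randomSeed()) {
  stopifnot(is(model, "GeneModel"), n >= 1)
  if (length(model@template@pauseSites) == 0) {
    stop("model has no sequence-dependent pause site")
  }
  ps <- model@template@pauseSites[[1]]
  p <- model@params
  ka <- if (ps@position <= p@kaBoundary) p@kaSlow else p@kaFast
  kpn <- pauseRate(ka, ps@efficiency)
  rates <- c(pause = kpn, activate = ka, pyrophosphorolysis = p@kpyr,
             prematureTermination = p@kpre)
  outcomes <- withr::with_seed(seed,
    sample(names(rates), n, replace = TRUE, prob = rates))
  counts <- table(factor(outcomes, levels = names(rates)))
  list(fractionPaused = unname(counts["pause"]) / n, n = n,
       outcomes = counts)
}
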