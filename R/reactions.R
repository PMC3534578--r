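#' Mass-action reactions with delayed product release
#'
#' A \code{DelayedReaction} couples a mass-action propensity (rate constant
#' times the product of reactant counts, falling factorials for stoichiometry
#' above one) with two product sets: instantaneous products, added the moment
#' the reaction fires, and delayed products, placed on a waiting list and
#' released after a draw from their [DelayDistribution-class].  An optional
#' guard restricts firing to states where given species counts lie within
#' bounds (used for occupancy-dependent channels).
#'
#' @slot name identifier used in printouts
#' @slot reactants named integer vector of reactant stoichiometries
#' @slot products named integer vector of instantaneous product
#'   stoichiometries
#' @slot delayed list of \code{list(species=, count=, delay=)} entries
#' @slot rate mass-action rate constant (per second, per molecule pairing as
#'   the order demands)
#' @slot guards data.frame with columns \code{species}, \code{min},
#'   \code{max}; the reaction has zero propensity unless every guard species
#'   count lies in its closed interval
#' @export
setClass("DelayedReaction",
  representation(name = "character", reactants = "numeric",
                 products = "numeric", delayed = "list", rate = "numeric",
                 guards = "data.frame"),
  validity = function(object) {
    if (!is.finite(object@rate) || object@rate < 0) {
      return("rate constant must be finite and non-negative")
    }
    if (length(object@reactants) && is.null(names(object@reactants))) {
      return("reactants must be a named vector")
    }
    if (length(object@products) && is.null(names(object@products))) {
      return("products must be a named vector")
    }
    for (d in object@delayed) {
      if (!all(c("species", "count", "delay") %in% names(d))) {
        return("each delayed product needs species, count and delay")
      }
      if (!is(d$delay, "DelayDistribution")) {
        return("delayed product delay must be a DelayDistribution")
      }
    }
    TRUE
  }
)

#' Construct a delayed reaction
#'
#' @param rate mass-action rate constant
#' @param reactants named numeric vector (species -> stoichiometry); empty
#'   for a zeroth-order source
#' @param products named numeric vector of instantaneous products
#' @param delayed list of \code{delayedProduct()} entries
#' @param guards optional data.frame(species, min, max)
#' @param name reaction label
#' @return a [DelayedReaction-class]
#' @examples
#' # A -> B + C(tau = 5 s)
#' delayedReaction(1, c(A = 1), c(B = 1),
#'                 delayed = list(delayedProduct("C", 1, delayPoint(5))))
#' @export
delayedReaction <- function(rate, reactants = numeric(), products = numeric(),
                            delayed = list(), guards = NULL,
                            name = "reaction") {
  if (is.null(guards)) {
    guards <- data.frame(species = character(), min = numeric(),
                         max = numeric())
  }
  new("DelayedReaction", name = name, reactants = reactants,
      products = products, delayed = delayed, rate = rate, guards = guards)
}

#' @rdname delayedReaction
#' @param species species name receiving the delayed product
#' @param count copies released per firing
#' @param delay a [DelayDistribution-class]
#' @export
delayedProduct <- function(species, count, delay) {
  list(species = species, count = count, delay = delay)
}

setMethod("show", "DelayedReaction", function(object) {
  lhs <- if (length(object@reactants)) {
    paste(sprintf("%s%s", ifelse(object@reactants > 1, object@reactants, ""),
                  names(object@reactants)), collapse = " + ")
  } else "0"
  rhs <- c(
    if (length(object@products)) {
      sprintf("%s%s", ifelse(object@products > 1, object@products, ""),
              names(object@products))
    },
    vapply(object@delayed, function(d) {
      sprintf("%s(tau~%s)", d$species, d$delay@kind)
    }, character(1))
  )
  cat(sprintf("%s: %s -> %s  [rate %g]\n", object@name, lhs,
              if (length(rhs)) paste(rhs, collapse = " + ") else "0",
              object@rate))
  invisible(object)
})

#' Simulation state of a delayed-SSA run
#'
#' Species counts, current time, and the waiting list of pending delayed
#' releases.
#'
#' @slot counts named numeric vector of species copy numbers
#' @slot time current simulation time (s)
#' @slot waiting data.frame with columns \code{time}, \code{species},
#'   \code{count}: products pending release
#' @slot status one of \code{"ok"}, \code{"exhausted"} (no reaction can fire
#'   and the waiting list is empty), \code{"completed"}
#' @export
setClass("SimState",
  representation(counts = "numeric", time = "numeric", waiting = "data.frame",
                 status = "character"),
  validity = function(object) {
    if (any(object@counts < 0)) return("species counts must be non-negative")
    if (nrow(object@waiting) &&
        any(object@waiting$time < object@time - 1e-9)) {
      return("waiting-list release times must not precede current time")
    }
    TRUE
  }
)

#' @rdname SimState-class
#' @param counts named numeric vector of initial copy numbers
#' @export
simState <- function(counts) {
  new("SimState", counts = counts, time = 0,
      waiting = data.frame(time = numeric(), species = character(),
                           count = numeric()),
      status = "ok")
}

setMethod("show", "SimState", function(object) {
  cat(sprintf("SimState at t = %g s (%s)\n", object@time, object@status))
  print(object@counts)
  if (nrow(object@waiting)) {
    cat(sprintf("%d pending delayed release(s)\n", nrow(object@waiting)))
  }
  invisible(object)
})

# Lower an R-level reaction list to the flat integer representation the C++
# engine consumes.  speciesNames fixes the index space.
lowerReactions <- function(reactions, speciesNames) {
  idx <- function(sp) {
    i <- match(sp, speciesNames)
    if (anyNA(i)) stop("unknown species: ", paste(sp[is.na(i)], collapse = ", "))
    i - 1L
  }
  lapply(reactions, function(r) {
    validObject(r)
    del <- r@delayed
    list(
      reactIdx = idx(names(r@reactants)),
      reactStoich = as.integer(r@reactants),
      prodIdx = idx(names(r@products)),
      prodStoich = as.integer(r@products),
      delIdx = if (length(del)) idx(vapply(del, `[[`, "", "species")) else integer(),
      delCount = vapply(del, function(d) as.integer(d$count), integer(1)),
      delKind = vapply(del, function(d) delayKindCode(d$delay), integer(1)),
      delP1 = vapply(del, function(d) d$delay@p1, numeric(1)),
      delP2 = vapply(del, function(d) d$delay@p2, numeric(1)),
      rate = r@rate,
      guardIdx = idx(r@guards$species),
      guardMin = as.numeric(r@guards$min),
      guardMax = as.numeric(r@guards$max)
    )
  })
}

speciesUniverse <- function(reactions, init) {
  nm <- names(init)
  for (r in reactions) {
    nm <- union(nm, names(r@reactants))
    nm <- union(nm, names(r@products))
    nm <- union(nm, vapply(r@delayed, `[[`, "", "species"))
    nm <- union(nm, r@guards$species)
  }
  nm
}

#' Simulate a delayed stochastic reaction network
#'
#' Exact stochastic simulation (direct method) extended with a waiting list:
#' delayed products are enqueued with a sampled release time and injected
#' when that time is reached.  When a reaction firing and a release fall at
#' the same instant the release is processed first.  Sampling takes the state
#' after all events with event time at or before the sample time.
#'
#' @param reactions list of [DelayedReaction-class] objects
#' @param init named numeric vector of initial copy numbers; species that
#'   appear only in reactions start at 0
#' @param tEnd end time (s)
#' @param sampleInterval sampling interval (s)
#' @param observables character vector of species to record (default: all)
#' @param seed integer seed; identical seed and configuration give a
#'   bit-identical trajectory
#' @return matrix with a \code{time} column and one integer column per
#'   observable, sampled at 0, `sampleInterval`, ...; attributes
#'   \code{status}, \code{nEvents}, \code{finalState} and \code{seed}
#' @examples
#' bd <- list(
#'   delayedReaction(5, products = c(X = 1), name = "birth"),
#'   delayedReaction(0.1, reactants = c(X = 1), name = "death")
#' )
#' tr <- simulateReactions(bd, c(X = 0), tEnd = 100, seed = 1)
#' @export
simulateReactions <- function(reactions, init, tEnd, sampleInterval = 1,
                              observables = NULL, seed = randomSeed()) {
  stopifnot(tEnd > 0, sampleInterval > 0)
  allSp <- speciesUniverse(reactions, init)
  counts <- stats::setNames(numeric(length(allSp)), allSp)
  counts[names(init)] <- init
  if (is.null(observables)) observables <- allSp
  low <- lowerReactions(reactions, allSp)
  res <- .cpp_ssa_run(counts, low, tEnd, sampleInterval,
                      match(observables, allSp) - 1L, as.double(seed), 0,
                      list())
  out <- res$samples
  colnames(out) <- c("time", observables)
  attr(out, "status") <- res$status
  attr(out, "nEvents") <- res$nEvents
  attr(out, "finalState") <- stats::setNames(res$state, allSp)
  attr(out, "seed") <- seed
  out
}

#' Advance a delayed-SSA state by a number of events
#'
#' Fires reactions / processes waiting-list releases one at a time, starting
#' from an explicit [SimState-class].  If no reaction has positive propensity
#' and the waiting list is empty the state is returned unchanged with status
#' \code{"exhausted"}.
#'
#' @param state a [SimState-class]
#' @param reactions list of [DelayedReaction-class]
#' @param nEvents number of events to process
#' @param seed integer seed for this step's random draws
#' @return the updated [SimState-class]
#' @export
ssaStep <- function(state, reactions, nEvents = 1, seed = randomSeed()) {
  stopifnot(is(state, "SimState"))
  allSp <- speciesUniverse(reactions, state@counts)
  counts <- stats::setNames(numeric(length(allSp)), allSp)
  counts[names(state@counts)] <- state@counts
  low <- lowerReactions(reactions, allSp)
  w <- state@waiting
  waiting <- if (nrow(w)) {
    list(w$time - state@time, match(w$species, allSp) - 1L,
         as.integer(w$count))
  } else {
    list(numeric(), integer(), integer())
  }
  res <- .cpp_ssa_run(counts, low, .Machine$double.xmax, 0, integer(),
                      as.double(seed), as.double(nEvents), waiting)
  status <- if (res$status == "exhausted") "exhausted" else "ok"
  new("SimState",
      counts = stats::setNames(res$state, allSp),
      time = state@time + res$time,
      waiting = data.frame(
        time = state@time + res$waitingTime,
        species = allSp[res$waitingSpecies + 1L],
        count = res$waitingCount),
      status = status)
}
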