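#' Release-delay distributions for delayed reaction products
#'
#' A \code{DelayDistribution} describes the waiting time between the firing
#' of a reaction and the release of one of its products.  Three families are
#' supported: a point mass (deterministic delay), an exponential (given by
#' its mean), and a normal truncated at zero.  Truncation is by rejection
#' resampling rather than clipping, so no atom appears at zero and the mean
#' of, say, N(40, 4^2) is preserved to numerical accuracy.
#'
#' @slot kind one of \code{"point"}, \code{"exponential"}, \code{"normal"}
#' @slot p1 the delay value (point mass) or mean (exponential, normal), in
#'   seconds
#' @slot p2 the standard deviation (normal only), in seconds
#'
#' @seealso [drawDelay()]
#' @export
setClass("DelayDistribution",
  representation(kind = "character", p1 = "numeric", p2 = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("point", "exponential", "normal")) {
      return("kind must be 'point', 'exponential' or 'normal'")
    }
    if (!is.finite(object@p1) || object@p1 < 0) {
      return("delay value/mean must be finite and non-negative")
    }
    if (object@kind == "normal" && (!is.finite(object@p2) || object@p2 < 0)) {
      return("standard deviation must be finite and non-negative")
    }
    TRUE
  }
)

#' @describeIn DelayDistribution a deterministic delay of \code{value}
#'   seconds; \code{delayPoint(0)} behaves as an instantaneous product.
#' @param value delay in seconds
#' @export
delayPoint <- function(value) {
  new("DelayDistribution", kind = "point", p1 = value, p2 = 0)
}

#' @describeIn DelayDistribution an exponentially distributed delay with the
#'   given mean (seconds).
#' @param mean mean delay in seconds
#' @export
delayExponential <- function(mean) {
  new("DelayDistribution", kind = "exponential", p1 = mean, p2 = 0)
}

#' @describeIn DelayDistribution a normal delay truncated at zero by
#'   rejection resampling.
#' @param sd standard deviation in seconds
#' @export
delayNormal <- function(mean, sd) {
  new("DelayDistribution", kind = "normal", p1 = mean, p2 = sd)
}

delayKindCode <- function(dist) {
  match(dist@kind, c("point", "exponential", "normal")) - 1L
}

#' Sample delays from a delay distribution
#'
#' All draws are non-negative; normal draws are rejection-resampled until
#' non-negative.
#'
#' @param dist a [DelayDistribution-class] object
#' @param n number of draws
#' @param seed integer seed; by default drawn from R's RNG stream so that
#'   \code{set.seed()} gives reproducibility
#' @return numeric vector of \code{n} delays, in seconds
#' @examples
#' drawDelay(delayPoint(5), 3)          # 5 5 5
#' mean(drawDelay(delayExponential(47), 1e4, seed = 1))
#' @export
drawDelay <- function(dist, n = 1, seed = randomSeed()) {
  stopifnot(is(dist, "DelayDistribution"))
  validObject(dist)
  .cpp_draw_delay(delayKindCode(dist), dist@p1, dist@p2, as.integer(n),
                  as.double(seed))
}

setMethod("show", "DelayDistribution", function(object) {
  switch(object@kind,
    point = cat(sprintf("DelayDistribution: point mass at %g s\n", object@p1)),
    exponential = cat(sprintf(
      "DelayDistribution: exponential, mean %g s\n", object@p1)),
    normal = cat(sprintf(
      "DelayDistribution: normal(%g, %g^2) truncated at 0, seconds\n",
      object@p1, object@p2))
  )
  invisible(object)
})
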