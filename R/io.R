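# Plain-text persistence: TSV matrices/trajectories with JSON metadata
# sidecars, YAML run configurations.

fnvHash <- function(x) {
  # tiny djb2-style rolling hash over the serialised object, for config
  # fingerprints (kept in 31 bits to stay inside R integer arithmetic)
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a time-series matrix as TSV
#'
#' The TSV holds one column per replicate row plus a leading \code{time}
#' column; a JSON sidecar (\code{<path>.json}) records the kind, sampling
#' interval, burn-in, model label and per-row seeds, so that a written
#' matrix round-trips exactly.
#'
#' @param matrix a [TimeSeriesMatrix-class]
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeTimeSeries <- function(matrix, path) {
  stopifnot(is(matrix, "TimeSeriesMatrix"))
  v <- t(matrix@values)
  colnames(v) <- sprintf("rep%d", seq_len(ncol(v)))
  df <- data.frame(
    time = matrix@burnin + (seq_len(nrow(v)) - 1) * matrix@sampleInterval)
  df <- cbind(df, as.data.frame(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(kind = matrix@kind, sampleInterval = matrix@sampleInterval,
               burnin = matrix@burnin, label = matrix@label,
               seeds = matrix@seeds)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(vals) <- NULL
  storage.mode(vals) <- "double"
  new("TimeSeriesMatrix", kind = meta$kind, values = vals,
      sampleInterval = meta$sampleInterval, burnin = meta$burnin,
      label = meta$label, seeds = as.numeric(meta$seeds))
}

#' Write a single simulated trajectory as TSV
#'
#' First column time (s), one integer column per observable; the JSON
#' sidecar carries the seed, model label and a configuration fingerprint.
#'
#' @param trajectory data.frame from [simulateGene()] or
#'   [simulateReactions()]
#' @param path output TSV path
#' @param config optional configuration object folded into the fingerprint
#' @export
writeTrajectory <- function(trajectory, path, config = NULL) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(seed = attr(trajectory, "seed"),
               label = attr(trajectory, "label"),
               nEvents = attr(trajectory, "nEvents"),
               configHash = fnvHash(config))
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Experiment run configuration
#'
#' @slot label model label ("A".."F")
#' @slot geneLength gene length (nt)
#' @slot replicates number of replicate runs F
#' @slot tEnd simulated time per run (s)
#' @slot sampleInterval sampling interval (s)
#' @slot burnin burn-in removed before analysis (s)
#' @slot seed master seed; per-replicate seeds are derived from it
#' @slot outDir output directory ("" = do not write)
#' @export
setClass("RunConfig",
  representation(label = "character", geneLength = "numeric",
                 replicates = "numeric", tEnd = "numeric",
                 sampleInterval = "numeric", burnin = "numeric",
                 seed = "numeric", outDir = "character"),
  validity = function(object) {
    if (object@tEnd <= 0 || object@sampleInterval <= 0) {
      return("durations must be positive")
    }
    if (object@replicates < 1) return("need at least one replicate")
    if (object@burnin >= object@tEnd) {
      return("burn-in must be shorter than the run")
    }
    TRUE
  }
)

#' @rdname RunConfig-class
#' @param label,geneLength,replicates,tEnd,sampleInterval,burnin,seed,outDir
#'   see the class slots
#' @export
runConfig <- function(label = "A", geneLength = 1000, replicates = 10,
                      tEnd = 1e6, sampleInterval = 1, burnin = 50000,
                      seed = 1, outDir = "") {
  new("RunConfig", label = label, geneLength = geneLength,
      replicates = replicates, tEnd = tEnd,
      sampleInterval = sampleInterval, burnin = burnin, seed = seed,
      outDir = outDir)
}

#' @rdname RunConfig-class
#' @param path YAML file with any of the constructor fields
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: model %s, %d x %g s (gene %d nt, burn-in %g s, seed %d)\n",
    object@label, as.integer(object@replicates), object@tEnd,
    as.integer(object@geneLength), object@burnin, as.integer(object@seed)))
  invisible(object)
})
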