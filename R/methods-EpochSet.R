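#' @describeIn EpochSet number of epochs
#' @param x an `EpochSet`.
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1L])

#' @describeIn EpochSet electrode labels
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)

#' @describeIn EpochSet time axis in ms
#' @export
setMethod("sampleTimes", "EpochSet", function(x) x@times)

#' @describeIn EpochSet per-epoch event metadata
#' @export
setMethod("epochEvents", "EpochSet", function(x) x@events)

#' @describeIn EpochSet raw data array
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' Subject identifier of an EpochSet
#' @param x an [EpochSet-class].
#' @return character scalar.
#' @export
subjectId <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@subject
}

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet for subject", object@subject, "\n")
  cat(sprintf("  %d epochs x %d channels x %d samples (%.0f-%.1f ms)\n",
              d[1L], d[2L], d[3L],
              min(object@times), max(object@times)))
  tab <- table(object@events$event)
  cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  average-referenced:", object@referenced,
      " baseline-corrected:", object@baselined, "\n")
})

#' Subset an EpochSet by epoch
#'
#' @param x an [EpochSet-class].
#' @param i epoch indices or logical vector over epochs.
#' @param j,drop,... ignored.
#' @return an [EpochSet-class] with the selected epochs.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  EpochSet(x@subject, x@data[i, , , drop = FALSE], x@times,
           x@events[i, , drop = FALSE], x@channels,
           referenced = x@referenced, baselined = x@baselined)
})

#' @describeIn ErpAverage data matrix
#' @param x an `ErpAverage`.
#' @export
setMethod("erpData", "ErpAverage", function(x) x@data)

#' @describeIn ErpAverage electrode labels
#' @export
setMethod("channelNames", "ErpAverage", function(x) x@channels)

#' @describeIn ErpAverage time axis in ms
#' @export
setMethod("sampleTimes", "ErpAverage", function(x) x@times)

#' @describeIn ErpAverage trial count behind the average
#' @export
setMethod("nTrials", "ErpAverage", function(x) x@nTrials)

setMethod("show", "ErpAverage", function(object) {
  cat("ErpAverage:", object@selector, "\n")
  cat(sprintf("  %d channels x %d samples, %g trials, %s\n",
              nrow(object@data), ncol(object@data), object@nTrials,
              if (object@referenced) "average-referenced" else "raw reference"))
})

#' @describeIn PermutationResult observed GMD
#' @param x a `PermutationResult`.
#' @export
setMethod("observedGmd", "PermutationResult", function(x) x@observedGmd)

#' @describeIn PermutationResult permutation p value
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @describeIn PermutationResult number of permutations
#' @export
setMethod("nPermutations", "PermutationResult", function(x) x@nPermutations)

#' Null-distribution summary quantiles
#' @param x a [PermutationResult-class].
#' @return named numeric vector.
#' @export
nullQuantiles <- function(x) {
  stopifnot(is(x, "PermutationResult"))
  x@nullQuantiles
}

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("GMD permutation test: observed GMD = %.4f, p = %.5g\n",
              object@observedGmd, object@pValue))
  cat(sprintf("  %g permutations (%s)\n", object@nPermutations,
              if (object@exact) "exact enumeration" else
                sprintf("sampled, seed %g", object@seed)))
})
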