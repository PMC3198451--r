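#' @import methods
#' @importFrom stats rnorm rbinom median cor lm pt quantile sd coef fft mvfft
#' @importFrom utils write.csv read.csv head
NULL

#' EpochSet: event-locked multichannel EEG segments for one subject
#'
#' Container for a stack of event-locked epochs: a numeric array of
#' `trials x channels x samples` (microvolts), the time axis in milliseconds
#' (time 0 = locking event), and one row of event metadata per epoch.
#' Event metadata carries the event class (`feedback`, `stop_success`,
#' `stop_failure_stop`, `stop_failure_response`), the task condition, hand,
#' feedback valence and expectancy cell, the originating trial index, and --
#' for response-locked epochs after failed stops -- the trial index of the
#' linked stop-locked epoch used for baseline correction.
#'
#' @slot subject subject identifier.
#' @slot data numeric array, `trials x channels x samples`, in microvolts.
#' @slot times numeric vector of sample times in ms relative to the event.
#' @slot events data.frame with one row per epoch.
#' @slot channels character vector of electrode labels.
#' @slot referenced logical; `TRUE` after common-average referencing.
#' @slot baselined logical; `TRUE` after baseline correction.
#'
#' @seealso [generateEpochs()], [commonAverageReference()],
#'   [baselineCorrect()], [erpAverage()]
#' @export
setClass("EpochSet",
  slots = c(
    subject    = "character",
    data       = "array",
    times      = "numeric",
    events     = "data.frame",
    channels   = "character",
    referenced = "logical",
    baselined  = "logical"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-dimensional array (trials x channels x samples)")
  if (d[1L] != nrow(object@events))
    return("number of epochs must match rows of the event table")
  if (d[2L] != length(object@channels))
    return("second array dimension must match the channel labels")
  if (d[3L] != length(object@times))
    return("third array dimension must match the time axis")
  if (anyDuplicated(object@channels))
    return("channel labels must be unique")
  if (!"event" %in% names(object@events))
    return("event table must have an 'event' column")
  TRUE
})

#' Construct an EpochSet
#'
#' @param subject subject identifier.
#' @param data `trials x channels x samples` numeric array (microvolts).
#' @param times time axis in ms (0 = locking event).
#' @param events data.frame of per-epoch metadata (needs an `event` column).
#' @param channels electrode labels matching `dim(data)[2]`.
#' @param referenced,baselined processing-state flags.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(subject, data, times, events, channels,
                     referenced = FALSE, baselined = FALSE) {
  new("EpochSet", subject = as.character(subject), data = data,
      times = as.numeric(times), events = as.data.frame(events),
      channels = as.character(channels),
      referenced = referenced, baselined = baselined)
}

#' ErpAverage: an averaged event-related potential
#'
#' A `channels x samples` matrix of averaged voltages with its time axis,
#' the number of trials entering the average and a free-text selector
#' describing what was averaged (condition, hand, event class).
#'
#' @slot data numeric matrix, `channels x samples`, microvolts.
#' @slot times numeric, ms.
#' @slot nTrials number of epochs averaged (difference waves record the
#'   smaller constituent count).
#' @slot selector character description of the selection.
#' @slot channels electrode labels.
#' @slot referenced logical average-reference flag, carried from the epochs.
#' @export
setClass("ErpAverage",
  slots = c(
    data       = "matrix",
    times      = "numeric",
    nTrials    = "numeric",
    selector   = "character",
    channels   = "character",
    referenced = "logical"
  )
)

setValidity("ErpAverage", function(object) {
  if (nrow(object@data) != length(object@channels))
    return("rows of data must match channel labels")
  if (ncol(object@data) != length(object@times))
    return("columns of data must match the time axis")
  if (object@nTrials < 1)
    return("nTrials must be >= 1")
  TRUE
})

#' PermutationResult: outcome of a GMD permutation (TANOVA) test
#'
#' @slot observedGmd observed global map dissimilarity between the two
#'   grand-average topographies (unitless, in `[0, 2]`).
#' @slot pValue permutation p value (`(1 + #null >= obs) / (1 + nPerm)` when
#'   sampled; exact proportion when the `2^n` flip space was enumerated).
#' @slot nPermutations number of permutations evaluated.
#' @slot seed RNG seed used (NA for exact enumeration).
#' @slot nullQuantiles named summary quantiles of the null distribution.
#' @slot exact logical; TRUE if the flip space was fully enumerated.
#' @export
setClass("PermutationResult",
  slots = c(
    observedGmd   = "numeric",
    pValue        = "numeric",
    nPermutations = "numeric",
    seed          = "numeric",
    nullQuantiles = "numeric",
    exact         = "logical"
  )
)

setValidity("PermutationResult", function(object) {
  if (object@observedGmd < 0 || object@observedGmd > 2 + 1e-12)
    return("observed GMD must lie in [0, 2]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p value must lie in (0, 1]")
  TRUE
})
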