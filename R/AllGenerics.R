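#' Number of epochs in a container
#' @param x an [EpochSet-class].
#' @return integer count of epochs.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Electrode labels
#' @param x an [EpochSet-class] or [ErpAverage-class].
#' @return character vector of channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Sample time axis (ms relative to the locking event)
#' @param x an [EpochSet-class] or [ErpAverage-class].
#' @return numeric vector of times in ms.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' Per-epoch event metadata
#' @param x an [EpochSet-class].
#' @return data.frame with one row per epoch.
#' @export
setGeneric("epochEvents", function(x) standardGeneric("epochEvents"))

#' Raw epoch data array
#' @param x an [EpochSet-class].
#' @return numeric array `trials x channels x samples` (microvolts).
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Averaged ERP data matrix
#' @param x an [ErpAverage-class].
#' @return numeric `channels x samples` matrix (microvolts).
#' @export
setGeneric("erpData", function(x) standardGeneric("erpData"))

#' Number of trials behind an average
#' @param x an [ErpAverage-class].
#' @return numeric trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Re-reference voltages to the common average of all electrodes
#'
#' Subtracts, at every sample, the mean over channels, so that the channel
#' mean is zero everywhere. Idempotent.
#'
#' @param x an [EpochSet-class] or [ErpAverage-class].
#' @return object of the same class, average-referenced.
#' @export
setGeneric("commonAverageReference",
           function(x) standardGeneric("commonAverageReference"))

#' Baseline-correct epochs or an average
#'
#' Subtracts, per channel (and per epoch for an `EpochSet`), the mean
#' voltage inside `window` from the whole trace.
#'
#' @param x an [EpochSet-class] or [ErpAverage-class].
#' @param window numeric length-2 interval in ms, default `c(-200, 0)`.
#' @return object of the same class, baseline-corrected.
#' @export
setGeneric("baselineCorrect",
           function(x, window = c(-200, 0)) standardGeneric("baselineCorrect"))

#' Observed GMD of a permutation test
#' @param x a [PermutationResult-class].
#' @return numeric scalar.
#' @export
setGeneric("observedGmd", function(x) standardGeneric("observedGmd"))

#' Permutation p value
#' @param x a [PermutationResult-class].
#' @return numeric scalar in (0, 1].
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Number of permutations evaluated
#' @param x a [PermutationResult-class].
#' @return numeric scalar.
#' @export
setGeneric("nPermutations", function(x) standardGeneric("nPermutations"))
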