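# Internal scans shared by the measurement operators and the generator's
# kernel normalization. Window endpoints are inclusive, but 0 ms (the
# event sample itself) is always excluded from post-event searches; ties
# resolve to the earliest sample.
minScan <- function(values, times, window) {
  idx <- which(times >= window[1] & times <= window[2] & times > 0)
  if (length(idx) == 0L) stop("empty search window")
  j <- idx[which.min(values[idx])]
  list(amplitude = values[j], latency = times[j])
}

troughToPeakScan <- function(values, times, troughWindow, searchFrom = 0) {
  tr <- minScan(values, times, troughWindow)
  pk <- which(times > searchFrom & times <= tr$latency & times > 0)
  if (length(pk) == 0L) stop("empty peak search range")
  j <- pk[which.max(values[pk])]
  list(amplitude = tr$amplitude - values[j], latency = tr$latency,
       peakLatency = times[j])
}

#' @describeIn commonAverageReference per-epoch, per-sample channel-mean
#'   subtraction.
#' @export
setMethod("commonAverageReference", "EpochSet", function(x) {
  # channel mean per (epoch, sample), subtracted everywhere
  m <- colMeans(aperm(x@data, c(2L, 1L, 3L)))
  initialize(x, data = sweep(x@data, c(1L, 3L), m), referenced = TRUE)
})

#' @describeIn commonAverageReference per-sample channel-mean subtraction.
#' @export
setMethod("commonAverageReference", "ErpAverage", function(x) {
  initialize(x, data = sweep(x@data, 2L, colMeans(x@data)),
             referenced = TRUE)
})

#' @describeIn baselineCorrect subtracts each epoch's per-channel mean over
#'   `window`.
#' @export
setMethod("baselineCorrect", "EpochSet", function(x, window = c(-200, 0)) {
  idx <- which(x@times >= window[1] & x@times <= window[2])
  if (length(idx) == 0L) stop("baseline window outside the epoch")
  b <- rowSums(x@data[, , idx, drop = FALSE], dims = 2L) / length(idx)
  initialize(x, data = sweep(x@data, c(1L, 2L), b), baselined = TRUE)
})

#' @describeIn baselineCorrect subtracts the per-channel mean over `window`.
#' @export
setMethod("baselineCorrect", "ErpAverage", function(x, window = c(-200, 0)) {
  idx <- which(x@times >= window[1] & x@times <= window[2])
  if (length(idx) == 0L) stop("baseline window outside the epoch")
  initialize(x, data = x@data - rowMeans(x@data[, idx, drop = FALSE]))
})

#' Baseline-correct response-locked epochs from their linked stop epochs
#'
#' The ERN's baseline is taken relative to the preceding stop-signal: each
#' `stop_failure_response` epoch is corrected with the per-channel mean of
#' its linked `stop_failure_stop` epoch over `window` (default the 200 ms
#' before the stop-signal). Other epochs are left untouched; the linkage
#' is the `link` column of the event table.
#'
#' @param x an [EpochSet-class] containing both `stop_failure_response`
#'   and `stop_failure_stop` epochs.
#' @param window baseline interval in ms of the stop-locked epoch.
#' @return the [EpochSet-class] with corrected response-locked epochs.
#' @export
linkedBaselineCorrect <- function(x, window = c(-200, 0)) {
  stopifnot(is(x, "EpochSet"))
  ev <- x@events
  idx <- which(x@times >= window[1] & x@times <= window[2])
  if (length(idx) == 0L) stop("baseline window outside the epoch")
  resp <- which(ev$event == "stop_failure_response")
  if (length(resp) == 0L) return(x)
  stopRows <- which(ev$event == "stop_failure_stop")
  j <- stopRows[match(ev$link[resp], ev$trial[stopRows])]
  if (anyNA(j))
    stop("no linked stop-locked epoch for response epoch of trial ",
         ev$link[resp[which(is.na(j))[1L]]])
  b <- rowSums(x@data[j, , idx, drop = FALSE], dims = 2L) / length(idx)
  d <- x@data
  d[resp, , ] <- d[resp, , , drop = FALSE] -
    array(b, c(length(resp), dim(d)[2L], dim(d)[3L]))
  initialize(x, data = d)
}

#' Average selected epochs into an ERP
#'
#' @param x an [EpochSet-class].
#' @param select logical or integer vector over epochs, or a character
#'   event class matched against the event table.
#' @param selector description stored with the average (defaults to
#'   `select` when that is a character).
#' @return an [ErpAverage-class].
#' @export
erpAverage <- function(x, select, selector = NULL) {
  stopifnot(is(x, "EpochSet"))
  if (is.character(select)) {
    if (is.null(selector)) selector <- select
    select <- x@events$event %in% select
  }
  idx <- if (is.logical(select)) which(select) else as.integer(select)
  if (length(idx) == 0L) stop("no epochs match the selection")
  d <- x@data[idx, , , drop = FALSE]
  avg <- apply(d, c(2L, 3L), mean)
  new("ErpAverage", data = avg, times = x@times, nTrials = length(idx),
      selector = if (is.null(selector)) "custom selection" else selector,
      channels = x@channels, referenced = x@referenced)
}

#' Samplewise difference of two ERPs
#'
#' `a - b` over matching channels and time axes. The three canonical
#' feedback contrasts are control (error - correct), unexpected
#' (easy-error - hard-correct, i.e. infrequent error - infrequent correct)
#' and expected (hard-error - easy-correct).
#'
#' @param a,b [ErpAverage-class] objects on identical axes.
#' @return an [ErpAverage-class]; `nTrials` records the smaller
#'   constituent count.
#' @export
differenceWave <- function(a, b) {
  stopifnot(is(a, "ErpAverage"), is(b, "ErpAverage"))
  if (!identical(a@channels, b@channels))
    stop("channel sets differ")
  if (length(a@times) != length(b@times) ||
      max(abs(a@times - b@times)) > 1e-9)
    stop("time axes differ")
  new("ErpAverage", data = a@data - b@data, times = a@times,
      nTrials = min(a@nTrials, b@nTrials),
      selector = paste(a@selector, "-", b@selector),
      channels = a@channels, referenced = a@referenced && b@referenced)
}

# One-row peak-measure record.
peakMeasure <- function(component, subject, hand, channel, amplitude,
                        latency, method, nTrials = NA_real_) {
  data.frame(component = component, subject = subject, hand = hand,
             channel = channel, amplitude_uV = amplitude,
             latency_ms = latency, method = method, n_trials = nTrials,
             stringsAsFactors = FALSE)
}

#' FRN peak: most negative deflection of a difference wave
#'
#' Scans the post-stimulus window (0 ms excluded, endpoints inclusive) of
#' one channel for the minimum; ties resolve to the earliest sample.
#'
#' @param diff an [ErpAverage-class] difference wave covering the window.
#' @param channel electrode label (default `"FCz"`).
#' @param window search window in ms, default `c(0, 600)`.
#' @param subject,hand metadata carried into the result.
#' @return one-row data.frame: `component`, `subject`, `hand`, `channel`,
#'   `amplitude_uV`, `latency_ms`, `method`, `n_trials`.
#' @export
frnPeak <- function(diff, channel = "FCz", window = c(0, 600),
                    subject = NA_character_, hand = NA_character_) {
  stopifnot(is(diff, "ErpAverage"))
  ch <- match(channel, diff@channels)
  if (is.na(ch)) stop("channel not present: ", channel)
  sc <- minScan(diff@data[ch, ], diff@times, window)
  peakMeasure("FRN", subject, hand, channel, sc$amplitude, sc$latency,
              "peak", diff@nTrials)
}

#' Trough-to-peak amplitude of an ERP component
#'
#' Finds the most negative deflection inside `troughWindow` and subtracts
#' the maximal (preceding positive) deflection between `searchFrom` and
#' the trough latency; reported as a negative magnitude. Window endpoints
#' are inclusive, 0 ms is excluded, ties resolve to the earliest sample.
#'
#' @param erp an [ErpAverage-class].
#' @param channel electrode label.
#' @param troughWindow trough search window in ms (N2: `c(120, 280)` after
#'   the stop-signal; ERN: `c(0, 120)` after the erroneous response).
#' @param searchFrom start of the preceding-peak search, ms (default 0).
#' @param component,subject,hand metadata carried into the result.
#' @return one-row data.frame as in [frnPeak()].
#' @export
troughToPeak <- function(erp, channel = "FCz", troughWindow,
                         searchFrom = 0, component = NA_character_,
                         subject = NA_character_, hand = NA_character_) {
  stopifnot(is(erp, "ErpAverage"))
  ch <- match(channel, erp@channels)
  if (is.na(ch)) stop("channel not present: ", channel)
  sc <- troughToPeakScan(erp@data[ch, ], erp@times, troughWindow,
                         searchFrom)
  peakMeasure(component, subject, hand, channel, sc$amplitude, sc$latency,
              "trough_to_peak", erp@nTrials)
}

# Feedback-cell selector helper.
feedbackCell <- function(ev, condition, valence, hand = NULL) {
  sel <- ev$event == "feedback" & ev$condition == condition &
    ev$valence == valence
  if (!is.null(hand)) sel <- sel & ev$hand == hand
  sel
}

#' Component measures of a prepared EpochSet
#'
#' Convenience wrappers running the canonical measurement of each
#' component on an already referenced and baseline-corrected
#' [EpochSet-class]: `measureFrn` forms the requested feedback difference
#' wave (averaging each constituent cell, then subtracting) and takes its
#' most negative deflection in 0-600 ms; `measureN2` the trough-to-peak of
#' the successful-stop average in 120-280 ms; `measureErn` the
#' trough-to-peak of the failed-stop response average in 0-120 ms (the
#' epochs must have been through [linkedBaselineCorrect()]).
#'
#' @param x an [EpochSet-class], average-referenced and baselined.
#' @param contrast for `measureFrn`: `"unexpected"`
#'   (easy-error - hard-correct), `"expected"` (hard-error - easy-correct)
#'   or `"control"` (control-error - control-correct).
#' @param channel electrode label, default `"FCz"`.
#' @param hand restrict to one hand (default both).
#' @return one-row peak-measure data.frame.
#' @export
measureFrn <- function(x, contrast = c("unexpected", "expected", "control"),
                       channel = "FCz", hand = NULL) {
  contrast <- match.arg(contrast)
  ev <- x@events
  cells <- switch(contrast,
    unexpected = list(c("easy", "error"), c("hard", "correct")),
    expected   = list(c("hard", "error"), c("easy", "correct")),
    control    = list(c("control", "error"), c("control", "correct")))
  a <- erpAverage(x, feedbackCell(ev, cells[[1]][1], cells[[1]][2], hand),
                  selector = paste(cells[[1]], collapse = "-"))
  b <- erpAverage(x, feedbackCell(ev, cells[[2]][1], cells[[2]][2], hand),
                  selector = paste(cells[[2]], collapse = "-"))
  dw <- differenceWave(a, b)
  m <- frnPeak(dw, channel, subject = x@subject,
               hand = if (is.null(hand)) "both" else hand)
  m$component <- paste0("FRN.", contrast)
  m
}

#' @rdname measureFrn
#' @export
measureN2 <- function(x, channel = "FCz", hand = NULL) {
  ev <- x@events
  sel <- ev$event == "stop_success"
  if (!is.null(hand)) sel <- sel & ev$hand == hand
  avg <- erpAverage(x, sel, selector = "stop_success")
  troughToPeak(avg, channel, troughWindow = c(120, 280), component = "N2",
               subject = x@subject,
               hand = if (is.null(hand)) "both" else hand)
}

#' @rdname measureFrn
#' @export
measureErn <- function(x, channel = "FCz", hand = NULL) {
  ev <- x@events
  sel <- ev$event == "stop_failure_response"
  if (!is.null(hand)) sel <- sel & ev$hand == hand
  avg <- erpAverage(x, sel, selector = "stop_failure_response")
  troughToPeak(avg, channel, troughWindow = c(0, 120), component = "ERN",
               subject = x@subject,
               hand = if (is.null(hand)) "both" else hand)
}

#' Odd/even half measures of one component for one subject
#'
#' Splits the component's constituent trials into odd- and even-indexed
#' halves (for the FRN, the odd/even split is applied within each
#' constituent cell of the difference wave before differencing, so both
#' halves have balanced cells) and applies the component's measurement to
#' each half average.
#'
#' @param x an [EpochSet-class], referenced and baselined (for the ERN,
#'   through [linkedBaselineCorrect()]).
#' @param component `"FRN"`, `"N2"` or `"ERN"`; the FRN uses the
#'   unexpected difference wave.
#' @param channel electrode label.
#' @return named numeric `c(odd = , even = )` amplitude pair (microvolts),
#'   or `NULL` when the subject lacks a trial in some half.
#' @export
splitHalfMeasures <- function(x, component = c("FRN", "N2", "ERN"),
                              channel = "FCz") {
  component <- match.arg(component)
  ev <- x@events
  halves <- function(idx) {
    k <- seq_along(idx)
    list(odd = idx[k %% 2L == 1L], even = idx[k %% 2L == 0L])
  }
  measureHalf <- function(idx, fun) fun(idx)
  if (component == "FRN") {
    ee <- halves(which(feedbackCell(ev, "easy", "error")))
    hc <- halves(which(feedbackCell(ev, "hard", "correct")))
    if (any(lengths(ee) == 0L) || any(lengths(hc) == 0L)) return(NULL)
    one <- function(h) {
      dw <- differenceWave(erpAverage(x, ee[[h]], "easy-error"),
                           erpAverage(x, hc[[h]], "hard-correct"))
      frnPeak(dw, channel)$amplitude_uV
    }
    c(odd = one("odd"), even = one("even"))
  } else {
    sel <- if (component == "N2") which(ev$event == "stop_success")
           else which(ev$event == "stop_failure_response")
    hs <- halves(sel)
    if (any(lengths(hs) == 0L)) return(NULL)
    win <- if (component == "N2") c(120, 280) else c(0, 120)
    one <- function(h)
      troughToPeak(erpAverage(x, hs[[h]], component), channel,
                   troughWindow = win)$amplitude_uV
    c(odd = one("odd"), even = one("even"))
  }
}

#' Write a peak-measure table as CSV
#'
#' @param measures data.frame of stacked peak-measure rows.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(measures, path) {
  write.csv(measures, path, row.names = FALSE)
  invisible(path)
}
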