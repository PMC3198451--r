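#' Specification of one simulated ERP component
#'
#' Describes how one component (FRN, N2 or ERN) is injected into synthetic
#' epochs: a biphasic temporal kernel (a negative Gaussian at `latency`
#' preceded by a smaller positive Gaussian), a fronto-central Gaussian
#' scalp topography, per-subject and per-trial amplitude variability, and
#' gain multipliers over the event cells the component responds to.
#'
#' The kernel is rescaled so that the component's own measurement operator
#' (raw minimum for the FRN difference wave, trough-to-peak for N2/ERN),
#' applied to the noiseless kernel after the standard baseline correction,
#' returns exactly -1. Injecting `amplitudeMean` therefore recovers
#' `amplitudeMean` exactly at the maximal electrode when noise is off.
#'
#' @param name `"FRN"`, `"N2"` or `"ERN"`.
#' @param amplitudeMean mean injected amplitude, microvolts (negative).
#' @param amplitudeSdBetween between-subject amplitude SD, microvolts.
#' @param amplitudeSdWithin across-trial amplitude SD, microvolts.
#' @param latency peak (trough) latency, ms after the locking event.
#' @param halfWidth temporal SD of the negative Gaussian lobe, ms.
#' @param posOffset,posWidth,posFrac preceding positive lobe: its latency
#'   lead before `latency`, its temporal SD, and its relative amplitude.
#' @param topoCenterLabel electrode label at the topography center.
#' @param topoSpread spatial Gaussian SD in layout (unit-disc) units.
#' @param lateralShift signed-by-hand ipsilateral x-shift of the topography
#'   center in layout units (left hand shifts left).
#' @param conditionGain named numeric gains over event cells; cells not
#'   listed get gain 0.
#' @param measure `"peak"` (raw minimum) or `"trough_to_peak"`.
#' @param window measurement search window in ms (post-event).
#' @param lock event class the component locks to: `"feedback"`,
#'   `"stop"` or `"response"`.
#' @return a validated list of class `"componentSpec"`.
#' @seealso [defaultComponentSpecs()] for the shipped FRN/N2/ERN settings.
#' @export
componentSpec <- function(name, amplitudeMean, amplitudeSdBetween,
                          amplitudeSdWithin, latency, halfWidth,
                          posOffset, posWidth, posFrac,
                          topoCenterLabel = "FCz", topoSpread = 0.45,
                          lateralShift = 0, conditionGain,
                          measure = c("peak", "trough_to_peak"),
                          window, lock) {
  measure <- match.arg(measure)
  stopifnot(amplitudeSdBetween >= 0, amplitudeSdWithin >= 0,
            latency > 0, halfWidth > 0, posWidth > 0, posFrac >= 0,
            topoSpread > 0, is.numeric(conditionGain),
            !is.null(names(conditionGain)),
            length(window) == 2, window[1] < window[2],
            lock %in% c("feedback", "stop", "response"))
  structure(list(name = name, amplitudeMean = amplitudeMean,
                 amplitudeSdBetween = amplitudeSdBetween,
                 amplitudeSdWithin = amplitudeSdWithin,
                 latency = latency, halfWidth = halfWidth,
                 posOffset = posOffset, posWidth = posWidth,
                 posFrac = posFrac, topoCenterLabel = topoCenterLabel,
                 topoSpread = topoSpread, lateralShift = lateralShift,
                 conditionGain = conditionGain, measure = measure,
                 window = window, lock = lock),
            class = "componentSpec")
}

#' Shipped FRN / N2 / ERN component specifications
#'
#' Amplitude means and between-subject SDs follow the left-hand column of
#' the study's FCz amplitude table: FRN (unexpected feedback)
#' -5.62 +/- 2.98 uV, N2 -6.14 +/- 2.94 uV, ERN -5.69 +/- 2.97 uV.
#' Latencies sit at the canonical values (FRN trough ~280 ms post-feedback,
#' N2 ~200 ms post-stop-signal, ERN ~60 ms post-response). FRN gains are
#' non-zero only on error feedback: 1.0 in the easy condition (unexpected
#' errors), 3.78/5.62 in the hard condition so the expected-feedback
#' difference wave lands at -3.78 uV, and 0.85 in the control condition.
#' The N2 carries an ipsilateral topography shift with the stop-signal
#' hand; a half-gain N2 is injected on failed stops.
#'
#' @return named list of three [componentSpec()] objects (`FRN`, `N2`,
#'   `ERN`).
#' @export
defaultComponentSpecs <- function() {
  list(
    FRN = componentSpec("FRN",
      amplitudeMean = -5.62, amplitudeSdBetween = 2.98,
      amplitudeSdWithin = 1.5, latency = 280, halfWidth = 45,
      posOffset = 90, posWidth = 50, posFrac = 0.4,
      conditionGain = c(control.error = 0.85, easy.error = 1,
                        hard.error = 3.78 / 5.62),
      measure = "peak", window = c(0, 600), lock = "feedback"),
    N2 = componentSpec("N2",
      amplitudeMean = -6.14, amplitudeSdBetween = 2.94,
      amplitudeSdWithin = 1.5, latency = 200, halfWidth = 35,
      posOffset = 80, posWidth = 40, posFrac = 0.45,
      lateralShift = 0.06,
      conditionGain = c(stop_success = 1, stop_failure_stop = 0.5),
      measure = "trough_to_peak", window = c(120, 280), lock = "stop"),
    ERN = componentSpec("ERN",
      amplitudeMean = -5.69, amplitudeSdBetween = 2.97,
      amplitudeSdWithin = 1.5, latency = 60, halfWidth = 22,
      posOffset = 45, posWidth = 18, posFrac = 0.5,
      conditionGain = c(stop_failure_response = 1),
      measure = "trough_to_peak", window = c(0, 120), lock = "response")
  )
}

#' Between-subject amplitude correlation of the three components
#'
#' Generator choice mirroring the reported regression structure between
#' the components: rho(N2, ERN) = 0.75, rho(ERN, FRN) = 0.55,
#' rho(N2, FRN) = 0.43. Order: FRN, N2, ERN.
#'
#' @return 3x3 correlation matrix with dimnames `FRN`, `N2`, `ERN`.
#' @export
defaultAmplitudeCorrelation <- function() {
  m <- matrix(c(1, 0.43, 0.55,
                0.43, 1, 0.75,
                0.55, 0.75, 1), 3, 3,
              dimnames = list(c("FRN", "N2", "ERN"),
                              c("FRN", "N2", "ERN")))
  m
}

#' Noise specification for synthetic epochs
#'
#' Temporally 1/f^alpha ("pink") noise, spatially correlated across the
#' montage with a Gaussian covariance over layout distance.
#'
#' @param spectralExponent alpha of the 1/f^alpha amplitude spectrum.
#' @param rms per-channel RMS amplitude in microvolts (0 disables noise).
#' @param spatialSmoothness Gaussian spatial covariance scale in layout
#'   (unit-disc) units.
#' @return a list of class `"noiseSpec"`.
#' @export
noiseSpec <- function(spectralExponent = 1, rms = 2,
                      spatialSmoothness = 0.4) {
  stopifnot(rms >= 0, spatialSmoothness > 0)
  structure(list(spectralExponent = spectralExponent, rms = rms,
                 spatialSmoothness = spatialSmoothness),
            class = "noiseSpec")
}
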