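#' Gaussian scalp topography of a component
#'
#' Evaluates a radially decaying Gaussian basis centered at the component's
#' center electrode (shifted along x by `lateralShift`, signed by hand:
#' left hand shifts left), subtracts the spatial mean (so the injected
#' signal is invariant under common-average referencing) and scales so the
#' maximal electrode has value 1. With the shipped shifts the maximal
#' electrode remains the center electrode, which makes noiseless
#' injection-recovery at that electrode exact.
#'
#' @param spec a [componentSpec()].
#' @param hand `"left"` or `"right"` (direction of the ipsilateral shift).
#' @param layout electrode layout from [makeLayout()].
#' @return named numeric vector over electrodes (zero mean, max 1).
#' @export
componentTopography <- function(spec, hand = c("left", "right"),
                                layout = makeLayout()) {
  hand <- match.arg(hand)
  center <- layout[layout$label == spec$topoCenterLabel, c("x", "y")]
  if (nrow(center) != 1L)
    stop("center electrode not in layout: ", spec$topoCenterLabel)
  cx <- center$x + spec$lateralShift * (if (hand == "left") -1 else 1)
  d2 <- (layout$x - cx)^2 + (layout$y - center$y)^2
  g <- exp(-d2 / (2 * spec$topoSpread^2))
  g <- g - mean(g)
  g <- g / max(g)
  names(g) <- layout$label
  g
}

# Biphasic unit kernel of a component on a given time axis: negative
# Gaussian at `latency` preceded by a smaller positive Gaussian. Rescaled
# so the component's own measurement operator (after the standard
# -200..0 ms baseline for feedback/stop-locked components) returns -1.
componentKernel <- function(spec, times) {
  neg <- exp(-0.5 * ((times - spec$latency) / spec$halfWidth)^2)
  pos <- spec$posFrac *
    exp(-0.5 * ((times - (spec$latency - spec$posOffset)) / spec$posWidth)^2)
  k <- pos - neg
  if (spec$lock %in% c("feedback", "stop")) {
    base <- times >= -200 & times <= 0
    k <- k - mean(k[base])
  }
  m <- if (spec$measure == "peak")
    minScan(k, times, spec$window)$amplitude
  else
    troughToPeakScan(k, times, spec$window, searchFrom = 0)$amplitude
  if (m >= 0) stop("degenerate component kernel for ", spec$name)
  k / abs(m)
}

#' Draw correlated between-subject component amplitudes
#'
#' One multivariate-normal draw per subject over the components, with the
#' means and between-subject SDs of `specs` and the given correlation
#' matrix. Uses the current RNG stream.
#'
#' @param specs named list of [componentSpec()]s.
#' @param correlation correlation matrix over the components (dimnames
#'   must cover `names(specs)`).
#' @param n number of subjects.
#' @return `n x length(specs)` matrix of amplitudes (microvolts).
#' @export
drawSubjectAmplitudes <- function(specs = defaultComponentSpecs(),
                                  correlation = defaultAmplitudeCorrelation(),
                                  n = 1L) {
  comps <- names(specs)
  C <- correlation[comps, comps, drop = FALSE]
  sds <- vapply(specs, function(s) s$amplitudeSdBetween, numeric(1))
  mus <- vapply(specs, function(s) s$amplitudeMean, numeric(1))
  Z <- matrix(rnorm(n * length(comps)), n, length(comps)) %*% chol(C)
  amps <- sweep(sweep(Z, 2, sds, "*"), 2, mus, "+")
  colnames(amps) <- comps
  amps
}

# 1/f^alpha amplitude filter over FFT bins, normalized so the filtered
# white-noise series has unit variance per sample. DC is removed.
noiseFilter <- function(ns, fs, alpha) {
  k <- 0:(ns - 1)
  f <- pmin(k, ns - k) * fs / ns
  h <- ifelse(f > 0, f^(-alpha / 2), 0)
  h / sqrt(mean(h^2))
}

# Build the per-epoch event table from a single-subject trial log.
buildEventTable <- function(trials, events = c("feedback", "stop")) {
  need <- c("index", "condition", "hand", "trial_type", "feedback",
            "stop_success")
  if (!all(need %in% names(trials)))
    stop("trial log lacks required columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  rows <- list()
  if ("feedback" %in% events) {
    est <- trials[trials$trial_type == "estimation", , drop = FALSE]
    if (any(is.na(est$feedback)))
      stop("estimation trials without feedback annotation")
    rows$feedback <- data.frame(
      event = "feedback", trial = est$index, condition = est$condition,
      hand = est$hand, valence = est$feedback,
      expectancy = expectancyCell(est$condition, est$feedback),
      link = NA_integer_, stringsAsFactors = FALSE)
  }
  if ("stop" %in% events) {
    st <- trials[trials$trial_type == "stop", , drop = FALSE]
    if (any(is.na(st$stop_success)))
      stop("stop trials without inhibition annotation")
    ok <- st[st$stop_success, , drop = FALSE]
    bad <- st[!st$stop_success, , drop = FALSE]
    rows$stop_success <- data.frame(
      event = "stop_success", trial = ok$index, condition = ok$condition,
      hand = ok$hand, valence = NA_character_, expectancy = NA_character_,
      link = NA_integer_, stringsAsFactors = FALSE)
    rows$stop_failure_stop <- data.frame(
      event = "stop_failure_stop", trial = bad$index,
      condition = bad$condition, hand = bad$hand,
      valence = NA_character_, expectancy = NA_character_,
      link = NA_integer_, stringsAsFactors = FALSE)
    rows$stop_failure_response <- data.frame(
      event = "stop_failure_response", trial = bad$index,
      condition = bad$condition, hand = bad$hand,
      valence = NA_character_, expectancy = NA_character_,
      link = bad$index, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  ev
}

# Expectancy cell of a feedback event: infrequent outcomes (easy errors,
# hard correct) are unexpected; frequent ones expected; control is its own
# cell.
expectancyCell <- function(condition, valence) {
  ifelse(condition == "control", "control",
  ifelse((condition == "easy" & valence == "error") |
         (condition == "hard" & valence == "correct"),
         "unexpected", "expected"))
}

#' Generate synthetic event-locked epochs from a trial log
#'
#' For every feedback event an FRN kernel is injected, scaled by the
#' condition x valence gain of the FRN spec; for every successful stop an
#' N2 at the stop-locked latency; for every failed stop a (half-gain) N2
#' into the stop-locked epoch plus an ERN into the response-locked epoch.
#' Each subject's component amplitudes are drawn once (between-subject SD,
#' correlated across components) and jittered per trial (within SD).
#' Spatially smooth 1/f noise is added on top. Deterministic per seed.
#'
#' Epochs span -200..600 ms around their locking event, sampled at 600 Hz
#' (480 samples); `decimate = k` keeps every k-th sample for fast tests.
#'
#' @param trials trial log of one subject (from [runSession()], or one
#'   subject's rows of [simulateCohort()] output).
#' @param specs named list of [componentSpec()]s.
#' @param noise a [noiseSpec()]; `rms = 0` gives noiseless epochs.
#' @param layout electrode layout, [makeLayout()].
#' @param seed integer seed for this subject's amplitude, jitter and noise
#'   draws.
#' @param subject subject id (defaults to the log's `subject` column, or
#'   `"s01"`).
#' @param events event classes to generate: `"feedback"`, `"stop"`, or both.
#' @param decimate integer temporal decimation factor (1 = full 600 Hz).
#' @param amplitudeCorrelation between-subject component correlation
#'   matrix, [defaultAmplitudeCorrelation()].
#' @return an [EpochSet-class] (not yet referenced or baselined).
#' @examples
#' log <- runSession(taskConfig(), agentParams(), seed = 2)
#' eps <- generateEpochs(log, noise = noiseSpec(rms = 0), seed = 2,
#'                       decimate = 4)
#' eps
#' @export
generateEpochs <- function(trials, specs = defaultComponentSpecs(),
                           noise = noiseSpec(), layout = makeLayout(),
                           seed = 1L, subject = NULL,
                           events = c("feedback", "stop"), decimate = 1L,
                           amplitudeCorrelation =
                             defaultAmplitudeCorrelation()) {
  if (is.null(subject)) {
    subject <- if ("subject" %in% names(trials)) {
      u <- unique(trials$subject)
      if (length(u) != 1L)
        stop("trial log holds several subjects; pass one subject's rows")
      u
    } else "s01"
  }
  ev <- buildEventTable(trials, events)
  if (nrow(ev) == 0L) stop("no epochs to generate for requested events")

  fs <- 600 / decimate
  times <- seq(-200, by = 1000 / 600, length.out = 480)
  if (decimate > 1L) times <- times[seq(1L, 480L, by = decimate)]
  ns <- length(times)
  nc <- nrow(layout)

  set.seed(seed)
  subjAmp <- drawSubjectAmplitudes(specs, amplitudeCorrelation, n = 1L)[1L, ]
  kernels <- lapply(specs, componentKernel, times = times)
  topos <- lapply(specs, function(sp)
    list(left = componentTopography(sp, "left", layout),
         right = componentTopography(sp, "right", layout)))

  data <- array(0, c(nrow(ev), nc, ns))
  bases <- list()  # precomputed topo x kernel outer products
  for (i in seq_len(nrow(ev))) {
    for (comp in names(specs)) {
      sp <- specs[[comp]]
      key <- if (sp$lock == "feedback" && ev$event[i] == "feedback")
        paste(ev$condition[i], ev$valence[i], sep = ".")
      else if (sp$lock == "stop" &&
               ev$event[i] %in% c("stop_success", "stop_failure_stop"))
        ev$event[i]
      else if (sp$lock == "response" &&
               ev$event[i] == "stop_failure_response")
        ev$event[i]
      else NA_character_
      if (is.na(key)) next
      g <- sp$conditionGain[key]
      if (is.na(g) || g == 0) next
      bkey <- paste(comp, ev$hand[i])
      if (is.null(bases[[bkey]]))
        bases[[bkey]] <- topos[[comp]][[ev$hand[i]]] %o% kernels[[comp]]
      amp <- subjAmp[comp] + rnorm(1, 0, sp$amplitudeSdWithin)
      data[i, , ] <- data[i, , ] + (-amp * g) * bases[[bkey]]
    }
  }

  if (noise$rms > 0) {
    h <- noiseFilter(ns, fs, noise$spectralExponent)
    d2 <- outer(layout$x, layout$x, "-")^2 + outer(layout$y, layout$y, "-")^2
    K <- exp(-d2 / (2 * noise$spatialSmoothness^2))
    U <- chol(K + 1e-8 * diag(nc))
    chunk <- 32L
    starts <- seq(1L, nrow(ev), by = chunk)
    for (s in starts) {
      idx <- s:min(s + chunk - 1L, nrow(ev))
      m <- length(idx)
      # columns are time series (trial-major blocks of channels)
      W <- matrix(rnorm(ns * nc * m), ns, nc * m)
      Z <- Re(mvfft(mvfft(W) * h, inverse = TRUE)) / ns
      dim(Z) <- c(ns, nc, m)
      Z <- matrix(aperm(Z, c(1L, 3L, 2L)), ns * m, nc) %*% U
      dim(Z) <- c(ns, m, nc)
      data[idx, , ] <- data[idx, , , drop = FALSE] +
        aperm(Z, c(2L, 3L, 1L)) * noise$rms
    }
  }

  EpochSet(subject, data, times, ev, layout$label)
}

#' Persist / restore an EpochSet
#'
#' Writes one file set per subject into `dir`: the epoch array
#' (`<subject>-data.rds`), the event table (`<subject>-events.csv`) and
#' the time axis plus channel labels (`<subject>-axes.csv`).
#'
#' @param x an [EpochSet-class].
#' @param dir output directory (created if missing).
#' @param subject subject id to restore.
#' @return `writeEpochSet` the directory invisibly; `readEpochSet` an
#'   [EpochSet-class].
#' @export
writeEpochSet <- function(x, dir) {
  stopifnot(is(x, "EpochSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- x@subject
  saveRDS(x@data, file.path(dir, paste0(s, "-data.rds")))
  write.csv(x@events, file.path(dir, paste0(s, "-events.csv")),
            row.names = FALSE)
  axes <- data.frame(
    kind = c(rep("time_ms", length(x@times)),
             rep("channel", length(x@channels)),
             "referenced", "baselined"),
    value = c(x@times, x@channels, x@referenced, x@baselined))
  write.csv(axes, file.path(dir, paste0(s, "-axes.csv")), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(dir, subject) {
  data <- readRDS(file.path(dir, paste0(subject, "-data.rds")))
  eventsPath <- file.path(dir, paste0(subject, "-events.csv"))
  ev <- read.csv(eventsPath, stringsAsFactors = FALSE)
  axes <- read.csv(file.path(dir, paste0(subject, "-axes.csv")),
                   stringsAsFactors = FALSE)
  EpochSet(subject, data,
           as.numeric(axes$value[axes$kind == "time_ms"]),
           ev, axes$value[axes$kind == "channel"],
           referenced = as.logical(axes$value[axes$kind == "referenced"]),
           baselined = as.logical(axes$value[axes$kind == "baselined"]))
}
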