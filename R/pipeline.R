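#' Canonical preprocessing chain for synthetic epochs
#'
#' Applies, in order: common-average referencing; per-epoch baseline
#' correction over `window` for feedback- and stop-locked epochs; and
#' linked baseline correction for response-locked (failed-stop) epochs,
#' whose baseline is the `window` interval of their linked stop-locked
#' epoch (the interval preceding the stop-signal).
#'
#' @param x an [EpochSet-class] straight from [generateEpochs()].
#' @param window baseline interval in ms.
#' @return referenced, baselined [EpochSet-class].
#' @export
prepareEpochs <- function(x, window = c(-200, 0)) {
  stopifnot(is(x, "EpochSet"))
  x <- commonAverageReference(x)
  idx <- which(x@times >= window[1] & x@times <= window[2])
  if (length(idx) == 0L) stop("baseline window outside the epoch")
  b <- rowSums(x@data[, , idx, drop = FALSE], dims = 2L) / length(idx)
  b[x@events$event == "stop_failure_response", ] <- 0
  x <- initialize(x, data = sweep(x@data, c(1L, 2L), b), baselined = TRUE)
  if (any(x@events$event == "stop_failure_response"))
    x <- linkedBaselineCorrect(x, window)
  x
}

#' Default end-to-end study configuration
#'
#' The `study` profile runs the full design: 24 subjects, the full
#' 720-trial task, 600 Hz epochs, 100,000 permutations. The `fast`
#' profile trims the permutation count and decimates the epochs for quick
#' smoke runs; it does not change the generator's scientific defaults.
#'
#' @param profile `"study"` (full scale) or `"fast"`.
#' @param seed root seed; all stages derive their streams from it.
#' @param outputDir optional directory for trial logs, peak tables and the
#'   JSON report.
#' @return nested list of class `"runConfig"`.
#' @export
defaultRunConfig <- function(profile = c("study", "fast"), seed = 1L,
                             outputDir = NULL) {
  profile <- match.arg(profile)
  structure(list(
    profile = profile,
    seed = as.integer(seed),
    nSubjects = 24L,
    task = taskConfig(),
    agents = agentParams(),
    specs = defaultComponentSpecs(),
    noise = noiseSpec(),
    amplitudeCorrelation = defaultAmplitudeCorrelation(),
    analysis = list(channel = "FCz",
                    nPermutations = if (profile == "study") 100000L
                                    else 10000L,
                    decimate = if (profile == "study") 1L else 2L),
    outputDir = outputDir), class = "runConfig")
}

#' Read a study configuration from a YAML file
#'
#' Accepts a structured key/value file with (all optional) sections
#' `profile`, `seed`, `n_subjects`, `task`, `agents`, `noise`,
#' `analysis`, `output_dir`; unspecified values keep the defaults of
#' [defaultRunConfig()]. Task and agent subsections use the argument
#' names of [taskConfig()] and [agentParams()].
#'
#' @param path YAML file path.
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- defaultRunConfig(profile = y$profile %||% "study",
                          seed = y$seed %||% 1L,
                          outputDir = y$output_dir)
  if (!is.null(y$n_subjects)) cfg$nSubjects <- as.integer(y$n_subjects)
  if (!is.null(y$task)) cfg$task <- do.call(taskConfig, y$task)
  if (!is.null(y$agents)) cfg$agents <- do.call(agentParams, y$agents)
  if (!is.null(y$noise)) cfg$noise <- do.call(noiseSpec, y$noise)
  for (k in names(y$analysis)) cfg$analysis[[k]] <- y$analysis[[k]]
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-subject stage: generate, preprocess, measure, and keep the small
# per-subject averages needed for group topography statistics.
subjectStage <- function(log, cfg, seed) {
  eps <- generateEpochs(log, specs = cfg$specs, noise = cfg$noise,
                        seed = seed, decimate = cfg$analysis$decimate,
                        amplitudeCorrelation = cfg$amplitudeCorrelation)
  eps <- prepareEpochs(eps)
  ch <- cfg$analysis$channel
  tryNA <- function(expr) tryCatch(expr, error = function(e) NULL)
  avgFor <- function(component, hand) {
    ev <- eps@events
    sel <- switch(component,
      FRN = NULL,
      N2 = ev$event == "stop_success",
      ERN = ev$event == "stop_failure_response")
    if (component == "FRN") {
      a <- tryNA(erpAverage(eps, feedbackCell(ev, "easy", "error", hand)))
      b <- tryNA(erpAverage(eps, feedbackCell(ev, "hard", "correct", hand)))
      if (is.null(a) || is.null(b)) return(NULL)
      differenceWave(a, b)
    } else {
      if (!is.null(hand)) sel <- sel & ev$hand == hand
      tryNA(erpAverage(eps, sel, selector = component))
    }
  }
  measures <- rbind(
    tryNA(measureFrn(eps, "unexpected", ch)),
    tryNA(measureFrn(eps, "expected", ch)),
    tryNA(measureFrn(eps, "control", ch)),
    tryNA(measureN2(eps, ch)), tryNA(measureErn(eps, ch)),
    tryNA(measureFrn(eps, "unexpected", ch, hand = "left")),
    tryNA(measureFrn(eps, "unexpected", ch, hand = "right")),
    tryNA(measureN2(eps, ch, hand = "left")),
    tryNA(measureN2(eps, ch, hand = "right")),
    tryNA(measureErn(eps, ch, hand = "left")),
    tryNA(measureErn(eps, ch, hand = "right")))
  halves <- lapply(c(FRN = "FRN", N2 = "N2", ERN = "ERN"),
                   function(cc) splitHalfMeasures(eps, cc, ch))
  averages <- list()
  for (comp in c("FRN", "N2", "ERN"))
    for (hand in c("left", "right")) {
      a <- avgFor(comp, hand)
      if (!is.null(a)) averages[[paste(comp, hand, sep = ".")]] <- a@data
    }
  list(measures = measures, halves = halves, averages = averages,
       times = eps@times, channels = eps@channels)
}

#' Run the full simulated study
#'
#' Orchestrates simulate -> generate EEG -> preprocess -> quantify ->
#' statistics with full seed provenance: simulates the cohort, builds and
#' measures every subject's epochs, then computes the group-level
#' behavioral summaries, component amplitude table, GMD permutation tests
#' (left vs right hand per component and pairwise component contrasts
#' within hand), split-half reliabilities, and standardized bivariate
#' regressions between the components. Identical configuration and seed
#' give an identical report.
#'
#' @param config a `runConfig` from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return report list (also written as JSON along with trial-log and
#'   peak-table CSVs when `config$outputDir` is set).
#' @export
runStudy <- function(config = defaultRunConfig()) {
  seed <- config$seed
  cohort <- simulateCohort(config$task, config$agents, config$nSubjects,
                           seed = seed)
  eegSeeds <- subjectSeeds(seed + 1L, config$nSubjects)
  permSeed <- subjectSeeds(seed + 2L, 1L)

  subjects <- sprintf("s%02d", seq_len(config$nSubjects))
  stages <- lapply(seq_along(subjects), function(i)
    subjectStage(cohort[cohort$subject == subjects[i], ], config,
                 eegSeeds[i]))
  names(stages) <- subjects

  warnings <- character(0)
  measures <- do.call(rbind, lapply(subjects, function(s) {
    m <- stages[[s]]$measures
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    m$subject <- s
    m
  }))
  if (is.null(measures))
    stop("no component could be measured for any subject")
  lowTrials <- measures$n_trials < 10
  if (any(lowTrials, na.rm = TRUE))
    warnings <- c(warnings, sprintf(
      "%d measure(s) rest on fewer than 10 trials", sum(lowTrials)))

  # amplitude table: grand mean +/- SD of each component at the channel
  pooled <- measures[measures$hand == "both", ]
  keyComp <- c(FRN = "FRN.unexpected", N2 = "N2", ERN = "ERN")
  amplitudes <- do.call(rbind, lapply(names(keyComp), function(k) {
    v <- pooled$amplitude_uV[pooled$component == keyComp[k]]
    data.frame(component = k,
               mean_uV = if (length(v)) mean(v) else NA_real_,
               sd_uV = if (length(v) > 1) sd(v) else NA_real_,
               n_subjects = length(v))
  }))

  # reliability
  reliability <- do.call(rbind, lapply(c("FRN", "N2", "ERN"), function(cc) {
    h <- lapply(stages, function(st) st$halves[[cc]])
    names(h) <- subjects
    tryCatch(withCallingHandlers(
      splitHalfReliability(h, component = cc, config$analysis$channel),
      warning = function(w) {
        warnings <<- c(warnings, paste0(cc, " reliability: ",
                                        conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        warnings <<- c(warnings, paste0(cc, " reliability skipped: ",
                                        conditionMessage(e)))
        data.frame(component = cc, channel = config$analysis$channel,
                   r_half = NA_real_, r_sb = NA_real_,
                   n_subjects = NA_integer_, n_excluded = NA_integer_)
      })
  }))

  # regressions between z-normalized component measures
  wide <- lapply(keyComp, function(k) {
    v <- pooled[pooled$component == k, ]
    v$amplitude_uV[match(subjects, v$subject)]
  })
  regPairs <- list(c("FRN", "N2"), c("FRN", "ERN"), c("N2", "ERN"))
  regressions <- do.call(rbind, lapply(regPairs, function(pr) {
    res <- tryCatch(
      bivariateRegression(wide[[pr[1]]], wide[[pr[2]]]),
      error = function(e) {
        warnings <<- c(warnings, sprintf("regression %s~%s skipped: %s",
                                         pr[2], pr[1],
                                         conditionMessage(e)))
        data.frame(beta = NA_real_, sem = NA_real_, t = NA_real_,
                   p = NA_real_, r2 = NA_real_, n = NA_integer_)
      })
    cbind(data.frame(x = pr[1], y = pr[2]), res)
  }))

  # GMD permutation tests on per-subject maps at the grand-average peak
  gmdTests <- list()
  times <- stages[[1]]$times
  channels <- stages[[1]]$channels
  chIdx <- match(config$analysis$channel, channels)
  grandPeakLatency <- function(key, component) {
    mats <- lapply(stages, function(st) st$averages[[key]])
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (length(mats) < 2L) return(NULL)
    g <- Reduce(`+`, mats) / length(mats)
    sc <- if (component == "FRN") minScan(g[chIdx, ], times, c(0, 600))
          else troughToPeakScan(g[chIdx, ], times,
                                if (component == "N2") c(120, 280)
                                else c(0, 120))
    list(latency = sc$latency, n = length(mats))
  }
  subjectMaps <- function(key, latency) {
    mats <- lapply(stages, function(st) st$averages[[key]])
    keep <- !vapply(mats, is.null, logical(1))
    j <- which.min(abs(times - latency))
    do.call(rbind, lapply(mats[keep], function(m) m[, j]))
  }
  peakLat <- list()
  for (comp in c("FRN", "N2", "ERN"))
    for (hand in c("left", "right")) {
      key <- paste(comp, hand, sep = ".")
      peakLat[[key]] <- grandPeakLatency(key, comp)
    }
  addTest <- function(label, keyA, keyB, latA, latB) {
    if (is.null(peakLat[[keyA]]) || is.null(peakLat[[keyB]])) {
      warnings <<- c(warnings, paste("GMD test skipped (missing maps):",
                                     label))
      return(NULL)
    }
    A <- subjectMaps(keyA, peakLat[[keyA]]$latency)
    B <- subjectMaps(keyB, peakLat[[keyB]]$latency)
    if (nrow(A) != nrow(B)) {
      warnings <<- c(warnings, paste("GMD test skipped (unpaired maps):",
                                     label))
      return(NULL)
    }
    res <- gmdPermutationTest(A, B, nPerm = config$analysis$nPermutations,
                              seed = permSeed)
    gmdTests[[label]] <<- list(observed_gmd = observedGmd(res),
                               p = pValue(res),
                               n_perm = nPermutations(res),
                               n_subjects = nrow(A),
                               seed = res@seed)
  }
  for (comp in c("FRN", "N2", "ERN"))
    addTest(paste0(comp, ".left_vs_right"),
            paste(comp, "left", sep = "."), paste(comp, "right", sep = "."))
  pairs <- list(c("FRN", "N2"), c("FRN", "ERN"), c("N2", "ERN"))
  for (hand in c("left", "right"))
    for (pr in pairs)
      addTest(paste0(pr[1], "_vs_", pr[2], ".", hand),
              paste(pr[1], hand, sep = "."), paste(pr[2], hand, sep = "."))

  behavior <- behaviorSummary(cohort)
  report <- list(
    schema_version = "1.0",
    profile = config$profile,
    seed = seed,
    n_subjects = config$nSubjects,
    behavioral = list(conditions = behavior$conditions,
                      adaptation = behavior$adaptation,
                      stop = behavior$stop,
                      transfer = behavior$transfer),
    amplitudes = amplitudes,
    gmd = gmdTests,
    reliability = reliability,
    regressions = regressions,
    warnings = warnings)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeTrialLog(cohort, file.path(config$outputDir, "trials.csv"))
    writePeakTable(measures, file.path(config$outputDir, "peaks.csv"))
    jsonlite::write_json(report, file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
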