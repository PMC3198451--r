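#' Task configuration for the time-estimation / stop-signal paradigm
#'
#' The task asks an agent to reproduce a 1000 ms interval; a response is
#' "on time" if it falls inside an adaptive response time window (RTW)
#' centered on 1000 ms. Window width is staircased per condition:
#' symmetrically (+/-10 ms) in the control condition, +12 ms on error /
#' -4 ms on correct in the easy condition (error rate driven towards 1/4),
#' and +4/-12 in the hard condition (error rate towards 3/4). A fifth of
#' trials are stop trials: a stop-signal is presented `lead` ms before the
#' expected response (mean of the last 8 estimation RTs), with the lead
#' staircased by 7 ms to track ~50% successful inhibition.
#'
#' @param conditions condition tags, run in `conditionOrder`.
#' @param blocksPerCondition blocks per condition (default 8).
#' @param trialsPerBlock trials per block (default 30).
#' @param stopFraction proportion of stop trials per block (default 0.20).
#' @param rtwInitWidth initial total RTW width in ms (200, i.e. 1000+/-100).
#' @param rtwSteps named list, per condition `c(error=, correct=)` step in ms
#'   applied to the total width (grow on error, shrink on correct).
#' @param rtwMinWidth floor of the total window width in ms.
#' @param stopLeadInit initial stop-signal lead before the expected response.
#' @param stopLeadStep staircase step for the lead in ms (default 7).
#' @param stopLeadWindow running-mean length for the expected response.
#' @param targetMs target interval; the RTW is centered here.
#' @param feedbackDelay ms between response and feedback (bookkeeping only;
#'   the generator locks feedback epochs to the feedback event itself).
#' @param itiRange inter-trial interval range in ms (bookkeeping only).
#' @param firstHand hand used in the first block; hands alternate per block.
#' @param conditionOrder order in which conditions are run; the RTW reached
#'   at the end of the first condition is the starting width of every later
#'   condition.
#' @return a validated list of class `"taskConfig"`.
#' @examples
#' cfg <- taskConfig()
#' cfg$rtwSteps$easy
#' @export
taskConfig <- function(conditions = c("control", "easy", "hard"),
                       blocksPerCondition = 8L,
                       trialsPerBlock = 30L,
                       stopFraction = 0.20,
                       rtwInitWidth = 200,
                       rtwSteps = list(control = c(error = 10, correct = 10),
                                       easy    = c(error = 12, correct = 4),
                                       hard    = c(error = 4,  correct = 12)),
                       rtwMinWidth = 20,
                       stopLeadInit = 150,
                       stopLeadStep = 7,
                       stopLeadWindow = 8L,
                       targetMs = 1000,
                       feedbackDelay = 600,
                       itiRange = c(200, 900),
                       firstHand = "left",
                       conditionOrder = conditions) {
  stopifnot(length(conditions) >= 1, !anyDuplicated(conditions),
            setequal(conditions, conditionOrder),
            blocksPerCondition >= 1, trialsPerBlock >= 1,
            stopFraction >= 0, stopFraction < 1,
            rtwInitWidth >= rtwMinWidth, rtwMinWidth > 0,
            stopLeadInit >= 0, stopLeadStep >= 0, stopLeadWindow >= 1,
            firstHand %in% c("left", "right"))
  if (!all(conditions %in% names(rtwSteps)))
    stop("rtwSteps must provide a step pair for every condition")
  for (s in rtwSteps[conditions])
    stopifnot(all(c("error", "correct") %in% names(s)), all(s >= 0))
  structure(list(conditions = conditions,
                 blocksPerCondition = as.integer(blocksPerCondition),
                 trialsPerBlock = as.integer(trialsPerBlock),
                 stopFraction = stopFraction,
                 rtwInitWidth = rtwInitWidth,
                 rtwSteps = rtwSteps,
                 rtwMinWidth = rtwMinWidth,
                 stopLeadInit = stopLeadInit,
                 stopLeadStep = stopLeadStep,
                 stopLeadWindow = as.integer(stopLeadWindow),
                 targetMs = targetMs,
                 feedbackDelay = feedbackDelay,
                 itiRange = itiRange,
                 firstHand = firstHand,
                 conditionOrder = conditionOrder),
            class = "taskConfig")
}

#' Agent (simulated participant) parameters
#'
#' The agent's estimation RT on each trial is
#' `target + bias + Normal(0, rtSd^2)`; `bias` random-walks with step SD
#' `driftSd` per trial and, after error feedback, is pulled 50% towards 0
#' with an extra `Normal(0, postErrorAdjustSd^2)` recentring perturbation
#' (so RT changes are larger after errors than after correct feedback).
#' Stop trials follow an independent horse race: inhibition succeeds iff
#' `stopOnset + SSRT < plannedRt`, with SSRT drawn
#' `Normal(ssrtMean, ssrtSd^2)` and an optional left-hand advantage
#' (`ssrtHandDelta` ms subtracted from the left-hand SSRT mean).
#'
#' @param rtSd Gaussian timing-noise SD in ms.
#' @param driftSd random-walk drift of the internal target, ms per trial.
#' @param postErrorAdjustSd extra recentring SD applied after error feedback.
#' @param ssrtMean,ssrtSd stop-signal reaction time distribution, ms.
#' @param ssrtHandDelta left-hand SSRT advantage in ms (default 0).
#' @return a validated list of class `"agentParams"`.
#' @export
agentParams <- function(rtSd = 140, driftSd = 8, postErrorAdjustSd = 60,
                        ssrtMean = 190, ssrtSd = 30, ssrtHandDelta = 0) {
  stopifnot(rtSd >= 0, driftSd >= 0, postErrorAdjustSd >= 0,
            ssrtMean > 0, ssrtSd >= 0)
  structure(list(rtSd = rtSd, driftSd = driftSd,
                 postErrorAdjustSd = postErrorAdjustSd,
                 ssrtMean = ssrtMean, ssrtSd = ssrtSd,
                 ssrtHandDelta = ssrtHandDelta),
            class = "agentParams")
}

#' Staircase update of the response time window
#'
#' Grows the total window width by the condition's error step after an
#' error, shrinks it by the correct step after a correct response, clamped
#' at the configured floor.
#'
#' @param width current total window width, ms.
#' @param condition condition tag (must be configured in `config$rtwSteps`).
#' @param outcome `"correct"` or `"error"`.
#' @param config a [taskConfig()].
#' @return updated width in ms.
#' @examples
#' updateRtw(300, "easy", "error")    # 312
#' updateRtw(300, "hard", "correct")  # 288
#' @export
updateRtw <- function(width, condition, outcome, config = taskConfig()) {
  steps <- config$rtwSteps[[condition]]
  if (is.null(steps))
    stop("unknown condition tag: ", condition)
  outcome <- match.arg(outcome, c("correct", "error"))
  w <- if (outcome == "error") width + steps[["error"]]
       else width - steps[["correct"]]
  max(w, config$rtwMinWidth)
}

#' Classify an estimation response against the current window
#'
#' On time iff `|rt - target| <= width / 2` (boundaries inclusive).
#'
#' @param rt response time, ms (> 0).
#' @param width total window width, ms (> 0).
#' @param center window center, ms.
#' @return `"correct"` or `"error"`.
#' @export
classifyResponse <- function(rt, width, center = 1000) {
  stopifnot(all(rt > 0), all(width > 0))
  ifelse(abs(rt - center) <= width / 2, "correct", "error")
}

#' Staircase update of the stop-signal lead
#'
#' After successful inhibition the lead shrinks (the stop-signal moves
#' later, closer to the expected response: harder); after a failed
#' inhibition it grows. Floored at 0.
#'
#' @param lead current lead in ms.
#' @param stopSuccess logical.
#' @param step staircase step, ms.
#' @return updated lead in ms.
#' @export
updateStopLead <- function(lead, stopSuccess, step = 7) {
  stopifnot(lead >= 0)
  if (isTRUE(stopSuccess)) max(lead - step, 0) else lead + step
}

#' Stop-signal onset from the recent response history
#'
#' Onset (ms after the estimation cue) is the mean of the last up-to-8
#' estimation RTs minus the current lead. With an empty history the target
#' interval (1000 ms) stands in for the mean.
#'
#' @param recentRts numeric vector of recent estimation RTs (most recent
#'   window, may be empty).
#' @param lead current stop lead, ms.
#' @param target fallback expected response time, ms.
#' @return onset in ms (floored at 0).
#' @export
stopOnset <- function(recentRts, lead, target = 1000) {
  expected <- if (length(recentRts) == 0L) target else mean(recentRts)
  max(expected - lead, 0)
}

#' Horse-race outcome of one stop trial
#'
#' The go process would finish at `plannedRt`; the stop process finishes at
#' `onset + ssrt`. Inhibition succeeds iff the stop process wins
#' (`onset + ssrt < plannedRt`); on failure the planned response is
#' committed.
#'
#' @param plannedRt planned response time, ms.
#' @param onset stop-signal onset, ms (>= 0).
#' @param ssrt stop-signal reaction time draw, ms.
#' @return list with `success` (logical) and `rt` (committed RT on failure,
#'   `NA` on success).
#' @export
simulateStopTrial <- function(plannedRt, onset, ssrt) {
  stopifnot(onset >= 0)
  if (onset + ssrt < plannedRt) list(success = TRUE, rt = NA_real_)
  else list(success = FALSE, rt = plannedRt)
}

#' Simulate one full session of the task
#'
#' Runs `length(conditions) x blocksPerCondition x trialsPerBlock` trials
#' for one agent. Hands alternate every block starting from
#' `config$firstHand`; each block contains
#' `round(trialsPerBlock * stopFraction)` randomly positioned stop trials.
#' The RTW width reached at the end of the first condition in
#' `conditionOrder` is the starting width for every later condition. Stop
#' trials never update the RTW, and RTs committed on failed stops do not
#' enter the running mean that schedules stop-signal onsets.
#'
#' @param config a [taskConfig()].
#' @param params an [agentParams()].
#' @param seed integer seed; identical `(config, params, seed)` give
#'   byte-identical trial logs.
#' @return data.frame, one row per trial: `index`, `block` (global, 1-based),
#'   `condition`, `hand`, `trial_type` (`estimation`/`stop`), `rt` (ms, `NA`
#'   on successful inhibition), `rtw_width` (total width in force), `on_time`
#'   (logical, estimation only), `stop_lead`, `stop_onset`, `stop_success`
#'   (stop only), `feedback` (`correct`/`error`, estimation only).
#' @examples
#' log <- runSession(taskConfig(), agentParams(), seed = 1)
#' table(log$trial_type)
#' @export
runSession <- function(config = taskConfig(), params = agentParams(),
                       seed = 1L) {
  set.seed(seed)
  nCond <- length(config$conditionOrder)
  nPerBlock <- config$trialsPerBlock
  nBlocks <- nCond * config$blocksPerCondition
  nTotal <- nBlocks * nPerBlock
  nStopPerBlock <- round(nPerBlock * config$stopFraction)

  out <- data.frame(
    index = seq_len(nTotal), block = NA_integer_,
    condition = NA_character_, hand = NA_character_,
    trial_type = NA_character_, rt = NA_real_, rtw_width = NA_real_,
    on_time = NA, stop_lead = NA_real_, stop_onset = NA_real_,
    stop_success = NA, feedback = NA_character_,
    stringsAsFactors = FALSE)

  hands <- c("left", "right")
  otherHand <- setdiff(hands, config$firstHand)
  width <- config$rtwInitWidth
  carryWidth <- NA_real_
  lead <- config$stopLeadInit
  bias <- 0
  recent <- numeric(0)
  row <- 0L
  globalBlock <- 0L

  for (ci in seq_along(config$conditionOrder)) {
    cond <- config$conditionOrder[ci]
    if (ci > 1L) width <- carryWidth
    for (b in seq_len(config$blocksPerCondition)) {
      globalBlock <- globalBlock + 1L
      hand <- if (globalBlock %% 2L == 1L) config$firstHand else otherHand
      stopPos <- if (nStopPerBlock > 0L)
        sample.int(nPerBlock, nStopPerBlock) else integer(0)
      for (t in seq_len(nPerBlock)) {
        row <- row + 1L
        plannedRt <- max(config$targetMs + bias + rnorm(1, 0, params$rtSd), 1)
        out$block[row] <- globalBlock
        out$condition[row] <- cond
        out$hand[row] <- hand
        out$rtw_width[row] <- width
        if (t %in% stopPos) {
          onset <- stopOnset(recent, lead, config$targetMs)
          mu <- params$ssrtMean -
            if (hand == "left") params$ssrtHandDelta else 0
          ssrt <- max(rnorm(1, mu, params$ssrtSd), 0)
          res <- simulateStopTrial(plannedRt, onset, ssrt)
          out$trial_type[row] <- "stop"
          out$rt[row] <- res$rt
          out$stop_lead[row] <- lead
          out$stop_onset[row] <- onset
          out$stop_success[row] <- res$success
          lead <- updateStopLead(lead, res$success, config$stopLeadStep)
        } else {
          fb <- classifyResponse(plannedRt, width, config$targetMs)
          out$trial_type[row] <- "estimation"
          out$rt[row] <- plannedRt
          out$on_time[row] <- fb == "correct"
          out$feedback[row] <- fb
          width <- updateRtw(width, cond, fb, config)
          recent <- c(recent, plannedRt)
          if (length(recent) > config$stopLeadWindow)
            recent <- recent[-1L]
          if (fb == "error")
            bias <- 0.5 * bias + rnorm(1, 0, params$postErrorAdjustSd)
        }
        bias <- bias + rnorm(1, 0, params$driftSd)
      }
    }
    if (ci == 1L) carryWidth <- width
  }
  out
}

#' Simulate a cohort of agents
#'
#' Derives one independent substream per subject from the root seed and
#' runs [runSession()] for each.
#'
#' @param config a [taskConfig()].
#' @param params an [agentParams()] shared by all agents.
#' @param nSubjects number of agents (default 24).
#' @param seed root integer seed.
#' @return data.frame of trial logs with a leading `subject` column
#'   (`"s01"`, `"s02"`, ...).
#' @export
simulateCohort <- function(config = taskConfig(), params = agentParams(),
                           nSubjects = 24L, seed = 1L) {
  stopifnot(nSubjects >= 1)
  seeds <- subjectSeeds(seed, nSubjects)
  logs <- lapply(seq_len(nSubjects), function(i) {
    log <- runSession(config, params, seed = seeds[i])
    cbind(subject = sprintf("s%02d", i), log, stringsAsFactors = FALSE)
  })
  do.call(rbind, logs)
}

# Independent per-subject substreams from one root seed.
subjectSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Write / read a trial log as CSV
#'
#' One trial per row, header row, missing values empty.
#'
#' @param log trial-log data.frame from [runSession()] or
#'   [simulateCohort()].
#' @param path file path.
#' @return `writeTrialLog` returns `path` invisibly; `readTrialLog` the
#'   data.frame.
#' @export
writeTrialLog <- function(log, path) {
  write.csv(log, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTrialLog
#' @export
readTrialLog <- function(path) {
  log <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("on_time", "stop_success"))
    if (col %in% names(log)) log[[col]] <- as.logical(log[[col]])
  log
}
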