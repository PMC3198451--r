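#' Behavioral summary of a trial log
#'
#' Computes the behavioral statistics of the paradigm from a trial log
#' (one subject, or a cohort log with a `subject` column -- statistics are
#' then pooled over rows):
#'
#' * `conditions`: percent on-time responses and median RTW width per
#'   condition x hand (estimation trials);
#' * `adaptation`: mean absolute response-time change from the previous
#'   estimation trial, grouped by the previous trial's expectancy x
#'   valence feedback cell (easy/hard conditions; control is its own
#'   expectancy level). Only within-block estimation-to-estimation pairs
#'   count; pairs spanning a stop trial feed the transfer analysis
#'   instead;
#' * `stop`: success rate per hand, plus mean lead and mean onset per
#'   condition;
#' * `transfer`: estimation accuracy on the trial immediately before vs
#'   immediately after each stop trial.
#'
#' @param trials trial-log data.frame.
#' @return list of class `"behaviorSummary"` with elements `conditions`,
#'   `adaptation`, `stop`, `transfer`.
#' @export
behaviorSummary <- function(trials) {
  est <- trials[trials$trial_type == "estimation", , drop = FALSE]
  stp <- trials[trials$trial_type == "stop", , drop = FALSE]

  conditions <- do.call(rbind, lapply(
    split(est, list(est$condition, est$hand), drop = TRUE),
    function(d) data.frame(condition = d$condition[1], hand = d$hand[1],
                           percent_correct = 100 * mean(d$on_time),
                           percent_error = 100 * mean(!d$on_time),
                           median_rtw_width = median(d$rtw_width),
                           n_trials = nrow(d))))
  rownames(conditions) <- NULL

  # consecutive estimation pairs within a block (and subject, if present)
  grp <- if ("subject" %in% names(trials))
    paste(trials$subject, trials$block) else as.character(trials$block)
  ord <- seq_len(nrow(trials))
  pairs <- data.frame(prev = ord[-nrow(trials)], cur = ord[-1],
                      sameBlock = grp[-nrow(trials)] == grp[-1])
  estPair <- pairs$sameBlock &
    trials$trial_type[pairs$prev] == "estimation" &
    trials$trial_type[pairs$cur] == "estimation"
  pp <- pairs[estPair, , drop = FALSE]
  adapt <- data.frame(
    expectancy = expectancyCell(trials$condition[pp$prev],
                                trials$feedback[pp$prev]),
    valence = trials$feedback[pp$prev],
    condition = trials$condition[pp$prev],
    abs_drt = abs(trials$rt[pp$cur] - trials$rt[pp$prev]))
  adaptation <- do.call(rbind, lapply(
    split(adapt, list(adapt$expectancy, adapt$valence), drop = TRUE),
    function(d) data.frame(expectancy = d$expectancy[1],
                           valence = d$valence[1],
                           mean_abs_drt = mean(d$abs_drt),
                           n_pairs = nrow(d))))
  rownames(adaptation) <- NULL
  byCondition <- do.call(rbind, lapply(
    split(adapt, list(adapt$condition, adapt$valence), drop = TRUE),
    function(d) data.frame(condition = d$condition[1],
                           prev_feedback = d$valence[1],
                           mean_abs_drt = mean(d$abs_drt),
                           n_pairs = nrow(d))))
  rownames(byCondition) <- NULL

  stopByHand <- do.call(rbind, lapply(split(stp, stp$hand), function(d)
    data.frame(hand = d$hand[1],
               percent_success = 100 * mean(d$stop_success),
               n_trials = nrow(d))))
  rownames(stopByHand) <- NULL
  stopByCondition <- do.call(rbind, lapply(
    split(stp, stp$condition), function(d)
      data.frame(condition = d$condition[1],
                 mean_lead = mean(d$stop_lead),
                 mean_onset = mean(d$stop_onset),
                 percent_success = 100 * mean(d$stop_success))))
  rownames(stopByCondition) <- NULL

  stopRows <- which(trials$trial_type == "stop")
  pre <- stopRows - 1L
  post <- stopRows + 1L
  okPre <- pre >= 1 & grp[pmax(pre, 1)] == grp[stopRows] &
    trials$trial_type[pmax(pre, 1)] == "estimation"
  okPost <- post <= nrow(trials) &
    grp[pmin(post, nrow(trials))] == grp[stopRows] &
    trials$trial_type[pmin(post, nrow(trials))] == "estimation"
  transfer <- data.frame(
    percent_correct_pre = 100 * mean(trials$on_time[pre[okPre]]),
    percent_correct_post = 100 * mean(trials$on_time[post[okPost]]),
    n_pre = sum(okPre), n_post = sum(okPost))

  structure(list(conditions = conditions,
                 adaptation = adaptation,
                 adaptation_by_condition = byCondition,
                 stop = list(by_hand = stopByHand,
                             by_condition = stopByCondition,
                             percent_success = 100 * mean(stp$stop_success)),
                 transfer = transfer),
            class = "behaviorSummary")
}

#' @export
print.behaviorSummary <- function(x, ...) {
  cat("Behavioral summary\n\nPer condition x hand:\n")
  print(x$conditions, row.names = FALSE)
  cat("\n|dRT| after previous feedback (expectancy x valence):\n")
  print(x$adaptation, row.names = FALSE)
  cat(sprintf("\nStop success overall: %.1f%%\n", x$stop$percent_success))
  print(x$stop$by_hand, row.names = FALSE)
  cat("\nTransfer (estimation accuracy around stop trials):\n")
  print(x$transfer, row.names = FALSE)
  invisible(x)
}
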