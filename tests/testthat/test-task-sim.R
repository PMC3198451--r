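test_that("RTW staircase applies the condition-specific steps with a floor", {
  expect_equal(updateRtw(300, "easy", "error"), 312)
  expect_equal(updateRtw(300, "easy", "correct"), 296)
  expect_equal(updateRtw(300, "hard", "correct"), 288)
  expect_equal(updateRtw(300, "hard", "error"), 304)
  expect_equal(updateRtw(300, "control", "correct"), 290)
  expect_equal(updateRtw(300, "control", "error"), 310)
  cfg <- taskConfig()
  expect_equal(updateRtw(cfg$rtwMinWidth, "hard", "correct", cfg),
               cfg$rtwMinWidth)
  expect_error(updateRtw(300, "impossible", "error"), "unknown condition")
})

test_that("response classification is inclusive at the window boundaries", {
  expect_equal(classifyResponse(1000, 200), "correct")
  expect_equal(classifyResponse(1100, 200), "correct")
  expect_equal(classifyResponse(900, 200), "correct")
  expect_equal(classifyResponse(1101, 200), "error")
  expect_equal(classifyResponse(899, 200), "error")
})

test_that("stop-lead staircase tightens after success, floors at zero", {
  expect_equal(updateStopLead(150, TRUE), 143)
  expect_equal(updateStopLead(150, FALSE), 157)
  expect_equal(updateStopLead(3, TRUE), 0)
})

test_that("stop onset follows the 8-trial running mean minus the lead", {
  expect_equal(stopOnset(rep(1000, 8), 150), 850)
  expect_equal(stopOnset(rep(1000, 8), 0), 1000)
  expect_equal(stopOnset(rep(c(900, 1100), 4), 150), 850)
  expect_equal(stopOnset(numeric(0), 150), 850)  # documented fallback
})

test_that("horse race decides stop trials and is fair at the tracked point", {
  expect_true(simulateStopTrial(1000, 850, 100)$success)
  res <- simulateStopTrial(1000, 850, 200)
  expect_false(res$success)
  expect_equal(res$rt, 1000)
  # symmetric SSRT around the onset-to-response gap -> 50% success
  set.seed(42)
  n <- 2e4
  wins <- vapply(rnorm(n, 190, 30), function(ssrt)
    simulateStopTrial(1040, 1040 - 190, ssrt)$success, logical(1))
  expect_lt(abs(mean(wins) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("a session has the configured trial bookkeeping", {
  log <- runSession(taskConfig(), agentParams(), seed = 5)
  expect_equal(nrow(log), 720)
  expect_equal(sum(log$trial_type == "stop"), 144)
  expect_equal(sum(log$trial_type == "estimation"), 576)
  # stop trials carry stop state, estimation trials carry feedback
  stp <- log[log$trial_type == "stop", ]
  est <- log[log$trial_type == "estimation", ]
  expect_true(all(!is.na(stp$stop_lead) & !is.na(stp$stop_onset) &
                    !is.na(stp$stop_success)))
  expect_true(all(is.na(stp$feedback)))
  expect_true(all(!is.na(est$feedback) & !is.na(est$on_time)))
  # on_time consistent with the recorded width
  expect_equal(est$on_time, abs(est$rt - 1000) <= est$rtw_width / 2)
  # one hand per block, alternating
  handPerBlock <- tapply(log$hand, log$block, unique)
  expect_true(all(lengths(handPerBlock) == 1))
  expect_true(all(head(unlist(handPerBlock), -1) !=
                    unlist(handPerBlock)[-1]))
  # failed stops commit the planned response, successes have none
  expect_true(all(is.na(stp$rt[stp$stop_success])))
  expect_true(all(!is.na(stp$rt[!stp$stop_success])))
})

test_that("sessions are reproducible and disabling stops removes them", {
  a <- runSession(taskConfig(), agentParams(), seed = 7)
  b <- runSession(taskConfig(), agentParams(), seed = 7)
  expect_identical(a, b)
  c <- runSession(taskConfig(), agentParams(), seed = 8)
  expect_false(identical(a, c))
  noStop <- runSession(taskConfig(stopFraction = 0), agentParams(),
                       seed = 7)
  expect_equal(nrow(noStop), 720)
  expect_true(all(noStop$trial_type == "estimation"))
})

test_that("the control-condition end width seeds both later conditions", {
  log <- runSession(taskConfig(stopFraction = 0), agentParams(), seed = 9)
  firstOf <- function(cond) log$rtw_width[log$condition == cond][1]
  expect_equal(firstOf("easy"), firstOf("hard"))
  lastControl <- utils::tail(log[log$condition == "control", ], 1)
  carried <- updateRtw(lastControl$rtw_width, "control",
                       lastControl$feedback)
  expect_equal(firstOf("easy"), carried)
})

test_that("staircase equilibria match the Monte-Carlo oracle at zero drift", {
  cfg <- taskConfig(blocksPerCondition = 40L, stopFraction = 0)
  par <- agentParams(driftSd = 0, postErrorAdjustSd = 0)
  log <- runSession(cfg, par, seed = 11)
  expected <- c(control = 0.50, easy = 0.75, hard = 0.25)
  steps <- list(control = c(10, 10), easy = c(12, 4), hard = c(4, 12))
  for (cond in names(expected)) {
    d <- log[log$condition == cond, ]
    d <- d[(nrow(d) %/% 2):nrow(d), ]  # asymptotic portion
    acc <- mean(d$on_time)
    se <- sqrt(0.25 / nrow(d))
    oracle <- staircaseOracleAccuracy(steps[[cond]][1], steps[[cond]][2],
                                      rtSd = 140, seed = 101)
    expect_lt(abs(acc - expected[[cond]]), 3 * se + 0.02)
    expect_lt(abs(acc - oracle), 3 * se + 0.02)
  }
})

test_that("stop success tracks 50% and a left-hand SSRT advantage shows", {
  cfg <- taskConfig(blocksPerCondition = 40L)
  log <- runSession(cfg, agentParams(), seed = 13)
  stp <- log[log$trial_type == "stop", ]
  expect_lt(abs(mean(stp$stop_success) - 0.5),
            3 * sqrt(0.25 / nrow(stp)) + 0.03)
  # left-hand advantage: shorter left SSRT -> more left-hand successes
  logH <- runSession(cfg, agentParams(ssrtHandDelta = 40), seed = 13)
  stpH <- logH[logH$trial_type == "stop", ]
  rates <- tapply(stpH$stop_success, stpH$hand, mean)
  expect_gt(rates[["left"]], rates[["right"]])
})

test_that("RT adjustments are larger after error than correct feedback", {
  co <- simulateCohort(nSubjects = 6L, seed = 17)
  bs <- behaviorSummary(co)
  byc <- bs$adaptation_by_condition
  for (cond in unique(byc$condition)) {
    afterErr <- byc$mean_abs_drt[byc$condition == cond &
                                   byc$prev_feedback == "error"]
    afterOk <- byc$mean_abs_drt[byc$condition == cond &
                                  byc$prev_feedback == "correct"]
    expect_gt(afterErr, afterOk)
  }
})
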