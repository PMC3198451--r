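times120 <- seq(-200, by = 1000 / 600, length.out = 480)

test_that("common average referencing zeroes the channel mean everywhere", {
  d <- array(rnorm(4 * 5 * 10), c(4, 5, 10))
  eps <- toyEpochs(d + 7, times = 1:10)  # constant offset on all channels
  ref <- commonAverageReference(eps)
  m <- apply(epochData(ref), c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-9)
  # idempotence
  ref2 <- commonAverageReference(ref)
  expect_equal(epochData(ref2), epochData(ref))
  # a constant across channels vanishes entirely
  flat <- toyEpochs(array(3, c(2, 4, 6)), times = 1:6)
  expect_lt(max(abs(epochData(commonAverageReference(flat)))), 1e-12)
})

test_that("baseline correction subtracts the pre-event mean per channel", {
  # flat epoch -> zeros
  flat <- toyEpochs(array(5, c(1, 2, 480)), times = times120)
  expect_lt(max(abs(epochData(baselineCorrect(flat)))), 1e-12)
  # step 0 -> 4 uV at t = 0 with a -200..0 baseline
  step <- array(rep(ifelse(times120 > 0, 4, 0), each = 2), c(1, 2, 480))
  bc <- baselineCorrect(toyEpochs(step, times = times120))
  expect_equal(epochData(bc)[1, 1, 480], 4, tolerance = 1e-6)
  # zero-mean baseline input unchanged
  zm <- toyEpochs(array(rep(sin(times120 / 20), each = 2), c(1, 2, 480)),
                  times = times120)
  zmv <- epochData(zm)[1, 1, ]
  centered <- zmv - mean(zmv[times120 >= -200 & times120 <= 0])
  expect_equal(epochData(baselineCorrect(zm))[1, 1, ], centered)
  expect_error(baselineCorrect(flat, window = c(-900, -800)),
               "outside the epoch")
})

test_that("linked baseline uses the stop-locked epoch of a failed stop", {
  d <- array(0, c(2, 3, 480))
  d[1, , ] <- 1      # stop-locked epoch, baseline mean 1
  d[2, , ] <- 3      # response-locked epoch
  ev <- data.frame(event = c("stop_failure_stop", "stop_failure_response"),
                   trial = c(17L, 17L), link = c(NA, 17L))
  eps <- toyEpochs(d, times = times120, events = ev)
  out <- linkedBaselineCorrect(eps)
  expect_equal(unique(as.vector(epochData(out)[2, , ])), 2)
  expect_equal(epochData(out)[1, , ], epochData(eps)[1, , ])  # untouched
  evBad <- ev; evBad$link[2] <- 99L
  expect_error(linkedBaselineCorrect(toyEpochs(d, times120, evBad)),
               "no linked stop-locked epoch")
})

test_that("averaging and difference waves are linear and consistent", {
  d <- array(rnorm(6 * 4 * 20), c(6, 4, 20))
  d[4:6, , ] <- rep(d[1, , ], each = 3)  # 3 identical epochs
  ev <- data.frame(event = c("a", "b", "b", "c", "c", "c"))
  eps <- toyEpochs(d, times = 1:20, events = ev)
  # average of identical epochs equals the epoch
  avgC <- erpAverage(eps, epochEvents(eps)$event == "c", "c")
  expect_equal(erpData(avgC), d[1, , ])
  expect_equal(nTrials(avgC), 3)
  a <- erpAverage(eps, epochEvents(eps)$event == "a", "a")
  b <- erpAverage(eps, epochEvents(eps)$event == "b", "b")
  expect_lt(max(abs(erpData(differenceWave(a, a)))), 1e-12)
  expect_equal(erpData(differenceWave(a, b)),
               -erpData(differenceWave(b, a)))
  # adding a common wave to both sides leaves the difference unchanged
  common <- matrix(rnorm(4 * 20), 4, 20)
  ac <- methods::initialize(a, data = erpData(a) + common)
  bc <- methods::initialize(b, data = erpData(b) + common)
  expect_equal(erpData(differenceWave(ac, bc)),
               erpData(differenceWave(a, b)))
  expect_error(differenceWave(a, toyErp(rnorm(10), 1:10)), "channel")
})

test_that("FRN peak search matches the exhaustive oracle on random waves", {
  set.seed(31)
  for (i in 1:300) {
    w <- randomWave(times120)
    erp <- toyErp(w, times120)
    got <- frnPeak(erp, "FCz", window = c(0, 600))
    want <- minScanOracle(w, times120, c(0, 600))
    expect_identical(got$amplitude_uV, want$amplitude)
    expect_identical(got$latency_ms, want$latency)
  }
  # boundary: monotone rising wave -> minimum at the first post-0 sample
  rising <- toyErp(seq(-1, 5, length.out = 480), times120)
  m <- frnPeak(rising, "FCz")
  expect_equal(m$latency_ms, times120[times120 > 0][1])
  expect_error(frnPeak(toyErp(rnorm(480), times120), "nope"),
               "channel not present")
})

test_that("trough-to-peak matches the double-scan oracle on random waves", {
  set.seed(32)
  for (i in 1:350) {
    w <- randomWave(times120)
    erp <- toyErp(w, times120)
    win <- if (i %% 2 == 0) c(120, 280) else c(0, 120)
    got <- troughToPeak(erp, "FCz", troughWindow = win)
    want <- troughToPeakOracle(w, times120, win)
    expect_identical(got$amplitude_uV, want$amplitude)
    expect_identical(got$latency_ms, want$latency)
    expect_lte(got$amplitude_uV, 0)
  }
  # constructed wave: +2 uV peak at 80 ms, -4 uV trough at 200 ms -> -6
  w <- 2 * exp(-0.5 * ((times120 - 80) / 15)^2) -
    4 * exp(-0.5 * ((times120 - 200) / 20)^2)
  got <- troughToPeak(toyErp(w, times120), "FCz",
                      troughWindow = c(120, 280))
  expect_equal(got$amplitude_uV, -6, tolerance = 1e-3)
  # flat zero wave -> 0
  expect_equal(troughToPeak(toyErp(rep(0, 480), times120), "FCz",
                            troughWindow = c(120, 280))$amplitude_uV, 0)
})

test_that("peak measures ignore baseline offsets removed by correction", {
  set.seed(33)
  w <- randomWave(times120)
  d <- array(w, c(1, 1, 480))
  eps <- toyEpochs(d, times = times120, channels = "FCz")
  shifted <- toyEpochs(d + 11.5, times = times120, channels = "FCz")
  a <- erpAverage(baselineCorrect(eps), 1, "w")
  b <- erpAverage(baselineCorrect(shifted), 1, "w")
  expect_equal(frnPeak(a, "FCz")$amplitude_uV,
               frnPeak(b, "FCz")$amplitude_uV)
  expect_equal(troughToPeak(a, "FCz", c(120, 280))$amplitude_uV,
               troughToPeak(b, "FCz", c(120, 280))$amplitude_uV)
})
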