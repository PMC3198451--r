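test_that("component topographies are symmetric, mirrored, and peak at FCz", {
  lay <- makeLayout()
  mi <- erpmon:::mirrorIndex(lay)
  specs <- defaultComponentSpecs()

  # no lateral shift: invariant under the left/right electrode mirror
  frnL <- componentTopography(specs$FRN, "left", lay)
  frnR <- componentTopography(specs$FRN, "right", lay)
  expect_equal(frnL, frnR)
  expect_equal(unname(frnL[mi]), unname(frnL), tolerance = 1e-12)

  # N2 with ipsilateral shift: left/right maps are exact mirror images
  n2L <- componentTopography(specs$N2, "left", lay)
  n2R <- componentTopography(specs$N2, "right", lay)
  expect_equal(unname(n2L[mi]), unname(n2R), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(n2L, n2R)))

  # maximal electrode is the configured center; maps are centered
  expect_equal(names(which.max(frnL)), "FCz")
  expect_equal(names(which.max(n2L)), "FCz")  # shift < electrode spacing
  expect_equal(mean(frnL), 0, tolerance = 1e-14)
  expect_equal(max(frnL), 1)
})

test_that("noiseless injection-recovery is exact for all components", {
  log <- runSession(seed = 21)
  specs <- flatSpecs()
  eps <- prepareEpochs(generateEpochs(log, specs = specs,
                                      noise = noiseSpec(rms = 0),
                                      seed = 21))
  frn <- measureFrn(eps, "unexpected")
  expect_equal(frn$amplitude_uV, -5.62)
  # the biphasic kernel's combined trough sits within ~10 ms of the
  # nominal latency (the positive lobe shifts it slightly)
  expect_lt(abs(frn$latency_ms - 280), 10)
  expect_equal(measureFrn(eps, "expected")$amplitude_uV, -3.78)
  n2 <- measureN2(eps)
  expect_equal(n2$amplitude_uV, -6.14)
  expect_lt(abs(n2$latency_ms - 200), 10)
  ern <- measureErn(eps)
  expect_equal(ern$amplitude_uV, -5.69)
  expect_lt(abs(ern$latency_ms - 60), 10)
})

test_that("recovered amplitudes scale linearly with the injected means", {
  log <- runSession(taskConfig(blocksPerCondition = 2L), seed = 22)
  specs <- flatSpecs()
  double <- specs
  for (comp in names(double))
    double[[comp]]$amplitudeMean <- 2 * double[[comp]]$amplitudeMean
  e1 <- prepareEpochs(generateEpochs(log, specs = specs,
                                     noise = noiseSpec(rms = 0),
                                     seed = 1, decimate = 2L))
  e2 <- prepareEpochs(generateEpochs(log, specs = double,
                                     noise = noiseSpec(rms = 0),
                                     seed = 1, decimate = 2L))
  expect_equal(2 * measureFrn(e1, "unexpected")$amplitude_uV,
               measureFrn(e2, "unexpected")$amplitude_uV)
  expect_equal(2 * measureN2(e1)$amplitude_uV, measureN2(e2)$amplitude_uV)
  expect_equal(2 * measureErn(e1)$amplitude_uV,
               measureErn(e2)$amplitude_uV)
})

test_that("zero injected amplitude leaves only noise-level residue", {
  log <- runSession(taskConfig(blocksPerCondition = 2L), seed = 23)
  zero <- flatSpecs()
  for (comp in names(zero)) zero[[comp]]$amplitudeMean <- 0
  e0 <- prepareEpochs(generateEpochs(log, specs = zero,
                                     noise = noiseSpec(rms = 0),
                                     seed = 2, decimate = 2L))
  expect_equal(measureFrn(e0, "unexpected")$amplitude_uV, 0)
  expect_equal(measureN2(e0)$amplitude_uV, 0)
  # with modest noise the measured residue stays at the noise scale
  en <- prepareEpochs(generateEpochs(log, specs = zero,
                                     noise = noiseSpec(rms = 1),
                                     seed = 2, decimate = 2L))
  nMin <- min(table(epochEvents(en)$event))
  expect_lt(abs(measureFrn(en, "unexpected")$amplitude_uV),
            6 * 1 / sqrt(nMin))
})

test_that("between-subject amplitude draws honour the correlation matrix", {
  set.seed(99)
  amps <- drawSubjectAmplitudes(n = 500)
  C <- cor(amps)
  target <- defaultAmplitudeCorrelation()
  expect_lt(max(abs(C - target)), 0.1)
  mus <- colMeans(amps)
  expect_lt(abs(mus["FRN"] - (-5.62)), 3 * 2.98 / sqrt(500))
})

test_that("epoch generation is deterministic per seed", {
  log <- runSession(taskConfig(blocksPerCondition = 1L), seed = 24)
  a <- generateEpochs(log, seed = 3, decimate = 4L)
  b <- generateEpochs(log, seed = 3, decimate = 4L)
  expect_identical(epochData(a), epochData(b))
  c <- generateEpochs(log, seed = 4, decimate = 4L)
  expect_false(identical(epochData(a), epochData(c)))
})

test_that("epoch containers have the documented shape and event classes", {
  log <- runSession(seed = 25)
  eps <- generateEpochs(log, noise = noiseSpec(rms = 0), seed = 5)
  expect_equal(length(sampleTimes(eps)), 480)
  expect_equal(length(channelNames(eps)), 80)
  expect_equal(sampleTimes(eps)[1], -200)
  expect_equal(diff(sampleTimes(eps))[1], 1000 / 600)
  expect_equal(sum(abs(sampleTimes(eps))  < 1e-9), 1)  # a true 0 sample
  ev <- epochEvents(eps)
  expect_setequal(unique(ev$event),
                  c("feedback", "stop_success", "stop_failure_stop",
                    "stop_failure_response"))
  # one feedback epoch per estimation trial, two per failed stop
  expect_equal(sum(ev$event == "feedback"),
               sum(log$trial_type == "estimation"))
  expect_equal(sum(ev$event == "stop_failure_stop"),
               sum(ev$event == "stop_failure_response"))
  # a log without annotations is rejected
  broken <- log
  broken$feedback <- NA
  expect_error(generateEpochs(broken, seed = 1), "without feedback")
})
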