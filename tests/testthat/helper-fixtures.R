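# Shared fixtures built in code.

# A small task for fast EEG tests: 2 blocks per condition.
tinyTask <- function(blocks = 2L) taskConfig(blocksPerCondition = blocks)

# Component specs with all between/within amplitude variation off.
flatSpecs <- function(specs = defaultComponentSpecs()) {
  for (comp in names(specs)) {
    specs[[comp]]$amplitudeSdBetween <- 0
    specs[[comp]]$amplitudeSdWithin <- 0
  }
  specs
}

# Hand-built EpochSet: one event class, explicit data array.
toyEpochs <- function(data, times, events = NULL,
                      channels = paste0("ch", seq_len(dim(data)[2]))) {
  if (is.null(events))
    events <- data.frame(event = rep("feedback", dim(data)[1]))
  EpochSet("toy", data, times, events, channels)
}

# Hand-built single-channel ErpAverage on an arbitrary axis.
toyErp <- function(values, times, channel = "FCz") {
  new("ErpAverage", data = matrix(values, nrow = 1), times = times,
      nTrials = 1, selector = "toy", channels = channel,
      referenced = TRUE)
}

# Memoised 24-subject study at the full paradigm scale (feedback epochs only;
# everything FRN-related), shared by the acceptance tests.
.acceptanceCache <- new.env(parent = emptyenv())
acceptanceFrnStudy <- function() {
  if (!is.null(.acceptanceCache$frn)) return(.acceptanceCache$frn)
  cohort <- simulateCohort(nSubjects = 24L, seed = 2024L)
  eegSeeds <- sapply(1:24, function(i) 2024L + 7919L * i)
  frn <- numeric(24)
  halves <- vector("list", 24)
  for (i in 1:24) {
    s <- sprintf("s%02d", i)
    eps <- generateEpochs(cohort[cohort$subject == s, ],
                          seed = eegSeeds[i], events = "feedback")
    eps <- prepareEpochs(eps)
    frn[i] <- measureFrn(eps, "unexpected")$amplitude_uV
    halves[[i]] <- splitHalfMeasures(eps, "FRN")
  }
  names(halves) <- sprintf("s%02d", 1:24)
  .acceptanceCache$frn <- list(cohort = cohort, frn = frn, halves = halves)
  .acceptanceCache$frn
}
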