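test_that("AO+MI timeline has the paradigm's trial structure", {
  spec <- sessionSpec("AO_MI", nTrials = 300, seed = 3)
  tl <- withr::with_seed(3, TrialTimeline(tstn:::.buildTimeline(spec)$events,
                                          "AO_MI"))
  ev <- timelineEvents(tl)
  expect_equal(nTrials(tl), 300)
  counts <- table(ev$trial, ev$block_kind)
  expect_true(all(counts[, "AO_MI"] == 2))
  expect_true(all(counts[, "MI"] == 1))
  expect_true(all(counts[, "REST"] == 3))
  # 150/150 class balance, random order
  cls <- ev$class_label[ev$block_kind == "MI"]
  expect_equal(sum(cls == "LEFT"), 150)
  expect_equal(sum(cls == "RIGHT"), 150)
  # rest durations drawn from the configured 5-7 s range
  rests <- ev$duration_s[ev$block_kind == "REST"]
  expect_true(all(rests >= 5 & rests <= 7))
  # task blocks preceded by rest, onsets increasing (validity already ran)
  expect_true(validObject(tl))
})

test_that("MI-FB timeline has 150 trials with a 50/50/50 class mix", {
  spec <- sessionSpec("MI_FB", seed = 4)
  tl <- withr::with_seed(4, TrialTimeline(tstn:::.buildTimeline(spec)$events,
                                          "MI_FB"))
  ev <- timelineEvents(tl)
  expect_equal(nTrials(tl), 150)
  cls <- ev$class_label[ev$block_kind == "MI_FB_TASK"]
  expect_equal(as.vector(table(factor(cls, CLASS_LEVELS))), c(50, 50, 50))
  expect_true(all(ev$duration_s[ev$block_kind == "MI_FB_TASK"] == 3))
})

test_that("invalid class mixes are configuration errors", {
  expect_error(sessionSpec("AO_MI", nTrials = 30,
                           classMix = c(LEFT = 10, RIGHT = 10, REST = 10)),
               "classMix")
  expect_error(sessionSpec("MI_FB", nTrials = 30,
                           classMix = c(LEFT = 15, RIGHT = 15)),
               "classMix")
  expect_error(sessionSpec("AO_MI", nTrials = 30,
                           classMix = c(LEFT = 10, RIGHT = 10)),
               "sum to nTrials")
})

test_that("identical spec and seed give bit-identical sessions", {
  spec <- sessionSpec("AO_MI", nTrials = 4, seed = 99)
  a <- generateSession(spec, erdModel())
  b <- generateSession(spec, erdModel())
  expect_identical(signalMatrix(a$recording), signalMatrix(b$recording))
  expect_identical(timelineEvents(a$timeline), timelineEvents(b$timeline))
  expect_identical(a$labels, b$labels)
  # and the generator restores the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(generateSession(spec, erdModel())); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("rest-window spectrum peaks in the mu band", {
  ses <- smallAOMI()
  ev <- timelineEvents(ses$timeline)
  fs <- samplingRate(ses$recording)
  sig <- signalMatrix(ses$recording)
  rests <- ev[ev$block_kind == "REST", ][1:20, ]
  n <- 2 * fs
  pxx <- 0
  for (i in seq_len(nrow(rests))) {
    i0 <- floor(rests$onset_s[i] * fs) + 1
    x <- sig["C3", i0:(i0 + n - 1)]
    pxx <- pxx + Mod(fft(x))^2
  }
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= 2 & f <= fs / 2    # ignore the 1/f divergence at DC
  peak <- f[keep][which.max(pxx[keep])]
  expect_gte(peak, 8)
  expect_lte(peak, 13)
})

test_that("programmed ERD depth is recovered from band power", {
  # all task blocks suppress C3 so every task window counts; >= 100 windows
  for (depth in c(0.2, 0.4)) {
    spec <- sessionSpec("AO_MI", nTrials = 34, seed = 120 + round(100 * depth))
    erd <- erdModel(erdDepth = depth,
                    profile = list(LEFT = c(C3 = 1), RIGHT = c(C3 = 1),
                                   REST = numeric()))
    ses <- generateSession(spec, erd)
    ev <- timelineEvents(ses$timeline)
    fs <- samplingRate(ses$recording)
    x <- signalMatrix(ses$recording)["C3", ]
    task <- ev[ev$block_kind != "REST", ]
    expect_gte(nrow(task), 100)
    bpTask <- bpRest <- numeric(nrow(task))
    for (i in seq_len(nrow(task))) {
      i0 <- floor(task$onset_s[i] * fs) + 1
      n <- floor(task$duration_s[i] * fs)
      bpTask[i] <- oracleBandPower(x[i0:(i0 + n - 1)], fs, c(8, 13))
      bpRest[i] <- oracleBandPower(x[(i0 - n):(i0 - 1)], fs, c(8, 13))
    }
    drop <- 1 - mean(bpTask) / mean(bpRest)
    expect_lt(abs(drop - depth), 0.05)
  }
})

test_that("ERD restricted to one class only affects that class's windows", {
  spec <- sessionSpec("AO_MI", nTrials = 70, seed = 77)
  erd <- erdModel(erdDepth = 0.3,
                  profile = list(LEFT = numeric(), RIGHT = c(C3 = 1),
                                 REST = numeric()))
  ses <- generateSession(spec, erd)
  ev <- timelineEvents(ses$timeline)
  fs <- samplingRate(ses$recording)
  x <- signalMatrix(ses$recording)["C3", ]
  ratioFor <- function(cls) {
    task <- ev[ev$block_kind != "REST" & ev$class_label == cls, ]
    bpT <- bpR <- numeric(nrow(task))
    for (i in seq_len(nrow(task))) {
      i0 <- floor(task$onset_s[i] * fs) + 1
      n <- floor(task$duration_s[i] * fs)
      bpT[i] <- oracleBandPower(x[i0:(i0 + n - 1)], fs, c(8, 13))
      bpR[i] <- oracleBandPower(x[(i0 - n):(i0 - 1)], fs, c(8, 13))
    }
    mean(bpT) / mean(bpR)
  }
  expect_lt(abs(ratioFor("RIGHT") - 0.7), 0.05)
  expect_lt(abs(ratioFor("LEFT") - 1), 0.05)
})

test_that("session drift is deterministic and monotone in the schedule", {
  base <- erdModel(erdDepth = 0.3)
  expect_identical(simulateSessionDrift(base, 0), base)
  d1 <- simulateSessionDrift(base, 1)$erdDepth
  d2 <- simulateSessionDrift(base, 2)$erdDepth
  d3 <- simulateSessionDrift(base, 3)$erdDepth
  expect_true(d1 > base$erdDepth && d2 > d1 && d3 > d2)
  expect_identical(simulateSessionDrift(base, 2)$erdDepth, d2)
  expect_lte(simulateSessionDrift(base, 50)$erdDepth, 0.9)
  expect_error(simulateSessionDrift(base, -1), "step")
})
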