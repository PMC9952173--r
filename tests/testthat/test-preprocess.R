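# amplitude of a steady-state sinusoid in the middle of a filtered trace
.midAmplitude <- function(x, fs, freq) {
  n <- length(x)
  mid <- x[round(n / 3):round(2 * n / 3)]
  t <- seq_along(mid) / fs
  2 * Mod(mean(mid * exp(-2i * pi * freq * t)))
}

# squared magnitude response of the band-pass applied forward-backward,
# evaluated directly from the transfer-function polynomials (independent
# of the filtering routine)
.analyticGain2 <- function(cfg, fs, freq) {
  bf <- signal::butter(cfg$filterOrder, cfg$band / (fs / 2), type = "pass")
  w <- 2 * pi * freq / fs
  z <- exp(-1i * w * (seq_along(bf$b) - 1))
  H <- sum(bf$b * z) / sum(bf$a * z)
  Mod(H)^2
}

test_that("band-pass gain matches the analytic Butterworth response", {
  fs <- 1000
  cfg <- preprocConfig()
  t <- seq_len(20 * fs) / fs
  for (freq in c(10, 30, 0.5, 60)) {
    rec <- RawRecording(matrix(sin(2 * pi * freq * t), 1), fs, "C3")
    out <- bandpassFilter(rec, cfg)
    measured <- .midAmplitude(signalMatrix(out)[1, ], fs, freq)
    expected <- .analyticGain2(cfg, fs, freq)
    if (expected > 1e-8) {
      # within 1 dB of the analytic forward-backward response
      expect_lt(abs(10 * log10(measured / expected)), 1, label = paste(freq, "Hz"))
    } else {
      expect_lt(measured, 1e-4)  # deep stopband: just confirm suppression
    }
  }
  expect_gt(.analyticGain2(cfg, fs, 10), 10^(-0.1))  # 10 Hz is in passband
})

test_that("band-pass of the zero signal is zero and preserves shape", {
  fs <- 1000
  rec <- RawRecording(matrix(0, 3, 4 * fs), fs, c("a", "b", "c"))
  out <- bandpassFilter(rec)
  expect_equal(signalMatrix(out), signalMatrix(rec))
  expect_equal(samplingRate(out), fs)
  expect_error(bandpassFilter(RawRecording(matrix(0, 1, 100), 60, "a")),
               "Nyquist")
})

test_that("decimation preserves duration, DC and low-frequency content", {
  fs <- 1000
  cfg <- preprocConfig()
  n <- 2 * fs
  const <- RawRecording(matrix(5, 1, n), fs, "a")
  dn <- downsampleRecording(const, cfg)
  expect_equal(ncol(signalMatrix(dn)), 500)   # 2 s at 250 Hz
  expect_equal(samplingRate(dn), 250)
  mid <- signalMatrix(dn)[1, 50:450]
  expect_lt(max(abs(mid - 5) / 5), 0.012)  # within the decimator passband ripple

  t <- seq_len(10 * fs) / fs
  sine <- RawRecording(matrix(sin(2 * pi * 5 * t), 1, length(t)), fs, "a")
  ds <- downsampleRecording(sine, cfg)
  ideal <- sin(2 * pi * 5 * seq(1, length(t), by = 4) / fs)
  mid <- 200:2300
  rmsErr <- sqrt(mean((signalMatrix(ds)[1, mid] - ideal[mid])^2)) /
    sqrt(mean(ideal[mid]^2))
  expect_lt(rmsErr, 0.01)

  expect_error(downsampleRecording(RawRecording(matrix(0, 1, 300), 300, "a"),
                                   cfg), "integer multiple")
})

test_that("epoch counts follow the timeline and the skip rule exactly", {
  cfg <- preprocConfig()
  fs <- 250
  withr::local_seed(42)
  for (rep in 1:5) {
    # random MI_FB-like timeline with some deliberately short task blocks
    nTr <- 8
    rows <- list(); t0 <- 0
    for (tr in seq_len(nTr)) {
      r <- runif(1, 4, 6)
      rows[[length(rows) + 1]] <- data.frame(trial = tr, block_kind = "REST",
                                             class_label = NA_character_,
                                             onset_s = t0, duration_s = r)
      t0 <- t0 + r
      dur <- sample(c(1, 3), 1)   # 1-s blocks are shorter than the 2-s epoch
      rows[[length(rows) + 1]] <- data.frame(trial = tr,
                                             block_kind = "MI_FB_TASK",
                                             class_label = sample(CLASS_LEVELS, 1),
                                             onset_s = t0, duration_s = dur)
      t0 <- t0 + dur
    }
    tl <- TrialTimeline(do.call(rbind, rows), "MI_FB")
    rec <- RawRecording(matrix(rnorm(2 * ceiling(t0 + 1) * fs), 2), fs,
                        c("C3", "C4"), meta = list(sessionKind = "MI_FB"))
    want <- oracleEpochCounts(tl, cfg$epochLen)
    sets <- suppressWarnings(assembleEpochs(rec, tl, cfg))
    expect_equal(nTrials(sets$task), want$task)
  }
})

test_that("AO+MI assembly yields two task epochs and one REST epoch per trial", {
  ses <- smallAOMI()
  sets <- ses$epochs
  expect_equal(nTrials(sets$train), 3 * 24)
  expect_equal(as.vector(table(epochLabels(sets$train))), c(24, 24, 24))
  expect_equal(nTrials(sets$mi), 24)
  expect_true(all(epochLabels(sets$mi) %in% c("LEFT", "RIGHT")))
  # REST epochs come from the trial's first rest period
  prov <- sets$train@provenance
  expect_equal(sum(prov$block_kind == "REST"), 24)
  expect_equal(dim(epochData(sets$train))[3], 500)
})

test_that("a too-short task block drops exactly that epoch", {
  fs <- 250
  rows <- data.frame(
    trial = c(1, 1, 2, 2, 3, 3),
    block_kind = rep(c("REST", "MI_FB_TASK"), 3),
    class_label = c(NA, "LEFT", NA, "RIGHT", NA, "REST"),
    onset_s = c(0, 5, 8, 13, 16, 21),
    duration_s = c(5, 3, 5, 1, 5, 3))
  tl <- TrialTimeline(rows, "MI_FB")
  rec <- RawRecording(matrix(rnorm(fs * 26), 1), fs, "C3")
  expect_warning(sets <- assembleEpochs(rec, tl, preprocConfig()),
                 "shorter than the epoch")
  expect_equal(nTrials(sets$task), 2)
  expect_identical(sets$task@provenance$trial_index, c(1, 3))
})

test_that("filtering commutes with epoching away from segment edges", {
  fs <- 250
  withr::local_seed(9)
  x <- rnorm(40 * fs)
  cfg <- preprocConfig()
  bf <- signal::butter(cfg$filterOrder, cfg$band / (fs / 2), type = "pass")
  whole <- signal::filtfilt(bf, x)
  win <- (20 * fs + 1):(22 * fs)        # a 2-s epoch deep inside
  a <- whole[win]
  margin <- 4 * fs                      # 4-s guard on both sides
  seg <- signal::filtfilt(bf, x[(min(win) - margin):(max(win) + margin)])
  b <- seg[(margin + 1):(margin + length(win))]
  expect_lt(sqrt(mean((a - b)^2)), 1e-6)
})
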