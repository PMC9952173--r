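# Shared fixtures, generated in code and cached per test-file run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# small AO+MI session, preprocessed and epoched (24 trials -> 72 train epochs)
smallAOMI <- function() fixture("smallAOMI", function() {
  spec <- sessionSpec("AO_MI", nTrials = 24, seed = 7)
  ses <- generateSession(spec, erdModel(erdDepth = 0.4))
  cfg <- preprocConfig()
  prep <- preprocessRecording(ses$recording, cfg)
  c(ses, list(prep = prep, epochs = assembleEpochs(prep, ses$timeline, cfg),
              cfg = cfg))
})

# random symmetric positive-definite matrix
randomSPD <- function(n, jitter = 0.1) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + jitter * diag(n)
}

# toy 3-class EpochSet with hand-controllable variance structure
toyEpochSet <- function(n = 12, nch = 4, nsamp = 50, fs = 25, seed = 1) {
  withr::local_seed(seed)
  dat <- array(rnorm(n * nch * nsamp), c(n, nch, nsamp))
  labels <- rep(CLASS_LEVELS, length.out = n)
  EpochSet(dat, labels, fs, c(0, nsamp / fs))
}

# a filter bank of the right shape for synthetic feature tests
fakeBank <- function(nch = 8, seed = 1) {
  withr::local_seed(seed)
  new("SpatialFilterBank", Z = matrix(rnorm(6 * nch), 6, nch),
      solutions = vector("list", 3), classes = CLASS_LEVELS,
      channelLabels = paste0("ch", seq_len(nch)))
}

# AO+MI session with ERD on C3 for both classes, epoched with 2 s of
# pre-onset context; ~100 task epochs at the default size
erdSession <- function(depth, n = 34, seed = 55) {
  spec <- sessionSpec("AO_MI", nTrials = n, seed = seed + round(100 * depth))
  erd <- erdModel(erdDepth = depth,
                  profile = list(LEFT = c(C3 = 1), RIGHT = c(C3 = 1),
                                 REST = numeric()))
  ses <- generateSession(spec, erd)
  cfg <- preprocConfig()
  prep <- preprocessRecording(ses$recording, cfg)
  sets <- assembleEpochs(prep, ses$timeline, cfg, preOnset = 2)
  task <- c(sets$train[sets$train@provenance$block_kind == "AO_MI"], sets$mi)
  rest <- sets$train[sets$train@provenance$block_kind == "REST"]
  list(task = task, rest = rest)
}

# expand a confusion matrix into label/prediction vectors
.vectorsFromConfusion <- function(conf) {
  labs <- preds <- character(0)
  for (i in 1:3) for (j in 1:3) {
    labs <- c(labs, rep(CLASS_LEVELS[i], conf[i, j]))
    preds <- c(preds, rep(CLASS_LEVELS[j], conf[i, j]))
  }
  list(labels = labs, predictions = preds)
}

# random parameter set and feature epochs for a given geometry
randomModel <- function(d = 40, k1 = 11, seed = 1) {
  initTSTN(fakeBank(seed = seed), d = d, conv1Kernel = k1, seed = seed + 1)
}

randomFeats <- function(dims, n = 1, seed = 1, normalize = TRUE) {
  withr::local_seed(seed)
  x <- array(rnorm(dims$featChannels * dims$d * n),
             c(dims$featChannels, dims$d, n))
  if (normalize)
    for (i in seq_len(n)) x[, , i] <- x[, , i] / sqrt(mean(x[, , i]^2))
  x
}
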