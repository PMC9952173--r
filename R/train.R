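#' @include model.R
NULL

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.0002,
#' batch size 50, dropout 0.3 in the spatial and 0.5 in the temporal
#' transformer, ten-fold cross validation; the gradient-epoch budget (100,
#' with patience-20 early stopping on held-out loss) is a package default.
#'
#' @param learningRate Adam learning rate.
#' @param batchSize mini-batch size.
#' @param dropoutSpatial dropout rate on the spatial-attention output.
#' @param dropoutTemporal dropout rate on the temporal-attention output.
#' @param folds cross-validation folds (>= 2).
#' @param maxEpochs maximum gradient epochs.
#' @param patience early-stopping patience (epochs without improvement of
#'   the held-out loss).
#' @param seed master seed for fold assignment, initialization, shuffling
#'   and dropout.
#' @return a `TrainConfig` (validated named list).
#' @export
trainConfig <- function(learningRate = 2e-4, batchSize = 50L,
                        dropoutSpatial = 0.3, dropoutTemporal = 0.5,
                        folds = 10L, maxEpochs = 100L, patience = 20L,
                        seed = 1L) {
  .assertScalarNum(learningRate, "learningRate", lower = 1e-12)
  if (batchSize < 1L) stop("batchSize must be >= 1", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  for (p in c(dropoutSpatial, dropoutTemporal))
    if (p < 0 || p >= 1) stop("dropout rates must lie in [0, 1)", call. = FALSE)
  cfg <- list(learningRate = learningRate, batchSize = as.integer(batchSize),
              dropoutSpatial = dropoutSpatial, dropoutTemporal = dropoutTemporal,
              folds = as.integer(folds), maxEpochs = as.integer(maxEpochs),
              patience = as.integer(patience), seed = as.integer(seed))
  class(cfg) <- "TrainConfig"
  cfg
}

.labelsToIdx <- function(labels) as.integer(factor(labels, levels = CLASS_LEVELS))

# evaluation-mode loss/accuracy on a feature cube
.evalFeats <- function(params, dims, feats, yIdx) {
  out <- tstn_loss_cpp(params, feats, yIdx, dims)
  pred <- max.col(out$probs, ties.method = "first")
  list(loss = out$loss, acc = mean(pred == yIdx))
}

# one Adam training run over a feature cube with optional early stopping.
# Draws shuffles and dropout masks from the current RNG stream (the caller
# seeds it). Returns the best-validation parameter snapshot (or the final
# parameters when no validation set is supplied).
.trainLoop <- function(params, dims, featsTr, yTr, cfg,
                       featsVal = NULL, yVal = NULL, nEpochs = cfg$maxEpochs) {
  n <- dim(featsTr)[3L]
  C <- dims$featChannels
  d <- dims$d
  f2 <- dims$conv2Filters
  L2 <- (dims$d - dims$conv1Kernel + 1L) %/% dims$conv2Stride
  m <- lapply(params, function(x) x * 0)
  v <- lapply(params, function(x) x * 0)
  pS <- cfg$dropoutSpatial
  pT <- cfg$dropoutTemporal
  best <- list(loss = Inf, epoch = 0L, acc = NA_real_, params = NULL)
  wait <- 0L
  t <- 0L
  history <- numeric(0)
  for (ep in seq_len(nEpochs)) {
    ord <- sample.int(n)
    for (b in seq_len(ceiling(n / cfg$batchSize))) {
      idx <- ord[((b - 1L) * cfg$batchSize + 1L):min(b * cfg$batchSize, n)]
      nb <- length(idx)
      maskB <- if (pS > 0)
        matrix((runif(C * nb * d) >= pS) / (1 - pS), C * nb, d)
      else matrix(1, C * nb, d)
      maskF <- if (pT > 0)
        matrix((runif(f2 * nb * L2) >= pT) / (1 - pT), f2 * nb, L2)
      else matrix(1, f2 * nb, L2)
      out <- tstn_fwd_bwd_cpp(params, featsTr[, , idx, drop = FALSE],
                              yTr[idx], maskB, maskF, dims)
      t <- t + 1L
      adam_step_cpp(params, out$grads, m, v, cfg$learningRate,
                    0.9, 0.999, 1e-8, t)
    }
    if (!is.null(featsVal)) {
      valRes <- .evalFeats(params, dims, featsVal, yVal)
      history <- c(history, valRes$loss)
      if (valRes$loss < best$loss - 1e-6) {
        best <- list(loss = valRes$loss, epoch = ep, acc = valRes$acc,
                     params = .copyParams(params))
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (is.null(featsVal))
    best <- list(loss = NA_real_, epoch = nEpochs, acc = NA_real_,
                 params = params)
  best$history <- history
  best
}

#' Fit a TSTN classifier
#'
#' Mini-batch Adam on the cross-entropy loss. With `crossValidate = TRUE`
#' the data are split into `cfg$folds` random folds; for each fold the CSP
#' bank is fitted on the training split only, the network is trained with
#' early stopping on the held-out split (90% / 10% by default), and the
#' fold's held-out accuracy at its best epoch is recorded. The returned
#' model is refitted on all data, with the gradient-epoch count set to the
#' median of the per-fold best epochs, and carries the fold-wise records
#' in `meta$cv`. With `crossValidate = FALSE` a single random 10% holdout
#' drives early stopping and the best-holdout parameter snapshot is
#' returned (the warm-start path of the continual-learning cascade).
#' Fully seeded: identical data and config give identical parameters.
#'
#' @param epochs training [EpochSet-class] (all three classes present).
#' @param cfg a [trainConfig].
#' @param model optional [TSTNModel-class] used as a warm start; when NULL
#'   a fresh model is initialized per fit.
#' @param stage lineage tag stored in the model metadata.
#' @param crossValidate run the fold loop (see Details).
#' @return a fitted [TSTNModel-class]; `meta$cv` holds per-fold validation
#'   accuracy, loss and best epoch when cross-validating.
#' @export
fitTSTN <- function(epochs, cfg = trainConfig(), model = NULL,
                    stage = "AO_MI", crossValidate = TRUE) {
  stopifnot(is(epochs, "EpochSet"))
  n <- nTrials(epochs)
  counts <- table(epochs@labels)
  if (any(counts == 0L))
    stop("data error: class ", paste(names(counts)[counts == 0L], collapse = ", "),
         " missing from the training data", call. = FALSE)
  yAll <- .labelsToIdx(epochs@labels)

  withSeed(cfg$seed, {
    if (crossValidate) {
      if (min(counts) < cfg$folds)
        stop("data error: need at least `folds` trials per class", call. = FALSE)
      foldId <- sample(rep_len(seq_len(cfg$folds), n))
      cv <- data.frame(fold = seq_len(cfg$folds), bestEpoch = NA_integer_,
                       valLoss = NA_real_, valAcc = NA_real_)
      for (f in seq_len(cfg$folds)) {
        tr <- foldId != f
        bank <- buildOVRBank(epochs[tr])
        proto <- if (is.null(model))
          initTSTN(bank, dropout = c(cfg$dropoutSpatial, cfg$dropoutTemporal),
                   seed = cfg$seed + 101L * f)
        else model
        featsTr <- .featsCube(proto, applyBank(bank, epochs[tr]))
        featsVal <- .featsCube(proto, applyBank(bank, epochs[!tr]))
        params <- .copyParams(proto@params)
        res <- .trainLoop(params, proto@dims, featsTr, yAll[tr], cfg,
                          featsVal, yAll[!tr])
        cv$bestEpoch[f] <- res$epoch
        cv$valLoss[f] <- res$loss
        cv$valAcc[f] <- res$acc
      }
      nFinal <- max(1L, as.integer(round(median(cv$bestEpoch))))
      bank <- buildOVRBank(epochs)
      proto <- if (is.null(model))
        initTSTN(bank, dropout = c(cfg$dropoutSpatial, cfg$dropoutTemporal),
                 seed = cfg$seed)
      else model
      feats <- .featsCube(proto, applyBank(bank, epochs))
      params <- .copyParams(proto@params)
      res <- .trainLoop(params, proto@dims, feats, yAll, cfg, nEpochs = nFinal)
      new("TSTNModel", bank = bank, params = res$params, dims = proto@dims,
          dropout = c(cfg$dropoutSpatial, cfg$dropoutTemporal),
          meta = list(stage = stage, seed = cfg$seed, cv = cv,
                      finalEpochs = nFinal))
    } else {
      holdout <- sample.int(n, size = max(1L, round(0.1 * n)))
      tr <- setdiff(seq_len(n), holdout)
      bank <- buildOVRBank(epochs[tr])
      proto <- if (is.null(model))
        initTSTN(bank, dropout = c(cfg$dropoutSpatial, cfg$dropoutTemporal),
                 seed = cfg$seed)
      else model
      featsTr <- .featsCube(proto, applyBank(bank, epochs[tr]))
      featsVal <- .featsCube(proto, applyBank(bank, epochs[holdout]))
      params <- .copyParams(proto@params)
      res <- .trainLoop(params, proto@dims, featsTr, yAll[tr], cfg,
                        featsVal, yAll[holdout])
      final <- if (is.null(res$params)) params else res$params
      new("TSTNModel", bank = bank, params = final, dims = proto@dims,
          dropout = c(cfg$dropoutSpatial, cfg$dropoutTemporal),
          meta = list(stage = stage, seed = cfg$seed,
                      bestEpoch = res$epoch, valLoss = res$loss,
                      valAcc = res$acc))
    }
  })
}

#' Evaluate a model on an epoch set
#'
#' Evaluation-mode forward per trial; predictions are the argmax class
#' (ties toward the lowest class index). An empty epoch set yields empty
#' predictions and a NULL report.
#'
#' @param model a fitted [TSTNModel-class].
#' @param epochs an [EpochSet-class].
#' @return list with `predictions` (factor), `probabilities` (N x 3) and
#'   `report` (a [MetricsReport-class], or NULL for empty input).
#' @export
evaluateModel <- function(model, epochs) {
  stopifnot(is(epochs, "EpochSet"))
  if (nTrials(epochs) == 0L) {
    return(list(predictions = factor(character(), levels = CLASS_LEVELS),
                probabilities = matrix(0, 0, 3,
                                       dimnames = list(NULL, CLASS_LEVELS)),
                report = NULL))
  }
  probs <- tstnForward(model, epochs)
  pred <- predictClasses(probs)
  list(predictions = pred, probabilities = probs,
       report = computeMetrics(epochs@labels, pred))
}

#' Indices of correctly classified trials
#'
#' @param predictions factor/character of predicted labels.
#' @param labels factor/character of true labels (same length).
#' @return integer vector of 1-based indices where prediction equals label,
#'   in original order; a warning is emitted when none match.
#' @export
selectCorrect <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("data error: predictions and labels differ in length", call. = FALSE)
  idx <- which(as.character(predictions) == as.character(labels))
  if (!length(idx) && length(labels))
    warning("no correctly classified trials to select")
  idx
}

CASCADE_STAGES <- c("AO_MI", "MI", "MI_FB_1", "MI_FB_2", "MI_FB_3")

#' Continual-learning state
#'
#' Bundles the current model, the cumulative training pool and the
#' per-stage metric history of the training cascade.
#'
#' @slot stage current stage name (`AO_MI`, `MI`, `MI_FB_1`, ...).
#' @slot model the current [TSTNModel-class].
#' @slot pool cumulative training [EpochSet-class].
#' @slot history list of per-stage records (stage, trial counts, metrics).
#' @export
setClass("ContinualState",
  representation(stage = "character", model = "TSTNModel",
                 pool = "EpochSet", history = "list"))

#' Construct the initial continual-learning state
#' @param model the initial model (fitted on the AO+MI pool).
#' @param pool the epochs the model was fitted on.
#' @return a [ContinualState-class] at stage `AO_MI`.
#' @export
continualState <- function(model, pool) {
  new("ContinualState", stage = "AO_MI", model = model, pool = pool,
      history = list())
}

setMethod("show", "ContinualState", function(object) {
  cat(sprintf("ContinualState: stage %s, pool %d trials, %d stage records\n",
              object@stage, nTrials(object@pool), length(object@history)))
  for (h in object@history)
    cat(sprintf("  %s: tested %d, selected %d, accuracy %.3f\n",
                h$stage, h$nTested, h$nSelected,
                if (is.null(h$metrics)) NA_real_ else h$metrics@accuracy))
})

#' One continual-learning step
#'
#' Evaluates the current model on the new session's epochs (this pre-update
#' accuracy is the reported per-stage test performance), appends the
#' correctly classified trials to the cumulative training pool, and
#' retrains from the current parameters on the updated pool (CSP bank
#' refitted on the pool). When no trial is selected the stage advances
#' with the model unchanged, with a warning.
#'
#' @param state a [ContinualState-class].
#' @param newEpochs the next session's [EpochSet-class].
#' @param cfg a [trainConfig]; the warm-start fit uses a single 10%
#'   holdout for early stopping rather than the full fold loop.
#' @return the advanced [ContinualState-class].
#' @export
continualStep <- function(state, newEpochs, cfg = trainConfig()) {
  stopifnot(is(state, "ContinualState"), is(newEpochs, "EpochSet"))
  pos <- match(state@stage, CASCADE_STAGES)
  if (is.na(pos) || pos >= length(CASCADE_STAGES))
    stop("cascade already at its final stage", call. = FALSE)
  nextStage <- CASCADE_STAGES[pos + 1L]
  ev <- evaluateModel(state@model, newEpochs)
  sel <- selectCorrect(ev$predictions, newEpochs@labels)
  rec <- list(stage = nextStage, nTested = nTrials(newEpochs),
              nSelected = length(sel), metrics = ev$report)
  if (!length(sel)) {
    warning("no trials selected; model carried over unchanged")
    return(new("ContinualState", stage = nextStage, model = state@model,
               pool = state@pool, history = c(state@history, list(rec))))
  }
  pool <- c(state@pool, newEpochs[sel])
  model <- fitTSTN(pool, cfg, model = state@model, stage = nextStage,
                   crossValidate = FALSE)
  new("ContinualState", stage = nextStage, model = model, pool = pool,
      history = c(state@history, list(rec)))
}

#' Offline replay of an MI-feedback session
#'
#' Processes the session's trials in chronological order with the model
#' frozen (no within-session updates), emitting the per-trial feedback
#' decision and its correctness — the offline equivalent of driving the
#' online feedback display. Identical to batch evaluation of the same
#' epochs under a frozen model.
#'
#' @param model a fitted [TSTNModel-class].
#' @param recording the raw session [RawRecording-class].
#' @param timeline the session [TrialTimeline-class]; must be `MI_FB`.
#' @param cfg a [preprocConfig] used to preprocess and epoch the session.
#' @return data.frame with columns `trial`, `label`, `decision`, `correct`.
#' @export
replayOnline <- function(model, recording, timeline, cfg = preprocConfig()) {
  if (timeline@sessionKind != "MI_FB")
    stop("configuration error: online replay requires an MI_FB session",
         call. = FALSE)
  prep <- preprocessRecording(recording, cfg)
  epochs <- assembleEpochs(prep, timeline, cfg)$task
  n <- nTrials(epochs)
  decision <- character(n)
  for (i in seq_len(n)) {
    pr <- tstnForward(model, epochs@data[i, , ])
    decision[i] <- CLASS_LEVELS[which.max(pr[1L, ])]
  }
  data.frame(trial = epochs@provenance$trial_index,
             label = as.character(epochs@labels),
             decision = decision,
             correct = decision == as.character(epochs@labels))
}
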