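#' @include tstn-package.R
NULL

# ---------------------------------------------------------------- RawRecording

#' Continuous multichannel EEG recording
#'
#' Holds a channels x samples signal matrix in microvolts together with the
#' sampling rate, ordered channel labels and free-form provenance metadata
#' (subject id, session kind, generator seed, ...).
#'
#' @slot signal numeric matrix, channels x samples, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector, one label per signal row.
#' @slot meta named list of provenance metadata.
#' @export
setClass("RawRecording",
  representation(signal = "matrix", samplingRate = "numeric",
                 channelLabels = "character", meta = "list"),
  prototype(signal = matrix(0, 0, 0), samplingRate = 1, meta = list()))

setValidity("RawRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (nrow(object@signal) != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal the number of signal rows")
  if (anyNA(object@signal))
    msg <- c(msg, "signal must not contain NA/NaN values")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param samplingRate sampling rate in Hz.
#' @param channelLabels ordered channel labels.
#' @param meta named list of provenance metadata.
#' @return a [RawRecording-class] object.
#' @export
RawRecording <- function(signal, samplingRate, channelLabels, meta = list()) {
  rownames(signal) <- channelLabels
  new("RawRecording", signal = signal, samplingRate = as.numeric(samplingRate),
      channelLabels = as.character(channelLabels), meta = meta)
}

# ---------------------------------------------------------------- TrialTimeline

#' Trial timeline of a session
#'
#' Ordered, non-overlapping blocks (rest and task) with onsets in seconds
#' from recording start, durations, block kinds and per-task class labels.
#' Epoch windows elsewhere in the package are half-open `[start, end)`.
#'
#' @slot events data.frame with columns `trial`, `block_kind`, `class_label`,
#'   `onset_s`, `duration_s`.
#' @slot sessionKind `"AO_MI"` or `"MI_FB"`.
#' @export
setClass("TrialTimeline",
  representation(events = "data.frame", sessionKind = "character"))

setValidity("TrialTimeline", function(object) {
  ev <- object@events
  need <- c("trial", "block_kind", "class_label", "onset_s", "duration_s")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (!all(ev$block_kind %in% BLOCK_KINDS))
    msg <- c(msg, "unknown block kind")
  if (any(ev$duration_s <= 0))
    msg <- c(msg, "all durations must be > 0")
  if (nrow(ev) > 1) {
    if (is.unsorted(ev$onset_s, strictly = TRUE))
      msg <- c(msg, "onsets must be strictly increasing")
    ends <- ev$onset_s + ev$duration_s
    if (any(ev$onset_s[-1] < ends[-nrow(ev)] - 1e-9))
      msg <- c(msg, "blocks must not overlap")
  }
  task <- which(ev$block_kind != "REST")
  if (any(task == 1L) || (length(task) && !all(ev$block_kind[task - 1L] == "REST")))
    msg <- c(msg, "every task block must be preceded by a REST block")
  if (!object@sessionKind %in% c("AO_MI", "MI_FB"))
    msg <- c(msg, "sessionKind must be AO_MI or MI_FB")
  if (length(msg)) msg else TRUE
})

#' Construct a TrialTimeline
#' @param events data.frame of blocks (see [TrialTimeline-class]).
#' @param sessionKind `"AO_MI"` or `"MI_FB"`.
#' @return a [TrialTimeline-class] object.
#' @export
TrialTimeline <- function(events, sessionKind) {
  rownames(events) <- NULL
  new("TrialTimeline", events = events, sessionKind = sessionKind)
}

# -------------------------------------------------------------------- EpochSet

#' Set of labeled EEG epochs
#'
#' A trials x channels x samples array with per-trial class labels, the
#' epoch window relative to block onset, and per-trial provenance.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot labels factor with levels `LEFT`, `RIGHT`, `REST`.
#' @slot samplingRate sampling rate in Hz.
#' @slot epochWindow numeric length 2, `(start_s, end_s)` relative to block
#'   onset; half-open.
#' @slot provenance data.frame with columns `session_id`, `block_kind`,
#'   `trial_index`.
#' @export
setClass("EpochSet",
  representation(data = "array", labels = "factor", samplingRate = "numeric",
                 epochWindow = "numeric", provenance = "data.frame"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    return("data must be a 3-dimensional trials x channels x samples array")
  n <- dim(object@data)[1L]
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must equal the trial count")
  if (!identical(levels(object@labels), CLASS_LEVELS))
    msg <- c(msg, "labels must use levels LEFT, RIGHT, REST")
  if (nrow(object@provenance) != n)
    msg <- c(msg, "provenance must have one row per trial")
  if (length(object@epochWindow) != 2L ||
      object@epochWindow[2L] <= object@epochWindow[1L])
    msg <- c(msg, "epochWindow must be an increasing (start, end) pair")
  nsamp <- round(diff(object@epochWindow) * object@samplingRate)
  if (n > 0 && abs(nsamp - dim(object@data)[3L]) > 1e-6)
    msg <- c(msg, "window length times rate must equal the sample count")
  if (anyNA(object@data))
    msg <- c(msg, "data must not contain NA/NaN values")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param data trials x channels x samples array.
#' @param labels class labels (character or factor, levels LEFT/RIGHT/REST).
#' @param samplingRate sampling rate in Hz.
#' @param epochWindow `(start_s, end_s)` relative to block onset.
#' @param provenance per-trial data.frame (`session_id`, `block_kind`,
#'   `trial_index`); a default is built when omitted.
#' @return an [EpochSet-class] object.
#' @export
EpochSet <- function(data, labels, samplingRate, epochWindow = c(0, 2),
                     provenance = NULL) {
  n <- dim(data)[1L]
  if (is.null(provenance)) {
    provenance <- data.frame(session_id = rep("session", n),
                             block_kind = rep(NA_character_, n),
                             trial_index = seq_len(n))
  }
  rownames(provenance) <- NULL
  new("EpochSet", data = data,
      labels = factor(as.character(labels), levels = CLASS_LEVELS),
      samplingRate = as.numeric(samplingRate),
      epochWindow = as.numeric(epochWindow), provenance = provenance)
}

# ------------------------------------------------------ CSP solution and bank

#' Solution of one CSP simultaneous-diagonalization problem
#'
#' Eigenvector matrix `P` and descending eigenvalues `D` satisfying
#' `t(P) %*% R1 %*% P = diag(D)` and `t(P) %*% R2 %*% P = I`.
#'
#' @slot P channels x channels eigenvector matrix (columns are filters).
#' @slot D descending eigenvalues.
#' @slot classPair character length 2: target class, rest-of-classes.
#' @export
setClass("CspSolution",
  representation(P = "matrix", D = "numeric", classPair = "character"))

setValidity("CspSolution", function(object) {
  msg <- character()
  if (nrow(object@P) != ncol(object@P))
    msg <- c(msg, "P must be square")
  if (length(object@D) != ncol(object@P))
    msg <- c(msg, "one eigenvalue per column of P")
  if (is.unsorted(rev(object@D)))
    msg <- c(msg, "eigenvalues must be sorted in descending order")
  if (length(msg)) msg else TRUE
})

#' One-versus-rest CSP spatial filter bank
#'
#' The stacked spatial filter `Z` (2 filters per one-versus-rest problem, in
#' fixed class order LEFT, RIGHT, REST) plus the per-problem eigen structure.
#'
#' @slot Z 6 x channels filter matrix; rows are the transposed top-2
#'   eigenvectors of each one-versus-rest problem.
#' @slot solutions list of [CspSolution-class], one per class.
#' @slot classes the class order used to stack `Z`.
#' @slot channelLabels channel labels the bank was fitted on.
#' @export
setClass("SpatialFilterBank",
  representation(Z = "matrix", solutions = "list", classes = "character",
                 channelLabels = "character"))

setValidity("SpatialFilterBank", function(object) {
  msg <- character()
  if (nrow(object@Z) != 2L * length(object@solutions))
    msg <- c(msg, "Z must have 2 rows per one-versus-rest problem")
  if (!all(is.finite(object@Z)))
    msg <- c(msg, "Z must be finite")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------------------- TSTNModel

#' Transformer-based spatial-temporal network (TSTN) model
#'
#' All learned parameters of the classifier: the CSP bank, the spatial
#' self-attention projections, the convolutional patch embedding, the
#' temporal multi-head attention, and the pooled fully-connected head.
#'
#' @slot bank a [SpatialFilterBank-class].
#' @slot params named list of parameter arrays (see [initTSTN]).
#' @slot dims named list of architecture dimensions.
#' @slot dropout numeric length 2: spatial and temporal dropout rates.
#' @slot meta named list: training lineage, seed, cross-validation records.
#' @export
setClass("TSTNModel",
  representation(bank = "SpatialFilterBank", params = "list", dims = "list",
                 dropout = "numeric", meta = "list"))

setValidity("TSTNModel", function(object) {
  p <- object@params
  d <- object@dims
  msg <- character()
  need <- c("Wq", "Wk", "Wv", "c1W", "c1b", "c2W", "c2b",
            "Wtq", "Wtk", "Wtv", "Wo", "gamma", "beta", "fcW", "fcb")
  if (!all(need %in% names(p)))
    return(paste("params must contain", paste(setdiff(need, names(p)), collapse = ", ")))
  if (!all(dim(p$Wq) == d$d) || !all(dim(p$Wk) == d$d) || !all(dim(p$Wv) == d$d))
    msg <- c(msg, "attention projections must be d x d")
  L1 <- d$d - d$conv1Kernel + 1L
  if (L1 %% d$conv2Stride != 0L)
    msg <- c(msg, "conv1 output length must be divisible by the conv2 stride")
  if (!all(dim(p$c2W) == c(d$conv2Filters, d$conv1Filters * d$featChannels * d$conv2Kernel)))
    msg <- c(msg, "conv2 weight shape inconsistent with dims")
  if (d$conv2Filters != 2L * d$heads)
    msg <- c(msg, "patch count must equal 2 x head count")
  if (!all(dim(p$Wo) == d$conv2Filters))
    msg <- c(msg, "Wo must be square of size patch count")
  if (!all(dim(p$fcW) == c(3L, d$conv2Filters)))
    msg <- c(msg, "classifier head must map patch features to 3 classes")
  if (length(object@dropout) != 2L || any(object@dropout < 0) || any(object@dropout >= 1))
    msg <- c(msg, "dropout rates must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

# ----------------------------------------------------------------------- RPMap

#' Relative-power (ERD/ERS) map
#'
#' Time x channel relative band-power changes in percent,
#' `RP = (A - R) / R * 100`, with band and window metadata.
#'
#' @slot values time-bins x channels matrix of RP values in percent.
#' @slot band analysis band in Hz.
#' @slot referenceWindow reference window in seconds relative to task onset.
#' @slot analysisWindow analysis window in seconds relative to task onset.
#' @slot timeBins bin centers in seconds relative to task onset.
#' @slot channels channel labels.
#' @slot nTrials number of trials averaged.
#' @export
setClass("RPMap",
  representation(values = "matrix", band = "numeric",
                 referenceWindow = "numeric", analysisWindow = "numeric",
                 timeBins = "numeric", channels = "character",
                 nTrials = "integer"))

setValidity("RPMap", function(object) {
  msg <- character()
  if (!all(is.finite(object@values)))
    msg <- c(msg, "RP values must be finite")
  if (any(object@values < -100 - 1e-9))
    msg <- c(msg, "RP cannot fall below -100% (power is nonnegative)")
  if (ncol(object@values) != length(object@channels))
    msg <- c(msg, "one column per channel")
  if (nrow(object@values) != length(object@timeBins))
    msg <- c(msg, "one row per time bin")
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------------- MetricsReport

#' Confusion-matrix metrics for the three-class problem
#'
#' @slot confusion 3 x 3 count matrix, rows = true class, cols = predicted.
#' @slot accuracy overall accuracy (trace / total).
#' @slot specificity macro-averaged one-versus-rest specificity.
#' @slot f1 macro-averaged F1 score.
#' @slot perClass data.frame with per-class recall, specificity, precision, F1.
#' @slot n number of trials.
#' @export
setClass("MetricsReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 specificity = "numeric", f1 = "numeric",
                 perClass = "data.frame", n = "integer"))

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (any(object@confusion < 0) || sum(object@confusion) != object@n)
    msg <- c(msg, "confusion entries must be nonnegative counts summing to n")
  for (v in c(object@accuracy, object@specificity, object@f1))
    if (v < -1e-12 || v > 1 + 1e-12)
      msg <- c(msg, "metrics must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
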