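#' @include AllClasses.R
NULL

#' Preprocessing configuration
#'
#' @param band band-pass edges in Hz (default 4-40).
#' @param filterOrder Butterworth order of the band-pass prototype
#'   (default 3, i.e. a 3rd-order IIR band-pass design).
#' @param targetRate decimation target in Hz (default 250); the raw rate
#'   must be an integer multiple.
#' @param epochLen epoch length in seconds (default 2).
#' @param restEpochRule which window inside a trial's rest period supplies
#'   the REST-class training epoch for AO+MI sessions; `"pre_task"` (the
#'   default and only rule) takes the last `epochLen` seconds before the
#'   trial's first task-block onset, maximizing distance from task activity.
#' @return a `PreprocConfig` (validated named list).
#' @export
preprocConfig <- function(band = c(4, 40), filterOrder = 3L, targetRate = 250,
                          epochLen = 2, restEpochRule = "pre_task") {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high", call. = FALSE)
  .assertScalarNum(targetRate, "targetRate", lower = 1)
  if (band[2] >= targetRate / 2)
    stop("configuration error: band upper edge must lie below the target Nyquist",
         call. = FALSE)
  .assertScalarNum(epochLen, "epochLen", lower = 1e-3)
  if (abs(epochLen * targetRate - round(epochLen * targetRate)) > 1e-9)
    stop("epochLen times targetRate must be an integer", call. = FALSE)
  restEpochRule <- match.arg(restEpochRule, "pre_task")
  cfg <- list(band = as.numeric(band), filterOrder = as.integer(filterOrder),
              targetRate = targetRate, epochLen = epochLen,
              restEpochRule = restEpochRule)
  class(cfg) <- "PreprocConfig"
  cfg
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the band-pass forward and backward (`signal::filtfilt`), so the
#' effective magnitude response is the squared Butterworth response and the
#' phase is zero (no group-delay misalignment of epochs).
#'
#' @param rec a [RawRecording-class].
#' @param cfg a [preprocConfig].
#' @return the filtered [RawRecording-class] (same shape and rate).
#' @export
bandpassFilter <- function(rec, cfg = preprocConfig()) {
  stopifnot(is(rec, "RawRecording"))
  fs <- rec@samplingRate
  if (cfg$band[2] >= fs / 2)
    stop("configuration error: band exceeds the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(cfg$filterOrder, cfg$band / (fs / 2), type = "pass")
  out <- rec@signal
  for (c in seq_len(nrow(out)))
    out[c, ] <- signal::filtfilt(bf, rec@signal[c, ])
  RawRecording(out, fs, rec@channelLabels, rec@meta)
}

#' Anti-aliased decimation to the target rate
#'
#' Integer-ratio decimation with a zero-phase anti-aliasing filter
#' (`signal::decimate` with its IIR design applied forward-backward).
#' Duration is preserved: a 2-s epoch at 1 kHz becomes 500 samples at
#' 250 Hz.
#'
#' @param rec a [RawRecording-class].
#' @param cfg a [preprocConfig].
#' @return the decimated [RawRecording-class].
#' @export
downsampleRecording <- function(rec, cfg = preprocConfig()) {
  stopifnot(is(rec, "RawRecording"))
  fs <- rec@samplingRate
  q <- fs / cfg$targetRate
  if (abs(q - round(q)) > 1e-9)
    stop("configuration error: raw rate must be an integer multiple of targetRate",
         call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  n <- ceiling(ncol(rec@signal) / q)
  out <- matrix(0, nrow(rec@signal), n)
  for (c in seq_len(nrow(out)))
    out[c, ] <- signal::decimate(rec@signal[c, ], q, ftype = "iir")
  RawRecording(out, cfg$targetRate, rec@channelLabels, rec@meta)
}

#' Band-pass filter and decimate in one step
#' @inheritParams bandpassFilter
#' @return the preprocessed [RawRecording-class] at `cfg$targetRate`.
#' @export
preprocessRecording <- function(rec, cfg = preprocConfig()) {
  downsampleRecording(bandpassFilter(rec, cfg), cfg)
}

# cut one epoch [onset - preOnset, onset - preOnset + len) from the signal;
# returns NULL when it falls outside the recording
.cutEpoch <- function(sig, fs, onset, preOnset, len) {
  i0 <- floor((onset - preOnset) * fs) + 1L
  i1 <- i0 + as.integer(round((preOnset + len) * fs)) - 1L
  if (i0 < 1L || i1 > ncol(sig)) return(NULL)
  sig[, i0:i1, drop = FALSE]
}

#' Cut a preprocessed recording into labeled epochs
#'
#' Assembly rules follow the session structure. For an `AO_MI` session the
#' result has two sets: `train` holds one epoch per AO+MI block (two per
#' trial, labeled LEFT/RIGHT) plus one REST-class epoch per trial taken
#' from the trial's first rest period (last `epochLen` seconds before the
#' first task onset); `mi` holds the per-trial MI-block epochs, the
#' "MI without feedback" test set. For an `MI_FB` session the single set
#' `task` holds one epoch per task block labeled LEFT/RIGHT/REST.
#'
#' Task blocks shorter than `epochLen` are skipped with a warning; epochs
#' (including requested pre-onset context) falling outside the recording
#' are skipped likewise.
#'
#' @param rec the preprocessed [RawRecording-class].
#' @param timeline the session's [TrialTimeline-class].
#' @param cfg a [preprocConfig].
#' @param preOnset seconds of pre-onset context to include in every task
#'   epoch (0 for classification; 2 for ERD analysis). The epoch window
#'   becomes `[-preOnset, epochLen)` relative to block onset.
#' @return named list of [EpochSet-class] objects (see Details).
#' @export
assembleEpochs <- function(rec, timeline, cfg = preprocConfig(), preOnset = 0) {
  stopifnot(is(rec, "RawRecording"), is(timeline, "TrialTimeline"))
  fs <- rec@samplingRate
  ev <- timeline@events
  if (nrow(ev) > 1) {
    ends <- ev$onset_s + ev$duration_s
    if (any(ev$onset_s[-1] < ends[-nrow(ev)] - 1e-9))
      stop("timeline error: overlapping blocks", call. = FALSE)
  }
  len <- cfg$epochLen
  nsamp <- as.integer(round((preOnset + len) * fs))
  sessId <- if (is.null(rec@meta$sessionKind)) "session" else
    sprintf("%s-seed%s", rec@meta$sessionKind,
            if (is.null(rec@meta$seed)) "NA" else rec@meta$seed)

  collect <- function(rows, labels) {
    keep <- list(); kl <- character(); kp <- list()
    for (i in seq_along(rows)) {
      r <- ev[rows[i], ]
      if (r$block_kind != "REST" && r$duration_s < len - 1e-9) {
        warning(sprintf("trial %d: %s block shorter than the epoch length, skipped",
                        r$trial, r$block_kind))
        next
      }
      x <- .cutEpoch(rec@signal, fs, r$onset_s, preOnset, len)
      if (is.null(x)) {
        warning(sprintf("trial %d: epoch outside the recording, skipped", r$trial))
        next
      }
      keep[[length(keep) + 1L]] <- x
      kl <- c(kl, labels[i])
      kp[[length(kp) + 1L]] <- data.frame(session_id = sessId,
                                          block_kind = r$block_kind,
                                          trial_index = r$trial)
    }
    dat <- array(0, c(length(keep), nrow(rec@signal), nsamp),
                 dimnames = list(NULL, rec@channelLabels, NULL))
    for (i in seq_along(keep)) dat[i, , ] <- keep[[i]]
    EpochSet(dat, kl, fs, c(-preOnset + 0, len),
             if (length(kp)) do.call(rbind, kp) else NULL)
  }

  if (timeline@sessionKind == "AO_MI") {
    ao <- which(ev$block_kind == "AO_MI")
    mi <- which(ev$block_kind == "MI")
    # REST-class epochs: synthetic onset epochLen seconds before the first
    # task block of each trial, inside the trial's first rest period
    restRows <- integer(); restOnsets <- numeric()
    for (tr in sort(unique(ev$trial))) {
      rows <- which(ev$trial == tr)
      firstTask <- rows[ev$block_kind[rows] != "REST"][1L]
      firstRest <- rows[ev$block_kind[rows] == "REST"][1L]
      if (is.na(firstTask) || is.na(firstRest)) next
      if (ev$duration_s[firstRest] < len + preOnset - 1e-9) {
        warning(sprintf("trial %d: rest period too short for a REST epoch, skipped", tr))
        next
      }
      restRows <- c(restRows, firstRest)
      restOnsets <- c(restOnsets, ev$onset_s[firstTask] - len)
    }
    restSet <- NULL
    if (length(restRows)) {
      evRest <- ev
      evRest$onset_s[restRows] <- restOnsets  # re-anchor rest epochs
      holdEv <- ev; ev <- evRest
      restSet <- collect(restRows, rep("REST", length(restRows)))
      ev <- holdEv
    }
    train <- collect(ao, ev$class_label[ao])
    if (!is.null(restSet) && nTrials(restSet) > 0) train <- c(train, restSet)
    list(train = train, mi = collect(mi, ev$class_label[mi]))
  } else {
    task <- which(ev$block_kind == "MI_FB_TASK")
    list(task = collect(task, ev$class_label[task]))
  }
}
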