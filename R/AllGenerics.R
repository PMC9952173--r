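#' @include AllClasses.R
NULL

#' Sampling rate accessor
#' @param x a RawRecording or EpochSet.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "RawRecording", function(x) x@samplingRate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)

#' Channel labels accessor
#' @param x a RawRecording or SpatialFilterBank.
#' @return character vector of channel labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "RawRecording", function(x) x@channelLabels)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "SpatialFilterBank", function(x) x@channelLabels)

#' Signal matrix accessor
#' @param x a RawRecording.
#' @return channels x samples numeric matrix in microvolts.
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "RawRecording", function(x) x@signal)

#' Number of trials
#' @param x an EpochSet or TrialTimeline.
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname nTrials
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])

#' @rdname nTrials
#' @export
setMethod("nTrials", "TrialTimeline", function(x) {
  if (nrow(x@events) == 0L) 0L else max(x@events$trial)
})

#' Epoch data accessor
#' @param x an EpochSet.
#' @return trials x channels x samples array.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname epochData
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' Epoch labels accessor
#' @param x an EpochSet.
#' @return factor of class labels.
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname epochLabels
#' @export
setMethod("epochLabels", "EpochSet", function(x) x@labels)

#' Timeline events accessor
#' @param x a TrialTimeline.
#' @return data.frame of blocks.
#' @export
setGeneric("timelineEvents", function(x) standardGeneric("timelineEvents"))

#' @rdname timelineEvents
#' @export
setMethod("timelineEvents", "TrialTimeline", function(x) x@events)

#' Spatial filter matrix accessor
#' @param x a SpatialFilterBank.
#' @return the stacked 6 x channels filter matrix Z.
#' @export
setGeneric("filterMatrix", function(x) standardGeneric("filterMatrix"))

#' @rdname filterMatrix
#' @export
setMethod("filterMatrix", "SpatialFilterBank", function(x) x@Z)

#' Relative-power values accessor
#' @param x an RPMap.
#' @return time-bins x channels matrix of RP percentages.
#' @export
setGeneric("rpValues", function(x) standardGeneric("rpValues"))

#' @rdname rpValues
#' @export
setMethod("rpValues", "RPMap", function(x) x@values)

#' Subset an EpochSet by trial index
#' @param x an EpochSet.
#' @param i trial indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an EpochSet with the selected trials.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nTrials(x))[i]
  EpochSet(x@data[idx, , , drop = FALSE], x@labels[idx], x@samplingRate,
           x@epochWindow, x@provenance[idx, , drop = FALSE])
})

#' Concatenate EpochSets trial-wise
#' @param x an EpochSet.
#' @param ... further EpochSets with matching geometry.
#' @return the combined EpochSet.
#' @export
setMethod("c", "EpochSet", function(x, ...) {
  rest <- list(...)
  if (!length(rest)) return(x)
  sets <- c(list(x), rest)
  dims <- vapply(sets, function(s) dim(s@data)[-1L], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("EpochSets must share channel and sample counts", call. = FALSE)
  rates <- vapply(sets, samplingRate, numeric(1))
  if (any(abs(rates - rates[1]) > 1e-9))
    stop("EpochSets must share the sampling rate", call. = FALSE)
  dat <- do.call(abind3, lapply(sets, epochData))
  EpochSet(dat, unlist(lapply(sets, function(s) as.character(s@labels))),
           x@samplingRate, x@epochWindow,
           do.call(rbind, lapply(sets, function(s) s@provenance)))
})

# bind 3-D arrays along the first (trial) dimension
abind3 <- function(...) {
  arrs <- list(...)
  ntot <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  d <- dim(arrs[[1L]])
  out <- array(0, c(ntot, d[2L], d[3L]),
               dimnames = list(NULL, dimnames(arrs[[1L]])[[2L]], NULL))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1L]
    if (n > 0) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

# ------------------------------------------------------------------ show methods

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal), object@samplingRate,
              ncol(object@signal) / object@samplingRate))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TrialTimeline", function(object) {
  ev <- object@events
  cat(sprintf("TrialTimeline (%s): %d trials, %d blocks, %.1f s\n",
              object@sessionKind, nTrials(object), nrow(ev),
              if (nrow(ev)) max(ev$onset_s + ev$duration_s) else 0))
  print(table(ev$block_kind))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              d[1L], d[2L], d[3L], object@samplingRate,
              object@epochWindow[1L], object@epochWindow[2L]))
  if (d[1L]) print(table(object@labels))
})

setMethod("show", "SpatialFilterBank", function(object) {
  cat(sprintf("SpatialFilterBank: Z is %d x %d (one-versus-rest classes: %s)\n",
              nrow(object@Z), ncol(object@Z),
              paste(object@classes, collapse = ", ")))
})

setMethod("show", "TSTNModel", function(object) {
  d <- object@dims
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("TSTNModel: d=%d, conv1 %dx%d, conv2 %d filters (stride %d), %d heads; %d parameters\n",
              d$d, d$conv1Kernel, d$conv1Filters, d$conv2Filters,
              d$conv2Stride, d$heads, np))
  cat(sprintf("  dropout: spatial %.2f, temporal %.2f; lineage: %s\n",
              object@dropout[1L], object@dropout[2L],
              if (is.null(object@meta$stage)) "init" else object@meta$stage))
})

setMethod("show", "RPMap", function(object) {
  cat(sprintf("RPMap: %d time bins x %d channels, band %g-%g Hz, reference [%g, %g) s, %d trials\n",
              nrow(object@values), ncol(object@values), object@band[1L],
              object@band[2L], object@referenceWindow[1L],
              object@referenceWindow[2L], object@nTrials))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: n=%d accuracy=%.3f macro specificity=%.3f macro F1=%.3f\n",
              object@n, object@accuracy, object@specificity, object@f1))
  print(object@confusion)
})
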