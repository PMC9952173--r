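#' @include AllClasses.R
NULL

.EPOCH_ARCHIVE_VERSION <- 1L
.MODEL_ARCHIVE_VERSION <- 1L

# fixed-width ASCII field helpers for the EDF header
.edfField <- function(x, width) {
  s <- format(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' European Data Format: 256-byte global header, one 256-byte header block
#' per channel, then 1-second data records of 16-bit little-endian integers.
#' Physical units are microvolts with a symmetric per-channel physical range,
#' so the round trip is lossless up to 16-bit quantization. Recordings whose
#' length is not a whole number of seconds are zero-padded to the next full
#' record (with a warning).
#'
#' @param rec a [RawRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "RawRecording"))
  sig <- rec@signal
  fs <- rec@samplingRate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  nch <- nrow(sig)
  n <- ncol(sig)
  nrec <- ceiling(n / fs)
  if (nrec * fs != n) {
    warning("signal padded with zeros to a whole number of 1-s records")
    sig <- cbind(sig, matrix(0, nch, nrec * fs - n))
  }

  physMax <- pmax(apply(abs(sig), 1, max), 1e-6)
  physMaxStr <- vapply(physMax, function(p) .edfField(signif(p * 1.000001, 6), 8),
                       character(1))
  physMaxUsed <- as.numeric(physMaxStr)  # quantize against the written value

  meta <- rec@meta
  recId <- sprintf("tstn session=%s seed=%s",
                   if (is.null(meta$sessionKind)) "NA" else meta$sessionKind,
                   if (is.null(meta$seed)) "NA" else meta$seed)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfField("0", 8),
    .edfField("X X X X", 80),
    .edfField(recId, 80),
    .edfField("01.01.00", 8), .edfField("00.00.00", 8),
    .edfField(256 * (nch + 1L), 8),
    .edfField("", 44),
    .edfField(nrec, 8),
    .edfField(1, 8),
    .edfField(nch, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste(vapply(vals, .edfField, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  }
  fld(rec@channelLabels, 16)
  fld(rep("", nch), 80)                       # transducer
  fld(rep("uV", nch), 8)                      # physical dimension
  fld(vapply(-physMaxUsed, function(p) .edfField(p, 8), character(1)), 8)
  fld(physMaxStr, 8)
  fld(rep(-32768L, nch), 8)
  fld(rep(32767L, nch), 8)
  fld(rep("", nch), 80)                       # prefiltering
  fld(rep(fs, nch), 8)                        # samples per record
  fld(rep("", nch), 32)                       # reserved

  scale <- 65535 / (2 * physMaxUsed)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (c in seq_len(nch)) {
      d <- round((sig[c, idx] + physMaxUsed[c]) * scale[c]) - 32768
      d <- pmin(32767, pmax(-32768, d))
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.edfRead <- function(con, width, n = 1L) {
  raw <- readChar(con, width * n, useBytes = TRUE)
  if (is.na(nchar(raw, type = "bytes")) || nchar(raw, type = "bytes") < width * n)
    stop(sprintf("malformed EDF: header truncated at byte offset %d",
                 seek(con)), call. = FALSE)
  trimws(substring(raw, (seq_len(n) - 1L) * width + 1L, seq_len(n) * width))
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @param requiredChannels optional channel labels that must all be present;
#'   a missing one raises a configuration error.
#' @return a [RawRecording-class] with the signal in microvolts.
#' @export
readEDF <- function(path, requiredChannels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  .edfRead(con, 8)                       # version
  .edfRead(con, 80)                      # patient id
  recId <- .edfRead(con, 80)
  .edfRead(con, 8); .edfRead(con, 8)     # date, time
  headerBytes <- as.integer(.edfRead(con, 8))
  .edfRead(con, 44)
  nrec <- as.integer(.edfRead(con, 8))
  recDur <- as.numeric(.edfRead(con, 8))
  nch <- as.integer(.edfRead(con, 4))
  if (is.na(nch) || nch <= 0 || is.na(nrec) || nrec < 0)
    stop("malformed EDF: invalid channel/record counts in header", call. = FALSE)
  labels <- .edfRead(con, 16, nch)
  .edfRead(con, 80, nch)
  .edfRead(con, 8, nch)                  # physical dimension
  physMin <- as.numeric(.edfRead(con, 8, nch))
  physMax <- as.numeric(.edfRead(con, 8, nch))
  digMin <- as.numeric(.edfRead(con, 8, nch))
  digMax <- as.numeric(.edfRead(con, 8, nch))
  .edfRead(con, 80, nch)
  spr <- as.integer(.edfRead(con, 8, nch))
  .edfRead(con, 32, nch)
  if (seek(con) != headerBytes)
    stop(sprintf("malformed EDF: header size mismatch at byte offset %d",
                 seek(con)), call. = FALSE)
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: channels have differing sampling rates", call. = FALSE)
  fs <- spr[1L] / recDur

  n <- nrec * spr[1L]
  sig <- matrix(0, nch, n)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (c in seq_len(nch)) {
      d <- readBin(con, "integer", n = spr[1L], size = 2L, endian = "little",
                   signed = TRUE)
      if (length(d) < spr[1L])
        stop(sprintf("malformed EDF: data truncated at byte offset %d",
                     seek(con)), call. = FALSE)
      sig[c, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (d - digMin[c]) * scale[c] + physMin[c]
    }
  }
  if (!is.null(requiredChannels) && !all(requiredChannels %in% labels))
    stop("configuration error: missing channels: ",
         paste(setdiff(requiredChannels, labels), collapse = ", "),
         call. = FALSE)
  meta <- list()
  m <- regmatches(recId, regexec("session=(\\S+) seed=(\\S+)", recId))[[1L]]
  if (length(m) == 3L) {
    meta$sessionKind <- m[2L]
    meta$seed <- suppressWarnings(as.integer(m[3L]))
  }
  RawRecording(sig, fs, labels, meta = meta)
}

#' Write a trial timeline as a tab-separated event table
#'
#' Columns: `onset_s`, `duration_s`, `block_kind`, `class_label`, `trial`.
#' Timestamps are seconds, 0-based from recording start.
#'
#' @param timeline a [TrialTimeline-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(timeline, path) {
  stopifnot(is(timeline, "TrialTimeline"))
  ev <- timeline@events[, c("onset_s", "duration_s", "block_kind",
                            "class_label", "trial")]
  hdr <- sprintf("# tstn event table\tsession_kind=%s", timeline@sessionKind)
  writeLines(hdr, path)
  suppressWarnings(write.table(ev, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a tab-separated event table
#' @param path event-table path written by [writeEventTable].
#' @return a [TrialTimeline-class].
#' @export
readEventTable <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- sub(".*session_kind=", "", first)
  ev <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  ev$class_label <- as.character(ev$class_label)
  ev$class_label[ev$class_label %in% c("NA", "")] <- NA_character_
  TrialTimeline(ev[, c("trial", "block_kind", "class_label", "onset_s",
                       "duration_s")], kind)
}

#' Write an epoch archive
#'
#' Single-file archive of an [EpochSet-class]: the epoch array, labels,
#' sampling rate, epoch window and per-trial provenance plus a format
#' version, serialized losslessly. Reading a file with a newer format
#' version than this package supports raises an incompatibility error.
#'
#' @param epochs an [EpochSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEpochArchive <- function(epochs, path) {
  stopifnot(is(epochs, "EpochSet"))
  saveRDS(list(format = "tstn-epoch-archive",
               version = .EPOCH_ARCHIVE_VERSION,
               data = epochs@data, labels = as.character(epochs@labels),
               samplingRate = epochs@samplingRate,
               epochWindow = epochs@epochWindow,
               provenance = epochs@provenance),
          path, version = 3L)
  invisible(path)
}

#' Read an epoch archive
#' @param path archive path written by [writeEpochArchive].
#' @return an [EpochSet-class].
#' @export
readEpochArchive <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable epoch archive: ", conditionMessage(e), call. = FALSE))
  if (!is.list(x) || !identical(x$format, "tstn-epoch-archive"))
    stop("not a tstn epoch archive", call. = FALSE)
  if (x$version > .EPOCH_ARCHIVE_VERSION)
    stop(sprintf("incompatible epoch-archive version %d (this build supports <= %d)",
                 x$version, .EPOCH_ARCHIVE_VERSION), call. = FALSE)
  EpochSet(x$data, x$labels, x$samplingRate, x$epochWindow, x$provenance)
}

#' Serialize a fitted TSTN model
#'
#' Versioned single-file archive holding the CSP bank, every parameter
#' tensor, architecture dimensions, dropout rates and training lineage.
#'
#' @param model a [TSTNModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTSTNModel <- function(model, path) {
  stopifnot(is(model, "TSTNModel"))
  saveRDS(list(format = "tstn-model", version = .MODEL_ARCHIVE_VERSION,
               bank = list(Z = model@bank@Z,
                           solutions = lapply(model@bank@solutions, function(s)
                             if (is.null(s)) NULL
                             else list(P = s@P, D = s@D, classPair = s@classPair)),
                           classes = model@bank@classes,
                           channelLabels = model@bank@channelLabels),
               params = model@params, dims = model@dims,
               dropout = model@dropout, meta = model@meta),
          path, version = 3L)
  invisible(path)
}

#' Read a serialized TSTN model
#' @param path archive path written by [writeTSTNModel].
#' @return a [TSTNModel-class].
#' @export
readTSTNModel <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable model archive: ", conditionMessage(e), call. = FALSE))
  if (!is.list(x) || !identical(x$format, "tstn-model"))
    stop("not a tstn model archive", call. = FALSE)
  if (x$version > .MODEL_ARCHIVE_VERSION)
    stop(sprintf("incompatible model-archive version %d (this build supports <= %d)",
                 x$version, .MODEL_ARCHIVE_VERSION), call. = FALSE)
  bank <- new("SpatialFilterBank", Z = x$bank$Z,
              solutions = lapply(x$bank$solutions, function(s)
                if (is.null(s)) NULL
                else new("CspSolution", P = s$P, D = s$D, classPair = s$classPair)),
              classes = x$bank$classes, channelLabels = x$bank$channelLabels)
  new("TSTNModel", bank = bank, params = x$params, dims = x$dims,
      dropout = x$dropout, meta = x$meta)
}
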