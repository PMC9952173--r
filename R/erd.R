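#' @include AllClasses.R
NULL

#' Relative-power (ERD/ERS) analysis configuration
#'
#' @param band analysis band in Hz (default the mu/alpha band 8-13).
#' @param referenceWindow reference window in seconds relative to task
#'   onset (default -2 to 0, the pre-cue rest).
#' @param analysisWindow analysis window in seconds relative to task onset;
#'   NULL (default) runs to the end of the epoch.
#' @param filterOrder Butterworth order of the band isolation filter.
#' @param timeResolution seconds per relative-power time bin.
#' @param edgeTrim seconds discarded from both ends of each epoch before
#'   binning; the band-isolation filter and envelope estimator are not
#'   reliable inside this start-up zone.
#' @return an `RpConfig` (validated named list).
#' @export
rpConfig <- function(band = c(8, 13), referenceWindow = c(-2, 0),
                     analysisWindow = NULL, filterOrder = 4L,
                     timeResolution = 0.1, edgeTrim = 0.3) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high", call. = FALSE)
  if (length(referenceWindow) != 2L || referenceWindow[1] >= referenceWindow[2])
    stop("referenceWindow must be increasing", call. = FALSE)
  if (!is.null(analysisWindow)) {
    if (length(analysisWindow) != 2L || analysisWindow[1] >= analysisWindow[2])
      stop("analysisWindow must be increasing", call. = FALSE)
    if (referenceWindow[2] > analysisWindow[1] + 1e-9)
      stop("reference window must precede the analysis window", call. = FALSE)
  }
  .assertScalarNum(timeResolution, "timeResolution", lower = 1e-3)
  .assertScalarNum(edgeTrim, "edgeTrim", lower = 0)
  cfg <- list(band = as.numeric(band),
              referenceWindow = as.numeric(referenceWindow),
              analysisWindow = if (is.null(analysisWindow)) NULL
                               else as.numeric(analysisWindow),
              filterOrder = as.integer(filterOrder),
              timeResolution = timeResolution, edgeTrim = edgeTrim)
  class(cfg) <- "RpConfig"
  cfg
}

#' Relative power change in percent
#'
#' `RP = (A - R) / R * 100`, the percentage change of task-window band
#' power `A` against reference-window band power `R`; negative values are
#' event-related desynchronization (ERD), positive values ERS.
#'
#' @param A task-window band power (vectorized).
#' @param R reference band power, strictly positive.
#' @return relative power in percent.
#' @export
relativePower <- function(A, R) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("undefined reference: R must be strictly positive", call. = FALSE)
  (A - R) / R * 100
}

# zero-phase band-pass plus analytic amplitude, with reflection padding so
# both the filter start-up transient and the FFT wrap-around of the Hilbert
# transform fall on the padding instead of the epoch's own samples
.bandAmplitudePadded <- function(bf, x, np) {
  n <- length(x)
  np <- min(np, n - 1L)
  xp <- c(rev(x[2:(np + 1L)]), x, rev(x[(n - np):(n - 1L)]))
  .analyticAmplitude(signal::filtfilt(bf, xp))[(np + 1L):(np + n)]
}

# analytic-signal amplitude via the frequency-domain Hilbert transform
.analyticAmplitude <- function(x) {
  n <- length(x)
  X <- fft(x)
  hmul <- numeric(n)
  if (n %% 2L == 0L) {
    hmul[1L] <- 1
    hmul[n / 2L + 1L] <- 1
    hmul[2L:(n / 2L)] <- 2
  } else {
    hmul[1L] <- 1
    hmul[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(fft(X * hmul, inverse = TRUE) / n)
}

#' Time x channel relative-power (ERD/ERS) map
#'
#' For every channel: band-pass each trial to `cfg$band` (zero-phase
#' Butterworth), take the squared analytic amplitude as instantaneous band
#' power, average over the selected trials, bin in time, and express each
#' bin relative to the mean reference-window power via
#' `RP = (A - R) / R * 100`. Epochs must carry enough pre-onset context to
#' cover the reference window (see the `preOnset` argument of
#' [assembleEpochs]). When analyzing classifier output, pass the correct
#' trials as `trialMask` so only correctly classified trials contribute.
#'
#' @param epochs an [EpochSet-class] whose window covers the reference.
#' @param cfg an [rpConfig].
#' @param trialMask logical (or integer index) mask of trials to average;
#'   NULL means all trials. Selecting zero trials is an error.
#' @return an [RPMap-class].
#' @export
erdMap <- function(epochs, cfg = rpConfig(), trialMask = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@samplingRate
  win <- epochs@epochWindow
  if (win[1L] + cfg$edgeTrim >= cfg$referenceWindow[2L] - 1e-9)
    stop("data error: epochs lack pre-onset context for the reference window",
         call. = FALSE)
  if (cfg$band[2L] >= fs / 2)
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  n <- nTrials(epochs)
  idx <- if (is.null(trialMask)) seq_len(n) else seq_len(n)[trialMask]
  if (is.logical(trialMask) && length(trialMask) != n)
    stop("data error: mask length must equal the trial count", call. = FALSE)
  if (!length(idx) || anyNA(idx))
    stop("data error: trial mask selects no valid trials", call. = FALSE)

  nsamp <- dim(epochs@data)[3L]
  nch <- dim(epochs@data)[2L]
  bf <- signal::butter(cfg$filterOrder, cfg$band / (fs / 2), type = "pass")
  np <- as.integer(round(fs))   # 1 s of reflected context on both sides
  meanPower <- matrix(0, nsamp, nch)
  for (i in idx) {
    for (ch in seq_len(nch)) {
      amp <- .bandAmplitudePadded(bf, epochs@data[i, ch, ], np)
      meanPower[, ch] <- meanPower[, ch] + amp^2
    }
  }
  meanPower <- meanPower / length(idx)

  tvec <- win[1L] + (seq_len(nsamp) - 0.5) / fs
  usable <- c(win[1L] + cfg$edgeTrim, win[2L] - cfg$edgeTrim)
  refSel <- tvec >= max(cfg$referenceWindow[1L], usable[1L]) &
    tvec < cfg$referenceWindow[2L]
  if (!any(refSel))
    stop("data error: reference window contains no samples", call. = FALSE)
  R <- colMeans(meanPower[refSel, , drop = FALSE])
  if (any(R <= 0))
    stop("undefined reference: zero reference power", call. = FALSE)

  aw <- if (is.null(cfg$analysisWindow)) usable else
    c(max(cfg$analysisWindow[1L], usable[1L]),
      min(cfg$analysisWindow[2L], usable[2L]))
  edges <- seq(aw[1L], aw[2L] + 1e-9, by = cfg$timeResolution)
  if (length(edges) < 2L)
    stop("analysis window shorter than one time bin", call. = FALSE)
  nb <- length(edges) - 1L
  vals <- matrix(0, nb, nch)
  for (b in seq_len(nb)) {
    sel <- tvec >= edges[b] & tvec < edges[b + 1L]
    A <- colMeans(meanPower[sel, , drop = FALSE])
    vals[b, ] <- relativePower(A, R)
  }
  chLabels <- if (!is.null(dimnames(epochs@data)[[2L]])) dimnames(epochs@data)[[2L]]
              else paste0("ch", seq_len(nch))
  colnames(vals) <- chLabels
  new("RPMap", values = vals, band = cfg$band,
      referenceWindow = cfg$referenceWindow,
      analysisWindow = as.numeric(aw),
      timeBins = (edges[-1L] + edges[-length(edges)]) / 2,
      channels = chLabels, nTrials = length(idx))
}

#' Write an RP map as CSV
#'
#' Long format with columns `time_bin_s`, `channel`, `rp_percent`.
#'
#' @param map an [RPMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRPMap <- function(map, path) {
  stopifnot(is(map, "RPMap"))
  df <- data.frame(time_bin_s = rep(map@timeBins, length(map@channels)),
                   channel = rep(map@channels, each = length(map@timeBins)),
                   rp_percent = as.vector(map@values))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot an RP map
#'
#' Time x channel image with a diverging palette centered at 0% (blue =
#' ERD, red = ERS).
#'
#' @param map an [RPMap-class].
#' @param zlim symmetric color range in percent; defaults to the data range.
#' @return invisibly, NULL.
#' @export
plotRPMap <- function(map, zlim = NULL) {
  stopifnot(is(map, "RPMap"))
  if (is.null(zlim)) {
    m <- max(abs(map@values), 1e-6)
    zlim <- c(-m, m)
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  graphics::image(map@timeBins, seq_along(map@channels),
                  pmin(pmax(map@values, zlim[1]), zlim[2]),
                  col = pal, zlim = zlim,
                  xlab = "time relative to task onset (s)", ylab = "",
                  yaxt = "n", main = sprintf("relative power, %g-%g Hz (%% of reference)",
                                             map@band[1], map@band[2]))
  graphics::axis(2, at = seq_along(map@channels), labels = map@channels,
                 las = 2, cex.axis = 0.8)
  invisible(NULL)
}
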