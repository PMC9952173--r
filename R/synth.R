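#' @include AllClasses.R
NULL

DEFAULT_MONTAGE <- c("FC1", "FC2", "C3", "Cz", "C4", "P1", "P2", "EX8")

#' Session specification for the synthetic EEG generator
#'
#' Describes one recording session: the session kind with its trial
#' structure, the per-class trial counts, the trial timing, the sampling
#' rate and montage, and the seed that makes generation reproducible.
#'
#' An `AO_MI` session contains, per trial, two AO+MI blocks and one MI
#' block, each preceded by a rest period drawn uniformly from `restRange`;
#' classes are LEFT/RIGHT only. An `MI_FB` session contains one task block
#' per trial (preceded by a rest/preparation period and followed by a 2-s
#' feedback interval, modelled as rest); classes are LEFT/RIGHT/REST.
#'
#' @param sessionKind `"AO_MI"` or `"MI_FB"`.
#' @param nTrials total trial count (default 300 for AO_MI, 150 for MI_FB).
#' @param classMix named per-class trial counts; must sum to `nTrials`.
#'   Defaults to 150/150 LEFT/RIGHT (AO_MI) or 50/50/50 (MI_FB).
#' @param restRange rest-period duration range in seconds (uniform draw).
#' @param taskDur task-block duration in seconds (2 for AO+MI / MI blocks,
#'   3 for MI-FB task blocks).
#' @param samplingRate sampling rate in Hz.
#' @param montage ordered channel labels. The default uses the seven named
#'   10-20 positions FC1, FC2, C3, Cz, C4, P1, P2 plus a configurable
#'   eighth channel labelled `"EX8"`.
#' @param seed integer seed controlling all randomness in the session.
#' @return a `SessionSpec` (validated named list).
#' @export
sessionSpec <- function(sessionKind = c("AO_MI", "MI_FB"),
                        nTrials = NULL, classMix = NULL,
                        restRange = c(5, 7), taskDur = NULL,
                        samplingRate = 1000, montage = DEFAULT_MONTAGE,
                        seed = 1L) {
  sessionKind <- match.arg(sessionKind)
  if (is.null(nTrials))
    nTrials <- if (sessionKind == "AO_MI") 300L else 150L
  nTrials <- as.integer(nTrials)
  if (is.null(taskDur)) taskDur <- if (sessionKind == "AO_MI") 2 else 3
  if (is.null(classMix)) {
    classMix <- if (sessionKind == "AO_MI") {
      c(LEFT = nTrials %/% 2L, RIGHT = nTrials - nTrials %/% 2L)
    } else {
      n3 <- nTrials %/% 3L
      c(LEFT = n3, RIGHT = n3, REST = nTrials - 2L * n3)
    }
  }
  wanted <- if (sessionKind == "AO_MI") c("LEFT", "RIGHT") else CLASS_LEVELS
  if (!setequal(names(classMix), wanted))
    stop(sprintf("classMix for a %s session must name exactly: %s",
                 sessionKind, paste(wanted, collapse = ", ")), call. = FALSE)
  classMix <- classMix[wanted]
  if (sum(classMix) != nTrials)
    stop("classMix must sum to nTrials", call. = FALSE)
  if (length(restRange) != 2L || any(restRange <= 0) || restRange[1] > restRange[2])
    stop("restRange must be an increasing pair of positive durations", call. = FALSE)
  .assertScalarNum(taskDur, "taskDur", lower = 1e-3)
  .assertScalarNum(samplingRate, "samplingRate", lower = 1)
  spec <- list(sessionKind = sessionKind, nTrials = nTrials,
               classMix = classMix, restRange = as.numeric(restRange),
               taskDur = taskDur, samplingRate = samplingRate,
               montage = as.character(montage), seed = as.integer(seed))
  class(spec) <- "SessionSpec"
  spec
}

#' Mu-rhythm / ERD model for the synthetic generator
#'
#' The synthetic EEG is the sum of 1/f ("pink") background noise, a white
#' noise floor, and a mu-band sinusoid with a per-trial random phase whose
#' amplitude drops during task blocks (event-related desynchronization).
#' During a task block of class `k`, the instantaneous mu band power on
#' channel `c` is multiplied by `1 - erdDepth * profile[[k]][c]`, so a
#' profile weight of 1 programs the full depth on that channel.
#'
#' The default profile lateralizes the effect (LEFT imagery suppresses the
#' contralateral C4, RIGHT suppresses C3, with a half-weight on Cz). Real
#' recordings need not lateralize; the profile is fully configurable,
#' including symmetric regimes.
#'
#' @param muFreq mu-rhythm frequency in Hz.
#' @param muBand mu/alpha band in Hz (metadata used by analysis defaults).
#' @param baselineMuAmp per-channel mu amplitude in microvolts (named
#'   vector; unnamed scalar recycles over the montage). Defaults to 10 on
#'   C3/Cz/C4, 6 on FC1/FC2/P1/P2, 4 elsewhere.
#' @param erdDepth fractional band-power decrease in `[0, 1]` applied during
#'   matching task blocks.
#' @param profile named list mapping each class to a named vector of
#'   per-channel weights in `[0, 1]` multiplying `erdDepth`.
#' @param noise list with `pinkExponent` (spectral slope of the 1/f
#'   component), `pinkScale` (its standard deviation, microvolts) and
#'   `whiteSd` (white floor standard deviation, microvolts).
#' @param driftRate per-step fractional deepening of `erdDepth` used by
#'   [simulateSessionDrift].
#' @return an `ErdModel` (validated named list).
#' @export
erdModel <- function(muFreq = 10, muBand = c(8, 13), baselineMuAmp = NULL,
                     erdDepth = 0.4,
                     profile = list(LEFT = c(C4 = 1, Cz = 0.5),
                                    RIGHT = c(C3 = 1, Cz = 0.5),
                                    REST = numeric()),
                     noise = list(pinkExponent = 1, pinkScale = 2, whiteSd = 1),
                     driftRate = 0.15) {
  .assertScalarNum(muFreq, "muFreq", lower = 0.1)
  .assertScalarNum(erdDepth, "erdDepth", lower = 0, upper = 1)
  if (length(muBand) != 2L || muBand[1] >= muBand[2])
    stop("muBand must be an increasing Hz interval", call. = FALSE)
  for (k in names(profile)) {
    w <- profile[[k]]
    if (length(w) && (any(w < 0) || any(w > 1)))
      stop("profile weights must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(baselineMuAmp) && any(baselineMuAmp < 0))
    stop("amplitudes must be nonnegative", call. = FALSE)
  m <- list(muFreq = muFreq, muBand = as.numeric(muBand),
            baselineMuAmp = baselineMuAmp, erdDepth = erdDepth,
            profile = profile, noise = noise, driftRate = driftRate)
  class(m) <- "ErdModel"
  m
}

# resolve the per-channel baseline amplitude vector for a montage
.muAmpForMontage <- function(erd, montage) {
  amp <- erd$baselineMuAmp
  if (is.null(amp)) {
    amp <- setNames(rep(4, length(montage)), montage)
    amp[montage %in% c("C3", "Cz", "C4")] <- 10
    amp[montage %in% c("FC1", "FC2", "P1", "P2")] <- 6
  } else if (is.null(names(amp))) {
    amp <- setNames(rep_len(as.numeric(amp), length(montage)), montage)
  } else {
    full <- setNames(rep(0, length(montage)), montage)
    full[intersect(names(amp), montage)] <- amp[intersect(names(amp), montage)]
    amp <- full
  }
  amp
}

#' Deterministic between-session change of the ERD model
#'
#' Returns the ERD model for continual-learning step `step`: the base model
#' at step 0, then a geometrically deepening ERD (capped at 0.9) emulating
#' the sharper sensorimotor modulation of later feedback sessions.
#'
#' @param base an [erdModel].
#' @param step nonnegative integer session index.
#' @return an `ErdModel`.
#' @export
simulateSessionDrift <- function(base, step) {
  if (!inherits(base, "ErdModel")) stop("base must be an ErdModel", call. = FALSE)
  step <- as.integer(step)
  if (step < 0) stop("step must be >= 0", call. = FALSE)
  if (step == 0L) return(base)
  out <- base
  out$erdDepth <- min(0.9, base$erdDepth * (1 + base$driftRate)^step)
  out
}

# build the block table for one session; durations in seconds
.buildTimeline <- function(spec) {
  classes <- sample(rep(names(spec$classMix), spec$classMix))
  rows <- list()
  t0 <- 0
  for (tr in seq_len(spec$nTrials)) {
    cls <- classes[tr]
    if (spec$sessionKind == "AO_MI") {
      kinds <- c("AO_MI", "AO_MI", "MI")
      for (b in 1:3) {
        r <- runif(1, spec$restRange[1], spec$restRange[2])
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr, block_kind = "REST", class_label = NA_character_,
          onset_s = t0, duration_s = r)
        t0 <- t0 + r
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr, block_kind = kinds[b], class_label = cls,
          onset_s = t0, duration_s = spec$taskDur)
        t0 <- t0 + spec$taskDur
      }
    } else {
      r <- runif(1, spec$restRange[1], spec$restRange[2])
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, block_kind = "REST", class_label = NA_character_,
        onset_s = t0, duration_s = r)
      t0 <- t0 + r
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, block_kind = "MI_FB_TASK", class_label = cls,
        onset_s = t0, duration_s = spec$taskDur)
      t0 <- t0 + spec$taskDur
      # 2-s feedback interval; the virtual-character rendering itself is out
      # of scope, the subject is at rest for classification purposes
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, block_kind = "REST", class_label = NA_character_,
        onset_s = t0, duration_s = 2)
      t0 <- t0 + 2
    }
  }
  ev <- do.call(rbind, rows)
  list(events = ev, classes = classes, duration = t0)
}

# 1/f^alpha noise via spectral shaping, unit variance before scaling
.pinkNoise <- function(n, exponent) {
  nfft <- n + n %% 2L  # even length simplifies Hermitian assembly
  nf <- nfft %/% 2L
  f <- seq_len(nf - 1L)
  mag <- f^(-exponent / 2)
  re <- rnorm(nf - 1L)
  im <- rnorm(nf - 1L)
  spec <- complex(real = re * mag, imaginary = im * mag)
  full <- c(0, spec, 0, Conj(rev(spec)))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate a synthetic EEG session
#'
#' Produces a continuous recording following the session's trial structure:
#' 1/f background plus white noise plus a mu-rhythm sinusoid (random phase
#' per trial) whose instantaneous band power is reduced by the programmed
#' ERD depth on designated channels during task blocks of the matching
#' class. The recording is padded with a final rest segment to a whole
#' second so that 1-s EDF data records tile it exactly. Identical
#' `(spec, erd)` inputs give bit-identical output.
#'
#' @param spec a [sessionSpec].
#' @param erd an [erdModel].
#' @return list with elements `recording` ([RawRecording-class]),
#'   `timeline` ([TrialTimeline-class]) and `labels` (per-trial factor).
#' @export
generateSession <- function(spec, erd = erdModel()) {
  if (!inherits(spec, "SessionSpec")) stop("spec must be a SessionSpec", call. = FALSE)
  if (!inherits(erd, "ErdModel")) stop("erd must be an ErdModel", call. = FALSE)
  if (spec$samplingRate <= 2 * max(erd$muFreq, erd$muBand[2]))
    stop("sampling rate must exceed twice the highest synthesized frequency",
         call. = FALSE)
  withSeed(spec$seed, {
    tl <- .buildTimeline(spec)
    fs <- spec$samplingRate
    dur <- ceiling(tl$duration)           # pad the tail to a whole second
    n <- as.integer(round(dur * fs))
    nch <- length(spec$montage)
    amp <- .muAmpForMontage(erd, spec$montage)

    # per-trial random phase, one draw per trial, shared across channels
    phases <- runif(spec$nTrials + 1L, 0, 2 * pi)
    tvec <- (seq_len(n) - 1L) / fs
    trialStart <- vapply(split(tl$events$onset_s, tl$events$trial), min,
                         numeric(1))
    phaseIdx <- findInterval(tvec, trialStart) + 1L  # 1 before first trial
    carrier <- sin(2 * pi * erd$muFreq * tvec + phases[phaseIdx])

    # per-channel power gain: 1 at rest, 1 - depth*weight inside task blocks
    ev <- tl$events
    task <- ev[ev$block_kind != "REST", , drop = FALSE]
    gain <- matrix(1, nch, n, dimnames = list(spec$montage, NULL))
    for (i in seq_len(nrow(task))) {
      w <- erd$profile[[task$class_label[i]]]
      w <- w[names(w) %in% spec$montage]
      if (!length(w)) next
      i0 <- floor(task$onset_s[i] * fs) + 1L
      i1 <- min(n, floor((task$onset_s[i] + task$duration_s[i]) * fs))
      gain[names(w), i0:i1] <- sqrt(pmax(0, 1 - erd$erdDepth * w))
    }

    sig <- matrix(0, nch, n, dimnames = list(spec$montage, NULL))
    for (c in seq_len(nch)) {
      pink <- .pinkNoise(n, erd$noise$pinkExponent) * erd$noise$pinkScale
      white <- rnorm(n, sd = erd$noise$whiteSd)
      sig[c, ] <- amp[c] * gain[c, ] * carrier + pink + white
    }

    rec <- RawRecording(sig, fs, spec$montage,
                        meta = list(sessionKind = spec$sessionKind,
                                    seed = spec$seed,
                                    erdDepth = erd$erdDepth,
                                    generator = "tstn::generateSession"))
    timeline <- TrialTimeline(tl$events, spec$sessionKind)
    list(recording = rec, timeline = timeline,
         labels = factor(tl$classes, levels = CLASS_LEVELS))
  })
}
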