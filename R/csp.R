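#' @include AllClasses.R
NULL

#' Class covariance estimate
#'
#' Spatial covariance of the epochs in `classes`: the mean over trials of
#' the per-trial outer product `X %*% t(X)`, each trial's matrix divided by
#' its trace beforehand (the standard CSP normalization, which makes the
#' filter bank invariant to global amplitude scaling). Symmetric positive
#' semi-definite by construction.
#'
#' @param epochs an [EpochSet-class].
#' @param classes class labels to pool (one for the target class, two for
#'   the rest-of-classes pool).
#' @param normalization `"trace"` (default) or `"none"`.
#' @return a channels x channels covariance matrix with attributes
#'   `nTrialsUsed` and `normalization`.
#' @export
classCovariance <- function(epochs, classes, normalization = c("trace", "none")) {
  stopifnot(is(epochs, "EpochSet"))
  normalization <- match.arg(normalization)
  idx <- which(epochs@labels %in% classes)
  if (!length(idx))
    stop("data error: no trials for class(es) ", paste(classes, collapse = "/"),
         call. = FALSE)
  nch <- dim(epochs@data)[2L]
  acc <- matrix(0, nch, nch)
  for (i in idx) {
    X <- epochs@data[i, , ]
    R <- tcrossprod(X)
    if (normalization == "trace") R <- R / sum(diag(R))
    acc <- acc + R
  }
  R <- acc / length(idx)
  R <- (R + t(R)) / 2
  structure(R, nTrialsUsed = length(idx), normalization = normalization)
}

#' Solve one CSP simultaneous-diagonalization problem
#'
#' Finds `P` with `t(P) %*% R1 %*% P` diagonal (eigenvalues descending) and
#' `t(P) %*% R2 %*% P = I`, by whitening `R2` and eigendecomposing the
#' whitened `R1`. The sign of each column is fixed so its largest-magnitude
#' entry is positive; eigenvalue ties keep the whitened eigendecomposition's
#' column order.
#'
#' @param R1 target-class covariance (channels x channels, symmetric).
#' @param R2 rest-of-classes covariance; must be strictly positive definite
#'   (smallest eigenvalue above `1e-10` times its trace).
#' @param classPair character length 2 naming the discrimination (metadata).
#' @param epsilon optional ridge added as `epsilon * I` to `R2` before
#'   solving, for near-singular pools; suggested magnitude
#'   `1e-9 * sum(diag(R2))`.
#' @return a [CspSolution-class].
#' @export
solveCSP <- function(R1, R2, classPair = c("target", "rest"), epsilon = NULL) {
  R1 <- (R1 + t(R1)) / 2
  R2 <- (R2 + t(R2)) / 2
  if (!is.null(epsilon)) R2 <- R2 + epsilon * diag(nrow(R2))
  e2 <- eigen(R2, symmetric = TRUE)
  if (min(e2$values) <= 1e-10 * sum(diag(R2)))
    stop("numerical error: R2 is singular or near-singular; regularize by ",
         "passing epsilon (e.g. 1e-9 * sum(diag(R2)))", call. = FALSE)
  W <- diag(1 / sqrt(e2$values)) %*% t(e2$vectors)   # whitener: W R2 W' = I
  M <- W %*% R1 %*% t(W)
  M <- (M + t(M)) / 2
  e1 <- eigen(M, symmetric = TRUE)                   # descending by default
  P <- t(W) %*% e1$vectors
  for (j in seq_len(ncol(P))) {
    if (P[which.max(abs(P[, j])), j] < 0) P[, j] <- -P[, j]
  }
  new("CspSolution", P = P, D = e1$values, classPair = as.character(classPair))
}

#' Build the one-versus-rest CSP filter bank
#'
#' Solves one CSP problem per class (target covariance versus the pooled
#' covariance of the two other classes) and stacks the transposed top-2
#' eigenvector columns of each solution into the 6 x channels spatial
#' filter `Z`, in fixed class order LEFT, RIGHT, REST.
#'
#' @param epochs an [EpochSet-class] containing all three classes.
#' @param epsilon optional ridge forwarded to [solveCSP].
#' @return a [SpatialFilterBank-class].
#' @export
buildOVRBank <- function(epochs, epsilon = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  present <- levels(droplevels(epochs@labels))
  missing <- setdiff(CLASS_LEVELS, present)
  if (length(missing))
    stop("data error: class ", paste(missing, collapse = ", "),
         " missing from the epochs", call. = FALSE)
  sols <- vector("list", length(CLASS_LEVELS))
  names(sols) <- CLASS_LEVELS
  Z <- NULL
  for (k in CLASS_LEVELS) {
    others <- setdiff(CLASS_LEVELS, k)
    R1 <- classCovariance(epochs, k)
    R2 <- classCovariance(epochs, others)
    sol <- solveCSP(R1, R2, classPair = c(k, paste(others, collapse = "+")),
                    epsilon = epsilon)
    sols[[k]] <- sol
    Zk <- t(sol@P[, 1:2, drop = FALSE])
    rownames(Zk) <- paste(k, 1:2, sep = ".")
    Z <- rbind(Z, Zk)
  }
  labs <- if (!is.null(dimnames(epochs@data)[[2]])) dimnames(epochs@data)[[2]]
          else character()
  new("SpatialFilterBank", Z = Z, solutions = sols, classes = CLASS_LEVELS,
      channelLabels = labs)
}

#' Apply the spatial filter bank
#'
#' Linear filtering `S = Z %*% X`, producing the 6 feature-channel signals
#' of an epoch (or of every epoch of a set).
#'
#' @param bank a [SpatialFilterBank-class].
#' @param x either a channels x samples matrix (one epoch) or an
#'   [EpochSet-class].
#' @return a 6 x samples matrix for a single epoch; for an EpochSet, a
#'   3-D array with dimensions (6, samples, trials).
#' @export
applyBank <- function(bank, x) {
  stopifnot(is(bank, "SpatialFilterBank"))
  Z <- bank@Z
  if (is(x, "EpochSet")) {
    d <- dim(x@data)
    if (d[2L] != ncol(Z))
      stop("data error: epoch channel count does not match the bank", call. = FALSE)
    out <- array(0, c(nrow(Z), d[3L], d[1L]))
    for (i in seq_len(d[1L])) out[, , i] <- Z %*% x@data[i, , ]
    return(out)
  }
  if (!is.matrix(x) || nrow(x) != ncol(Z))
    stop("data error: epoch channel count does not match the bank", call. = FALSE)
  Z %*% x
}
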