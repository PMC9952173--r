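#' @include csp.R
NULL

.softmaxRows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Spatial self-attention over feature channels
#'
#' Scaled dot-product self-attention with the six CSP feature-channel time
#' vectors (rows of `S`) as input vectors: `q_i = Wq a_i`, `k_i = Wk a_i`,
#' `v_i = Wv a_i`, attention weights `softmax_j(q_i . k_j / sqrt(d))`, and
#' output row `b_i = sum_j alpha_ij v_j`. The attention-weight matrix is
#' attached as attribute `"weights"` (each row sums to 1).
#'
#' @param S feature epoch, rows = feature channels, columns = time (d).
#' @param Wq,Wk,Wv d x d projection matrices.
#' @return the enhanced feature matrix `B`, same shape as `S`.
#' @export
spatialAttention <- function(S, Wq, Wk, Wv) {
  d <- ncol(S)
  if (!all(dim(Wq) == d) || !all(dim(Wk) == d) || !all(dim(Wv) == d))
    stop("shape error: projections must be d x d with d = ncol(S)", call. = FALSE)
  Q <- S %*% t(Wq)
  K <- S %*% t(Wk)
  V <- S %*% t(Wv)
  A <- .softmaxRows(Q %*% t(K) / sqrt(d))
  structure(A %*% V, weights = A)
}

#' Convolutional patch embedding
#'
#' Two-stage embedding of an enhanced feature epoch: a 1-D convolution
#' (kernel `k1`, `f1` filters, stride 1, no padding) applied along time to
#' each feature channel independently, then a 2-D convolution whose kernel
#' spans all feature channels and `k2` time samples with time stride `k2`
#' (no padding), producing `f2` patches. With the default geometry
#' (6 x 500 input, k1 = 51, f1 = 2, f2 = 10, k2 = 5) the output is exactly
#' 10 patches x 90 samples.
#'
#' @param B feature-channels x time matrix.
#' @param c1W k1 x f1 matrix of 1-D kernels.
#' @param c1b length-f1 bias.
#' @param c2W f2 x (f1 * channels * k2) weight matrix; column order has
#'   depth fastest, then channel, then time tap.
#' @param c2b length-f2 bias.
#' @return f2 x L2 matrix of embedded patches.
#' @export
embedPatches <- function(B, c1W, c1b, c2W, c2b) {
  C <- nrow(B); d <- ncol(B)
  k1 <- nrow(c1W); f1 <- ncol(c1W); f2 <- nrow(c2W)
  k2 <- ncol(c2W) / (f1 * C)
  if (k2 != round(k2))
    stop("shape error: conv2 width inconsistent with input channels", call. = FALSE)
  k2 <- as.integer(k2)
  L1 <- d - k1 + 1L
  if (L1 <= 0 || L1 %% k2 != 0L)
    stop("shape error: conv1 output not divisible by the conv2 stride", call. = FALSE)
  L2 <- L1 %/% k2
  # conv1: depth f1, per-channel, valid
  C1 <- array(0, c(f1, C, L1))
  for (f in seq_len(f1)) {
    acc <- matrix(0, C, L1)
    for (u in seq_len(k1)) acc <- acc + c1W[u, f] * B[, u:(u + L1 - 1L), drop = FALSE]
    C1[f, , ] <- acc + c1b[f]
  }
  # conv2: gather the (depth, channel, tap) window of each output position
  X <- matrix(0, f1 * C * k2, L2)
  for (u in seq_len(k2)) {
    for (ch in seq_len(C)) {
      for (dd in seq_len(f1)) {
        row <- dd + f1 * (ch - 1L) + f1 * C * (u - 1L)
        X[row, ] <- C1[dd, ch, seq(u, by = k2, length.out = L2)]
      }
    }
  }
  c2W %*% X + c2b
}

#' Temporal multi-head attention over embedded patches
#'
#' The `f2` patches are partitioned in order into `h = f2 / 2` consecutive
#' pairs `E_i` (2 x L2). Head `i` applies scaled dot-product attention with
#' key dimension L2 to `(Wtq_i E_i, Wtk_i E_i, Wtv_i E_i)`; head outputs
#' are concatenated row-wise and mixed by the final weight matrix:
#' `F = Wo %*% Concat(head_1, ..., head_h)`.
#'
#' @param P f2 x L2 patch matrix.
#' @param Wtq,Wtk,Wtv 2 x 2 x h arrays of per-head projections.
#' @param Wo f2 x f2 output mixing matrix.
#' @return the f2 x L2 temporal-attention output `F`.
#' @export
temporalMHA <- function(P, Wtq, Wtk, Wtv, Wo) {
  f2 <- nrow(P); L2 <- ncol(P)
  h <- dim(Wtq)[3L]
  if (f2 != 2L * h)
    stop("shape error: patch count must equal 2 x head count", call. = FALSE)
  Cc <- matrix(0, f2, L2)
  for (i in seq_len(h)) {
    rows <- (2L * i - 1L):(2L * i)
    E <- P[rows, , drop = FALSE]
    Qi <- Wtq[, , i] %*% E
    Ki <- Wtk[, , i] %*% E
    Vi <- Wtv[, , i] %*% E
    A <- .softmaxRows(Qi %*% t(Ki) / sqrt(L2))
    Cc[rows, ] <- A %*% Vi
  }
  Wo %*% Cc
}

#' Pooled, normalized fully-connected classifier head
#'
#' Pools each patch row of `F` to its log mean power (the band-power
#' statistic CSP features are built to carry), normalizes the pooled
#' vector (zero mean, unit variance across features, then a learned
#' per-feature scale and shift), and maps it through a fully-connected
#' layer to 3 class logits; softmax gives the class probabilities.
#'
#' @param F f2 x L2 matrix from the temporal attention stage.
#' @param gamma,beta learned per-feature scale and shift (length f2).
#' @param fcW 3 x f2 weight matrix.
#' @param fcb length-3 bias.
#' @return named length-3 probability vector (sums to 1).
#' @export
classifyHead <- function(F, gamma, beta, fcW, fcb) {
  p <- log(rowMeans(F^2) + .POOL_EPS)
  mu <- mean(p)
  sig <- sqrt(mean((p - mu)^2) + .LN_EPS)
  z <- (p - mu) / sig
  y <- gamma * z + beta
  logits <- drop(fcW %*% y + fcb)
  e <- exp(logits - max(logits))
  setNames(e / sum(e), CLASS_LEVELS)
}

# fresh parameter list for the given dims; attention projections start near
# identity so the untrained network is close to a pass-through
.initParams <- function(dims, seed, attnNoise = 0.01) {
  withSeed(seed, {
    d <- dims$d; k1 <- dims$conv1Kernel; f1 <- dims$conv1Filters
    f2 <- dims$conv2Filters; k2 <- dims$conv2Kernel; h <- dims$heads
    C <- dims$featChannels
    nearIdent <- function(n) diag(n) + matrix(runif(n * n, -attnNoise, attnNoise), n)
    glorot <- function(nr, nc) {
      a <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -a, a), nr, nc)
    }
    headsNear <- function() {
      w <- array(0, c(2, 2, h))
      for (i in seq_len(h)) w[, , i] <- nearIdent(2)
      w
    }
    list(Wq = nearIdent(d), Wk = nearIdent(d), Wv = nearIdent(d),
         c1W = glorot(k1, f1), c1b = numeric(f1),
         c2W = glorot(f2, f1 * C * k2), c2b = numeric(f2),
         Wtq = headsNear(), Wtk = headsNear(), Wtv = headsNear(),
         Wo = nearIdent(f2),
         gamma = rep(1, f2), beta = numeric(f2),
         fcW = glorot(3L, f2), fcb = numeric(3L))
  })
}

# deep-copy a parameter list (guards against in-place Adam updates)
.copyParams <- function(p) lapply(p, function(x) x + 0)

#' Initialize a TSTN model
#'
#' Builds the full parameter set for the spatial-attention /
#' patch-embedding / temporal-attention / classifier stack on top of a
#' fitted CSP bank. Defaults reproduce the reference geometry for 2-s
#' epochs at 250 Hz: d = 500, conv1 kernel 51 with 2 filters, conv2 with
#' 10 filters and a 6 x 5 kernel at time stride 5 (10 patches x 90
#' samples), 5 temporal heads. Weight matrices are drawn from a scaled
#' uniform distribution under `seed`; attention projections start at
#' identity plus small noise.
#'
#' @param bank a [SpatialFilterBank-class].
#' @param d time samples per epoch.
#' @param conv1Kernel,conv1Filters 1-D convolution geometry.
#' @param conv2Filters,conv2Kernel 2-D convolution geometry (kernel height
#'   always spans all feature channels; time stride equals `conv2Kernel`).
#' @param heads temporal attention head count (`conv2Filters / 2`).
#' @param dropout length-2 vector: spatial and temporal dropout rates.
#' @param seed initialization seed.
#' @return a [TSTNModel-class].
#' @export
initTSTN <- function(bank, d = 500L, conv1Kernel = 51L, conv1Filters = 2L,
                     conv2Filters = 10L, conv2Kernel = 5L,
                     heads = conv2Filters %/% 2L,
                     dropout = c(0.3, 0.5), seed = 1L) {
  stopifnot(is(bank, "SpatialFilterBank"))
  dims <- list(d = as.integer(d), conv1Kernel = as.integer(conv1Kernel),
               conv1Filters = as.integer(conv1Filters),
               conv2Filters = as.integer(conv2Filters),
               conv2Kernel = as.integer(conv2Kernel),
               conv2Stride = as.integer(conv2Kernel),
               heads = as.integer(heads),
               featChannels = nrow(bank@Z))
  L1 <- dims$d - dims$conv1Kernel + 1L
  if (L1 <= 0L || L1 %% dims$conv2Stride != 0L)
    stop("conv1 output length must be positive and divisible by the conv2 stride",
         call. = FALSE)
  params <- .initParams(dims, seed)
  new("TSTNModel", bank = bank, params = params, dims = dims,
      dropout = as.numeric(dropout),
      meta = list(stage = "init", seed = as.integer(seed)))
}

# features cube (featChannels x d x N) from various inputs, RMS-normalized
# per epoch so attention scores stay in softmax's dynamic range
.featsCube <- function(model, x) {
  C <- model@dims$featChannels
  d <- model@dims$d
  if (is(x, "EpochSet")) {
    feats <- applyBank(model@bank, x)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    feats <- x
  } else if (is.matrix(x)) {
    if (nrow(x) == ncol(model@bank@Z)) x <- applyBank(model@bank, x)
    feats <- array(x, c(nrow(x), ncol(x), 1L))
  } else {
    stop("shape error: expected an EpochSet, feature array or epoch matrix",
         call. = FALSE)
  }
  if (dim(feats)[1L] != C || dim(feats)[2L] != d)
    stop(sprintf("shape error: features must be %d x %d per epoch", C, d),
         call. = FALSE)
  for (i in seq_len(dim(feats)[3L])) {
    r <- sqrt(mean(feats[, , i]^2))
    if (r > 0) feats[, , i] <- feats[, , i] / r
  }
  feats
}

#' TSTN forward pass
#'
#' Full evaluation-mode forward: CSP filtering (when given raw epochs),
#' per-epoch RMS normalization, spatial self-attention, convolutional
#' patch embedding, temporal multi-head attention, and the pooled
#' classifier head. Deterministic: dropout is disabled.
#'
#' @param model a [TSTNModel-class].
#' @param x an [EpochSet-class], a (featChannels x d x N) feature array, or
#'   a single epoch matrix (raw channels or feature channels).
#' @return N x 3 matrix of class probabilities (columns LEFT, RIGHT, REST).
#' @export
tstnForward <- function(model, x) {
  stopifnot(is(model, "TSTNModel"))
  feats <- .featsCube(model, x)
  probs <- tstn_forward_cpp(model@params, feats, model@dims)
  colnames(probs) <- CLASS_LEVELS
  probs
}

#' Predicted classes from probabilities
#'
#' Argmax with ties broken toward the lowest class index
#' (LEFT before RIGHT before REST).
#'
#' @param probs N x 3 probability matrix.
#' @return factor of predicted labels.
#' @export
predictClasses <- function(probs) {
  if (nrow(probs) == 0L) return(factor(character(), levels = CLASS_LEVELS))
  idx <- apply(probs, 1L, which.max)
  factor(CLASS_LEVELS[idx], levels = CLASS_LEVELS)
}
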