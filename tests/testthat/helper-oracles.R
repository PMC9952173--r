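# Independent oracles: deliberately naive loop-based reimplementations and
# closed forms, kept free of the package's production code paths.

# softmax of a numeric vector
oracleSoftmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# scaled dot-product self-attention by explicit loops
oracleSpatialAttention <- function(S, Wq, Wk, Wv) {
  n <- nrow(S); d <- ncol(S)
  Q <- matrix(0, n, d); K <- matrix(0, n, d); V <- matrix(0, n, d)
  for (i in seq_len(n)) {
    for (t in seq_len(d)) {
      Q[i, t] <- sum(Wq[t, ] * S[i, ])
      K[i, t] <- sum(Wk[t, ] * S[i, ])
      V[i, t] <- sum(Wv[t, ] * S[i, ])
    }
  }
  B <- matrix(0, n, d)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sc <- numeric(n)
    for (j in seq_len(n)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    A[i, ] <- oracleSoftmax(sc)
    for (j in seq_len(n)) B[i, ] <- B[i, ] + A[i, j] * V[j, ]
  }
  attr(B, "weights") <- A
  B
}

# two-stage convolutional patch embedding by explicit loops
oracleEmbedPatches <- function(B, c1W, c1b, c2W, c2b) {
  C <- nrow(B); d <- ncol(B)
  k1 <- nrow(c1W); f1 <- ncol(c1W); f2 <- nrow(c2W)
  k2 <- ncol(c2W) / (f1 * C)
  L1 <- d - k1 + 1; L2 <- L1 / k2
  C1 <- array(0, c(f1, C, L1))
  for (f in 1:f1) for (ch in 1:C) for (t in 1:L1) {
    s <- 0
    for (u in 1:k1) s <- s + c1W[u, f] * B[ch, t + u - 1]
    C1[f, ch, t] <- s + c1b[f]
  }
  P <- matrix(0, f2, L2)
  for (f in 1:f2) for (t in 1:L2) {
    s <- 0
    for (u in 1:k2) for (ch in 1:C) for (dd in 1:f1) {
      col <- dd + f1 * (ch - 1) + f1 * C * (u - 1)
      s <- s + c2W[f, col] * C1[dd, ch, (t - 1) * k2 + u]
    }
    P[f, t] <- s + c2b[f]
  }
  P
}

# temporal multi-head attention by explicit loops
oracleTemporalMHA <- function(P, Wtq, Wtk, Wtv, Wo) {
  f2 <- nrow(P); L2 <- ncol(P); h <- dim(Wtq)[3]
  Cc <- matrix(0, f2, L2)
  for (i in 1:h) {
    E <- P[(2 * i - 1):(2 * i), , drop = FALSE]
    Qi <- Wtq[, , i] %*% E
    Ki <- Wtk[, , i] %*% E
    Vi <- Wtv[, , i] %*% E
    for (r in 1:2) {
      sc <- c(sum(Qi[r, ] * Ki[1, ]), sum(Qi[r, ] * Ki[2, ])) / sqrt(L2)
      a <- oracleSoftmax(sc)
      Cc[2 * (i - 1) + r, ] <- a[1] * Vi[1, ] + a[2] * Vi[2, ]
    }
  }
  Fo <- matrix(0, f2, L2)
  for (r in 1:f2) for (t in 1:L2) Fo[r, t] <- sum(Wo[r, ] * Cc[, t])
  Fo
}

# pooled, normalized classifier head by explicit arithmetic
oracleHead <- function(Fo, gamma, beta, fcW, fcb, poolEps = 1e-8, lnEps = 1e-5) {
  f2 <- nrow(Fo)
  p <- numeric(f2)
  for (k in 1:f2) p[k] <- log(mean(Fo[k, ]^2) + poolEps)
  mu <- mean(p)
  sig <- sqrt(mean((p - mu)^2) + lnEps)
  y <- gamma * (p - mu) / sig + beta
  logits <- as.numeric(fcW %*% y + fcb)
  oracleSoftmax(logits)
}

# full forward: RMS normalization + all stages, by the loop oracles
oracleForward <- function(params, S) {
  S <- S / sqrt(mean(S^2))
  B <- oracleSpatialAttention(S, params$Wq, params$Wk, params$Wv)
  P <- oracleEmbedPatches(B, params$c1W, params$c1b, params$c2W, params$c2b)
  Fo <- oracleTemporalMHA(P, params$Wtq, params$Wtk, params$Wtv, params$Wo)
  oracleHead(Fo, params$gamma, params$beta, params$fcW, params$fcb)
}

# one-sided periodogram band power (microvolts^2 within [lo, hi] Hz)
oracleBandPower <- function(x, fs, band) {
  n <- length(x)
  X <- fft(x)
  psd2 <- Mod(X)^2 / n^2           # two-sided power per bin
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2] & f <= fs / 2
  2 * sum(psd2[sel])
}

# generalized eigendecomposition oracle for CSP: eigen of solve(R2) %*% R1,
# columns rescaled to v' R2 v = 1, sign fixed, descending eigenvalues
oracleGeneralizedEigen <- function(R1, R2) {
  e <- eigen(solve(R2) %*% R1)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  V <- Re(e$vectors)[, ord, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    nrm <- sqrt(drop(t(V[, j]) %*% R2 %*% V[, j]))
    V[, j] <- V[, j] / nrm
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  list(values = vals, vectors = V)
}

# expected epoch counts implied by a timeline and the skip rule
oracleEpochCounts <- function(timeline, epochLen, preOnset = 0) {
  ev <- timelineEvents(timeline)
  long <- ev$duration_s >= epochLen - 1e-9
  list(ao = sum(ev$block_kind == "AO_MI" & long),
       mi = sum(ev$block_kind == "MI" & long),
       task = sum(ev$block_kind == "MI_FB_TASK" & long))
}
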