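test_that("spatial attention: equal inputs give uniform weights", {
  d <- 12
  row <- rnorm(d)
  S <- matrix(rep(row, each = 6), 6, d)
  B <- spatialAttention(S, diag(d), diag(d), diag(d))
  A <- attr(B, "weights")
  expect_equal(A, matrix(1 / 6, 6, 6), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(B), S, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("spatial attention weights always sum to one", {
  withr::local_seed(4)
  for (i in 1:5) {
    d <- sample(6:30, 1)
    S <- matrix(rnorm(6 * d, sd = runif(1, 0.5, 20)), 6, d)
    A <- attr(spatialAttention(S, diag(d) + matrix(rnorm(d * d, 0, .1), d),
                               diag(d), diag(d)), "weights")
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-12)
  }
})

test_that("spatial attention matches the loop oracle on toy inputs", {
  withr::local_seed(5)
  d <- 8
  S <- matrix(rnorm(6 * d), 6, d)
  Wq <- matrix(rnorm(d * d), d); Wk <- matrix(rnorm(d * d), d)
  Wv <- matrix(rnorm(d * d), d)
  got <- spatialAttention(S, Wq, Wk, Wv)
  want <- oracleSpatialAttention(S, Wq, Wk, Wv)
  expect_equal(unclass(got), unclass(want), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(got, "weights"), attr(want, "weights"), tolerance = 1e-10)
  expect_error(spatialAttention(S, diag(7), diag(7), diag(7)), "shape")
})

test_that("patch embedding produces 10 patches of 90 samples from 6 x 500", {
  m <- randomModel(d = 500, k1 = 51, seed = 8)
  p <- m@params
  B <- matrix(rnorm(6 * 500), 6)
  P <- embedPatches(B, p$c1W, p$c1b, p$c2W, p$c2b)
  expect_equal(dim(P), c(10, 90))
  expect_equal(embedPatches(matrix(0, 6, 500), p$c1W, 0 * p$c1b, p$c2W,
                            0 * p$c2b), matrix(0, 10, 90))
  expect_error(embedPatches(matrix(0, 6, 499), p$c1W, p$c1b, p$c2W, p$c2b),
               "shape")
})

test_that("an isolated kernel tap lands where the stride arithmetic says", {
  d <- 40; k1 <- 11; k2 <- 5; C <- 6
  c1W <- matrix(0, k1, 2); c1b <- numeric(2)
  c2W <- matrix(0, 10, 2 * C * k2); c2b <- numeric(10)
  u0 <- 4; f0 <- 2; w <- 1.7         # conv1: single tap
  ch0 <- 3; u2 <- 3; fOut <- 6; v <- -0.9
  c1W[u0, f0] <- w
  c2W[fOut, f0 + 2 * (ch0 - 1) + 2 * C * (u2 - 1)] <- v
  t0 <- 16                            # impulse position in the input
  B <- matrix(0, C, d); B[ch0, t0] <- 1
  P <- embedPatches(B, c1W, c1b, c2W, c2b)
  # conv1 puts w at time t1 = t0 - u0 + 1; conv2 output t sees t1 when
  # (t - 1) * k2 + u2 == t1
  t1 <- t0 - u0 + 1
  tOut <- (t1 - u2) / k2 + 1
  expect_equal(tOut, round(tOut))     # chosen to land on the stride grid
  want <- matrix(0, 10, (d - k1 + 1) / k2)
  want[fOut, tOut] <- w * v
  expect_equal(P, want)
  expect_equal(P, oracleEmbedPatches(B, c1W, c1b, c2W, c2b))
})

test_that("patch embedding matches the loop oracle on random draws", {
  withr::local_seed(6)
  for (i in 1:3) {
    m <- randomModel(d = 40, k1 = 11, seed = 10 + i)
    p <- m@params
    B <- matrix(rnorm(6 * 40), 6)
    expect_equal(embedPatches(B, p$c1W, p$c1b, p$c2W, p$c2b),
                 oracleEmbedPatches(B, p$c1W, p$c1b, p$c2W, p$c2b),
                 tolerance = 1e-10)
  }
})

test_that("temporal attention: identity weights pass identical rows through", {
  L2 <- 12
  P <- matrix(0, 10, L2)
  for (i in 1:5) {
    row <- rnorm(L2)
    P[2 * i - 1, ] <- row
    P[2 * i, ] <- row                 # both rows of E_i identical
  }
  eye2 <- array(diag(2), c(2, 2, 5))
  Fo <- temporalMHA(P, eye2, eye2, eye2, diag(10))
  expect_equal(Fo, P, tolerance = 1e-12)
})

test_that("temporal attention matches the loop oracle", {
  withr::local_seed(7)
  P <- matrix(rnorm(10 * 15), 10)
  Wtq <- array(rnorm(20), c(2, 2, 5)); Wtk <- array(rnorm(20), c(2, 2, 5))
  Wtv <- array(rnorm(20), c(2, 2, 5)); Wo <- matrix(rnorm(100), 10)
  expect_equal(temporalMHA(P, Wtq, Wtk, Wtv, Wo),
               oracleTemporalMHA(P, Wtq, Wtk, Wtv, Wo), tolerance = 1e-10)
  expect_equal(dim(temporalMHA(P, Wtq, Wtk, Wtv, Wo)), c(10, 15))
  expect_error(temporalMHA(P[1:8, ], Wtq, Wtk, Wtv, Wo), "shape")
})

test_that("the classifier head emits a proper probability vector", {
  withr::local_seed(8)
  Fo <- matrix(rnorm(10 * 90), 10)
  gamma <- runif(10, 0.5, 2); beta <- rnorm(10)
  pr <- classifyHead(Fo, gamma, beta, matrix(rnorm(30), 3), rnorm(3))
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # zero weights and biases: equal logits, uniform prediction
  expect_equal(unname(classifyHead(Fo, gamma, beta, matrix(0, 3, 10),
                                   numeric(3))), rep(1 / 3, 3))
})

test_that("evaluation-mode forward is deterministic and batch-consistent", {
  model <- randomModel(d = 40, k1 = 11, seed = 21)
  feats <- randomFeats(model@dims, n = 7, seed = 22)
  p1 <- tstnForward(model, feats)
  p2 <- tstnForward(model, feats)
  expect_identical(p1, p2)
  for (i in 1:7) {
    single <- tstnForward(model, feats[, , i])
    expect_equal(p1[i, ], single[1, ], tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(p1)), rep(1, 7), tolerance = 1e-12)
})

test_that("the production forward equals the loop-oracle pipeline", {
  model <- randomModel(d = 40, k1 = 11, seed = 23)
  withr::local_seed(24)
  x <- array(rnorm(6 * 40 * 4), c(6, 40, 4))   # un-normalized features
  got <- tstnForward(model, x)
  for (i in 1:4)
    expect_equal(unname(got[i, ]), unname(oracleForward(model@params, x[, , i])),
                 tolerance = 1e-10)
})

test_that("seeds change initial values but never shapes or counts", {
  a <- randomModel(d = 40, k1 = 11, seed = 31)
  b <- randomModel(d = 40, k1 = 11, seed = 32)
  expect_identical(lapply(a@params, dim), lapply(b@params, dim))
  expect_identical(sum(vapply(a@params, length, 1L)),
                   sum(vapply(b@params, length, 1L)))
  expect_false(identical(a@params$Wq, b@params$Wq))
  # the reference geometry's parameter count is fixed
  full <- initTSTN(fakeBank(), seed = 1)
  expect_identical(sum(vapply(full@params, length, 1L)), 750927L)
})
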