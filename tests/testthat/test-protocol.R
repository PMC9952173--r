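# cheap training configuration for protocol tests (full defaults are
# exercised in the acceptance suite at scale)
cheapCfg <- function(seed = 5) trainConfig(maxEpochs = 16L, patience = 6L,
                                           seed = seed)

fittedSmall <- function() fixture("fittedSmall", function() {
  fitTSTN(smallAOMI()$epochs$train, cheapCfg(), crossValidate = FALSE)
})

smallMIFB <- function() fixture("smallMIFB", function() {
  spec <- sessionSpec("MI_FB", nTrials = 12, seed = 41)
  ses <- generateSession(spec, erdModel(erdDepth = 0.4))
  cfg <- preprocConfig()
  prep <- preprocessRecording(ses$recording, cfg)
  c(ses, list(prep = prep, task = assembleEpochs(prep, ses$timeline, cfg)$task,
              cfg = cfg))
})

test_that("fitting is deterministic under a fixed seed", {
  full <- smallAOMI()$epochs$train
  eps <- full[c(which(epochLabels(full) == "LEFT")[1:12],
                which(epochLabels(full) == "RIGHT")[1:12],
                which(epochLabels(full) == "REST")[1:12])]
  cfg <- trainConfig(maxEpochs = 2L, patience = 2L, seed = 9)
  m1 <- fitTSTN(eps, cfg, crossValidate = FALSE)
  m2 <- fitTSTN(eps, cfg, crossValidate = FALSE)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@bank@Z, m2@bank@Z)
})

test_that("training data with a missing class is a data error", {
  eps <- smallAOMI()$epochs$train
  expect_error(fitTSTN(eps[epochLabels(eps) != "REST"], cheapCfg()), "REST")
})

test_that("a trained model separates strong-ERD epochs", {
  model <- fittedSmall()
  ev <- evaluateModel(model, smallAOMI()$epochs$train)
  expect_gte(ev$report@accuracy, 0.95)
  mi <- evaluateModel(model, smallAOMI()$epochs$mi)
  expect_gte(mi$report@accuracy, 0.85)
})

test_that("evaluation of an empty epoch set is flagged, not computed", {
  model <- fittedSmall()
  empty <- smallAOMI()$epochs$train[integer(0)]
  ev <- evaluateModel(model, empty)
  expect_length(ev$predictions, 0)
  expect_null(ev$report)
})

test_that("probability ties resolve to the lowest class index", {
  probs <- rbind(c(0.4, 0.4, 0.2), c(0.2, 0.4, 0.4), c(1, 1, 1) / 3)
  expect_equal(as.character(predictClasses(probs)), c("LEFT", "RIGHT", "LEFT"))
})

test_that("selectCorrect returns matching indices in order", {
  expect_equal(selectCorrect(c("LEFT", "RIGHT"), c("LEFT", "RIGHT")), 1:2)
  expect_warning(out <- selectCorrect(c("LEFT", "LEFT"), c("RIGHT", "REST")),
                 "no correctly classified")
  expect_length(out, 0)
  expect_equal(selectCorrect(c("LEFT", "REST", "REST", "LEFT"),
                             c("LEFT", "RIGHT", "REST", "LEFT")), c(1, 3, 4))
  expect_error(selectCorrect("LEFT", c("LEFT", "LEFT")), "length")
})

test_that("a continual step conserves the pool arithmetic", {
  model <- fittedSmall()
  pool <- smallAOMI()$epochs$train
  state <- continualState(model, pool)
  newEps <- smallAOMI()$epochs$mi
  pre <- evaluateModel(model, newEps)
  nCorrect <- sum(as.character(pre$predictions) == as.character(epochLabels(newEps)))
  st2 <- continualStep(state, newEps, cheapCfg())
  expect_identical(st2@stage, "MI")
  expect_equal(nTrials(st2@pool), nTrials(pool) + nCorrect)
  expect_length(st2@history, 1)
  rec <- st2@history[[1]]
  expect_equal(rec$nSelected, nCorrect)
  # the recorded metrics are the PRE-update evaluation
  expect_equal(rec$metrics@accuracy, pre$report@accuracy)
  # selection soundness: every appended trial was correct at addition time
  added <- seq(nTrials(pool) + 1, nTrials(st2@pool))
  expect_true(all(as.character(epochLabels(st2@pool))[added] %in%
                    as.character(pre$predictions[selectCorrect(pre$predictions,
                                                               epochLabels(newEps))])))
})

test_that("post-step accuracy on the step's selected trials does not drop", {
  model <- fittedSmall()
  state <- continualState(model, smallAOMI()$epochs$train)
  newEps <- smallAOMI()$epochs$mi
  pre <- evaluateModel(model, newEps)
  sel <- selectCorrect(pre$predictions, epochLabels(newEps))
  st2 <- continualStep(state, newEps, cheapCfg())
  post <- evaluateModel(st2@model, newEps[sel])
  expect_gte(post$report@accuracy, 1)   # pre-step accuracy on them is 1
})

test_that("the cascade stage sequence and record count are fixed", {
  model <- fittedSmall()
  state <- continualState(model, smallAOMI()$epochs$train)
  expect_identical(state@stage, "AO_MI")
  st <- continualStep(state, smallAOMI()$epochs$mi, cheapCfg())
  st <- continualStep(st, smallMIFB()$task, cheapCfg())
  expect_identical(st@stage, "MI_FB_1")
  expect_length(st@history, 2)
  expect_identical(vapply(st@history, `[[`, "", "stage"), c("MI", "MI_FB_1"))
})

test_that("online replay equals frozen batch evaluation", {
  model <- fittedSmall()
  ses <- smallMIFB()
  r1 <- replayOnline(model, ses$recording, ses$timeline, ses$cfg)
  r2 <- replayOnline(model, ses$recording, ses$timeline, ses$cfg)
  expect_identical(r1, r2)
  ev <- evaluateModel(model, ses$task)
  expect_identical(r1$decision, as.character(ev$predictions))
  expect_equal(mean(r1$correct), ev$report@accuracy)
  expect_error(replayOnline(model, smallAOMI()$recording,
                            smallAOMI()$timeline, ses$cfg),
               "MI_FB")
})
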