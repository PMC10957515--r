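# Small configurations keep these training tests in the seconds range;
# the full-size learnability run lives in the acceptance suite.

tinySetup <- function(nDrugs = 6, nTargets = 5, seed = 3, ...) {
  ds <- generateSyntheticDtiset(nDrugs = nDrugs, nTargets = nTargets,
                                seed = seed, ...)
  cfg <- modelConfig(
    encoder = encoderConfig(kHops = 2, nLayers = 1, hiddenDim = 4),
    maxDrugLen = 64, maxProtLen = 64, mlpHidden = 8, dropout = 0
  )
  inputs <- prepareModelInputs(ds, cfg)
  list(ds = ds, cfg = cfg, inputs = inputs)
}

test_that("a one-epoch run on a handful of samples completes", {
  tz <- tinySetup()
  s <- tz$ds$samples[1:8, ]
  fit <- trainModel(s, s, tz$inputs, tz$cfg,
                    runConfig(epochs = 1, batchSize = 4, seed = 1))
  expect_true(all(is.finite(fit$log$loss)))
  expect_equal(nrow(fit$log), 1)
})

test_that("training loss trends down on a separable noise-free set", {
  ds <- generateSyntheticDtiset(nDrugs = 8, nTargets = 6, seed = 3)
  cfg <- modelConfig(
    encoder = encoderConfig(kHops = 2, nLayers = 1, hiddenDim = 8),
    maxDrugLen = 64, maxProtLen = 64, mlpHidden = 16, dropout = 0
  )
  inputs <- prepareModelInputs(ds, cfg)
  sp <- splitSamples(ds$samples, splitSpec("random", seed = 2))
  fit <- trainModel(sp$train, sp$val, inputs, cfg,
                    runConfig(epochs = 25, patience = 25, seed = 4))
  l <- fit$log$loss
  expect_gte(nrow(fit$log), 10)
  # trend, not strict monotonicity: last epochs clearly below first
  expect_lt(mean(tail(l, 5)), 0.6 * mean(head(l, 5)))
  expect_lt(tail(l, 1), head(l, 1))
})

test_that("the same seed reproduces training bitwise", {
  tz <- tinySetup()
  s <- tz$ds$samples
  sp <- splitSamples(s, splitSpec("random", seed = 5))
  f1 <- trainModel(sp$train, sp$val, tz$inputs, tz$cfg,
                   runConfig(epochs = 3, seed = 11))
  f2 <- trainModel(sp$train, sp$val, tz$inputs, tz$cfg,
                   runConfig(epochs = 3, seed = 11))
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  f3 <- trainModel(sp$train, sp$val, tz$inputs, tz$cfg,
                   runConfig(epochs = 3, seed = 12))
  expect_false(identical(f3$log$loss, f1$log$loss))
})

test_that("AUROC equals the pairwise-concordance oracle", {
  set.seed(50)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(
      aurocScore(scores, labels),
      concordanceAuroc(scores, labels),
      tolerance = 1e-9
    )
  }
})

test_that("AUPRC behaves on canonical cases", {
  # perfect separation
  expect_equal(auprcScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand case: scores rank pos, neg, pos, neg
  # ranks: P(1)=1/1, N, P(3): prec 2/3 -> AP = 0.5*1 + 0.5*2/3
  expect_equal(
    auprcScore(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)),
    0.5 * 1 + 0.5 * (2 / 3)
  )
  # all-tied scores: precision equals prevalence
  expect_equal(auprcScore(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  # single-class input is undefined
  expect_true(is.na(auprcScore(runif(5), rep(1, 5))))
})

test_that("evaluation reports the full metric suite", {
  tz <- tinySetup()
  s <- tz$ds$samples
  params <- initModelParams(tz$cfg, 2L)
  ev <- evaluateModel(params, tz$cfg, s, tz$inputs)
  expect_true(all(c("auroc", "auprc", "sensitivity", "specificity")
                  %in% names(ev)))
  expect_length(ev$scores, nrow(s))
  expect_true(all(ev$scores > 0 & ev$scores < 1))

  # hand-checkable sensitivity/specificity at threshold 0.5
  fakeInputs <- tz$inputs
  ev2 <- local({
    scores <- c(0.9, 0.6, 0.4, 0.2, 0.8, 0.3)
    labels <- c(1, 1, 1, 0, 0, 0)
    pred <- as.integer(scores >= 0.5)
    list(
      sens = sum(pred & labels) / sum(labels),
      spec = sum(!pred & !labels) / sum(!labels),
      auroc = concordanceAuroc(scores, labels)
    )
  })
  expect_equal(ev2$sens, 2 / 3)
  expect_equal(ev2$spec, 2 / 3)

  # single-class test set: ranking metrics undefined
  ones <- s[s$label == 1, ]
  evOne <- evaluateModel(params, tz$cfg, ones, tz$inputs)
  expect_true(is.na(evOne$auroc))
  expect_true(is.na(evOne$auprc))
})

test_that("perfect and uninformative scores give AUROC 1 and 0.5", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0)), 1)
  expect_equal(aurocScore(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
})

test_that("repeated runs aggregate with sample standard deviation", {
  tz <- tinySetup()
  sp <- splitSamples(tz$ds$samples, splitSpec("random", seed = 7))
  rr <- repeatRuns(sp$train, sp$val, sp$test, tz$inputs, tz$cfg,
                   runConfig(epochs = 2, seed = 5), n = 3)
  expect_equal(nrow(rr$perRun), 3)
  expect_equal(rr$summary$metric,
               c("auroc", "auprc", "sensitivity", "specificity"))
  # aggregation arithmetic against the per-run table
  expect_equal(rr$summary$mean[1], mean(rr$perRun$auroc))
  expect_equal(rr$summary$sd[1], sd(rr$perRun$auroc))
  # n = 1: mean equals the single run, sd = 0
  rr1 <- repeatRuns(sp$train, sp$val, sp$test, tz$inputs, tz$cfg,
                    runConfig(epochs = 2, seed = 5), n = 1)
  expect_equal(rr1$summary$mean[1], rr1$perRun$auroc[1])
  expect_equal(rr1$summary$sd, rep(0, 4))
})

test_that("cold-start generalization beats chance when the rule is
           protein-sided", {
  ds <- generateSyntheticDtiset(nDrugs = 10, nTargets = 10, seed = 23,
                                interactionRule = "motif_only")
  cfg <- modelConfig(
    encoder = encoderConfig(kHops = 2, nLayers = 1, hiddenDim = 6),
    maxDrugLen = 64, maxProtLen = 64, mlpHidden = 16, dropout = 0
  )
  inputs <- prepareModelInputs(ds, cfg)
  sp <- splitSamples(ds$samples, splitSpec("unseen_drug", seed = 3))
  fit <- trainModel(sp$train, sp$val, inputs, cfg,
                    runConfig(epochs = 15, patience = 15, seed = 1))
  ev <- evaluateModel(fit$params, cfg, sp$test, inputs)
  expect_gt(ev$auroc, 0.6)
})
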