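test_that("predicted probabilities match a step-by-step forward oracle", {
  set.seed(16)
  for (cell in c("lstm", "gru", "rnn")) {
    H <- 5L; L <- 3L; d <- 4L; T <- 3L
    W <- pstnet:::cpp_rnn_init(d, H, L, cell, 33)
    x <- array(rnorm(2 * T * d), c(2, T, d))
    got <- as.numeric(pstnet:::cpp_rnn_predict(W, aperm(x, c(1, 3, 2)),
                                               cell, H, L))
    want <- rnnForwardOracle(W, x, cell, H, L)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(17)
  for (cell in c("lstm", "gru", "rnn")) {
    H <- 4L; L <- 2L; d <- 3L; n <- 5L; T <- 4L
    W <- pstnet:::cpp_rnn_init(d, H, L, cell, 44)
    X <- array(rnorm(n * d * T), c(n, d, T))
    y <- as.numeric(runif(n) > 0.5)
    lg <- pstnet:::cpp_rnn_lossgrad(W, X, y, cell, H, L, 1.0)
    eps <- 1e-6
    for (k in seq_along(W)) {
      for (idx in sample(length(W[[k]]), min(3, length(W[[k]])))) {
        Wp <- W; Wp[[k]][idx] <- Wp[[k]][idx] + eps
        Wm <- W; Wm[[k]][idx] <- Wm[[k]][idx] - eps
        num <- (pstnet:::cpp_rnn_lossgrad(Wp, X, y, cell, H, L, 1)$loss -
                pstnet:::cpp_rnn_lossgrad(Wm, X, y, cell, H, L, 1)$loss) /
          (2 * eps)
        expect_lt(abs(num - lg$grad[[k]][idx]), 1e-6)
      }
    }
  }
})

test_that("a zero-weight network outputs probability one half", {
  for (cell in c("lstm", "gru", "rnn")) {
    W <- pstnet:::cpp_rnn_init(3L, 4L, 2L, cell, 1)
    W <- lapply(W, function(m) m * 0)
    x <- array(rnorm(6 * 2 * 3), c(6, 3, 2))
    p <- as.numeric(pstnet:::cpp_rnn_predict(W, x, cell, 4L, 2L))
    expect_equal(p, rep(0.5, 6))
  }
})

test_that("a separable task trains to near-perfect validation AUC", {
  dat <- makeSeparableTask(n = 300, seed = 18)
  tr <- list(x = dat$x[1:200, , , drop = FALSE], y = dat$y[1:200])
  va <- list(x = dat$x[201:300, , , drop = FALSE], y = dat$y[201:300])
  cfg <- trainConfig(hiddenSize = 16, nLayers = 2, maxEpochs = 30,
                     patience = 0, seed = 19)
  st <- trainTask(tr, va, cfg)
  expect_gte(bestValAuc(st), 0.99)
  expect_gte(bestEpoch(st), 1)
})

test_that("training is deterministic and honors a zero epoch budget", {
  dat <- makeSeparableTask(n = 80, seed = 20)
  tr <- list(x = dat$x[1:60, , , drop = FALSE], y = dat$y[1:60])
  va <- list(x = dat$x[61:80, , , drop = FALSE], y = dat$y[61:80])
  cfg <- trainConfig(hiddenSize = 8, nLayers = 2, maxEpochs = 5,
                     patience = 0, seed = 21)
  s1 <- trainTask(tr, va, cfg)
  s2 <- trainTask(tr, va, cfg)
  expect_identical(classifierWeights(s1), classifierWeights(s2))
  expect_identical(bestEpoch(s1), bestEpoch(s2))

  cfg0 <- trainConfig(hiddenSize = 8, nLayers = 2, maxEpochs = 0, seed = 21)
  s0 <- trainTask(tr, va, cfg0, init = s1)
  expect_identical(classifierWeights(s0), classifierWeights(s1))
  expect_identical(bestEpoch(s0), 0L)
})

test_that("single-class validation folds are rejected with guidance", {
  dat <- makeSeparableTask(n = 40, seed = 22)
  tr <- list(x = dat$x[1:30, , , drop = FALSE], y = dat$y[1:30])
  va <- list(x = dat$x[31:40, , , drop = FALSE], y = rep(1, 10))
  cfg <- trainConfig(hiddenSize = 8, nLayers = 1, maxEpochs = 2, seed = 1)
  expect_error(trainTask(tr, va, cfg), "re-stratify")
})

test_that("progressive transfer initializes each task with the previous best weights", {
  cfg <- cohortConfig(nParticipants = 160, nFeatures = 8, nInformative = 3,
                      prevalenceFirst = 0.15, prevalenceLast = 0.4, seed = 23)
  panel <- generateCohort(cfg)
  labels <- deriveLabels(panel)
  seqc <- buildExpandingTasks(7, 3)
  trIdx <- 1:120; vaIdx <- 121:160
  trP <- pstnet:::subsetPanel(panel, trIdx)
  vaP <- pstnet:::subsetPanel(panel, vaIdx)
  trL <- newLabelSeries(labelMatrix(labels)[trIdx, ])
  vaL <- newLabelSeries(labelMatrix(labels)[vaIdx, ])
  trT <- materializeTasks(trP, trL, seqc)
  vaT <- materializeTasks(vaP, vaL, seqc)
  tcfg <- trainConfig(hiddenSize = 8, nLayers = 2, maxEpochs = 4,
                      patience = 0, seed = 24)
  fit <- progressiveTrain(trT, vaT, tcfg, keepAll = TRUE)
  expect_equal(nrow(fit$taskLog), 4)
  # retraining task k from task k-1's state with the same per-task seed
  # reproduces the stored state exactly: the transferred initialization is
  # bit-identical to the previous best weights
  for (k in 2:4) {
    tk <- tcfg
    tk@seed <- pstnet:::deriveSeed(tcfg@seed, paste0("task", k))
    redo <- trainTask(trT[[k]], vaT[[k]], tk, init = fit$states[[k - 1]])
    expect_identical(classifierWeights(redo),
                     classifierWeights(fit$states[[k]]))
  }
  # a zero-budget continuation leaves the transferred weights untouched, so
  # its predictions coincide with the donor state's on identical inputs
  tk0 <- tcfg; tk0@maxEpochs <- 0L
  frozen <- trainTask(trT[[4]], vaT[[4]], tk0, init = fit$states[[3]])
  xs <- pstnet:::.applyScaling(vaT[[4]]$x,
                               list(center = frozen@center,
                                    scale = frozen@scale))
  pFrozen <- pstnet:::cpp_rnn_predict(classifierWeights(frozen),
                                      pstnet:::.toCube(xs), "lstm", 8L, 2L)
  pDonor <- pstnet:::cpp_rnn_predict(classifierWeights(fit$states[[3]]),
                                     pstnet:::.toCube(xs), "lstm", 8L, 2L)
  expect_identical(as.numeric(pFrozen), as.numeric(pDonor))
  # single-task sequence equals one-shot training
  single <- progressiveTrain(trT[1], vaT[1], tcfg)
  tk1 <- tcfg; tk1@seed <- pstnet:::deriveSeed(tcfg@seed, "task1")
  expect_identical(classifierWeights(single$state),
                   classifierWeights(trainTask(trT[[1]], vaT[[1]], tk1)))
})

test_that("evaluation is dropout-free and batch-partition invariant", {
  dat <- makeSeparableTask(n = 64, seed = 25)
  tr <- list(x = dat$x[1:48, , , drop = FALSE], y = dat$y[1:48])
  va <- list(x = dat$x[49:64, , , drop = FALSE], y = dat$y[49:64])
  cfg <- trainConfig(hiddenSize = 8, nLayers = 2, dropout = 0.5,
                     maxEpochs = 3, patience = 0, seed = 26)
  st <- trainTask(tr, va, cfg)
  p1 <- predictProba(st, va$x)
  p2 <- predictProba(st, va$x)
  expect_identical(p1, p2)
  ph <- c(predictProba(st, va$x[1:7, , , drop = FALSE]),
          predictProba(st, va$x[8:16, , , drop = FALSE]))
  expect_equal(ph, p1, tolerance = 1e-12)
  expect_error(predictProba(st, dat$x[, , 1:2, drop = FALSE]),
               "does not match")
})

test_that("the same loop trains GRU and plain RNN cells", {
  dat <- makeSeparableTask(n = 120, seed = 27)
  tr <- list(x = dat$x[1:90, , , drop = FALSE], y = dat$y[1:90])
  va <- list(x = dat$x[91:120, , , drop = FALSE], y = dat$y[91:120])
  for (cell in c("gru", "rnn")) {
    cfg <- trainConfig(cellKind = cell, hiddenSize = 8, nLayers = 2,
                       maxEpochs = 15, patience = 0, seed = 28)
    st <- trainTask(tr, va, cfg)
    expect_gte(bestValAuc(st), 0.95)
    expect_identical(st@cellKind, cell)
  }
})

test_that("non-progressive subset tasks slice the requested steps", {
  cfg <- cohortConfig(nParticipants = 60, nFeatures = 8, seed = 29)
  panel <- generateCohort(cfg)
  labels <- deriveLabels(panel)
  full <- makeSubsetTask(panel, labels, 1:6)
  expect_equal(dim(full$x), c(60, 6, 8))
  expect_identical(full$y, as.numeric(labelMatrix(labels)[, 7]))
  two <- makeSubsetTask(panel, labels, c(3, 6))
  expect_equal(dim(two$x)[2], 2)
  expect_identical(two$x[, 1, ], panelValues(panel)[, 3, ])
  expect_identical(two$x[, 2, ], panelValues(panel)[, 6, ])
  # the all-steps subset equals the final expanding task's tensors
  prog <- materializeTasks(panel, labels, buildExpandingTasks(7, 3))
  expect_identical(full$x, prog[[4]]$x)
  expect_identical(full$y, prog[[4]]$y)
  expect_error(makeSubsetTask(panel, labels, 1:7), "max")
})
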