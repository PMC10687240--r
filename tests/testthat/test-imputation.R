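test_that("observed cells are preserved bitwise and output is complete", {
  fx <- makeSinusoidalPanel(n = 60, missRate = 0.3, seed = 2)
  model <- fitImputer(fx$panel, epochs = 20, seed = 1)
  out <- imputePanel(model, fx$panel)
  expect_true(all(panelMask(out)))
  expect_identical(panelValues(out)[fx$mask], fx$truth[fx$mask])
  # a panel with nothing missing passes through unchanged
  full <- makePanel(fx$truth)
  expect_identical(panelValues(imputePanel(model, full)), panelValues(full))
})

test_that("training loss decreases over early epochs", {
  fx <- makeSinusoidalPanel(n = 80, missRate = 0.2, seed = 3)
  model <- fitImputer(fx$panel, epochs = 15, seed = 1)
  loss <- model@lossCurve
  expect_length(loss, 15)
  expect_lt(loss[10], loss[1])
  # near-monotone descent: no early epoch regresses by more than 5 %
  expect_true(all(diff(loss[1:10]) < 0.05 * loss[1]))
})

test_that("a constant series with gaps is imputed to the constant", {
  n <- 40; T <- 7
  vals <- array(3.7, c(n, T, 1)) + array(rnorm(n * T, sd = 1e-3), c(n, T, 1))
  set.seed(4)
  mask <- array(runif(n * T) > 0.4, c(n, T, 1))
  panel <- makePanel(vals, mask)
  model <- fitImputer(panel, epochs = 60, seed = 2)
  out <- imputePanel(model, panel)
  sdObs <- sd(vals[mask])
  expect_true(all(abs(panelValues(out)[!mask] - 3.7) < 1e-2 * max(sdObs, 1)))
})

test_that("recurrent imputation beats per-feature mean imputation on smooth signals", {
  fx <- makeSinusoidalPanel(n = 120, missRate = 0.3, seed = 5)
  model <- fitImputer(fx$panel, epochs = 60, seed = 1)
  out <- imputePanel(model, fx$panel)
  rmse <- function(est) sqrt(mean((est[!fx$mask] - fx$truth[!fx$mask])^2))
  meanImp <- fx$truth
  for (j in seq_len(dim(fx$truth)[3]))
    meanImp[, , j] <- mean(fx$truth[, , j][fx$mask[, , j]])
  expect_lt(rmse(panelValues(out)), rmse(meanImp))
})

test_that("linear-trend gaps are filled near the neighbour interpolation", {
  n <- 80; T <- 7
  set.seed(6)
  slopes <- runif(n, -1, 1); icepts <- rnorm(n)
  vals <- array(0, c(n, T, 2))
  for (i in seq_len(n)) {
    vals[i, , 1] <- icepts[i] + slopes[i] * seq_len(T)
    vals[i, , 2] <- icepts[i] - 0.5 * slopes[i] * seq_len(T)
  }
  mask <- array(runif(n * T * 2) > 0.25, c(n, T, 2))
  panel <- makePanel(vals, mask)
  model <- fitImputer(panel, epochs = 80, seed = 3)
  out <- imputePanel(model, panel)
  # compare masked interior cells against the linear interpolation oracle
  errs <- c()
  for (j in 1:2) {
    sdj <- sd(vals[, , j][mask[, , j]])
    for (i in seq_len(n)) {
      obs <- which(mask[i, , j])
      if (length(obs) < 2) next
      gaps <- setdiff(seq(min(obs), max(obs)), obs)
      if (!length(gaps)) next
      interp <- approx(obs, vals[i, obs, j], xout = gaps)$y
      errs <- c(errs, abs(panelValues(out)[i, gaps, j] - interp) / sdj)
    }
  }
  expect_gt(length(errs), 50)
  expect_lt(median(errs), 0.15)
  expect_lt(quantile(errs, 0.9), 0.5)
})

test_that("directional estimates agree on smooth signals", {
  fx <- makeSinusoidalPanel(n = 100, missRate = 0.2, seed = 7)
  model <- fitImputer(fx$panel, epochs = 60, seed = 1)
  est <- directionalEstimates(model, fx$panel)
  # interior steps only: at the ends one direction has no history yet
  dif <- abs(est$forward[, 2:6, ] - est$backward[, 2:6, ])
  expect_lt(median(dif), 0.35)
})

test_that("fitting is deterministic and validates its inputs", {
  fx <- makeSinusoidalPanel(n = 30, missRate = 0.3, seed = 8)
  m1 <- fitImputer(fx$panel, epochs = 5, seed = 9)
  m2 <- fitImputer(fx$panel, epochs = 5, seed = 9)
  expect_identical(m1@forwardWeights, m2@forwardWeights)
  expect_identical(m1@backwardWeights, m2@backwardWeights)

  # a fully masked feature is named in the error
  mask <- fx$mask; mask[, , 2] <- FALSE
  bad <- makePanel(fx$truth, mask)
  expect_error(fitImputer(bad, epochs = 2), "f2")
  # single-step panels cannot be imputed recurrently
  one <- makePanel(fx$truth[, 1, , drop = FALSE])
  expect_error(fitImputer(one), "two time-steps")
  # feature-set mismatch caught at imputation time
  sub <- pstnet:::subsetPanel(fx$panel, features = c(1, 2))
  expect_error(imputePanel(m1, sub), "mismatch")
})

test_that("the linear fallback imputer interpolates exactly", {
  T <- 5
  vals <- array(seq_len(T) * 2, c(1, T, 1))
  mask <- array(c(TRUE, FALSE, TRUE, FALSE, TRUE), c(1, T, 1))
  panel <- makePanel(vals, mask)
  model <- fitImputer(panel, method = "linear")
  out <- imputePanel(model, panel)
  expect_equal(as.vector(panelValues(out)), c(2, 4, 6, 8, 10))
})
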