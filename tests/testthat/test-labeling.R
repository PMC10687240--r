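# tiny panel with explicit biomarker values per participant-step
biomarkerPanel <- function(hba1c, fg, ogtt, flags = NULL) {
  n <- length(hba1c)
  vals <- array(0, c(n, 1, 3))
  vals[, 1, 1] <- hba1c; vals[, 1, 2] <- fg; vals[, 1, 3] <- ogtt
  dimnames(vals) <- list(NULL, NULL, c("hba1c", "fasting_glucose", "ogtt120"))
  sf <- array(FALSE, c(n, 1, 3))
  if (!is.null(flags)) sf[, 1, ] <- flags
  makePanel(vals, biomarkerIndex = c(hba1c = 1L, fasting_glucose = 2L,
                                     ogtt120 = 3L), surveyFlags = sf)
}

test_that("diagnostic thresholds are inclusive and OR-combined", {
  p <- biomarkerPanel(hba1c = c(6.5, 6.49, 5.0, 5.0, 5.0),
                      fg = c(100, 100, 126, 100, 100),
                      ogtt = c(150, 150, 150, 200, 150))
  expect_equal(as.vector(labelMatrix(deriveLabels(p))), c(1L, 0L, 1L, 1L, 0L))
  # a survey flag alone is sufficient
  pf <- biomarkerPanel(hba1c = 5, fg = 100, ogtt = 150,
                       flags = matrix(c(FALSE, TRUE, FALSE), 1))
  expect_equal(as.vector(labelMatrix(deriveLabels(pf))), 1L)
})

test_that("labels match an independent OR-of-criteria oracle on random records", {
  set.seed(7)
  n <- 1000
  hb <- runif(n, 4, 9); fg <- runif(n, 70, 220); og <- runif(n, 80, 300)
  fl <- matrix(runif(n * 3) < 0.05, n, 3)
  p <- biomarkerPanel(hb, fg, og)
  p@surveyFlags[, 1, ] <- fl
  got <- as.vector(labelMatrix(deriveLabels(p)))
  oracle <- integer(n)
  for (i in seq_len(n))
    oracle[i] <- as.integer(hb[i] >= 6.5 || fg[i] >= 126 || og[i] >= 200 ||
                              any(fl[i, ]))
  expect_identical(got, oracle)
})

test_that("derivation is pointwise and idempotent", {
  cfg <- cohortConfig(nParticipants = 120, nFeatures = 8, seed = 4)
  panel <- generateCohort(cfg)
  l1 <- deriveLabels(panel)
  l2 <- deriveLabels(panel)
  expect_identical(labelMatrix(l1), labelMatrix(l2))
  # permuting participants permutes labels identically (no coupling)
  perm <- sample(nParticipants(panel))
  lp <- deriveLabels(pstnet:::subsetPanel(panel, participants = perm))
  expect_identical(labelMatrix(lp), labelMatrix(l1)[perm, ])
})

test_that("observed-value labeling degrades gracefully under masking", {
  vals <- array(0, c(2, 1, 3))
  vals[, 1, 1] <- c(7.0, 7.0); vals[, 1, 2] <- 100; vals[, 1, 3] <- 150
  dimnames(vals) <- list(NULL, NULL, c("hba1c", "fasting_glucose", "ogtt120"))
  mask <- array(TRUE, c(2, 1, 3))
  mask[1, 1, 1] <- FALSE        # diagnostic HbA1c hidden, others observed
  mask[2, 1, ] <- FALSE         # everything hidden
  p <- makePanel(vals, mask, biomarkerIndex = c(hba1c = 1L,
                                                fasting_glucose = 2L,
                                                ogtt120 = 3L))
  expect_warning(l <- deriveLabels(p, use = "observed"), "no observable")
  expect_identical(as.vector(labelMatrix(l)), c(0L, NA_integer_))
})

test_that("baseline-positive exclusion reproduces the cohort-size arithmetic", {
  # 3995 participants, 616 positive at entry -> 3379 retained
  labels <- matrix(0L, 3995, 2)
  labels[seq_len(616), 1] <- 1L
  vals <- array(rnorm(3995 * 2 * 3), c(3995, 2, 3))
  dimnames(vals) <- list(NULL, NULL, c("hba1c", "fasting_glucose", "ogtt120"))
  panel <- makePanel(vals, biomarkerIndex = c(hba1c = 1L,
                                              fasting_glucose = 2L,
                                              ogtt120 = 3L))
  out <- excludeBaselinePositives(panel, newLabelSeries(labels))
  expect_equal(nParticipants(out$panel), 3379)
  expect_true(all(labelMatrix(out$labels)[, 1] == 0L))
  # idempotent
  out2 <- excludeBaselinePositives(out$panel, out$labels)
  expect_equal(nParticipants(out2$panel), 3379)
  expect_identical(labelMatrix(out2$labels), labelMatrix(out$labels))
})

test_that("degenerate exclusion cases behave", {
  vals <- array(0, c(3, 2, 3))
  dimnames(vals) <- list(NULL, NULL, c("hba1c", "fasting_glucose", "ogtt120"))
  panel <- makePanel(vals, biomarkerIndex = c(hba1c = 1L,
                                              fasting_glucose = 2L,
                                              ogtt120 = 3L))
  none <- newLabelSeries(matrix(0L, 3, 2))
  out <- excludeBaselinePositives(panel, none)
  expect_equal(nParticipants(out$panel), 3)   # identity when no positives
  all1 <- newLabelSeries(matrix(1L, 3, 2))
  expect_error(excludeBaselinePositives(panel, all1), "no participants")
})

test_that("prevalence summary reproduces printed percentages exactly", {
  mk <- function(n1, n0) c(rep(1L, n1), rep(0L, n0))
  labels <- newLabelSeries(cbind(mk(130, 3249), mk(303, 3076), mk(555, 2824)))
  out <- summarizePrevalence(labels)
  expect_equal(out$percent_label1, c(3.85, 8.97, 16.42))
  expect_equal(out$n_label0 + out$n_label1, rep(3379, 3))
  even <- summarizePrevalence(newLabelSeries(cbind(mk(7, 7))))
  expect_equal(even$percent_label1, 50.00)
})
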