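test_that("generation is bitwise deterministic for a fixed seed", {
  cfg <- cohortConfig(nParticipants = 150, nFeatures = 10, seed = 42)
  p1 <- generateCohort(cfg)
  p2 <- generateCohort(cfg)
  expect_identical(panelValues(p1), panelValues(p2))
  expect_identical(surveyFlags(p1), surveyFlags(p2))
  expect_identical(labelMatrix(deriveLabels(p1)), labelMatrix(deriveLabels(p2)))
})

test_that("prevalence calibration hits first/last-step targets within 1 pp", {
  cfg <- cohortConfig(nParticipants = 2000, nFeatures = 12, seed = 1,
                      prevalenceFirst = 0.0385, prevalenceLast = 0.1642)
  prev <- prevalence(deriveLabels(generateCohort(cfg)))
  expect_gte(prev[1], 0.0285); expect_lte(prev[1], 0.0485)
  expect_gte(prev[7], 0.1542); expect_lte(prev[7], 0.1742)
})

test_that("disease is absorbing: prevalence is non-decreasing in time", {
  for (s in 1:3) {
    cfg <- cohortConfig(nParticipants = 800, nFeatures = 8, nInformative = 2,
                        seed = s)
    prev <- prevalence(deriveLabels(generateCohort(cfg)))
    expect_true(all(diff(prev) >= 0))
  }
})

test_that("labels re-derive from stored pre-mask biomarkers after masking", {
  cfg <- cohortConfig(nParticipants = 300, nFeatures = 8,
                      missingRateRange = c(0.4, 0.6), seed = 5)
  panel <- generateCohort(cfg)
  before <- deriveLabels(panel)
  masked <- injectMissingness(panel, cfg)
  after <- deriveLabels(masked)
  expect_identical(labelMatrix(before), labelMatrix(after))
})

test_that("flat prevalence targets with no informative features calibrate", {
  cfg <- cohortConfig(nParticipants = 400, nFeatures = 8, nInformative = 0,
                      prevalenceFirst = 0.5, prevalenceLast = 0.5, seed = 3)
  prev <- prevalence(deriveLabels(generateCohort(cfg)))
  expect_lt(abs(prev[1] - 0.5), 0.011)
  expect_lt(abs(prev[7] - 0.5), 0.011)
})

test_that("unreachable prevalence targets raise a calibration error", {
  # 25 participants: achievable prevalences are multiples of 4 pp, so a 2 %
  # target cannot be hit within the 1 pp contract
  cfg <- cohortConfig(nParticipants = 25, nFeatures = 8, nInformative = 0,
                      prevalenceFirst = 0.02, prevalenceLast = 0.16, seed = 1)
  expect_error(generateCohort(cfg), "calibration failed")
})

test_that("missingness injection is MCAR at the configured rates", {
  cfg0 <- cohortConfig(nParticipants = 200, nFeatures = 8,
                       missingRateRange = c(0, 0), seed = 2)
  panel <- generateCohort(cfg0)
  expect_identical(panelMask(injectMissingness(panel, cfg0)),
                   panelMask(panel))  # zero rate leaves everything observed

  cfg3 <- cohortConfig(nParticipants = 1500, nFeatures = 8,
                       missingRateRange = c(0.3, 0.3), seed = 2)
  masked <- injectMissingness(generateCohort(cfg3), cfg3)
  obsFrac <- apply(panelMask(masked), 3, mean)
  expect_true(all(abs(obsFrac - 0.7) < 0.02))
  expect_error(injectMissingness(masked, cfg3), "fully observed")
})

test_that("missingRateRange outside [0, 0.95] is rejected", {
  expect_error(cohortConfig(100, missingRateRange = c(0.5, 0.99)),
               "missingRateRange")
  expect_error(cohortConfig(100, prevalenceFirst = 0.3,
                            prevalenceLast = 0.2), "prevalence")
})

test_that("cohort CSV + sidecar round-trips", {
  cfg <- cohortConfig(nParticipants = 40, nSteps = 4, nFeatures = 6,
                      nInformative = 1, prevalenceFirst = 0.1,
                      prevalenceLast = 0.3, missingRateRange = c(0.2, 0.4),
                      seed = 9)
  panel <- injectMissingness(generateCohort(cfg), cfg)
  prefix <- file.path(tempdir(), "cohort_rt")
  writeCohort(panel, prefix)
  back <- readCohort(prefix)
  expect_equal(panelValues(back), panelValues(panel), ignore_attr = TRUE)
  expect_identical(panelMask(back)[], panelMask(panel)[])
  expect_equal(completeValues(back), completeValues(panel),
               ignore_attr = TRUE)
  expect_identical(surveyFlags(back)[], surveyFlags(panel)[])
  expect_identical(unname(biomarkerIndex(back)), unname(biomarkerIndex(panel)))
})
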