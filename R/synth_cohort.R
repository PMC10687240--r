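#' @include AllClasses.R
NULL

## Synthetic longitudinal cohort generator.
##
## Generative model: each participant carries a latent glycemia trajectory
## z_t following a random walk with drift (AR(1) innovations). The signed
## distance s_t = z_t - c to a latent diagnostic level c drives three
## biomarker columns (HbA1c, fasting glucose, 120-min OGTT) as affine + noise
## transforms whose inclusive thresholds reproduce the diagnostic criteria.
## Once a participant's derived label turns positive, the latent trajectory
## is floored well above c at later steps (absorbing disease state), so
## prevalence rises monotonically. A subset of the remaining features is
## linearly coupled to s_t (recoverable by L1 selection); the rest are
## correlated Gaussian noise. First- and last-step prevalence are calibrated
## by bisection: the baseline level sets the first step, the drift the last.

# evaluate an expression under a temporary RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# latent diagnostic level; biomarker slopes/noise SDs on the latent scale
.LATENT_C <- 2.0
.BIO_SLOPE <- c(hba1c = 0.8, fasting_glucose = 22, ogtt120 = 35)
.BIO_NOISE <- c(hba1c = 0.05, fasting_glucose = 2.0, ogtt120 = 4.0)
.BIO_THRESH <- c(hba1c = 6.5, fasting_glucose = 126, ogtt120 = 200)
.FLAG_PROB <- c(diagnosis_2y = 0.35, treatment_2y = 0.30, insulin_2y = 0.12)

# build the full cohort for given (mu1, drift) from pre-drawn noise;
# returns list(panel-building blocks, labels)
.buildCohort <- function(mu1, drift, noise, config, criteria) {
  n <- config@nParticipants; T <- config@nSteps; d <- config@nFeatures
  c0 <- .LATENT_C
  z <- matrix(0, n, T)
  bio <- array(0, c(n, T, 3))
  flags <- array(FALSE, c(n, T, 3))
  labels <- matrix(0L, n, T)
  everPos <- rep(FALSE, n)
  for (t in seq_len(T)) {
    if (t == 1L) {
      z[, 1] <- mu1 + noise$e1
    } else {
      z[, t] <- z[, t - 1] + drift + noise$eps[, t - 1]
      z[everPos, t] <- pmax(z[everPos, t], c0 + 0.5)
      # survey flags fire only for participants positive in the prior window
      for (j in 1:3)
        flags[, t, j] <- everPos & (noise$uflag[, t, j] < .FLAG_PROB[j])
    }
    s <- z[, t] - c0
    for (j in 1:3)
      bio[, t, j] <- .BIO_THRESH[j] + .BIO_SLOPE[j] * s + noise$ebio[, t, j]
    pos <- bio[, t, 1] >= criteria@hba1c |
      bio[, t, 2] >= criteria@fastingGlucose |
      bio[, t, 3] >= criteria@ogtt120 |
      flags[, t, 1] | flags[, t, 2] | flags[, t, 3]
    labels[, t] <- as.integer(pos)
    everPos <- everPos | pos
  }
  list(z = z, bio = bio, flags = flags, labels = labels)
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces a fully observed [CohortPanel-class] whose derived labels (see
#' [deriveLabels()]) match the configured first- and last-step prevalence to
#' within one percentage point. The generator is deterministic given
#' `config@seed`. Disease is absorbing: once a participant's label turns
#' positive it stays positive at later steps (up to negligible biomarker
#' noise), so prevalence is non-decreasing over time.
#'
#' @param config a [CohortConfig-class].
#' @param criteria the [DiagnosticCriteria-class] used for calibration;
#'   defaults to the standard thresholds.
#' @return A [CohortPanel-class] with all cells observed. Generator
#'   provenance (couplings, latent trajectory, calibrated drift) is kept in
#'   `panelMetadata()`.
#' @examples
#' panel <- generateCohort(cohortConfig(nParticipants = 300, seed = 1))
#' prevalence(deriveLabels(panel))
#' @export
generateCohort <- function(config, criteria = diagnosticCriteria()) {
  validObject(config)
  n <- config@nParticipants; T <- config@nSteps; d <- config@nFeatures
  nInf <- config@nInformative
  noise <- withSeed(deriveSeed(config@seed, "cohort"), list(
    e1 = rnorm(n),
    eps = matrix(rnorm(n * (T - 1), sd = 0.3), n, T - 1),
    ebio = array(rnorm(n * T * 3), c(n, T, 3)) *
      rep(.BIO_NOISE, each = n * T),
    uflag = array(runif(n * T * 3), c(n, T, 3)),
    efeat = array(rnorm(n * T * (d - 3)), c(n, T, max(d - 3, 1))),
    factor = matrix(rnorm(n * T), n, T)
  ))

  prevAt <- function(mu1, drift, step) {
    mean(.buildCohort(mu1, drift, noise, config, criteria)$labels[, step])
  }
  # bisect a monotone step function of the parameter; prevalence jumps in
  # increments of 1/n, so after narrowing the bracket both ends are probed
  # and the closer one wins (the midpoint may sit on the wrong side of a
  # jump in a small cohort)
  bisect <- function(f, lo, hi, target, what) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
    }
    cand <- c((lo + hi) / 2, lo, hi)
    err <- abs(vapply(cand, f, numeric(1)) - target)
    best <- cand[which.min(err)]
    if (min(err) > 0.01)
      stop("calibration failed: ", what, " prevalence target ", target,
           " unreachable")
    best
  }
  # step-1 prevalence is monotone in the baseline level mu1
  mu1 <- bisect(function(m) prevAt(m, 0, 1L), .LATENT_C - 8, .LATENT_C + 3,
                config@prevalenceFirst, "first-step")
  # last-step prevalence is monotone in the drift
  drift <- bisect(function(dr) prevAt(mu1, dr, T), -0.6, 1.5,
                  config@prevalenceLast, "last-step")
  built <- .buildCohort(mu1, drift, noise, config, criteria)

  # assemble features: biomarkers first, informative next, then noise
  values <- array(0, c(n, T, d))
  values[, , 1:3] <- built$bio
  s <- built$z - .LATENT_C
  couplings <- numeric(0)
  if (nInf > 0) {
    couplings <- (0.6 + 0.15 * (seq_len(nInf) %% 3)) *
      ifelse(seq_len(nInf) %% 2 == 0, -1, 1)
    for (j in seq_len(nInf))
      values[, , 3 + j] <- couplings[j] * s + noise$efeat[, , j]
  }
  nNoise <- d - 3 - nInf
  if (nNoise > 0) {
    for (j in seq_len(nNoise))
      values[, , 3 + nInf + j] <-
        0.4 * noise$factor + noise$efeat[, , nInf + j]
  }
  featureNames <- c(names(.BIO_THRESH),
                    if (nInf > 0) paste0("inf_", seq_len(nInf)),
                    if (nNoise > 0) paste0("noise_", seq_len(nNoise)))
  names(couplings) <- if (nInf > 0) paste0("inf_", seq_len(nInf))
  dimnames(values) <- list(NULL, NULL, featureNames)
  bi <- structure(1:3, names = names(.BIO_THRESH))
  new("CohortPanel",
    participantIds = sprintf("P%05d", seq_len(n)),
    values = values,
    mask = array(TRUE, dim(values)),
    completeValues = values,
    featureNames = featureNames,
    biomarkerIndex = bi,
    surveyFlags = built$flags,
    metadata = list(config = config, couplings = couplings,
                    informativeIndex = if (nInf > 0) 3L + seq_len(nInf)
                                       else integer(0),
                    mu1 = mu1, drift = drift, latent = built$z,
                    latentThreshold = .LATENT_C))
}

#' Inject completely-at-random missingness into a fully observed panel
#'
#' Each feature receives its own missing rate drawn uniformly from
#' `config@missingRateRange`; cells are then masked independently (MCAR).
#' Ground-truth values are retained in `completeValues()`, so labels derived
#' afterwards are unaffected by masking.
#'
#' @param panel a fully observed [CohortPanel-class] (mask all TRUE).
#' @param config the [CohortConfig-class] carrying `missingRateRange` and the
#'   seed from which the masking seed is derived.
#' @return The panel with `NA` at masked cells and an updated mask.
#' @export
injectMissingness <- function(panel, config) {
  validObject(config)
  if (!all(panel@mask))
    stop("injectMissingness expects a fully observed panel")
  n <- nParticipants(panel); T <- nSteps(panel); d <- nFeatures(panel)
  out <- withSeed(deriveSeed(config@seed, "missingness"), {
    rates <- runif(d, config@missingRateRange[1], config@missingRateRange[2])
    u <- array(runif(n * T * d), c(n, T, d))
    list(rates = rates, u = u)
  })
  mask <- out$u >= rep(out$rates, each = n * T)
  values <- panel@values
  values[!mask] <- NA_real_
  initialize(panel, values = values, mask = mask,
             metadata = c(panel@metadata, list(missingRates = out$rates)))
}

#' Write a cohort to long-format CSV with a JSON sidecar
#'
#' The CSV has one row per participant-time-step-feature cell with columns
#' `participant_id, time_step, feature, value, observed, complete_value`;
#' survey flags are appended as three extra 0/1 rows per participant-step.
#' The sidecar records feature names, biomarker roles, and survey flag names.
#'
#' @param panel a [CohortPanel-class].
#' @param prefix file path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
writeCohort <- function(panel, prefix) {
  n <- nParticipants(panel); T <- nSteps(panel); d <- nFeatures(panel)
  fl <- c("diagnosis_2y", "treatment_2y", "insulin_2y")
  long <- data.frame(
    participant_id = rep(panel@participantIds, times = T * d),
    time_step = rep(rep(seq_len(T), each = n), times = d),
    feature = rep(panel@featureNames, each = n * T),
    value = as.vector(panel@values),
    observed = as.vector(panel@mask),
    complete_value = as.vector(panel@completeValues))
  flags <- data.frame(
    participant_id = rep(panel@participantIds, times = T * 3),
    time_step = rep(rep(seq_len(T), each = n), times = 3),
    feature = rep(fl, each = n * T),
    value = as.numeric(as.vector(panel@surveyFlags)),
    observed = TRUE,
    complete_value = as.numeric(as.vector(panel@surveyFlags)))
  write.csv(rbind(long, flags), paste0(prefix, ".csv"), row.names = FALSE)
  sidecar <- list(feature_names = panel@featureNames,
                  biomarker_index = as.list(panel@biomarkerIndex),
                  survey_flag_names = fl,
                  n_participants = n, n_steps = T)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param prefix file path prefix used when writing.
#' @return A [CohortPanel-class].
#' @export
readCohort <- function(prefix) {
  long <- read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  fn <- side$feature_names
  ids <- unique(long$participant_id)
  n <- length(ids); T <- side$n_steps; d <- length(fn)
  values <- array(NA_real_, c(n, T, d))
  mask <- array(FALSE, c(n, T, d))
  complete <- array(0, c(n, T, d))
  pidx <- match(long$participant_id, ids)
  fidx <- match(long$feature, fn)
  feat <- !is.na(fidx)
  ii <- cbind(pidx[feat], long$time_step[feat], fidx[feat])
  values[ii] <- long$value[feat]
  mask[ii] <- long$observed[feat]
  complete[ii] <- long$complete_value[feat]
  flags <- array(FALSE, c(n, T, 3))
  for (j in seq_along(side$survey_flag_names)) {
    rows <- long$feature == side$survey_flag_names[j]
    flags[cbind(pidx[rows], long$time_step[rows], j)] <- long$value[rows] > 0
  }
  dimnames(values) <- list(NULL, NULL, fn)
  bi <- unlist(side$biomarker_index)
  new("CohortPanel", participantIds = as.character(ids), values = values,
      mask = mask, completeValues = complete, featureNames = fn,
      biomarkerIndex = structure(as.integer(bi), names = names(bi)),
      surveyFlags = flags, metadata = list())
}
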