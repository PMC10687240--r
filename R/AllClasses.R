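#' @include AllGenerics.R
NULL

## Central S4 data containers. Panels are participant x time-step x feature
## arrays with a parallel logical mask (TRUE = observed); completeValues keeps
## the pre-masking ground truth so labels can always be re-derived.

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Describes the shape and statistical structure of a synthetic longitudinal
#' cohort: size, number of biannual time-steps, feature inventory, how many
#' features are causally coupled to the outcome, the target label prevalence
#' at the first and last step, and the range of per-feature missingness.
#'
#' @slot nParticipants number of participants.
#' @slot nSteps number of time-steps (biannual waves); the study analog is 7.
#' @slot nFeatures number of continuous features (includes the three
#'   diagnostic biomarker columns).
#' @slot nInformative number of non-biomarker features linearly coupled to
#'   the latent glycemia trajectory.
#' @slot prevalenceFirst,prevalenceLast target label prevalence (fractions)
#'   at the first and last time-step; the study analog rises 0.0385 to 0.1642.
#' @slot missingRateRange length-2 numeric in `[0, 0.95]`; each feature's
#'   missing fraction is drawn uniformly from this range.
#' @slot seed integer seed; the generator is fully deterministic given it.
#'
#' @export
setClass("CohortConfig",
  representation(
    nParticipants = "integer",
    nSteps = "integer",
    nFeatures = "integer",
    nInformative = "integer",
    prevalenceFirst = "numeric",
    prevalenceLast = "numeric",
    missingRateRange = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be positive")
  if (object@nSteps < 2L) msg <- c(msg, "nSteps must be at least 2")
  if (object@nFeatures < 3L)
    msg <- c(msg, "nFeatures must be at least 3 (biomarker columns)")
  if (object@nInformative < 0L || object@nInformative > object@nFeatures - 3L)
    msg <- c(msg, "nInformative must be in [0, nFeatures - 3]")
  pf <- object@prevalenceFirst; pl <- object@prevalenceLast
  if (pf <= 0 || pf >= 1 || pl <= 0 || pl >= 1)
    msg <- c(msg, "prevalence targets must lie in (0, 1)")
  if (pf > pl)
    msg <- c(msg, "prevalenceFirst must not exceed prevalenceLast (prevalence rises)")
  mr <- object@missingRateRange
  if (length(mr) != 2L || any(mr < 0) || any(mr > 0.95) || mr[1] > mr[2])
    msg <- c(msg, "missingRateRange must be increasing within [0, 0.95]")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' @param nParticipants,nSteps,nFeatures,nInformative cohort shape; see
#'   [CohortConfig-class].
#' @param prevalenceFirst,prevalenceLast target first/last-step label
#'   prevalence as fractions in (0, 1).
#' @param missingRateRange length-2 numeric range of per-feature missing
#'   fractions, within `[0, 0.95]`.
#' @param seed integer seed.
#' @return A [CohortConfig-class] object.
#' @examples
#' cohortConfig(nParticipants = 200, seed = 7)
#' @export
cohortConfig <- function(nParticipants, nSteps = 7L, nFeatures = 12L,
                         nInformative = 5L, prevalenceFirst = 0.0385,
                         prevalenceLast = 0.1642,
                         missingRateRange = c(0, 0), seed = 1L) {
  new("CohortConfig",
    nParticipants = as.integer(nParticipants), nSteps = as.integer(nSteps),
    nFeatures = as.integer(nFeatures), nInformative = as.integer(nInformative),
    prevalenceFirst = prevalenceFirst, prevalenceLast = prevalenceLast,
    missingRateRange = as.numeric(missingRateRange), seed = as.integer(seed))
}

#' CohortPanel: a participant x time-step x feature longitudinal panel
#'
#' The central data container. `values` holds the observed measurements with
#' `NA` at masked cells; `mask` is the parallel logical observation indicator;
#' `completeValues` is the pre-masking ground truth (equal to `values` for
#' fully observed panels) used for label derivation in synthetic cohorts.
#' Three columns, designated by `biomarkerIndex`, play the HbA1c, fasting
#' glucose, and 120-min OGTT roles; `surveyFlags` carries the three
#' "last two years" diabetes survey items per participant-step.
#'
#' @slot participantIds character participant identifiers.
#' @slot values numeric array, participants x steps x features, NA = missing.
#' @slot mask logical array of the same shape, TRUE = observed.
#' @slot completeValues numeric array of the same shape, never NA.
#' @slot featureNames character feature labels.
#' @slot biomarkerIndex named integer index (hba1c, fasting_glucose, ogtt120)
#'   into the feature columns; may be empty for panels without biomarkers.
#' @slot surveyFlags logical array, participants x steps x 3.
#' @slot metadata list of generator provenance (config, couplings, latent
#'   trajectory) or empty.
#'
#' @export
setClass("CohortPanel",
  representation(
    participantIds = "character",
    values = "array",
    mask = "array",
    completeValues = "array",
    featureNames = "character",
    biomarkerIndex = "integer",
    surveyFlags = "array",
    metadata = "list"
  )
)

setValidity("CohortPanel", function(object) {
  msg <- character()
  dv <- dim(object@values)
  if (length(dv) != 3L) msg <- c(msg, "values must be a 3-d array")
  if (!identical(dim(object@mask), dv)) msg <- c(msg, "mask shape must match values")
  if (!identical(dim(object@completeValues), dv))
    msg <- c(msg, "completeValues shape must match values")
  if (length(object@participantIds) != dv[1])
    msg <- c(msg, "participantIds length must equal dim(values)[1]")
  if (length(object@featureNames) != dv[3])
    msg <- c(msg, "featureNames length must equal dim(values)[3]")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (any(!is.finite(object@values[object@mask])))
    msg <- c(msg, "values must be finite wherever mask is TRUE")
  if (any(!is.finite(object@completeValues)))
    msg <- c(msg, "completeValues must be finite everywhere")
  sf <- dim(object@surveyFlags)
  if (length(sf) != 3L || sf[3] != 3L || sf[1] != dv[1] || sf[2] != dv[2])
    msg <- c(msg, "surveyFlags must be participants x steps x 3")
  bi <- object@biomarkerIndex
  if (length(bi) && (any(bi < 1L) || any(bi > dv[3])))
    msg <- c(msg, "biomarkerIndex out of range")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortPanel-class number of participants
#' @param x a CohortPanel
#' @export
setMethod("nParticipants", "CohortPanel", function(x) dim(x@values)[1])

#' @describeIn CohortPanel-class number of time-steps
#' @export
setMethod("nSteps", "CohortPanel", function(x) dim(x@values)[2])

#' @describeIn CohortPanel-class number of features
#' @export
setMethod("nFeatures", "CohortPanel", function(x) dim(x@values)[3])

#' @describeIn CohortPanel-class feature labels
#' @export
setMethod("featureNames", "CohortPanel", function(x) x@featureNames)

#' @describeIn CohortPanel-class participant identifiers
#' @export
setMethod("participantIds", "CohortPanel", function(x) x@participantIds)

#' @describeIn CohortPanel-class observed values (NA at masked cells)
#' @export
setMethod("panelValues", "CohortPanel", function(x) x@values)

#' @describeIn CohortPanel-class logical observation mask
#' @export
setMethod("panelMask", "CohortPanel", function(x) x@mask)

#' @describeIn CohortPanel-class pre-masking ground-truth values
#' @export
setMethod("completeValues", "CohortPanel", function(x) x@completeValues)

#' @describeIn CohortPanel-class named biomarker column index
#' @export
setMethod("biomarkerIndex", "CohortPanel", function(x) x@biomarkerIndex)

#' @describeIn CohortPanel-class survey flag array
#' @export
setMethod("surveyFlags", "CohortPanel", function(x) x@surveyFlags)

#' @describeIn CohortPanel-class generator metadata list
#' @export
setMethod("panelMetadata", "CohortPanel", function(x) x@metadata)

setMethod("show", "CohortPanel", function(object) {
  d <- dim(object@values)
  miss <- mean(!object@mask)
  cat("CohortPanel:", d[1], "participants x", d[2], "time-steps x",
      d[3], "features\n")
  cat(sprintf("  missing: %.1f%% of cells; biomarkers: %s\n", 100 * miss,
              if (length(object@biomarkerIndex))
                paste(names(object@biomarkerIndex), collapse = ", ")
              else "none"))
})

# internal: subset a panel by participants and/or features
subsetPanel <- function(panel, participants = NULL, features = NULL) {
  pi <- if (is.null(participants)) seq_len(nParticipants(panel)) else participants
  fi <- if (is.null(features)) seq_len(nFeatures(panel)) else features
  if (is.character(fi)) fi <- match(fi, panel@featureNames)
  bi <- panel@biomarkerIndex
  if (length(bi)) {
    kept <- match(bi, fi)
    bi <- structure(kept[!is.na(kept)], names = names(bi)[!is.na(kept)])
    bi <- as.integer(bi)
    names(bi) <- names(panel@biomarkerIndex)[!is.na(kept)]
  }
  new("CohortPanel",
    participantIds = panel@participantIds[pi],
    values = panel@values[pi, , fi, drop = FALSE],
    mask = panel@mask[pi, , fi, drop = FALSE],
    completeValues = panel@completeValues[pi, , fi, drop = FALSE],
    featureNames = panel@featureNames[fi],
    biomarkerIndex = bi,
    surveyFlags = panel@surveyFlags[pi, , , drop = FALSE],
    metadata = panel@metadata)
}

#' LabelSeries: per-participant, per-step binary outcome labels
#'
#' @slot labels integer matrix (participants x steps) of 0/1 labels; NA marks
#'   a step at which no diagnostic criterion was observable.
#' @slot prevalence numeric per-step fraction of positive labels (computed
#'   over non-NA entries).
#' @export
setClass("LabelSeries",
  representation(labels = "matrix", prevalence = "numeric"))

setValidity("LabelSeries", function(object) {
  msg <- character()
  l <- object@labels
  if (!all(l[!is.na(l)] %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
  if (length(object@prevalence) != ncol(l))
    msg <- c(msg, "prevalence length must equal number of steps")
  if (length(msg)) msg else TRUE
})

#' @describeIn LabelSeries-class the participants x steps 0/1 matrix
#' @param x a LabelSeries
#' @export
setMethod("labelMatrix", "LabelSeries", function(x) x@labels)

#' @describeIn LabelSeries-class per-step positive fraction
#' @export
setMethod("prevalence", "LabelSeries", function(x) x@prevalence)

setMethod("show", "LabelSeries", function(object) {
  cat("LabelSeries:", nrow(object@labels), "participants x",
      ncol(object@labels), "steps\n")
  cat("  prevalence (%):",
      paste(sprintf("%.2f", 100 * object@prevalence), collapse = " "), "\n")
})

#' Construct a LabelSeries from a 0/1 matrix
#' @param labels integer matrix, participants x steps.
#' @return A [LabelSeries-class] with per-step prevalence filled in.
#' @export
newLabelSeries <- function(labels) {
  prev <- colMeans(labels == 1L, na.rm = TRUE)
  new("LabelSeries", labels = labels, prevalence = as.numeric(prev))
}

#' DiagnosticCriteria: thresholds defining diabetes onset
#'
#' A participant-step is labeled positive if at least one criterion holds:
#' HbA1c at or above 6.5 percent, fasting plasma glucose at or above
#' 126 mg/dL, 120-minute OGTT glucose at or above 200 mg/dL, or any of the
#' three diabetes survey flags (diagnosis, treatment, insulin therapy within
#' the last two years). All thresholds are inclusive.
#'
#' @slot hba1c HbA1c threshold in percent (default 6.5).
#' @slot fastingGlucose fasting plasma glucose threshold in mg/dL (126).
#' @slot ogtt120 120-minute OGTT glucose threshold in mg/dL (200).
#' @slot surveyFlagNames the three survey item names.
#' @export
setClass("DiagnosticCriteria",
  representation(hba1c = "numeric", fastingGlucose = "numeric",
                 ogtt120 = "numeric", surveyFlagNames = "character"))

setValidity("DiagnosticCriteria", function(object) {
  if (object@hba1c <= 0 || object@fastingGlucose <= 0 || object@ogtt120 <= 0)
    "all thresholds must be strictly positive" else TRUE
})

#' Construct DiagnosticCriteria
#' @param hba1c,fastingGlucose,ogtt120 inclusive diagnostic thresholds.
#' @param surveyFlagNames names of the three survey items.
#' @return A [DiagnosticCriteria-class] object.
#' @export
diagnosticCriteria <- function(hba1c = 6.5, fastingGlucose = 126,
                               ogtt120 = 200,
                               surveyFlagNames = c("diagnosis_2y",
                                                   "treatment_2y",
                                                   "insulin_2y")) {
  new("DiagnosticCriteria", hba1c = hba1c, fastingGlucose = fastingGlucose,
      ogtt120 = ogtt120, surveyFlagNames = surveyFlagNames)
}

#' WindowScheme: one task-construction scheme over the time axis
#'
#' @slot kind "expanding", "rolling", or "skipping".
#' @slot n initial window width in steps (expanding/rolling).
#' @slot w skip interval (skipping): inputs are every (w+1)-th step.
#' @slot N total number of time-steps.
#' @export
setClass("WindowScheme",
  representation(kind = "character", n = "integer", w = "integer",
                 N = "integer"))

setValidity("WindowScheme", function(object) {
  msg <- character()
  if (!object@kind %in% c("expanding", "rolling", "skipping"))
    msg <- c(msg, "kind must be expanding, rolling or skipping")
  if (object@kind %in% c("expanding", "rolling")) {
    if (object@n < 1L || object@n >= object@N)
      msg <- c(msg, "window width n must satisfy 1 <= n < N")
  } else if (object@kind == "skipping") {
    if (object@w < 1L || object@w > object@N - 3L)
      msg <- c(msg, "skip interval w must satisfy 1 <= w <= N - 3")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WindowScheme
#' @param kind "expanding", "rolling" or "skipping".
#' @param N total number of time-steps.
#' @param n initial window width (expanding/rolling; study analog 3).
#' @param w skip interval (skipping; 1 doubles, 2 triples the resolution).
#' @return A [WindowScheme-class].
#' @export
windowScheme <- function(kind, N, n = 3L, w = 1L) {
  new("WindowScheme", kind = kind, n = as.integer(n), w = as.integer(w),
      N = as.integer(N))
}

#' TaskSequence: the ordered supervised tasks of one submodel
#'
#' Each task is a pair of an ordered input-step index vector and the label
#' step it predicts; sequential training visits tasks in order, transferring
#' best-epoch weights forward.
#'
#' @slot tasks list of `list(input_steps =, label_step =)`.
#' @slot scheme the generating [WindowScheme-class].
#' @export
setClass("TaskSequence",
  representation(tasks = "list", scheme = "WindowScheme"))

setValidity("TaskSequence", function(object) {
  msg <- character()
  N <- object@scheme@N
  for (tk in object@tasks) {
    if (any(tk$input_steps < 1L) || tk$label_step > N)
      msg <- c(msg, "task step indices out of [1, N]")
    if (tk$label_step <= max(tk$input_steps))
      msg <- c(msg, "label step must follow every input step")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @describeIn TaskSequence-class list of tasks
#' @param x a TaskSequence
#' @export
setMethod("tasks", "TaskSequence", function(x) x@tasks)

#' @describeIn TaskSequence-class number of tasks (p)
#' @export
setMethod("taskCount", "TaskSequence", function(x) length(x@tasks))

setMethod("show", "TaskSequence", function(object) {
  cat("TaskSequence (", object@scheme@kind, "): ", length(object@tasks),
      " tasks\n", sep = "")
  for (tk in object@tasks)
    cat("  [", paste(tk$input_steps, collapse = ","), "] -> ",
        tk$label_step, "\n", sep = "")
})

#' ClassifierState: a trained multilayer recurrent classifier
#'
#' Architecture descriptor plus weights, the best epoch selected by
#' validation AUC, and the per-epoch training log. States are what the
#' progressive scheme transfers between tasks.
#'
#' @slot cellKind "lstm", "gru" or "rnn".
#' @slot nLayers,hiddenSize,inputSize architecture.
#' @slot weights named list of weight matrices.
#' @slot center,scale per-feature standardization fitted on training data.
#' @slot bestEpoch epoch whose weights are stored (0 = initialization).
#' @slot bestValAuc validation AUC at the best epoch (fraction).
#' @slot trainLog data.frame (epoch, train_loss, val_auc).
#' @export
setClass("ClassifierState",
  representation(cellKind = "character", nLayers = "integer",
                 hiddenSize = "integer", inputSize = "integer",
                 weights = "list", center = "numeric", scale = "numeric",
                 bestEpoch = "integer", bestValAuc = "numeric",
                 trainLog = "data.frame"))

setValidity("ClassifierState", function(object) {
  msg <- character()
  if (!object@cellKind %in% c("lstm", "gru", "rnn"))
    msg <- c(msg, "cellKind must be lstm, gru or rnn")
  g <- c(lstm = 4L, gru = 3L, rnn = 1L)[[object@cellKind]]
  W1 <- object@weights[["Wx1"]]
  if (!is.null(W1) &&
      !identical(dim(W1), c(object@inputSize, g * object@hiddenSize)))
    msg <- c(msg, "first-layer weight shape inconsistent with descriptor")
  if (length(object@weights) != 3L * object@nLayers + 2L)
    msg <- c(msg, "weight list length inconsistent with nLayers")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClassifierState-class named list of weight matrices
#' @param x a ClassifierState
#' @export
setMethod("classifierWeights", "ClassifierState", function(x) x@weights)

#' @describeIn ClassifierState-class best epoch index
#' @export
setMethod("bestEpoch", "ClassifierState", function(x) x@bestEpoch)

#' @describeIn ClassifierState-class validation AUC at the best epoch
#' @export
setMethod("bestValAuc", "ClassifierState", function(x) x@bestValAuc)

#' @describeIn ClassifierState-class per-epoch training log
#' @export
setMethod("trainLog", "ClassifierState", function(x) x@trainLog)

setMethod("show", "ClassifierState", function(object) {
  cat(sprintf("ClassifierState: %d-layer %s, hidden %d, input width %d\n",
              object@nLayers, toupper(object@cellKind), object@hiddenSize,
              object@inputSize))
  cat(sprintf("  best epoch %d, validation AUC %.4f\n", object@bestEpoch,
              object@bestValAuc))
})

#' ImputationModel: bidirectional recurrent imputer state
#'
#' @slot method "brits" (bidirectional recurrent estimator with temporal
#'   decay) or "linear" (per-series linear interpolation then feature mean).
#' @slot forwardWeights,backwardWeights directional estimator weights.
#' @slot featureNames features the model was fitted on.
#' @slot center,scale per-feature standardization from observed entries.
#' @slot hiddenSize recurrent state size.
#' @slot lossCurve per-epoch training loss.
#' @export
setClass("ImputationModel",
  representation(method = "character", forwardWeights = "list",
                 backwardWeights = "list", featureNames = "character",
                 center = "numeric", scale = "numeric",
                 hiddenSize = "integer", lossCurve = "numeric"))

setValidity("ImputationModel", function(object) {
  if (!object@method %in% c("brits", "linear"))
    "method must be 'brits' or 'linear'" else TRUE
})

setMethod("show", "ImputationModel", function(object) {
  cat("ImputationModel (", object@method, "): ",
      length(object@featureNames), " features", sep = "")
  if (length(object@lossCurve))
    cat(sprintf(", final loss %.4g", tail(object@lossCurve, 1)))
  cat("\n")
})

#' LassoResult: L1-penalized selection outcome
#'
#' @slot penaltyGrid penalties searched.
#' @slot chosenPenalty penalty minimizing cross-validated loss.
#' @slot coefficients named per-feature coefficients at the chosen penalty
#'   (standardized scale).
#' @slot selectedFeatures nonzero-coefficient features, ranked by decreasing
#'   absolute coefficient (name tie-break).
#' @slot intercept fitted intercept.
#' @slot cvLoss cross-validated loss per grid penalty.
#' @slot family "gaussian" or "binomial".
#' @export
setClass("LassoResult",
  representation(penaltyGrid = "numeric", chosenPenalty = "numeric",
                 coefficients = "numeric", selectedFeatures = "character",
                 intercept = "numeric", cvLoss = "numeric",
                 family = "character"))

#' @describeIn LassoResult-class ranked nonzero features
#' @param x a LassoResult
#' @export
setMethod("selectedFeatures", "LassoResult", function(x) x@selectedFeatures)

#' @describeIn LassoResult-class named coefficient vector
#' @export
setMethod("lassoCoefficients", "LassoResult", function(x) x@coefficients)

#' @describeIn LassoResult-class the cross-validated penalty
#' @export
setMethod("chosenPenalty", "LassoResult", function(x) x@chosenPenalty)

setMethod("show", "LassoResult", function(object) {
  cat(sprintf("LassoResult: %d/%d features selected at penalty %.4g\n",
              length(object@selectedFeatures), length(object@coefficients),
              object@chosenPenalty))
  top <- head(object@selectedFeatures, 5)
  if (length(top))
    cat("  top |coef|:", paste(top, collapse = ", "), "\n")
})

#' MetricsReport: evaluation summary over folds and repetitions
#'
#' One row per evaluated configuration (single submodels, baselines,
#' ensembles); columns are mean and SD in percent of accuracy, AUC, recall,
#' precision and F1 over repetition means.
#'
#' @slot table the summary data.frame.
#' @slot nFolds,nRepetitions cross-validation design.
#' @slot perRepetition long data.frame of per-repetition fold means.
#' @export
setClass("MetricsReport",
  representation(table = "data.frame", nFolds = "integer",
                 nRepetitions = "integer", perRepetition = "data.frame"))

#' @describeIn MetricsReport-class the summary table
#' @param x a MetricsReport
#' @export
setMethod("metricsTable", "MetricsReport", function(x) x@table)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %d folds x %d repetitions\n", object@nFolds,
              object@nRepetitions))
  tb <- object@table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-24s AUC %.2f +/- %.2f  acc %.2f  F1 %.2f\n",
                tb$model[i], tb$auc_mean[i], tb$auc_sd[i],
                tb$accuracy_mean[i], tb$f1_mean[i]))
})
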