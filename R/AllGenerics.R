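#' @export
setGeneric("nParticipants", function(x) standardGeneric("nParticipants"))

#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @export
setGeneric("participantIds", function(x) standardGeneric("participantIds"))

#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' @export
setGeneric("panelMask", function(x) standardGeneric("panelMask"))

#' @export
setGeneric("completeValues", function(x) standardGeneric("completeValues"))

#' @export
setGeneric("biomarkerIndex", function(x) standardGeneric("biomarkerIndex"))

#' @export
setGeneric("surveyFlags", function(x) standardGeneric("surveyFlags"))

#' @export
setGeneric("panelMetadata", function(x) standardGeneric("panelMetadata"))

#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @export
setGeneric("tasks", function(x) standardGeneric("tasks"))

#' @export
setGeneric("taskCount", function(x) standardGeneric("taskCount"))

#' @export
setGeneric("classifierWeights", function(x) standardGeneric("classifierWeights"))

#' @export
setGeneric("bestEpoch", function(x) standardGeneric("bestEpoch"))

#' @export
setGeneric("bestValAuc", function(x) standardGeneric("bestValAuc"))

#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))

#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @export
setGeneric("lassoCoefficients", function(x) standardGeneric("lassoCoefficients"))

#' @export
setGeneric("chosenPenalty", function(x) standardGeneric("chosenPenalty"))

#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
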