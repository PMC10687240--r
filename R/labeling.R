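## Diagnostic labeling: per-step binary diabetes labels as an OR over
## inclusive biomarker thresholds and survey flags, plus the study inclusion
## rule that removes participants already positive at the first step.

#' Derive per-step binary diabetes labels from diagnostic criteria
#'
#' A participant-step is positive if at least one criterion holds: HbA1c >=
#' 6.5 percent, fasting glucose >= 126 mg/dL, 120-min OGTT glucose >= 200
#' mg/dL, or any of the three survey flags. Thresholds are inclusive.
#'
#' By default the pre-masking ground-truth values (`completeValues()`) are
#' used, so labels are unaffected by injected missingness. With
#' `use = "observed"`, a missing biomarker simply drops that criterion; if
#' every criterion is unobservable at a step (all three biomarkers masked and
#' no flag set), the label is `NA` and a warning reports how many
#' participant-steps were undefined.
#'
#' @param panel a [CohortPanel-class] with `biomarkerIndex` set.
#' @param criteria a [DiagnosticCriteria-class].
#' @param use `"complete"` (default) or `"observed"`.
#' @return A [LabelSeries-class].
#' @export
deriveLabels <- function(panel, criteria = diagnosticCriteria(),
                         use = c("complete", "observed")) {
  use <- match.arg(use)
  bi <- panel@biomarkerIndex
  need <- c("hba1c", "fasting_glucose", "ogtt120")
  if (!all(need %in% names(bi)))
    stop("panel must designate biomarker columns: ",
         paste(setdiff(need, names(bi)), collapse = ", "))
  vals <- if (use == "complete") panel@completeValues else panel@values
  thr <- c(criteria@hba1c, criteria@fastingGlucose, criteria@ogtt120)
  n <- nParticipants(panel); T <- nSteps(panel)
  anyFlag <- panel@surveyFlags[, , 1] | panel@surveyFlags[, , 2] |
    panel@surveyFlags[, , 3]
  dim(anyFlag) <- c(n, T)
  pos <- matrix(FALSE, n, T)
  seen <- matrix(FALSE, n, T)
  for (j in 1:3) {
    b <- vals[, , bi[[need[j]]], drop = TRUE]
    dim(b) <- c(n, T)
    obs <- !is.na(b)
    pos <- pos | (obs & b >= thr[j])
    seen <- seen | obs
  }
  labels <- matrix(as.integer(pos | anyFlag), n, T)
  undefined <- !seen & !anyFlag
  if (any(undefined)) {
    labels[undefined] <- NA_integer_
    warning(sum(undefined),
            " participant-step(s) had no observable criterion; labels set NA")
  }
  newLabelSeries(labels)
}

#' Exclude participants already positive at the first time-step
#'
#' Mirrors the study inclusion rule: participants whose label at step 1 is
#' positive (prevalent disease at baseline) are removed, so the retained
#' cohort is disease-free at entry and later positives are incident cases.
#'
#' @param panel a [CohortPanel-class].
#' @param labels the matching [LabelSeries-class].
#' @return A list with elements `panel` and `labels`, both subset to
#'   participants with a defined, negative first-step label.
#' @export
excludeBaselinePositives <- function(panel, labels) {
  y1 <- labelMatrix(labels)[, 1]
  keep <- which(!is.na(y1) & y1 == 0L)
  if (length(keep) == 0L)
    stop("no participants remain after excluding baseline positives")
  list(panel = subsetPanel(panel, participants = keep),
       labels = newLabelSeries(labelMatrix(labels)[keep, , drop = FALSE]))
}

#' Summarize per-step label counts and prevalence
#'
#' @param labels a [LabelSeries-class].
#' @return A data.frame with one row per time-step: `time_step`, `n_label0`,
#'   `n_label1`, and `percent_label1` (half-up rounded to 2 decimals, the
#'   presentation convention of the study's prevalence table).
#' @examples
#' # 130 of 3379 positive -> 3.85 %
#' summarizePrevalence(
#'   newLabelSeries(matrix(rep(c(1L, 0L), c(130, 3249)), ncol = 1)))
#' @export
summarizePrevalence <- function(labels) {
  l <- labelMatrix(labels)
  n1 <- colSums(l == 1L, na.rm = TRUE)
  n0 <- colSums(l == 0L, na.rm = TRUE)
  data.frame(time_step = seq_len(ncol(l)), n_label0 = n0, n_label1 = n1,
             percent_label1 = roundHalfUp(100 * n1 / (n0 + n1), 2))
}
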