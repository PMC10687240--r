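## L1-penalized feature selection with the 80 %-missingness prefilter.
## The L1 path itself is fitted by glmnet; this module owns the design
## layout, standardization, deterministic cross-validated penalty choice,
## and the ranked coefficient report.

#' Drop features with excessive missingness
#'
#' Retains features whose missing fraction is strictly below `maxMissing` at
#' every time-step (the study keeps continuous features with less than 80
#' percent missing values in each time-step; the bound is strict, so a
#' feature at exactly 80 percent missing in any step is dropped).
#'
#' @param panel a [CohortPanel-class].
#' @param maxMissing fraction in (0, 1]; default 0.8.
#' @return The panel restricted to surviving features.
#' @export
missingnessFilter <- function(panel, maxMissing = 0.8) {
  frac <- apply(!panel@mask, c(2, 3), mean)  # steps x features
  keep <- which(apply(frac, 2, function(f) all(f < maxMissing)))
  if (length(keep) == 0L)
    stop("all features exceed the ", maxMissing, " missingness bound")
  subsetPanel(panel, features = keep)
}

#' Build a flat design table from a panel and labels
#'
#' Layout `"all_steps"` stacks one row per participant-time-step over steps
#' 1..N-1, pairing the features at step t with the label at step t; layout
#' `"last_step"` uses one row per participant, pairing the features at step
#' N-1 with the label at step N.
#'
#' @param panel an imputed (complete) [CohortPanel-class].
#' @param labels the matching [LabelSeries-class].
#' @param layout `"all_steps"` (default) or `"last_step"`.
#' @return list(x = numeric matrix, y = 0/1 vector).
#' @export
designTable <- function(panel, labels, layout = c("all_steps", "last_step")) {
  layout <- match.arg(layout)
  if (!all(panel@mask))
    stop("designTable expects an imputed (complete) panel")
  l <- labelMatrix(labels)
  N <- nSteps(panel)
  if (layout == "all_steps") {
    xs <- lapply(seq_len(N - 1L), function(t) panel@values[, t, , drop = TRUE])
    x <- do.call(rbind, xs)
    y <- as.vector(l[, seq_len(N - 1L)])
  } else {
    x <- panel@values[, N - 1L, , drop = TRUE]
    y <- l[, N]
  }
  colnames(x) <- featureNames(panel)
  ok <- !is.na(y)
  list(x = x[ok, , drop = FALSE], y = y[ok])
}

#' L1-penalized feature selection with cross-validated penalty choice
#'
#' Features are z-scored, then an L1-regularized regression of the 0/1 label
#' on the features is fitted along a penalty grid; the penalty minimizing
#' 5-fold cross-validated loss is chosen and its nonzero-coefficient support
#' is the selected set, ranked by decreasing absolute coefficient (name
#' tie-break). The default family is `"gaussian"` (L1 linear regression on
#' the binary label); `"binomial"` gives L1 logistic regression.
#'
#' @param x numeric design matrix (rows aligned with `y`), complete.
#' @param y binary 0/1 outcome vector.
#' @param penaltyGrid decreasing positive penalties; NULL lets glmnet choose.
#' @param cvFolds folds for penalty selection (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param family `"gaussian"` or `"binomial"`.
#' @param rule `"1se"` (default) picks the largest penalty whose
#'   cross-validated loss is within one standard error of the minimum - the
#'   usual sparser choice for support recovery; `"min"` picks the loss
#'   minimizer.
#' @return A [LassoResult-class].
#' @export
lassoSelect <- function(x, y, penaltyGrid = NULL, cvFolds = 5L, seed = 1L,
                        family = c("gaussian", "binomial"),
                        rule = c("1se", "min")) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  if (!is.null(penaltyGrid) && length(penaltyGrid) == 0L)
    stop("empty penalty grid")
  stopifnot(nrow(x) == length(y))
  sds <- apply(x, 2, sd)
  const <- sds < 1e-12
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  xs <- scale(x)
  foldid <- withSeed(deriveSeed(seed, "lasso-folds"),
                     sample(rep_len(seq_len(cvFolds), nrow(xs))))
  cv <- glmnet::cv.glmnet(xs, y, family = family, alpha = 1,
                          lambda = penaltyGrid, nfolds = cvFolds,
                          foldid = foldid, standardize = FALSE)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.numeric(coef(cv, s = lam))[-1]
  names(beta) <- colnames(xs)
  nz <- beta[beta != 0]
  ord <- order(-abs(nz), names(nz))
  new("LassoResult", penaltyGrid = as.numeric(cv$lambda),
      chosenPenalty = lam, coefficients = beta,
      selectedFeatures = names(nz)[ord],
      intercept = as.numeric(coef(cv, s = lam))[1],
      cvLoss = as.numeric(cv$cvm), family = family)
}

#' Coefficient report in ranked order
#'
#' @param result a [LassoResult-class].
#' @return data.frame (feature, coefficient, rank, selected) sorted by
#'   decreasing absolute coefficient, the usual presentation of an L1
#'   coefficient diagram.
#' @export
lassoReport <- function(result) {
  beta <- result@coefficients
  ord <- order(-abs(beta), names(beta))
  data.frame(feature = names(beta)[ord], coefficient = beta[ord],
             rank = seq_along(beta),
             selected = beta[ord] != 0, row.names = NULL)
}
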