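## Bidirectional recurrent imputation. A forward and a backward recurrent
## estimator each regress the feature vector at step t from a
## temporally-decayed hidden state (decay driven by per-feature gaps since
## the last observation); training minimizes squared reconstruction error on
## observed cells in both directions plus a forward/backward consistency
## penalty. Missing cells are filled with the unweighted mean of the two
## directional estimates; observed cells are never altered.

# panel values -> n x d x T cube with missing set to 0, plus 0/1 mask cube
.panelToCubes <- function(values, mask) {
  x <- aperm(values, c(1, 3, 2))
  m <- aperm(mask, c(1, 3, 2)) * 1.0
  x[is.na(x)] <- 0
  list(x = x, m = m)
}

#' Fit an imputation model on a partially observed panel
#'
#' The default `"brits"` method trains the bidirectional recurrent estimator
#' described above on the panel's observed cells after per-feature z-scoring
#' (statistics from observed entries only). The `"linear"` method is a fast
#' deterministic fallback - per participant-feature linear interpolation with
#' feature-mean fill - useful for quick pipelines; it requires no training.
#'
#' @param panel a [CohortPanel-class]; at least two time-steps, and every
#'   feature must have at least one observed value.
#' @param hiddenSize recurrent state size (default 16).
#' @param epochs training epochs (default 60).
#' @param learningRate Adam learning rate (default 5e-3).
#' @param consistencyWeight weight of the forward/backward agreement penalty
#'   (default 0.1).
#' @param batchSize minibatch size over participants (default 128).
#' @param seed integer seed; fitting is deterministic given it.
#' @param method `"brits"` or `"linear"`.
#' @return An [ImputationModel-class].
#' @export
fitImputer <- function(panel, hiddenSize = 16L, epochs = 60L,
                       learningRate = 5e-3, consistencyWeight = 0.1,
                       batchSize = 128L, seed = 1L,
                       method = c("brits", "linear")) {
  method <- match.arg(method)
  if (nSteps(panel) < 2L)
    stop("imputation needs at least two time-steps")
  nm <- featureNames(panel)
  obsCount <- apply(panel@mask, 3, sum)
  if (any(obsCount == 0L))
    stop("feature(s) with zero observed values: ",
         paste(nm[obsCount == 0L], collapse = ", "))
  center <- scale <- numeric(length(nm))
  for (j in seq_along(nm)) {
    v <- panel@values[, , j][panel@mask[, , j]]
    center[j] <- mean(v)
    scale[j] <- sd(v)
    if (!is.finite(scale[j]) || scale[j] < 1e-10) scale[j] <- 1
  }
  if (method == "linear")
    return(new("ImputationModel", method = "linear", forwardWeights = list(),
               backwardWeights = list(), featureNames = nm, center = center,
               scale = scale, hiddenSize = 0L, lossCurve = numeric(0)))
  z <- sweep(sweep(panel@values, 3, center, "-"), 3, scale, "/")
  cb <- .panelToCubes(z, panel@mask)
  fit <- cpp_brits_train(cb$x, cb$m, as.integer(hiddenSize),
                         as.integer(epochs), learningRate, consistencyWeight,
                         as.integer(batchSize), as.integer(seed))
  new("ImputationModel", method = "brits", forwardWeights = fit$wf,
      backwardWeights = fit$wb, featureNames = nm, center = center,
      scale = scale, hiddenSize = as.integer(hiddenSize),
      lossCurve = as.numeric(fit$loss))
}

#' Impute missing cells of a panel
#'
#' Observed cells are preserved exactly (bitwise); missing cells are filled
#' with the mean of the forward and backward estimates (method `"brits"`) or
#' with per-series linear interpolation falling back to the feature mean
#' (method `"linear"`). The returned panel is fully observed.
#'
#' @param model an [ImputationModel-class].
#' @param panel a [CohortPanel-class] with the same feature set the model was
#'   fitted on.
#' @return The imputed [CohortPanel-class] (mask all TRUE).
#' @export
imputePanel <- function(model, panel) {
  if (!identical(model@featureNames, featureNames(panel)))
    stop("feature set mismatch between imputation model and panel")
  values <- panel@values
  if (all(panel@mask)) return(panel)
  if (model@method == "brits") {
    z <- sweep(sweep(values, 3, model@center, "-"), 3, model@scale, "/")
    cb <- .panelToCubes(z, panel@mask)
    out <- cpp_brits_impute(model@forwardWeights, model@backwardWeights,
                            cb$x, cb$m)
    zi <- aperm(out$imputed, c(1, 3, 2))
    filled <- sweep(sweep(zi, 3, model@scale, "*"), 3, model@center, "+")
  } else {
    filled <- values
    n <- nParticipants(panel); T <- nSteps(panel)
    for (j in seq_len(nFeatures(panel))) {
      for (i in seq_len(n)) {
        y <- values[i, , j]
        if (!anyNA(y)) next
        obs <- which(!is.na(y))
        if (length(obs) >= 2L) {
          y <- approx(obs, y[obs], xout = seq_len(T), rule = 2)$y
        } else if (length(obs) == 1L) {
          y[] <- y[obs]
        } else {
          y[] <- model@center[j]
        }
        filled[i, , j] <- y
      }
    }
  }
  filled[panel@mask] <- values[panel@mask]  # observed cells kept bitwise
  initialize(panel, values = filled, mask = array(TRUE, dim(filled)))
}

#' Directional estimates of the recurrent imputer
#'
#' Returns the forward-only and backward-only reconstructions on the
#' original feature scale, mainly for diagnosing how well the two directions
#' agree under the consistency penalty.
#'
#' @param model a fitted `"brits"` [ImputationModel-class].
#' @param panel the panel to reconstruct.
#' @return A list of two participants x steps x features arrays,
#'   `forward` and `backward`.
#' @export
directionalEstimates <- function(model, panel) {
  stopifnot(model@method == "brits")
  z <- sweep(sweep(panel@values, 3, model@center, "-"), 3, model@scale, "/")
  cb <- .panelToCubes(z, panel@mask)
  out <- cpp_brits_impute(model@forwardWeights, model@backwardWeights,
                          cb$x, cb$m)
  unscale <- function(a)
    sweep(sweep(aperm(a, c(1, 3, 2)), 3, model@scale, "*"), 3,
          model@center, "+")
  list(forward = unscale(out$est_forward),
       backward = unscale(out$est_backward))
}
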