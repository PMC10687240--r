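## Progressive self-transfer training. One submodel is a multilayer
## recurrent classifier (LSTM by default) trained on an ordered task
## sequence: task 1 starts from fresh initialization, task k > 1 from the
## best-epoch weights of task k - 1, best epoch meaning maximal validation
## AUC (earliest on ties). Training minimizes binary cross-entropy on the
## sigmoid of the final-time-step output.

#' TrainConfig: hyperparameters of one recurrent classifier
#'
#' @slot cellKind "lstm" (default), "gru" or "rnn".
#' @slot hiddenSize recurrent units per layer (default 64).
#' @slot nLayers stacked recurrent layers (default 4; a fifth layer bought
#'   only marginal gains at the cost of much larger run-to-run spread in the
#'   source study, so 4 is the default).
#' @slot dropout dropout rate between layers during training (default 0.2).
#' @slot batchSize minibatch size (default 32).
#' @slot maxEpochs epoch budget (default 100).
#' @slot learningRate Adam learning rate (default 1e-3).
#' @slot patience epochs without validation-AUC improvement before stopping
#'   (default 15; 0 disables early stopping).
#' @slot posWeight weight of the positive class in the loss (default 1 = no
#'   reweighting).
#' @slot seed integer seed; training is deterministic given it.
#' @export
setClass("TrainConfig",
  representation(cellKind = "character", hiddenSize = "integer",
                 nLayers = "integer", dropout = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 learningRate = "numeric", patience = "integer",
                 posWeight = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@cellKind %in% c("lstm", "gru", "rnn"))
    msg <- c(msg, "cellKind must be lstm, gru or rnn")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (object@maxEpochs < 0L) msg <- c(msg, "maxEpochs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#' @param cellKind,hiddenSize,nLayers,dropout,batchSize,maxEpochs,learningRate,patience,posWeight,seed
#'   see [TrainConfig-class].
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(cellKind = "lstm", hiddenSize = 64L, nLayers = 4L,
                        dropout = 0.2, batchSize = 32L, maxEpochs = 100L,
                        learningRate = 1e-3, patience = 15L, posWeight = 1,
                        seed = 1L) {
  new("TrainConfig", cellKind = cellKind, hiddenSize = as.integer(hiddenSize),
      nLayers = as.integer(nLayers), dropout = dropout,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      learningRate = learningRate, patience = as.integer(patience),
      posWeight = posWeight, seed = as.integer(seed))
}

# participants x steps x features -> participants x features x steps cube
.toCube <- function(x) aperm(x, c(1, 3, 2))

# per-feature standardization statistics pooled over participants and steps
.fitScaling <- function(x) {
  d <- dim(x)[3]
  center <- scale <- numeric(d)
  for (j in seq_len(d)) {
    center[j] <- mean(x[, , j])
    scale[j] <- sd(as.vector(x[, , j]))
    if (!is.finite(scale[j]) || scale[j] < 1e-10) scale[j] <- 1
  }
  list(center = center, scale = scale)
}

.applyScaling <- function(x, sc)
  sweep(sweep(x, 3, sc$center, "-"), 3, sc$scale, "/")

#' Train one supervised task
#'
#' Minimizes binary cross-entropy (sigmoid head on the final-time-step
#' output) with Adam; after every epoch the validation AUC is computed and
#' the returned state carries the weights of the epoch with maximal
#' validation AUC (earliest on ties). With `init` given, training starts
#' from that state's weights (the progressive transfer step); input widths
#' must match. With `maxEpochs = 0` the initialization is returned
#' unchanged. Feature standardization is fitted on the training data only
#' and stored in the state.
#'
#' @param trainData,valData task datasets from [materializeTasks()]:
#'   `list(x = participants x steps x features, y = 0/1)`. The validation
#'   fold must contain both classes.
#' @param config a [TrainConfig-class].
#' @param init optional [ClassifierState-class] providing initial weights.
#' @return A [ClassifierState-class].
#' @export
trainTask <- function(trainData, valData, config, init = NULL) {
  validObject(config)
  d <- dim(trainData$x)[3]
  if (length(unique(valData$y)) < 2L)
    stop("validation fold contains a single class; AUC is undefined - ",
         "re-stratify the folds")
  if (!is.null(init)) {
    if (init@inputSize != d)
      stop("init state input width ", init@inputSize,
           " does not match task width ", d)
    initW <- init@weights
  } else initW <- list()
  sc <- .fitScaling(trainData$x)
  fit <- cpp_rnn_train(
    .toCube(.applyScaling(trainData$x, sc)), as.numeric(trainData$y),
    .toCube(.applyScaling(valData$x, sc)), as.numeric(valData$y),
    initW, config@cellKind, config@hiddenSize, config@nLayers,
    config@dropout, config@batchSize, config@maxEpochs, config@learningRate,
    config@patience, config@seed, config@posWeight)
  new("ClassifierState", cellKind = config@cellKind,
      nLayers = config@nLayers, hiddenSize = config@hiddenSize,
      inputSize = as.integer(d), weights = fit$weights,
      center = sc$center, scale = sc$scale,
      bestEpoch = as.integer(fit$best_epoch),
      bestValAuc = as.numeric(fit$best_val_auc),
      trainLog = as.data.frame(fit$log))
}

#' Predicted probabilities of a trained classifier
#'
#' Deterministic (dropout is disabled at evaluation); values lie in (0, 1)
#' and do not depend on how the inputs are batched.
#'
#' @param state a [ClassifierState-class].
#' @param x participants x steps x features array; the feature width must
#'   match the state.
#' @return numeric vector of per-participant probabilities.
#' @export
predictProba <- function(state, x) {
  if (dim(x)[3] != state@inputSize)
    stop("input width ", dim(x)[3], " does not match classifier width ",
         state@inputSize)
  xs <- .applyScaling(x, list(center = state@center, scale = state@scale))
  as.numeric(cpp_rnn_predict(state@weights, .toCube(xs), state@cellKind,
                             state@hiddenSize, state@nLayers))
}

#' Progressive self-transfer training over a task sequence
#'
#' Task 1 trains from fresh initialization; every later task is initialized
#' with the previous task's best-epoch weights. Per-task seeds are derived
#' deterministically from `config@seed`.
#'
#' @param trainTasks,valTasks aligned lists of task datasets (one per task)
#'   from [materializeTasks()] on the training and validation participants.
#' @param config a [TrainConfig-class].
#' @param keepAll if TRUE, all per-task states are returned.
#' @return list with `state` (final task's [ClassifierState-class]),
#'   `taskLog` (data.frame: task, best_epoch, best_val_auc), and optionally
#'   `states`.
#' @export
progressiveTrain <- function(trainTasks, valTasks, config, keepAll = FALSE) {
  stopifnot(length(trainTasks) >= 1L,
            length(trainTasks) == length(valTasks))
  state <- NULL
  states <- list()
  log <- data.frame(task = integer(0), best_epoch = integer(0),
                    best_val_auc = numeric(0))
  for (k in seq_along(trainTasks)) {
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, paste0("task", k))
    state <- trainTask(trainTasks[[k]], valTasks[[k]], cfg, init = state)
    log <- rbind(log, data.frame(task = k, best_epoch = state@bestEpoch,
                                 best_val_auc = state@bestValAuc))
    if (keepAll) states[[k]] <- state
  }
  out <- list(state = state, taskLog = log)
  if (keepAll) out$states <- states
  out
}

#' Build the one-shot dataset for a fixed input-step subset
#'
#' The non-progressive baselines train directly on a stated subset of input
#' steps (for example steps 1..6, 4..6, \{2,4,6\} or \{3,6\}) predicting the
#' final step's label.
#'
#' @param panel an imputed [CohortPanel-class].
#' @param labels the matching [LabelSeries-class].
#' @param inputSteps ordered step indices used as inputs.
#' @param labelStep predicted step (default the last).
#' @param features feature subset (NULL = all).
#' @return A task dataset `list(x, y, input_steps, label_step)`.
#' @export
makeSubsetTask <- function(panel, labels, inputSteps,
                           labelStep = nSteps(panel), features = NULL) {
  stopifnot(max(inputSteps) < labelStep)
  seqc <- .newTaskSequence(
    list(list(input_steps = as.integer(inputSteps),
              label_step = as.integer(labelStep))),
    windowScheme("rolling", nSteps(panel), n = length(inputSteps)))
  materializeTasks(panel, labels, seqc, features)[[1]]
}

#' One-shot (non-progressive) training on a fixed step subset
#'
#' Fresh-initialization training of the same classifier on a single task;
#' the baseline against which progressive transfer is compared.
#'
#' @param trainData,valData task datasets (see [makeSubsetTask()]).
#' @param config a [TrainConfig-class].
#' @return A [ClassifierState-class].
#' @export
trainNonProgressive <- function(trainData, valData, config) {
  trainTask(trainData, valData, config, init = NULL)
}
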