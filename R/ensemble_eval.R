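## Soft-voting ensembles and repeated stratified cross-validated evaluation.
## Each submodel contributes a probability vector on the held-out fold; an
## ensemble is the elementwise unweighted mean over its members. Metrics are
## accuracy, AUC (midrank-based), recall, precision and F1, in percent,
## aggregated as mean +/- SD over repetition means.

#' Soft-vote member probabilities
#'
#' @param memberProbs list of aligned probability vectors (equal lengths).
#' @return The elementwise unweighted mean vector.
#' @examples
#' softVote(list(c(0.2, 0.8), c(0.4, 0.6)))  # 0.3 0.7
#' @export
softVote <- function(memberProbs) {
  stopifnot(length(memberProbs) >= 1L)
  lens <- vapply(memberProbs, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("member probability vectors must have equal length")
  Reduce(`+`, memberProbs) / length(memberProbs)
}

#' Stratified k-fold assignment
#'
#' Participants are partitioned into `k` folds stratified on a binary label
#' (the study stratifies on the last time-step's label): within each class,
#' shuffled indices are dealt round-robin, so per-fold class counts differ
#' from perfect proportionality by at most one participant.
#'
#' @param y binary 0/1 label vector.
#' @param k number of folds (default 5).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return integer fold id per participant (1..k).
#' @export
stratifiedKFold <- function(y, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab < k))
    stop("each class needs at least k = ", k, " members (have ",
         paste(tab, collapse = "/"), ")")
  folds <- integer(length(y))
  withSeed(deriveSeed(seed, "kfold"), {
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Binary classification metrics in percent
#'
#' AUC is the midrank-based area under the ROC curve (equivalent to the
#' normalized Wilcoxon statistic, with ties handled by midranks); accuracy,
#' recall, precision and F1 are computed at a fixed probability threshold.
#' Precision and F1 are 0 when undefined (no positive predictions).
#'
#' @param yTrue binary 0/1 vector containing both classes.
#' @param prob aligned probability vector.
#' @param threshold classification threshold (default 0.5).
#' @return named numeric: accuracy, auc, recall, precision, f1 (percent).
#' @export
computeMetrics <- function(yTrue, prob, threshold = 0.5) {
  stopifnot(length(yTrue) == length(prob))
  if (length(unique(yTrue)) < 2L)
    stop("yTrue contains a single class; AUC is undefined")
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & yTrue == 1L)
  fp <- sum(pred == 1L & yTrue == 0L)
  fn <- sum(pred == 0L & yTrue == 1L)
  acc <- mean(pred == yTrue)
  rec <- tp / (tp + fn)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  auc <- cpp_auc(as.numeric(yTrue), as.numeric(prob))
  100 * c(accuracy = acc, auc = auc, recall = rec, precision = prec, f1 = f1)
}

# default ensemble combinations: both disjoint pairs, all triples, the
# quadruple (7 combinations)
defaultEnsembles <- function() {
  list(c(1, 2), c(3, 4), c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4),
       c(1, 2, 3, 4))
}

# default non-progressive input-step subsets for N steps (study analogs for
# N = 7: t1-t6, t4-t6, {t2,t4,t6}, {t3,t6})
defaultSubsets <- function(N) {
  list(full = seq_len(N - 1L),
       recent = seq(N - 3L, N - 1L),
       skip1 = seq(2L, N - 1L, by = 2L),
       skip2 = c(N - 4L, N - 1L))
}

.subsetLabels <- function(labels, idx)
  newLabelSeries(labelMatrix(labels)[idx, , drop = FALSE])

#' Run the full cross-validated experiment
#'
#' For each repetition, participants are stratified into `nFolds` folds on
#' the last step's label. Per fold, the four progressive submodels
#' (expanding, rolling, skipping w = 1, skipping w = 2), the non-progressive
#' step-subset baselines, and GRU/RNN one-shot baselines are trained on the
#' remaining folds and evaluated on the held-out fold; requested soft-voting
#' combinations of submodel probabilities are evaluated alongside. Metrics
#' are aggregated as mean +/- SD over the repetition means of fold means.
#'
#' @param panel an imputed (complete) [CohortPanel-class].
#' @param labels the matching [LabelSeries-class].
#' @param config a [TrainConfig-class] (LSTM cells for submodels).
#' @param features feature subset used as classifier input (NULL = all).
#' @param nRepetitions repetitions of the full cross-validation (default 10).
#' @param nFolds folds (default 5).
#' @param seed global seed; all repetition/fold/training seeds derive from it.
#' @param initialWindow expanding/rolling initial width (default 3).
#' @param ensembles list of member index vectors over submodels 1-4; NULL
#'   gives the seven standard combinations (2 pairs, 4 triples, quadruple).
#' @param subsets named list of non-progressive input-step subsets; NULL
#'   gives the four standard subsets.
#' @param baselineCells extra one-shot full-sequence baselines by cell kind
#'   (default GRU and RNN; the LSTM one equals the full non-progressive row).
#' @param threshold classification threshold (default 0.5).
#' @return A [MetricsReport-class].
#' @export
runExperiment <- function(panel, labels, config = trainConfig(),
                          features = NULL, nRepetitions = 10L, nFolds = 5L,
                          seed = 1L, initialWindow = 3L, ensembles = NULL,
                          subsets = NULL, baselineCells = c("gru", "rnn"),
                          threshold = 0.5) {
  N <- nSteps(panel)
  if (is.null(ensembles)) ensembles <- defaultEnsembles()
  if (is.null(subsets)) subsets <- defaultSubsets(N)
  yN <- labelMatrix(labels)[, N]
  seqs <- submodelSequences(N, initialWindow)
  rows <- list()
  for (r in seq_len(nRepetitions)) {
    repSeed <- deriveSeed(seed, paste0("rep", r))
    folds <- stratifiedKFold(yN, nFolds, repSeed)
    for (f in seq_len(nFolds)) {
      testIdx <- which(folds == f)
      trainIdx <- which(folds != f)
      trPanel <- subsetPanel(panel, participants = trainIdx)
      tePanel <- subsetPanel(panel, participants = testIdx)
      trLabels <- .subsetLabels(labels, trainIdx)
      teLabels <- .subsetLabels(labels, testIdx)
      yTest <- labelMatrix(teLabels)[, N]
      addRow <- function(model, prob) {
        m <- computeMetrics(yTest, prob, threshold)
        rows[[length(rows) + 1L]] <<-
          data.frame(repetition = r, fold = f, model = model, t(m))
      }
      foldSeed <- deriveSeed(repSeed, paste0("fold", f))
      subProbs <- list()
      for (s in seq_along(seqs)) {
        cfg <- config
        cfg@seed <- deriveSeed(foldSeed, names(seqs)[s])
        tr <- materializeTasks(trPanel, trLabels, seqs[[s]], features)
        te <- materializeTasks(tePanel, teLabels, seqs[[s]], features)
        fit <- progressiveTrain(tr, te, cfg)
        prob <- predictProba(fit$state, te[[length(te)]]$x)
        subProbs[[s]] <- prob
        addRow(names(seqs)[s], prob)
      }
      npFull <- NULL
      for (b in seq_along(subsets)) {
        cfg <- config
        cfg@seed <- deriveSeed(foldSeed, paste0("nonprog_", names(subsets)[b]))
        tr <- makeSubsetTask(trPanel, trLabels, subsets[[b]], N, features)
        te <- makeSubsetTask(tePanel, teLabels, subsets[[b]], N, features)
        st <- trainNonProgressive(tr, te, cfg)
        prob <- predictProba(st, te$x)
        if (identical(subsets[[b]], seq_len(N - 1L))) npFull <- prob
        addRow(paste0("nonprog_", names(subsets)[b]), prob)
      }
      for (cellk in baselineCells) {
        if (cellk == "lstm" && !is.null(npFull)) {
          addRow("baseline_lstm", npFull)
          next
        }
        cfg <- config
        cfg@cellKind <- cellk
        cfg@seed <- deriveSeed(foldSeed, paste0("baseline_", cellk))
        tr <- makeSubsetTask(trPanel, trLabels, seq_len(N - 1L), N, features)
        te <- makeSubsetTask(tePanel, teLabels, seq_len(N - 1L), N, features)
        st <- trainNonProgressive(tr, te, cfg)
        addRow(paste0("baseline_", cellk), predictProba(st, te$x))
      }
      for (e in ensembles) {
        nm <- paste0("ensemble_", paste(e, collapse = "+"))
        addRow(nm, softVote(subProbs[e]))
      }
    }
  }
  long <- do.call(rbind, rows)
  metricCols <- c("accuracy", "auc", "recall", "precision", "f1")
  # per-repetition fold means, then mean +/- SD over repetitions
  perRep <- aggregate(long[metricCols],
                      by = long[c("repetition", "model")], FUN = mean)
  agg <- function(fun, suffix) {
    a <- aggregate(perRep[metricCols], by = perRep["model"], FUN = fun)
    names(a)[-1] <- paste0(metricCols, suffix)
    a
  }
  tab <- merge(agg(mean, "_mean"), agg(function(v) {
    s <- sd(v)
    if (is.na(s)) 0 else s
  }, "_sd"), by = "model", sort = FALSE)
  if (nRepetitions < 2L)
    warning("single repetition: SDs reported as 0")
  order_ref <- c(names(seqs), paste0("nonprog_", names(subsets)),
                 paste0("baseline_", baselineCells),
                 vapply(ensembles, function(e)
                   paste0("ensemble_", paste(e, collapse = "+")),
                   character(1)))
  tab <- tab[order(match(tab$model, order_ref)), ]
  rownames(tab) <- NULL
  new("MetricsReport", table = tab, nFolds = as.integer(nFolds),
      nRepetitions = as.integer(nRepetitions), perRepetition = perRep)
}

#' Write a MetricsReport to CSV
#' @param report a [MetricsReport-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  write.csv(metricsTable(report), path, row.names = FALSE)
  invisible(path)
}
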