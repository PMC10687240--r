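## Task construction over the time axis: the ordered supervised tasks of the
## four submodels. Expanding windows grow from the initial width n; rolling
## windows keep width n and slide; skipping series take every (w+1)-th step
## backwards from the window end, coarsening the time resolution. Every
## scheme's final task predicts the last step N.

.newTaskSequence <- function(tasks, scheme) {
  new("TaskSequence", tasks = tasks, scheme = scheme)
}

#' Expanding-window task sequence
#'
#' Task i (i = 1..N-n) uses steps 1..(i+n-1) to predict the label at step
#' i+n: the window grows by one step per task, always anchored at step 1.
#'
#' @param N total time-steps.
#' @param n initial window width, 1 <= n < N.
#' @return A [TaskSequence-class] with N-n tasks.
#' @examples
#' tasks(buildExpandingTasks(7, 3))  # [1:3]->4, [1:4]->5, [1:5]->6, [1:6]->7
#' @export
buildExpandingTasks <- function(N, n) {
  scheme <- windowScheme("expanding", N, n = n)
  tk <- lapply(seq_len(N - n), function(i)
    list(input_steps = seq_len(i + n - 1L), label_step = as.integer(i + n)))
  .newTaskSequence(tk, scheme)
}

#' Rolling-window task sequence
#'
#' Task i (i = 1..N-n) uses steps i..(i+n-1) to predict the label at step
#' i+n: a fixed-width window slides forward one step per task.
#'
#' @inheritParams buildExpandingTasks
#' @return A [TaskSequence-class] with N-n tasks.
#' @export
buildRollingTasks <- function(N, n) {
  scheme <- windowScheme("rolling", N, n = n)
  tk <- lapply(seq_len(N - n), function(i)
    list(input_steps = as.integer(seq(i, i + n - 1L)),
         label_step = as.integer(i + n)))
  .newTaskSequence(tk, scheme)
}

#' Skipping-series task sequence (coarsened time resolution)
#'
#' Task i (i = 1..N-w-2) predicts the label at step i+w+2 from the steps
#' i + (1-s)(w+1), s = 0, 1, 2, ... while the index stays >= 1, in ascending
#' time order: every (w+1)-th step taken backwards from the window end until
#' the first step is reached. w = 1 doubles, w = 2 triples the effective
#' time interval.
#'
#' @param N total time-steps.
#' @param w skip interval, 1 <= w <= N-3.
#' @return A [TaskSequence-class] with N-w-2 tasks.
#' @examples
#' tasks(buildSkippingTasks(7, 1))  # [1,3]->4, [2,4]->5, [1,3,5]->6, [2,4,6]->7
#' @export
buildSkippingTasks <- function(N, w) {
  scheme <- windowScheme("skipping", N, w = w)
  tk <- lapply(seq_len(N - w - 2L), function(i) {
    steps <- integer(0)
    s <- 0L
    repeat {
      idx <- i + (1L - s) * (w + 1L)
      if (idx < 1L) break
      steps <- c(steps, idx)
      s <- s + 1L
    }
    list(input_steps = as.integer(sort(steps)),
         label_step = as.integer(i + w + 2L))
  })
  .newTaskSequence(tk, scheme)
}

#' Build the four study submodel sequences
#'
#' Submodel 1: expanding window (initial width `n`); submodel 2: rolling
#' window (width `n`); submodel 3: skipping series with w = 1; submodel 4:
#' skipping series with w = 2.
#'
#' @param N total time-steps (study analog 7).
#' @param n initial window width (study analog 3).
#' @return Named list of four [TaskSequence-class] objects.
#' @export
submodelSequences <- function(N = 7L, n = 3L) {
  list(submodel1 = buildExpandingTasks(N, n),
       submodel2 = buildRollingTasks(N, n),
       submodel3 = buildSkippingTasks(N, 1L),
       submodel4 = buildSkippingTasks(N, 2L))
}

#' Materialize a task sequence into supervised datasets
#'
#' For each task, extracts the selected features at the task's input steps as
#' an ordered sequence per participant and pairs it with the label at the
#' task's label step. The participant set is identical across the tasks of
#' one sequence.
#'
#' @param panel an imputed (complete) [CohortPanel-class].
#' @param labels the matching [LabelSeries-class]; labels must be defined at
#'   every label step.
#' @param sequence a [TaskSequence-class].
#' @param features feature names (or indices) to include; NULL = all.
#' @return A list with one element per task:
#'   `list(x = participants x steps x features array, y = 0/1 vector,
#'   input_steps =, label_step =)`.
#' @export
materializeTasks <- function(panel, labels, sequence, features = NULL) {
  if (!all(panel@mask))
    stop("materializeTasks expects an imputed (complete) panel")
  if (is.null(features)) features <- featureNames(panel)
  if (is.character(features)) {
    fi <- match(features, featureNames(panel))
    if (anyNA(fi)) stop("unknown feature(s): ",
                        paste(features[is.na(fi)], collapse = ", "))
  } else fi <- as.integer(features)
  if (length(fi) == 0L) stop("empty feature selection")
  l <- labelMatrix(labels)
  N <- nSteps(panel)
  lapply(tasks(sequence), function(tk) {
    if (tk$label_step > N || tk$label_step > ncol(l))
      stop("label step ", tk$label_step, " beyond available steps")
    y <- l[, tk$label_step]
    if (anyNA(y)) stop("labels undefined at step ", tk$label_step)
    list(x = panel@values[, tk$input_steps, fi, drop = FALSE],
         y = as.numeric(y), input_steps = tk$input_steps,
         label_step = tk$label_step)
  })
}

#' Serialize a task sequence to JSON
#' @param sequence a [TaskSequence-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTaskSequence <- function(sequence, path) {
  sc <- sequence@scheme
  jsonlite::write_json(
    list(scheme = list(kind = sc@kind, n = sc@n, w = sc@w, N = sc@N),
         tasks = lapply(tasks(sequence), function(tk)
           list(input_steps = tk$input_steps, label_step = tk$label_step))),
    path, auto_unbox = TRUE)
  invisible(path)
}
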