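#' The motion-detection task
#'
#' Two adjacent sensors view a stimulus at two consecutive times; the 16
#' possible two-step patterns split into 3 preferred-direction (PD)
#' patterns, 3 null-direction (ND) patterns and 10 stationary ones, after
#' the delay-and-compare logic of the Reichardt detector. The brain is
#' updated once after the first stimulus step and twice after the second
#' (the second stimulus stays clamped during both updates), mirroring the
#' delay, multiply and subtract stages. The sum of the two designated
#' output neurons at the final state codes the answer: 0 = ND,
#' 1 = stationary, 2 = PD.
#'
#' @param sensors Ids of the two sensory neurons (default N0, N1).
#' @param outputs Ids of the two output neurons (default N14, N15).
#' @return A task object of class `mb_task` holding the labelled trials,
#'   the per-update clamp schedule, and the scoring rule.
#' @export
md_task <- function(sensors = c(0L, 1L), outputs = c(14L, 15L)) {
  stopifnot(length(sensors) == 2L, length(outputs) == 2L)
  trials <- md_trials()
  n <- nrow(trials)
  schedule <- array(0L, dim = c(n, 3L, 2L))
  schedule[, 1L, ] <- as.matrix(trials[, c("a1", "b1")])
  schedule[, 2L, ] <- as.matrix(trials[, c("a2", "b2")])
  schedule[, 3L, ] <- as.matrix(trials[, c("a2", "b2")])
  structure(
    list(name = "md", trials = trials, schedule = schedule,
         sensors = as.integer(sensors), outputs = as.integer(outputs),
         score = function(final) {
           as.integer(rowSums(final[, outputs + 1L, drop = FALSE]) ==
                        trials$code)
         }),
    class = "mb_task"
  )
}

#' Labelled stimulus patterns of the motion-detection task
#'
#' All 16 two-step patterns on the two sensors. Writing a pattern as
#' (step-1 bits) -> (step-2 bits), the preferred direction (PD) patterns
#' are 10->01, 11->01 and 00->10; the null direction (ND) patterns are
#' 01->10, 11->10 and 01->11; the remaining 10 are stationary.
#'
#' @return A tibble with columns `trial`, `a1`, `b1`, `a2`, `b2` (sensor
#'   bits at the two steps), `label` and `code` (0 = ND, 1 = stationary,
#'   2 = PD).
#' @export
md_trials <- function() {
  pat <- expand.grid(a1 = 0:1, b1 = 0:1, a2 = 0:1, b2 = 0:1)
  key <- sprintf("%d%d->%d%d", pat$a1, pat$b1, pat$a2, pat$b2)
  pd <- c("10->01", "11->01", "00->10")
  nd <- c("01->10", "11->10", "01->11")
  label <- ifelse(key %in% pd, "PD", ifelse(key %in% nd, "ND", "stationary"))
  tibble::tibble(
    trial = seq_len(16L),
    a1 = pat$a1, b1 = pat$b1, a2 = pat$a2, b2 = pat$b2,
    pattern = key,
    label = label,
    code = c(ND = 0L, stationary = 1L, PD = 2L)[label]
  )
}

#' The sound-localization task
#'
#' Interaural time difference coded as a lag between single pulses
#' arriving at the left (N0) and right (N1) ear sensors over three time
#' steps, in the spirit of the Jeffress delay-line model. With the
#' default lag set \{-2, -1, 0, +1, +2\}, the earlier ear fires at step 1
#' and the other ear `|lag|` steps later (lag 0: both at step 1). The
#' brain is updated once per stimulus step; the trial is correct when,
#' at the final state, the designated output neuron for that lag is 1
#' and the other four designated outputs are 0 (one-hot).
#'
#' @param lag_set Integer lags (right minus left arrival step).
#' @param sensors Ids of the two ear sensors (default N0, N1).
#' @param outputs Ids of the designated output neurons, one per lag
#'   (default N11-N15).
#' @return A task object of class `mb_task`.
#' @export
sl_task <- function(lag_set = -2:2, sensors = c(0L, 1L), outputs = 11:15) {
  stopifnot(length(sensors) == 2L, length(outputs) == length(lag_set))
  trials <- sl_trials(lag_set)
  n_steps <- 3L
  n <- nrow(trials)
  schedule <- array(0L, dim = c(n, n_steps, 2L))
  for (i in seq_len(n)) {
    schedule[i, trials$left_step[i], 1L] <- 1L
    schedule[i, trials$right_step[i], 2L] <- 1L
  }
  outputs <- as.integer(outputs)
  structure(
    list(name = "sl", trials = trials, schedule = schedule,
         sensors = as.integer(sensors), outputs = outputs,
         score = function(final) {
           target <- matrix(0L, n, length(outputs))
           target[cbind(seq_len(n), trials$label + 1L)] <- 1L
           as.integer(rowSums(final[, outputs + 1L, drop = FALSE] == target) ==
                        length(outputs))
         }),
    class = "mb_task"
  )
}

#' Labelled stimulus sequences of the sound-localization task
#'
#' @inheritParams sl_task
#' @return A tibble with columns `trial`, `lag`, `label` (0-based angle
#'   index) and the 1-based steps at which each ear's pulse arrives.
#' @export
sl_trials <- function(lag_set = -2:2) {
  lag_set <- as.integer(lag_set)
  left <- pmax(1L, 1L - lag_set)
  right <- left + lag_set
  if (any(right < 1L) || any(right > 3L) || any(left > 3L)) {
    stop("Lags must fit inside the 3-step stimulus window.", call. = FALSE)
  }
  tibble::tibble(
    trial = seq_along(lag_set),
    lag = lag_set,
    label = seq_along(lag_set) - 1L,
    left_step = left,
    right_step = right
  )
}

check_task_brain <- function(brain, task) {
  ids <- c(task$sensors, task$outputs)
  if (any(ids < 0L) || any(ids >= brain$n_neurons)) {
    stop("Task sensor/output ids exceed the brain's neuron range.",
         call. = FALSE)
  }
  if (!all(task$sensors %in% brain$sensory_ids)) {
    stop("Brain's sensory neurons do not include the task sensors (",
         paste(task$sensors, collapse = ", "), ").", call. = FALSE)
  }
  invisible(TRUE)
}

task_final_states <- function(brain, task) {
  n_trials <- dim(task$schedule)[1]
  n_updates <- dim(task$schedule)[2]
  final <- matrix(0L, n_trials, brain$n_neurons)
  for (i in seq_len(n_trials)) {
    state <- integer(brain$n_neurons)
    for (u in seq_len(n_updates)) {
      clamp <- stats::setNames(task$schedule[i, u, ], task$sensors)
      state <- update_brain(brain, state, clamp)
    }
    final[i, ] <- state
  }
  final
}

#' Evaluate a brain on a task
#'
#' Runs every trial from the all-quiescent state under the task's clamp
#' schedule and scores the final state. Fitness is the fraction of
#' correct trials.
#'
#' @param brain A [markov_brain()].
#' @param task A task from [md_task()] or [sl_task()].
#' @return A list with `fitness` (in \[0, 1\]) and `per_trial`, a tibble
#'   of the task's trials with a `correct` column.
#' @export
evaluate_task <- function(brain, task) {
  check_task_brain(brain, task)
  final <- task_final_states(brain, task)
  correct <- task$score(final)
  per_trial <- dplyr::mutate(task$trials, correct = as.logical(correct))
  list(fitness = mean(correct), per_trial = per_trial)
}

#' @rdname evaluate_task
#' @param ... Passed to [md_task()] / [sl_task()].
#' @export
md_evaluate <- function(brain, ...) evaluate_task(brain, md_task(...))

#' @rdname evaluate_task
#' @export
sl_evaluate <- function(brain, ...) evaluate_task(brain, sl_task(...))

#' Record neural activity of a behaving brain
#'
#' Runs each task trial from the all-quiescent state and records the full
#' neuron state at every time step: the initial state plus the state
#' after each of the three updates (4 snapshots per trial; 64 snapshots
#' for motion detection, 20 for sound localization). Brains are
#' deterministic, so one recording per trial samples the behaviour
#' exhaustively.
#'
#' @param brain A [markov_brain()].
#' @param task A task from [md_task()] or [sl_task()].
#' @return An `mb_recording` tibble (see [as_recording()]).
#' @export
record <- function(brain, task) {
  check_task_brain(brain, task)
  n_trials <- dim(task$schedule)[1]
  n_updates <- dim(task$schedule)[2]
  trials <- lapply(seq_len(n_trials), function(i) {
    snap <- matrix(0L, n_updates + 1L, brain$n_neurons)
    state <- integer(brain$n_neurons)
    for (u in seq_len(n_updates)) {
      clamp <- stats::setNames(task$schedule[i, u, ], task$sensors)
      state <- update_brain(brain, state, clamp)
      snap[u + 1L, ] <- state
    }
    snap
  })
  as_recording(trials)
}
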