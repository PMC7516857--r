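#' Recordings of binary neural activity
#'
#' A recording is a tibble with columns `trial`, `time` and one 0/1 column
#' per neuron (`n0`, `n1`, ...). Transition pairs for the empirical
#' estimators are formed only between consecutive time steps within the
#' same trial; the inter-trial reset is never treated as a transition.
#'
#' `as_recording()` builds a recording from a list of trial matrices
#' (rows = time steps, columns = neurons).
#'
#' @param trials A list of integer matrices with entries in \{0, 1\}, all
#'   with the same number of columns.
#' @return A tibble of class `mb_recording` with attribute `n_neurons`.
#' @export
as_recording <- function(trials) {
  if (length(trials) == 0L) stop("`trials` must be non-empty.", call. = FALSE)
  n_neurons <- ncol(trials[[1]])
  ok <- vapply(trials, function(m) {
    is.matrix(m) && ncol(m) == n_neurons && all(m %in% c(0, 1))
  }, logical(1))
  if (!all(ok)) {
    stop("All trials must be 0/1 matrices with ", n_neurons, " columns.",
         call. = FALSE)
  }
  rows <- purrr::imap(trials, function(m, i) {
    out <- tibble::as_tibble(m, .name_repair = ~ paste0("n", seq_len(n_neurons) - 1L))
    dplyr::bind_cols(tibble::tibble(trial = i, time = seq_len(nrow(m)) - 1L), out)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_neurons") <- n_neurons
  class(out) <- c("mb_recording", class(out))
  out
}

neuron_col <- function(rec, id) {
  n <- attr(rec, "n_neurons") %||% (ncol(rec) - 2L)
  if (!all(id %in% (seq_len(n) - 1L))) {
    stop("Neuron id out of range [0, ", n - 1L, "].", call. = FALSE)
  }
  paste0("n", id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Within-trial transition pairs: for each neuron id in `now`, its value at
# time t; for each id in `nxt`, its value at t + 1.
transition_frame <- function(rec, now, nxt) {
  now_cols <- neuron_col(rec, now)
  nxt_cols <- neuron_col(rec, nxt)
  rec <- dplyr::arrange(rec, .data$trial, .data$time)
  grp <- dplyr::group_by(rec, .data$trial)
  out <- dplyr::transmute(
    grp,
    dplyr::across(dplyr::all_of(now_cols), ~.x, .names = "now_{.col}"),
    dplyr::across(dplyr::all_of(nxt_cols), ~dplyr::lead(.x), .names = "next_{.col}")
  )
  out <- dplyr::ungroup(out)
  out <- out[stats::complete.cases(out), setdiff(names(out), "trial"), drop = FALSE]
  if (nrow(out) == 0L) {
    stop("Recording contains no within-trial transitions.", call. = FALSE)
  }
  out
}

# Plug-in (maximum-likelihood) joint table over transition variables.
empirical_joint <- function(frame) {
  counts <- dplyr::count(frame, dplyr::across(dplyr::everything()))
  joint_table(counts[setdiff(names(counts), "n")], counts$n / sum(counts$n))
}

#' Empirical transfer entropy and processed information
#'
#' Plug-in estimators over pooled within-trial transitions with history
#' length one: `transfer_entropy()` returns I(dst_{t+1} : src_t | dst_t);
#' `conditional_transfer_entropy()` adds a third past variable to the
#' conditioning set, I(dst_{t+1} : src_t | dst_t, cond_t);
#' `processed_information()` is the self-pair analogue I(node_t : node_{t+1}).
#'
#' Probabilities are maximum-likelihood frequencies with no bias
#' correction, so on an exhaustively sampled deterministic process the
#' estimate is exact.
#'
#' @param rec A recording (see [as_recording()] or [record()]).
#' @param src,dst,cond,node Neuron ids (0-based).
#' @return Information in bits.
#' @export
transfer_entropy <- function(rec, src, dst) {
  if (src == dst) {
    stop("`src` and `dst` must differ; use processed_information() for ",
         "the information a neuron carries about its own next state.",
         call. = FALSE)
  }
  frame <- transition_frame(rec, now = c(src, dst), nxt = dst)
  joint <- empirical_joint(frame)
  conditional_mutual_information(
    joint,
    a = paste0("next_n", dst),
    b = paste0("now_n", src),
    c = paste0("now_n", dst)
  )
}

#' @rdname transfer_entropy
#' @export
conditional_transfer_entropy <- function(rec, src, dst, cond) {
  if (src == dst) {
    stop("`src` and `dst` must differ; use processed_information().",
         call. = FALSE)
  }
  if (cond %in% c(src, dst)) {
    stop("`cond` must differ from `src` and `dst`.", call. = FALSE)
  }
  frame <- transition_frame(rec, now = c(src, dst, cond), nxt = dst)
  joint <- empirical_joint(frame)
  conditional_mutual_information(
    joint,
    a = paste0("next_n", dst),
    b = paste0("now_n", src),
    c = paste0("now_n", c(dst, cond))
  )
}

#' @rdname transfer_entropy
#' @export
processed_information <- function(rec, node) {
  frame <- transition_frame(rec, now = node, nxt = node)
  joint <- empirical_joint(frame)
  mutual_information(
    joint,
    a = paste0("next_n", node),
    b = paste0("now_n", node)
  )
}
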