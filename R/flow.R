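#' Pairwise transfer-entropy matrix of a recording
#'
#' Estimates the plug-in transfer entropy for every ordered pair of
#' neurons from the pooled within-trial transitions of a recording. The
#' diagonal holds the processed information I(z_t : z_{t+1}) when
#' `include_self = TRUE`, else 0 (and the diagonal is excluded from
#' detection scoring by default either way).
#'
#' @param rec An `mb_recording` (see [record()]).
#' @param include_self Put processed information on the diagonal.
#' @return An n x n non-negative matrix of class `te_matrix`, rows =
#'   source neurons, columns = destinations, in bits.
#' @export
te_matrix <- function(rec, include_self = FALSE) {
  n <- attr(rec, "n_neurons")
  cols <- paste0("n", 0:(n - 1))
  rec <- dplyr::arrange(rec, .data$trial, .data$time)
  states <- as.matrix(rec[cols])
  trial <- rec$trial
  last <- c(trial[-1] != trial[-length(trial)], TRUE)
  now <- states[!last, , drop = FALSE]
  nxt <- states[-1, , drop = FALSE][!last[-length(last)], , drop = FALSE]
  if (nrow(now) == 0L) {
    stop("Recording contains no within-trial transitions.", call. = FALSE)
  }
  m <- matrix(0, n, n,
              dimnames = list(paste0("N", 0:(n - 1)), paste0("N", 0:(n - 1))))
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) {
        if (include_self) {
          counts <- tabulate(1L + 2L * nxt[, j] + now[, j], nbins = 4L)
          m[i, j] <- mi_from_counts(counts)
        }
        next
      }
      counts <- tabulate(1L + 4L * nxt[, j] + 2L * now[, i] + now[, j],
                         nbins = 8L)
      m[i, j] <- cmi_from_counts(counts)
    }
  }
  attr(m, "include_self") <- include_self
  class(m) <- c("te_matrix", class(m))
  m
}

# counts over (z1, s, d) in bit order 4*z1 + 2*s + d: I(z1 : s | d).
cmi_from_counts <- function(counts) {
  p <- counts / sum(counts)
  dim(p) <- c(2, 2, 2)  # [d, s, z1]
  h <- function(x) shannon(as.vector(x))
  v <- h(apply(p, c(1, 3), sum)) + h(apply(p, c(1, 2), sum)) -
    h(p) - h(apply(p, 1, sum))
  max(v, 0)
}

# counts over (z1, z) in bit order 2*z1 + z: I(z1 : z).
mi_from_counts <- function(counts) {
  p <- counts / sum(counts)
  dim(p) <- c(2, 2)
  v <- shannon(apply(p, 1, sum)) + shannon(apply(p, 2, sum)) -
    shannon(as.vector(p))
  max(v, 0)
}

#' Tidy a transfer-entropy matrix into a long tibble
#'
#' @param x A [te_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `source`, `destination` (0-based) and
#'   `te` (bits).
#' @method tidy te_matrix
#' @export
tidy.te_matrix <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    source = rep(0:(n - 1), times = n),
    destination = rep(0:(n - 1), each = n),
    te = as.vector(unclass(x))
  )
}

scoring_mask <- function(n, include_self) {
  mask <- matrix(TRUE, n, n)
  if (!include_self) diag(mask) <- FALSE
  mask
}

#' Score transfer-entropy detections against the ground truth
#'
#' An information flow i -> j is detected when TE(i -> j) exceeds the
#' threshold (strict inequality, so at threshold 0 "any non-zero value"
#' counts and exact zeros do not). Detections are compared with the
#' ground-truth influence map: hits are true edges detected, misses true
#' edges not detected, false alarms detections where no edge exists.
#' The hit rate divides hits by the number of true edges and the
#' false-alarm rate divides false alarms by the number of true
#' non-edges. Self-pairs are excluded unless `include_self = TRUE`.
#'
#' @param te A [te_matrix()].
#' @param truth An [influence_map()] of the same dimension.
#' @param threshold Detection threshold in bits, in \[0, 1\].
#' @param include_self Score the diagonal too.
#' @return A one-row tibble: `threshold`, `hits`, `misses`,
#'   `false_alarms`, `n_edges`, `n_nonedges`, `hit_rate`,
#'   `false_alarm_rate`.
#' @export
score_detection <- function(te, truth, threshold = 0, include_self = FALSE) {
  stopifnot(all(dim(te) == dim(truth)), threshold >= 0, threshold <= 1)
  mask <- scoring_mask(nrow(te), include_self)
  detected <- unclass(te) > threshold & mask
  edges <- unclass(truth) == 1L & mask
  hits <- sum(detected & edges)
  misses <- sum(edges & !detected)
  false_alarms <- sum(detected & !edges)
  n_edges <- sum(edges)
  n_nonedges <- sum(mask & !edges)
  tibble::tibble(
    threshold = threshold,
    hits = hits, misses = misses, false_alarms = false_alarms,
    n_edges = n_edges, n_nonedges = n_nonedges,
    hit_rate = if (n_edges > 0) hits / n_edges else NA_real_,
    false_alarm_rate = if (n_nonedges > 0) false_alarms / n_nonedges
                       else NA_real_
  )
}

#' Empirical ROC curve of transfer-entropy detection
#'
#' Scores the detection at each threshold and returns the (false-alarm
#' rate, hit rate) staircase, ordered by descending threshold so the
#' right-most point is the vanishing-threshold analysis. Both rates are
#' non-increasing in the threshold.
#'
#' @inheritParams score_detection
#' @param thresholds Thresholds in \[0, 1\]; default 101 evenly spaced
#'   values.
#' @return A tibble of class `te_roc`, one row per threshold.
#' @export
roc_curve <- function(te, truth, thresholds = seq(0, 1, length.out = 101),
                      include_self = FALSE) {
  pts <- purrr::map_dfr(sort(thresholds, decreasing = TRUE),
                        function(th) score_detection(te, truth, th,
                                                     include_self))
  class(pts) <- c("te_roc", class(pts))
  pts
}

#' Edge and non-edge transfer-entropy samples
#'
#' Splits the entries of a TE matrix by whether the ground truth has an
#' edge there; the two samples feed the binormal ROC fit.
#'
#' @inheritParams score_detection
#' @return A list with numeric vectors `edge` and `nonedge`.
#' @export
te_values_by_truth <- function(te, truth, include_self = FALSE) {
  mask <- scoring_mask(nrow(te), include_self)
  edges <- unclass(truth) == 1L & mask
  list(edge = unclass(te)[edges & mask],
       nonedge = unclass(te)[!edges & mask])
}

#' Binormal ROC fit
#'
#' Models TE given an existing flow as Normal(mu1, sigma1) and TE given
#' no flow as Normal(mu2, sigma2) (sample means and SDs of the two
#' samples). Under this model the hit rate is a closed-form function of
#' the false-alarm rate x:
#' f(x) = 1/2 erfc( (mu2 - mu1)/(sqrt(2) sigma1) +
#'                  (sigma2/sigma1) erfc^{-1}(2x) ),
#' an increasing curve through (0,0) and (1,1) that reduces to the
#' chance diagonal f(x) = x when the two class distributions coincide.
#'
#' @param edge_values TE values where the ground truth has an edge.
#' @param nonedge_values TE values where it has none.
#' @return An object of class `te_roc_fit` with fields `mu1`, `sigma1`,
#'   `mu2`, `sigma2` and `fun` (the fitted curve as an R function).
#' @export
fit_gaussian_roc <- function(edge_values, nonedge_values) {
  if (length(edge_values) == 0L || length(nonedge_values) == 0L) {
    stop("Both TE samples must be non-empty.", call. = FALSE)
  }
  mu1 <- mean(edge_values); sigma1 <- stats::sd(edge_values)
  mu2 <- mean(nonedge_values); sigma2 <- stats::sd(nonedge_values)
  if (!is.finite(sigma1) || !is.finite(sigma2) || sigma1 == 0 ||
      sigma2 == 0) {
    stop("Zero variance in a TE class; use the empirical ROC instead.",
         call. = FALSE)
  }
  f <- function(x) {
    stats::pnorm((mu1 - mu2 + sigma2 * stats::qnorm(x)) / sigma1)
  }
  structure(list(mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
                 fun = f),
            class = "te_roc_fit")
}

#' @export
print.te_roc_fit <- function(x, ...) {
  cat(sprintf(
    "<te_roc_fit> edge ~ N(%.3f, %.3f), non-edge ~ N(%.3f, %.3f)\n",
    x$mu1, x$sigma1, x$mu2, x$sigma2))
  invisible(x)
}

#' Tidy and summarise a binormal ROC fit
#'
#' `tidy()` evaluates the fitted curve on a grid of false-alarm rates;
#' `glance()` returns the four fitted parameters and the model AUC,
#' pnorm((mu1 - mu2) / sqrt(sigma1^2 + sigma2^2)).
#'
#' @param x A `te_roc_fit`.
#' @param x_grid Grid of false-alarm rates.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy te_roc_fit
#' @export
tidy.te_roc_fit <- function(x, x_grid = seq(0, 1, length.out = 201), ...) {
  tibble::tibble(false_alarm_rate = x_grid, hit_rate = x$fun(x_grid))
}

#' @rdname tidy.te_roc_fit
#' @method glance te_roc_fit
#' @export
glance.te_roc_fit <- function(x, ...) {
  tibble::tibble(
    mu1 = x$mu1, sigma1 = x$sigma1, mu2 = x$mu2, sigma2 = x$sigma2,
    auc = stats::pnorm((x$mu1 - x$mu2) / sqrt(x$sigma1^2 + x$sigma2^2))
  )
}

#' End-to-end flow analysis of one brain
#'
#' Records the brain behaving on the task, estimates the pairwise TE
#' matrix, derives the ground-truth influence map, and scores detection:
#' the vanishing-threshold counts plus the full ROC staircase.
#'
#' @param brain A [markov_brain()].
#' @param task A task from [md_task()] or [sl_task()].
#' @param thresholds Threshold grid for the ROC.
#' @param include_self Score self-pairs.
#' @return A list of class `flow_analysis`: `te`, `truth`, `detection`
#'   (threshold-0 scores) and `roc`.
#' @export
flow_analysis <- function(brain, task,
                          thresholds = seq(0, 1, length.out = 101),
                          include_self = FALSE) {
  rec <- record(brain, task)
  te <- te_matrix(rec, include_self = include_self)
  truth <- influence_map(brain)
  structure(
    list(te = te, truth = truth,
         detection = score_detection(te, truth, 0, include_self),
         roc = roc_curve(te, truth, thresholds, include_self)),
    class = "flow_analysis"
  )
}

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views: TE matrices and
#' influence maps as heat maps (rows = source, columns = destination),
#' ROC staircases as step curves with an optional binormal fit overlay.
#'
#' @param object A `te_matrix`, `influence_map` or `te_roc`.
#' @param fit Optional `te_roc_fit` overlaid on a ROC plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_matrix
#' @export
autoplot.te_matrix <- function(object, ...) {
  df <- tidy.te_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$destination, y = .data$source,
                                   fill = .data$te)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = unique(df$source)) +
    ggplot2::scale_x_continuous(breaks = unique(df$destination)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "TE (bits)") +
    ggplot2::labs(x = "destination neuron", y = "source neuron") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.te_matrix
#' @method autoplot influence_map
#' @export
autoplot.influence_map <- function(object, ...) {
  df <- tidy.influence_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$destination, y = .data$source,
                                   fill = factor(.data$edge))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = unique(df$source)) +
    ggplot2::scale_x_continuous(breaks = unique(df$destination)) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "grey10"),
                               name = "influence") +
    ggplot2::labs(x = "destination neuron", y = "source neuron") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.te_matrix
#' @method autoplot te_roc
#' @export
autoplot.te_roc <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$false_alarm_rate,
                                    y = .data$hit_rate)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false-alarm rate", y = "hit rate") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = tidy.te_roc_fit(fit),
      ggplot2::aes(x = .data$false_alarm_rate, y = .data$hit_rate),
      linetype = "dashed"
    )
  }
  p
}

#' Cohort gate-composition plot
#'
#' Bar chart of mean per-brain counts of each gate type, optionally
#' split by a grouping column (e.g. all vs essential gates).
#'
#' @param composition Output of [gate_composition()], optionally with an
#'   extra `group` column.
#' @return A ggplot object.
#' @export
plot_gate_composition <- function(composition) {
  grouping <- if ("group" %in% names(composition)) c("id", "group") else "id"
  df <- dplyr::summarise(
    dplyr::group_by(composition, dplyr::across(dplyr::all_of(grouping))),
    mean_count = mean(.data$count), .groups = "drop"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$mean_count))
  if ("group" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$group),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = "gate type", y = "mean gates per brain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
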