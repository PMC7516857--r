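#' Gate knockout
#'
#' Removes one gate together with all its input and output connections;
#' neurons it wrote may fall back to the quiescent default if nothing
#' else writes them. All other gates are untouched, so re-adding the
#' gate restores the original logic exactly.
#'
#' @param brain A [markov_brain()].
#' @param gate_index 1-based row index into the brain's gene matrix.
#' @return The mutant [markov_brain()].
#' @export
knockout_gate <- function(brain, gate_index) {
  stopifnot(gate_index >= 1L, gate_index <= nrow(brain$genes))
  mutant <- brain
  mutant$genes <- brain$genes[-gate_index, , drop = FALSE]
  mutant
}

#' Single-gate knockout assay
#'
#' Knocks out each gate in turn and re-measures task fitness from
#' scratch. A gate is essential when the mutant's fitness drops below
#' the intact brain's fitness (for a perfect brain: below 1); otherwise
#' it is redundant.
#'
#' @param brain A [markov_brain()].
#' @param task A task from [md_task()] or [sl_task()].
#' @return A tibble with one row per gate: `gate` (index), `id` (gate
#'   type), `mutant_fitness` and `essential`.
#' @export
knockout_assay <- function(brain, task) {
  intact <- evaluate_task(brain, task)$fitness
  n <- nrow(brain$genes)
  mutant_fitness <- vapply(seq_len(n), function(k) {
    evaluate_task(knockout_gate(brain, k), task)$fitness
  }, numeric(1))
  tibble::tibble(
    gate = seq_len(n),
    id = vapply(seq_len(n), function(k) gate_id_from_tt(brain$genes[k, 4:7]),
                character(1)),
    mutant_fitness = mutant_fitness,
    essential = mutant_fitness < intact
  )
}

#' @rdname knockout_assay
#' @return `essential_gates()` returns the integer indices of the
#'   essential gates.
#' @export
essential_gates <- function(brain, task) {
  if (nrow(brain$genes) == 0L) return(integer(0))
  assay <- knockout_assay(brain, task)
  assay$gate[assay$essential]
}

dedup_genes <- function(genes) {
  genes[!duplicated(genes), , drop = FALSE]
}

#' Gate-type composition of a cohort of brains
#'
#' Counts gates of each canonical type per brain. With `dedup = TRUE`
#' gates that are exact duplicates (same inputs, output and truth table)
#' are counted once. With `essential_only = TRUE` only gates essential
#' for `task` (single-knockout test) are counted.
#'
#' @param brains A list of [markov_brain()] objects.
#' @param essential_only Count only essential gates.
#' @param task Required when `essential_only = TRUE`.
#' @param dedup Drop duplicated gates before counting.
#' @return A tibble with columns `brain`, `id` (gate type), `name` and
#'   `count`, including zero counts so cohort means are straightforward.
#' @export
gate_composition <- function(brains, essential_only = FALSE, task = NULL,
                             dedup = TRUE) {
  cat <- gate_name_table()
  rows <- purrr::imap_dfr(brains, function(b, i) {
    genes <- b$genes
    if (essential_only) {
      if (is.null(task)) stop("`task` needed when essential_only = TRUE.",
                              call. = FALSE)
      genes <- genes[essential_gates(b, task), , drop = FALSE]
    }
    if (dedup) genes <- dedup_genes(genes)
    ids <- vapply(seq_len(nrow(genes)),
                  function(k) gate_id_from_tt(genes[k, 4:7]), character(1))
    tibble::tibble(brain = i, id = cat$id,
                   name = cat$name,
                   count = vapply(cat$id, function(g) sum(ids == g),
                                  numeric(1), USE.NAMES = FALSE))
  })
  rows
}

#' Theoretical transfer-entropy misestimate of a circuit
#'
#' Sums, over the essential gates of a brain, the analytic per-gate
#' transfer-entropy errors and correctly attributed flows of
#' [gate_table()], selecting the feedback columns for gates whose output
#' neuron is among their own inputs and the feedforward columns
#' otherwise. Per-gate values assume maximum-entropy inputs, so the
#' totals approximate (rather than measure) the in-circuit flow.
#'
#' The correctly attributed flow per gate is the sum of its two pairwise
#' terms minus its error: TE(x->z) + TE(y->z) in the feedforward case
#' and TE(y->z) + I(z:z1) minus the attribution mismatch in the feedback
#' case.
#'
#' @param brain A [markov_brain()].
#' @param essential Integer indices of essential gates; computed via
#'   `task` when omitted.
#' @param task Task used to determine essentiality when `essential` is
#'   missing.
#' @return A one-row tibble: `n_gates`, `n_essential`,
#'   `misestimate_bits`, `correct_bits`, and the per-essential-gate
#'   normalised `misestimate_per_gate`, `correct_per_gate`.
#' @export
theoretical_misestimate <- function(brain, essential = NULL, task = NULL) {
  if (is.null(essential)) {
    if (is.null(task)) stop("Provide `essential` or `task`.", call. = FALSE)
    essential <- essential_gates(brain, task)
  }
  tab <- gate_table()
  mis <- 0
  cor <- 0
  for (k in essential) {
    g <- brain$genes[k, ]
    row <- tab[tab$id == gate_id_from_tt(g[4:7]), ]
    if (g[["out"]] %in% c(g[["in1"]], g[["in2"]])) {
      mis <- mis + row$te_error_fb
      cor <- cor + row$te_y_fb + row$processed_fb - row$te_error_fb
    } else {
      mis <- mis + row$te_error_ff
      cor <- cor + row$te_x + row$te_y
    }
  }
  n_ess <- length(essential)
  tibble::tibble(
    n_gates = nrow(brain$genes),
    n_essential = n_ess,
    misestimate_bits = mis,
    correct_bits = cor,
    misestimate_per_gate = if (n_ess > 0) mis / n_ess else 0,
    correct_per_gate = if (n_ess > 0) cor / n_ess else 0
  )
}

#' Cohort summary with normal-approximation confidence intervals
#'
#' Means with 95% confidence intervals (mean +/- 1.96 SD/sqrt(n)) of
#' every numeric column of a per-brain table, e.g. the output of
#' [theoretical_misestimate()] row-bound over a cohort.
#'
#' @param df A data frame of per-brain values.
#' @return A tibble with one row per numeric column: `metric`, `n`,
#'   `mean`, `se`, `ci_lo`, `ci_hi`.
#' @export
cohort_summary <- function(df) {
  num <- df[vapply(df, is.numeric, logical(1))]
  purrr::imap_dfr(num, function(v, nm) {
    n <- sum(!is.na(v))
    m <- mean(v, na.rm = TRUE)
    se <- stats::sd(v, na.rm = TRUE) / sqrt(n)
    tibble::tibble(metric = nm, n = n, mean = m, se = se,
                   ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  })
}
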