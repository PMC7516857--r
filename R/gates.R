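#' Deterministic 2-to-1 Boolean gates
#'
#' A gate reads two neurons and writes one; its logic is a 4-bit truth
#' table giving the output for input pairs (00, 01, 10, 11) read as
#' (first input, second input). When the output neuron is also one of the
#' inputs the gate forms a feedback loop.
#'
#' @param in1,in2 Input neuron ids (0-based).
#' @param out Output neuron id (0-based).
#' @param truth_table Integer vector of 4 bits, outputs for inputs
#'   (00, 01, 10, 11).
#' @return A list of class `mb_gate`.
#' @export
gate <- function(in1, in2, out, truth_table) {
  if (length(truth_table) != 4L || !all(truth_table %in% c(0, 1))) {
    stop("`truth_table` must be 4 bits.", call. = FALSE)
  }
  structure(
    list(in1 = as.integer(in1), in2 = as.integer(in2), out = as.integer(out),
         truth_table = as.integer(truth_table)),
    class = "mb_gate"
  )
}

# Canonical names of the 16 truth tables, following the usual labelling of
# 2-to-1 logic: asymmetric AND/OR variants ("AND-NOT", "OR-NOT") negate one
# input, the two COPY/NOT variants pass through or negate a single input.
# `id` disambiguates duplicated display names by the input acted on.
gate_name_table <- function() {
  tibble::tribble(
    ~id,          ~name,      ~tt,
    "ZERO",       "ZERO",     c(0L, 0L, 0L, 0L),
    "AND",        "AND",      c(0L, 0L, 0L, 1L),
    "AND-NOT_X",  "AND-NOT",  c(0L, 0L, 1L, 0L),
    "AND-NOT_Y",  "AND-NOT",  c(0L, 1L, 0L, 0L),
    "NOR",        "NOR",      c(1L, 0L, 0L, 0L),
    "COPY_X",     "COPY",     c(0L, 0L, 1L, 1L),
    "COPY_Y",     "COPY",     c(0L, 1L, 0L, 1L),
    "XOR",        "XOR",      c(0L, 1L, 1L, 0L),
    "XNOR",       "XNOR",     c(1L, 0L, 0L, 1L),
    "NOT_Y",      "NOT",      c(1L, 0L, 1L, 0L),
    "NOT_X",      "NOT",      c(1L, 1L, 0L, 0L),
    "OR",         "OR",       c(0L, 1L, 1L, 1L),
    "OR-NOT_Y",   "OR-NOT",   c(1L, 0L, 1L, 1L),
    "OR-NOT_X",   "OR-NOT",   c(1L, 1L, 0L, 1L),
    "NAND",       "NAND",     c(1L, 1L, 1L, 0L),
    "ONE",        "ONE",      c(1L, 1L, 1L, 1L)
  )
}

#' Enumerate all 16 deterministic 2-to-1 gates
#'
#' @return A tibble with columns `id` (unique label), `name` (display
#'   name, duplicated across asymmetric variants) and `tt` (list column of
#'   4-bit truth tables for inputs 00, 01, 10, 11).
#' @export
enumerate_gates <- function() {
  gate_name_table()
}

gate_id_from_tt <- function(truth_table) {
  cat <- gate_name_table()
  idx <- which(vapply(cat$tt, identical, logical(1),
                      as.integer(truth_table)))
  cat$id[idx]
}

apply_tt <- function(tt, a, b) {
  tt[1L + 2L * a + b]
}

#' Analytic joint distribution of a gate process
#'
#' Feedforward wiring gives the joint of (x, y, z, z1) where z1 = f(x, y)
#' and x, y, z are independent uniform bits (z is the output's own,
#' uninfluential past). Feedback wiring gives the joint of (y, z, z1)
#' where z1 = f(y, z) with y, z independent uniform.
#'
#' @param truth_table 4-bit truth table (outputs for inputs 00, 01, 10, 11).
#' @param wiring `"feedforward"` or `"feedback"`.
#' @return A [joint_table()].
#' @export
analytic_joint <- function(truth_table, wiring = c("feedforward", "feedback")) {
  wiring <- match.arg(wiring)
  tt <- as.integer(truth_table)
  if (wiring == "feedforward") {
    states <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
    states$z1 <- apply_tt(tt, states$x, states$y)
    joint_table(states, rep(1 / 8, 8))
  } else {
    states <- expand.grid(y = 0:1, z = 0:1)
    states$z1 <- apply_tt(tt, states$y, states$z)
    joint_table(states, rep(1 / 4, 4))
  }
}

#' Classify a gate by how its output depends on its inputs
#'
#' `constant` gates ignore both inputs (ZERO, ONE); `dyadic` gates depend
#' on exactly one input (COPY/NOT variants); `cryptographic` gates are XOR
#' and XNOR, whose inputs each share zero information with the output
#' (one-time-pad structure); the remaining eight gates are `polyadic`
#' (AND/OR families), which depend on both inputs and partially obfuscate
#' them.
#'
#' @inheritParams analytic_joint
#' @return One of `"constant"`, `"dyadic"`, `"polyadic"`, `"cryptographic"`.
#' @export
classify_gate <- function(truth_table) {
  tt <- as.integer(truth_table)
  dep_x <- any(apply_tt(tt, 0L, 0:1) != apply_tt(tt, 1L, 0:1))
  dep_y <- any(apply_tt(tt, 0:1, 0L) != apply_tt(tt, 0:1, 1L))
  if (!dep_x && !dep_y) return("constant")
  if (xor(dep_x, dep_y)) return("dyadic")
  if (identical(tt, c(0L, 1L, 1L, 0L)) || identical(tt, c(1L, 0L, 0L, 1L))) {
    return("cryptographic")
  }
  "polyadic"
}

#' Analytic information quantities of a single gate
#'
#' Computes, for one truth table, the output entropy and pairwise
#' transfer entropies under maximum-entropy (uniform, independent) inputs,
#' for both wirings:
#'
#' * feedforward (z1 = f(x, y)): `h_out`, `te_x` = TE(x->z), `te_y` =
#'   TE(y->z), and the flow misestimate `te_error_ff` = H(z1) - te_x -
#'   te_y, which equals |I(x:y:z1|z)| — the information hidden from
#'   pairwise measures by encryption or obfuscation.
#' * feedback (z1 = f(y, z)): `te_y_fb` = TE(y->z), `processed_fb` =
#'   I(z:z1), and `te_error_fb`, the attribution mismatch |te_y_fb -
#'   processed_fb| for gates that depend on both inputs (zero otherwise):
#'   although the two terms always sum to H(z1), they split it unevenly
#'   between two equally influential sources.
#'
#' @inheritParams analytic_joint
#' @return A one-row tibble with columns `id`, `name`, `class`, `h_out`,
#'   `te_x`, `te_y`, `te_error_ff`, `te_y_fb`, `processed_fb`,
#'   `te_error_fb`.
#' @export
gate_analytics <- function(truth_table) {
  tt <- as.integer(truth_table)
  cls <- classify_gate(tt)
  ff <- analytic_joint(tt, "feedforward")
  fb <- analytic_joint(tt, "feedback")

  h_out <- entropy(ff, "z1")
  te_x <- conditional_mutual_information(ff, "x", "z1", "z")
  te_y <- conditional_mutual_information(ff, "y", "z1", "z")
  te_error_ff <- h_out - te_x - te_y

  te_y_fb <- conditional_mutual_information(fb, "y", "z1", "z")
  processed_fb <- mutual_information(fb, "z", "z1")
  depends_on_both <- cls %in% c("polyadic", "cryptographic")
  te_error_fb <- if (depends_on_both) abs(te_y_fb - processed_fb) else 0

  tibble::tibble(
    id = gate_id_from_tt(tt),
    name = gate_name_table()$name[gate_name_table()$id == gate_id_from_tt(tt)],
    class = cls,
    h_out = h_out,
    te_x = te_x,
    te_y = te_y,
    te_error_ff = te_error_ff,
    te_y_fb = te_y_fb,
    processed_fb = processed_fb,
    te_error_fb = te_error_fb
  )
}

#' Analytic gate table for all 16 gates
#'
#' One row per gate with the truth table and all analytic quantities of
#' [gate_analytics()], in the canonical enumeration order. Values are kept
#' at full precision; round at reporting time.
#'
#' @return A tibble with 16 rows.
#' @export
gate_table <- function() {
  cat <- gate_name_table()
  stats <- dplyr::bind_rows(lapply(cat$tt, gate_analytics))
  dplyr::bind_cols(cat["tt"], stats)[, c("id", "name", "class", "tt",
                                         "h_out", "te_x", "te_y",
                                         "te_error_ff", "te_y_fb",
                                         "processed_fb", "te_error_fb")]
}
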