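#' Discrete joint probability tables over named binary variables
#'
#' A `joint_table` is a tibble with one 0/1 column per variable and a
#' probability column `p`. It is the common currency of all exact
#' information quantities in the package: entropies, mutual informations,
#' transfer entropies and co-informations are computed by marginalising
#' and conditioning this table.
#'
#' @param states A data frame with one column per variable; entries must be
#'   0 or 1. Column names become the variable names.
#' @param p Numeric vector of probabilities, one per row of `states`.
#'   Must be non-negative and sum to 1 (within 1e-12). Rows with equal
#'   states are merged.
#' @return A tibble of class `joint_table` with the variable columns and `p`.
#' @examples
#' # Z = AND(X, Y) on uniform independent inputs
#' jt <- joint_table(
#'   expand.grid(x = 0:1, y = 0:1),
#'   p = rep(1 / 4, 4)
#' )
#' entropy(jt, "x")
#' @export
joint_table <- function(states, p) {
  states <- tibble::as_tibble(states)
  if (ncol(states) == 0L) {
    stop("`states` must have at least one variable column.", call. = FALSE)
  }
  if ("p" %in% names(states)) {
    stop("`states` must not contain a column named 'p'.", call. = FALSE)
  }
  if (!all(vapply(states, function(v) all(v %in% c(0, 1)), logical(1)))) {
    stop("All state entries must be 0 or 1.", call. = FALSE)
  }
  if (length(p) != nrow(states)) {
    stop("`p` must have one entry per state.", call. = FALSE)
  }
  if (any(p < -1e-12)) {
    stop("Probabilities must be non-negative.", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("Probabilities must sum to 1 (within 1e-12).", call. = FALSE)
  }
  out <- states
  out$p <- pmax(p, 0)
  out <- dplyr::summarise(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(names(states)))),
    p = sum(.data$p), .groups = "drop"
  )
  class(out) <- c("joint_table", class(out))
  out
}

#' @export
print.joint_table <- function(x, ...) {
  cat("<joint_table> over {", paste(jt_variables(x), collapse = ", "), "}\n",
      sep = "")
  NextMethod()
}

#' Variable names of a joint table
#'
#' @param joint A [joint_table()].
#' @return Character vector of variable names (all columns except `p`).
#' @export
jt_variables <- function(joint) {
  setdiff(names(joint), "p")
}

check_vars <- function(joint, vars, arg = "vars") {
  unknown <- setdiff(vars, jt_variables(joint))
  if (length(unknown) > 0) {
    stop("Unknown variable(s) in `", arg, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(vars)
}

check_disjoint <- function(...) {
  sets <- list(...)
  all_vars <- unlist(sets)
  if (anyDuplicated(all_vars)) {
    stop("Variable sets must be disjoint; overlapping: ",
         paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(NULL)
}

marginal_p <- function(joint, vars) {
  if (length(vars) == 0L) return(1)
  dplyr::summarise(
    dplyr::group_by(joint, dplyr::across(dplyr::all_of(vars))),
    p = sum(.data$p), .groups = "drop"
  )$p
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a marginal
#'
#' Computes the entropy, in bits, of the marginal distribution of `vars`
#' under the joint table (base-2 logarithm, with the convention
#' 0 log 0 = 0).
#'
#' @param joint A [joint_table()].
#' @param vars Non-empty character vector of variable names.
#' @return Entropy in bits, between 0 and `length(vars)`.
#' @export
entropy <- function(joint, vars) {
  if (length(vars) == 0L) {
    stop("`vars` must name at least one variable.", call. = FALSE)
  }
  check_vars(joint, vars)
  shannon(marginal_p(joint, vars))
}

#' Mutual information and conditional mutual information
#'
#' `mutual_information()` returns I(A:B) = H(A) + H(B) - H(A,B);
#' `conditional_mutual_information()` returns
#' I(A:B|C) = H(A,C) + H(B,C) - H(A,B,C) - H(C). Tiny negative values from
#' floating-point cancellation are clamped to zero.
#'
#' @inheritParams entropy
#' @param a,b,c Disjoint sets of variable names (`c` may be empty, in which
#'   case the conditional form reduces to the unconditional one).
#' @return Information in bits (non-negative).
#' @export
mutual_information <- function(joint, a, b) {
  conditional_mutual_information(joint, a, b, character(0))
}

#' @rdname mutual_information
#' @export
conditional_mutual_information <- function(joint, a, b, c = character(0)) {
  check_vars(joint, c(a, b, c))
  check_disjoint(a, b, c)
  v <- entropy(joint, c(a, c)) + entropy(joint, c(b, c)) -
    entropy(joint, c(a, b, c)) -
    (if (length(c) > 0) entropy(joint, c) else 0)
  max(v, 0)
}

#' Co-information of three variable sets
#'
#' I(A:B:C) = I(A:B) - I(A:B|C). Symmetric under any permutation of its
#' three arguments; negative values indicate synergy (encryption-like
#' relations such as XOR give -1 bit).
#'
#' @inheritParams mutual_information
#' @param cond Optional extra conditioning set: I(A:B:C|cond).
#' @return Co-information in bits; may be negative.
#' @export
co_information <- function(joint, a, b, c, cond = character(0)) {
  check_vars(joint, c(a, b, c, cond))
  check_disjoint(a, b, c, cond)
  conditional_mutual_information(joint, a, b, cond) -
    conditional_mutual_information(joint, a, b, c(c, cond))
}

#' Residual of the entropy decompositions of the gate process
#'
#' For a process Z with candidate sources, the output entropy H(z1)
#' (z1 is Z one step ahead) decomposes into transfer-entropy-like terms.
#' This function evaluates H(z1) minus the right-hand side of the chosen
#' identity; for any joint table satisfying the identity's preconditions
#' the residual is zero to numerical precision.
#'
#' * `"feedforward"`: over variables x, y, z, z1 with z1 a deterministic
#'   function of (x, y) and z independent of them:
#'   H(z1) = TE(y->z | x) + TE(x->z | y) + I(x:y:z1 | z).
#' * `"feedback"`: over y, z, z1 with z1 deterministic given (y, z):
#'   H(z1) = TE(y->z) + I(z:z1).
#' * `"general"`: over x, y, z, z1, no preconditions:
#'   H(z1) = TE(y->z | x) + TE(x->z | y) + I(x:y:z1 | z) + I(z:z1) +
#'   H(z1 | x, y, z).
#'
#' @param joint A [joint_table()] over variables `x`, `y`, `z`, `z1`
#'   (feedforward/general) or `y`, `z`, `z1` (feedback).
#' @param mode One of `"feedforward"`, `"feedback"`, `"general"`.
#' @return The residual in bits (should be ~0 when preconditions hold).
#' @export
decomposition_residual <- function(joint,
                                   mode = c("feedforward", "feedback",
                                            "general")) {
  mode <- match.arg(mode)
  if (mode == "feedback") {
    check_vars(joint, c("y", "z", "z1"))
    rhs <- conditional_mutual_information(joint, "y", "z1", "z") +
      mutual_information(joint, "z", "z1")
    return(entropy(joint, "z1") - rhs)
  }
  check_vars(joint, c("x", "y", "z", "z1"))
  te_y_given_x <- conditional_mutual_information(joint, "y", "z1", c("z", "x"))
  te_x_given_y <- conditional_mutual_information(joint, "x", "z1", c("z", "y"))
  coi <- co_information(joint, "x", "y", "z1", cond = "z")
  rhs <- te_y_given_x + te_x_given_y + coi
  if (mode == "general") {
    rhs <- rhs + mutual_information(joint, "z", "z1") +
      entropy(joint, c("x", "y", "z", "z1")) - entropy(joint, c("x", "y", "z"))
  }
  entropy(joint, "z1") - rhs
}

#' Random joint tables for property checks
#'
#' `random_joint_table()` draws a full-support random distribution over `k`
#' named binary variables (normalised exponential weights, so the table is
#' exchangeable over states). `random_feedforward_joint()` and
#' `random_feedback_joint()` draw random tables that satisfy the
#' preconditions of the corresponding entropy decomposition: a random
#' deterministic truth table for z1 and (for the feedforward case) a `z`
#' independent of the inputs.
#'
#' Randomness comes from the session RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param variables Character vector of variable names.
#' @return A [joint_table()].
#' @export
random_joint_table <- function(variables = c("x", "y", "z", "z1")) {
  k <- length(variables)
  states <- binary_states(k)
  names(states) <- variables
  w <- stats::rexp(nrow(states))
  joint_table(states, w / sum(w))
}

#' @rdname random_joint_table
#' @export
random_feedforward_joint <- function() {
  f <- sample(0:1, 4, replace = TRUE)
  w_xy <- stats::rexp(4); w_xy <- w_xy / sum(w_xy)
  pz1 <- stats::runif(1)
  xy <- expand.grid(x = 0:1, y = 0:1)
  states <- tidyr::crossing(xy, z = 0:1)
  idx <- 1 + 2 * states$x + states$y
  states$z1 <- f[idx]
  p <- w_xy[idx] * ifelse(states$z == 1, pz1, 1 - pz1)
  joint_table(states, p)
}

#' @rdname random_joint_table
#' @export
random_feedback_joint <- function() {
  f <- sample(0:1, 4, replace = TRUE)
  w <- stats::rexp(4); w <- w / sum(w)
  states <- expand.grid(y = 0:1, z = 0:1)
  idx <- 1 + 2 * states$y + states$z
  states$z1 <- f[idx]
  joint_table(states, w[idx])
}

binary_states <- function(k) {
  stats::setNames(
    expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE),
    paste0("v", seq_len(k))
  )
}

#' Read and write joint tables as JSON
#'
#' The JSON form stores the ordered variable names and a map from the
#' concatenated bit string of each state (in variable order) to its
#' probability.
#'
#' @param joint A [joint_table()].
#' @param path File path.
#' @return `write_joint_table()` returns `joint` invisibly;
#'   `read_joint_table()` returns a [joint_table()].
#' @export
write_joint_table <- function(joint, path) {
  vars <- jt_variables(joint)
  keys <- apply(as.matrix(joint[vars]), 1, paste, collapse = "")
  obj <- list(
    variables = vars,
    probabilities = stats::setNames(as.list(joint$p), keys)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(joint)
}

#' @rdname write_joint_table
#' @export
read_joint_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- obj$variables
  keys <- names(obj$probabilities)
  bits <- do.call(rbind, lapply(strsplit(keys, ""), as.integer))
  states <- stats::setNames(as.data.frame(bits), vars)
  joint_table(states, unname(unlist(obj$probabilities)))
}
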