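#' Markov Brains: deterministic networks of binary neurons
#'
#' A Markov Brain is a fixed set of binary neurons updated synchronously
#' by deterministic 2-to-1 logic gates. The genome is the gate list
#' itself: an integer matrix with one row per gate and columns `in1`,
#' `in2`, `out` (0-based neuron ids) and `tt00`, `tt01`, `tt10`, `tt11`
#' (the truth table for input pairs 00, 01, 10, 11).
#'
#' Update semantics: each gate reads the current state; every neuron that
#' at least one gate writes takes the bitwise OR of the incoming gate
#' outputs; a non-sensory neuron that no gate writes decays to 0
#' (quiescent); a sensory neuron that no gate writes holds its current
#' (externally clamped) value.
#'
#' @param genes Integer matrix with 7 columns as above (0 rows allowed),
#'   or a list of [gate()] objects.
#' @param n_neurons Number of neurons (default 16).
#' @param sensory_ids 0-based ids of sensory neurons.
#' @param output_ids 0-based ids of designated output (actuator) neurons.
#' @return A list of class `markov_brain`.
#' @export
markov_brain <- function(genes, n_neurons = 16L, sensory_ids = c(0L, 1L),
                         output_ids = integer(0)) {
  genes <- as_gene_matrix(genes)
  n_neurons <- as.integer(n_neurons)
  if (nrow(genes) > 0) {
    ids <- genes[, c("in1", "in2", "out")]
    if (any(ids < 0L) || any(ids >= n_neurons)) {
      stop("Gate neuron ids must lie in [0, ", n_neurons - 1L, "].",
           call. = FALSE)
    }
    if (!all(genes[, 4:7] %in% c(0L, 1L))) {
      stop("Truth-table entries must be 0 or 1.", call. = FALSE)
    }
  }
  structure(
    list(n_neurons = n_neurons, genes = genes,
         sensory_ids = as.integer(sensory_ids),
         output_ids = as.integer(output_ids)),
    class = "markov_brain"
  )
}

gene_cols <- c("in1", "in2", "out", "tt00", "tt01", "tt10", "tt11")

as_gene_matrix <- function(genes) {
  if (is.list(genes) && !is.data.frame(genes)) {
    rows <- lapply(genes, function(g) {
      c(g$in1, g$in2, g$out, g$truth_table)
    })
    genes <- do.call(rbind, c(rows, list(matrix(integer(0), 0, 7))))
  }
  genes <- matrix(as.integer(genes), ncol = 7,
                  dimnames = list(NULL, gene_cols))
  genes
}

#' @export
print.markov_brain <- function(x, ...) {
  cat("<markov_brain> ", x$n_neurons, " neurons, ", nrow(x$genes),
      " gates; sensory {", paste(x$sensory_ids, collapse = ","),
      "}, outputs {", paste(x$output_ids, collapse = ","), "}\n", sep = "")
  invisible(x)
}

resolve_clamp <- function(brain, clamp) {
  if (is.null(clamp)) return(NULL)
  if (is.null(names(clamp))) {
    if (length(clamp) != length(brain$sensory_ids)) {
      stop("Unnamed `clamp` must have one value per sensory neuron.",
           call. = FALSE)
    }
    ids <- brain$sensory_ids
  } else {
    ids <- as.integer(names(clamp))
  }
  if (!all(ids %in% brain$sensory_ids)) {
    stop("Clamp applies only to sensory neurons (",
         paste(brain$sensory_ids, collapse = ", "), ").", call. = FALSE)
  }
  stats::setNames(as.integer(clamp), ids)
}

#' Advance a Markov Brain by one synchronous update
#'
#' The clamp (stimulus) is written into the sensory neurons of `state`
#' first; every gate then reads the clamped state, and the next state is
#' assembled under the OR-combination rule described in [markov_brain()].
#'
#' @param brain A [markov_brain()].
#' @param state Integer vector of 0/1 of length `n_neurons`.
#' @param clamp Optional stimulus: an unnamed vector with one value per
#'   sensory neuron, or a named vector (names are neuron ids) for a
#'   partial assignment. Clamping a non-sensory neuron is an error.
#' @return The next state (integer vector).
#' @export
update_brain <- function(brain, state, clamp = NULL) {
  stopifnot(length(state) == brain$n_neurons)
  state <- as.integer(state)
  cl <- resolve_clamp(brain, clamp)
  if (!is.null(cl)) state[as.integer(names(cl)) + 1L] <- cl
  nxt <- integer(brain$n_neurons)
  written <- logical(brain$n_neurons)
  g <- brain$genes
  for (k in seq_len(nrow(g))) {
    v <- g[k, 3L + 1L + 2L * state[g[k, 1L] + 1L] + state[g[k, 2L] + 1L]]
    j <- g[k, 3L] + 1L
    nxt[j] <- max(nxt[j], v)
    written[j] <- TRUE
  }
  hold <- !written & seq_len(brain$n_neurons) %in% (brain$sensory_ids + 1L)
  nxt[hold] <- state[hold]
  nxt
}

# Vectorised update over a matrix of states (rows = cases), no clamp.
update_states <- function(brain, states) {
  n <- brain$n_neurons
  nxt <- matrix(0L, nrow(states), n)
  written <- logical(n)
  g <- brain$genes
  for (k in seq_len(nrow(g))) {
    idx <- 1L + 2L * states[, g[k, 1L] + 1L] + states[, g[k, 2L] + 1L]
    v <- g[k, 3L + idx]
    j <- g[k, 3L] + 1L
    nxt[, j] <- pmax(nxt[, j], v)
    written[j] <- TRUE
  }
  hold <- which(!written & seq_len(n) %in% (brain$sensory_ids + 1L))
  for (j in hold) nxt[, j] <- states[, j]
  nxt
}

#' Full logic table of a Markov Brain
#'
#' Evaluates the unclamped update on every one of the 2^n states,
#' yielding each neuron's next value as a Boolean function of the full
#' current state.
#'
#' @param brain A [markov_brain()] (n_neurons <= 20).
#' @return Integer matrix of dimension 2^n x n: row s + 1 holds the next
#'   state reached from the state whose bits (neuron 0 = least
#'   significant) encode the integer s.
#' @export
logic_table <- function(brain) {
  n <- brain$n_neurons
  if (n > 20L) stop("Logic table requires n_neurons <= 20.", call. = FALSE)
  s <- 0:(2^n - 1)
  states <- vapply(seq_len(n), function(j) bitwAnd(bitwShiftR(s, j - 1L), 1L),
                   integer(length(s)))
  update_states(brain, states)
}

#' Ground-truth influence map of a Markov Brain
#'
#' The influence map is the binary matrix of direct neuron-to-neuron
#' influences: entry (i, j) is 1 when the next value of neuron j, as a
#' Boolean function of the full current state, actually depends on the
#' current value of neuron i (some state exists where flipping bit i
#' flips j's next value). Deriving influence from functional dependence
#' rather than raw wiring automatically discards constant (ZERO/ONE)
#' gates and vestigial gate inputs that never affect the output.
#'
#' Dependence is tested exactly on each neuron's support (the inputs of
#' the gates that write it), which is equivalent to testing all 2^n
#' single-bit flips. Columns of sensory neurons are zeroed when
#' `clamp_sensory` is `TRUE` (the default): during behaviour their value
#' is set by the stimulus, so nothing inside the circuit truly influences
#' them.
#'
#' @param brain A [markov_brain()].
#' @param clamp_sensory Zero the columns of sensory neurons (default TRUE).
#' @return An n x n 0/1 matrix of class `influence_map` (rows = sources,
#'   columns = destinations), dimnames `N0` ... Self-influence appears on
#'   the diagonal; detection scoring excludes it by default.
#' @export
influence_map <- function(brain, clamp_sensory = TRUE) {
  n <- brain$n_neurons
  m <- matrix(0L, n, n,
              dimnames = list(paste0("N", 0:(n - 1)), paste0("N", 0:(n - 1))))
  g <- brain$genes
  for (j in seq_len(n) - 1L) {
    writers <- which(g[, "out"] == j)
    if (length(writers) == 0L) {
      if (j %in% brain$sensory_ids) m[j + 1L, j + 1L] <- 1L
      next
    }
    support <- sort(unique(as.integer(g[writers, c("in1", "in2")])))
    k <- length(support)
    assign <- as.matrix(expand.grid(rep(list(0:1), k)))
    f <- rep(0L, nrow(assign))
    for (w in writers) {
      a <- assign[, match(g[w, "in1"], support)]
      b <- assign[, match(g[w, "in2"], support)]
      f <- pmax(f, g[w, 3L + 1L + 2L * a + b])
    }
    for (pos in seq_len(k)) {
      i0 <- assign[, pos] == 0L
      other <- assign[, -pos, drop = FALSE]
      if (ncol(other) == 0L) {
        if (any(f[i0] != f[!i0])) m[support[pos] + 1L, j + 1L] <- 1L
        next
      }
      key0 <- apply(other[i0, , drop = FALSE], 1, paste, collapse = ",")
      key1 <- apply(other[!i0, , drop = FALSE], 1, paste, collapse = ",")
      f1 <- f[!i0][match(key0, key1)]
      if (any(f[i0] != f1)) m[support[pos] + 1L, j + 1L] <- 1L
    }
  }
  if (clamp_sensory) m[, brain$sensory_ids + 1L] <- 0L
  class(m) <- c("influence_map", class(m))
  m
}

#' @export
print.influence_map <- function(x, ...) {
  cat("<influence_map> ", sum(x), " directed edges\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Tidy an influence map into a long tibble
#'
#' @param x An [influence_map()].
#' @param ... Unused.
#' @return A tibble with columns `source`, `destination` (0-based ids)
#'   and `edge` (0/1).
#' @method tidy influence_map
#' @export
tidy.influence_map <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    source = rep(0:(n - 1), times = n),
    destination = rep(0:(n - 1), each = n),
    edge = as.integer(x[cbind(rep(1:n, times = n), rep(1:n, each = n))])
  )
}

#' Serialise Markov Brains as JSON genomes
#'
#' The JSON form records the neuron count, sensory and output ids, and
#' the gene list; `read_brain_json(write_brain_json(b, path))` round-trips
#' exactly.
#'
#' @param brain A [markov_brain()].
#' @param path File path.
#' @return `write_brain_json()` returns `brain` invisibly;
#'   `read_brain_json()` returns a [markov_brain()].
#' @export
write_brain_json <- function(brain, path) {
  obj <- list(
    n_neurons = brain$n_neurons,
    sensory_ids = brain$sensory_ids,
    output_ids = brain$output_ids,
    genes = apply(brain$genes, 1, function(r) {
      list(in1 = r[["in1"]], in2 = r[["in2"]], out = r[["out"]],
           truth_table = unname(r[4:7]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(brain)
}

#' @rdname write_brain_json
#' @export
read_brain_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- do.call(rbind, c(lapply(obj$genes, function(g) {
    c(g$in1, g$in2, g$out, unlist(g$truth_table))
  }), list(matrix(integer(0), 0, 7))))
  markov_brain(genes,
               n_neurons = obj$n_neurons,
               sensory_ids = unlist(obj$sensory_ids) %||% integer(0),
               output_ids = unlist(obj$output_ids) %||% integer(0))
}

#' Export a brain's wiring as a DOT graph
#'
#' Writes a directed graph with one node per used neuron and, for every
#' gate, edges from its inputs to its output labelled with the gate type
#' (for circuit diagrams via Graphviz).
#'
#' @param brain A [markov_brain()].
#' @param path File path.
#' @return `brain`, invisibly.
#' @export
write_brain_dot <- function(brain, path) {
  g <- brain$genes
  lines <- c("digraph brain {", "  rankdir=LR;")
  for (k in seq_len(nrow(g))) {
    id <- gate_id_from_tt(g[k, 4:7])
    lines <- c(lines,
               sprintf("  N%d -> N%d [label=\"%s\"];", g[k, "in1"], g[k, "out"], id),
               sprintf("  N%d -> N%d [label=\"%s\"];", g[k, "in2"], g[k, "out"], id))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(brain)
}

with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random Markov Brains
#'
#' Draws `n_gates` gates with truth tables sampled from the 16-gate
#' catalog (optionally weighted) and connections uniform over neurons.
#'
#' @param n_gates Number of gates.
#' @param gate_type_weights Optional numeric vector of length 16 (catalog
#'   order, see [enumerate_gates()]) of sampling weights.
#' @param seed Optional integer seed; the session RNG state is preserved.
#' @param n_neurons,sensory_ids,output_ids Passed to [markov_brain()].
#' @return A [markov_brain()].
#' @export
random_brain <- function(n_gates, gate_type_weights = NULL, seed = NULL,
                         n_neurons = 16L, sensory_ids = c(0L, 1L),
                         output_ids = integer(0)) {
  with_preserved_seed(seed, {
    cat <- gate_name_table()
    types <- sample.int(16L, n_gates, replace = TRUE, prob = gate_type_weights)
    genes <- do.call(rbind, c(lapply(types, function(t) {
      c(sample.int(n_neurons, 2L, replace = TRUE) - 1L,
        sample.int(n_neurons, 1L) - 1L,
        cat$tt[[t]])
    }), list(matrix(integer(0), 0, 7))))
    markov_brain(genes, n_neurons = n_neurons, sensory_ids = sensory_ids,
                 output_ids = output_ids)
  })
}

#' Exhaustively sampled one-step recording
#'
#' Builds a recording in which every assignment of the chosen neurons
#' (all others 0) is a separate two-snapshot trial: the initial state and
#' the state one unclamped update later. On such a recording the plug-in
#' estimators coincide exactly with the analytic values for the gates
#' involved, because every transition of the process is observed exactly
#' once.
#'
#' @param brain A [markov_brain()].
#' @param neurons Neuron ids (0-based) to enumerate over; default all
#'   neurons appearing in a gate.
#' @return An `mb_recording` with 2^length(neurons) trials.
#' @export
exhaustive_recording <- function(brain, neurons = NULL) {
  if (is.null(neurons)) {
    neurons <- sort(unique(as.integer(brain$genes[, c("in1", "in2", "out")])))
  }
  if (length(neurons) > 16L) {
    stop("Exhaustive enumeration limited to 16 neurons.", call. = FALSE)
  }
  assign <- as.matrix(expand.grid(rep(list(0:1), length(neurons))))
  trials <- lapply(seq_len(nrow(assign)), function(r) {
    s <- integer(brain$n_neurons)
    s[neurons + 1L] <- assign[r, ]
    rbind(s, update_brain(brain, s))
  })
  as_recording(trials)
}
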