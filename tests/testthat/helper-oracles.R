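# Independent oracles, written with plain loops and the raw definitions
# so they share no code path with the package functions they check.

log2s <- function(p) ifelse(p > 0, log2(p), 0)

# Entropy of a marginal by direct summation over an enumerated joint.
# `joint_df` is a data frame of 0/1 columns plus `p`.
oracle_entropy <- function(joint_df, vars) {
  key <- do.call(paste, joint_df[vars])
  p <- tapply(joint_df$p, key, sum)
  -sum(p * log2s(p))
}

oracle_cmi <- function(joint_df, a, b, cond = character(0)) {
  h <- function(v) oracle_entropy(joint_df, v)
  val <- h(c(a, cond)) + h(c(b, cond)) - h(c(a, b, cond)) -
    (if (length(cond)) h(cond) else 0)
  val
}

# Closed-form quantities for a 2-to-1 gate under uniform inputs, by
# enumerating the <= 16-state joint directly from the truth table.
oracle_gate_ff <- function(tt) {
  df <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  df$z1 <- tt[1 + 2 * df$x + df$y]
  df$p <- 1 / 8
  list(
    h_out = oracle_entropy(df, "z1"),
    te_x = oracle_cmi(df, "x", "z1", "z"),
    te_y = oracle_cmi(df, "y", "z1", "z")
  )
}

oracle_gate_fb <- function(tt) {
  df <- expand.grid(y = 0:1, z = 0:1)
  df$z1 <- tt[1 + 2 * df$y + df$z]
  df$p <- 1 / 4
  list(
    te_y = oracle_cmi(df, "y", "z1", "z"),
    processed = oracle_cmi(df, "z", "z1")
  )
}

# Brute-force influence map: simulate the update on every state and on
# every state with one bit flipped, and mark dependence wherever the
# destination's next value differs. Applies the same sensory-column
# convention as influence_map().
oracle_influence_flip <- function(brain) {
  n <- brain$n_neurons
  lt <- logic_table(brain)
  m <- matrix(0L, n, n)
  s <- 0:(2^n - 1)
  for (i in seq_len(n)) {
    partner <- bitwXor(s, bitwShiftL(1L, i - 1L)) + 1L
    diff <- lt != lt[partner, , drop = FALSE]
    m[i, ] <- as.integer(colSums(diff) > 0)
  }
  m[, brain$sensory_ids + 1L] <- 0L
  m
}

# Renumber every neuron of a brain under a permutation `perm` (0-based
# mapping: new id of neuron i is perm[i + 1]).
permute_brain <- function(brain, perm) {
  g <- brain$genes
  g[, c("in1", "in2", "out")] <- matrix(perm[g[, c("in1", "in2", "out")] + 1L],
                                        ncol = 3)
  markov_brain(g, n_neurons = brain$n_neurons,
               sensory_ids = perm[brain$sensory_ids + 1L],
               output_ids = perm[brain$output_ids + 1L])
}
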