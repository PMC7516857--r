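#' Named fixture circuits with known ground truth
#'
#' Hand-built Markov Brains whose logic, influence map and task fitness
#' are known by construction, so every pipeline stage can be tested
#' without running evolution:
#'
#' * `"gate_<ID>"` — one feedforward gate of the given catalog type (see
#'   [enumerate_gates()]) reading N0, N1 and writing N2.
#' * `"gate_<ID>_fb"` — the same gate wired as a feedback loop: it reads
#'   (N1, N2) and writes N2.
#' * `"xor_pair"` — XOR of N0, N1 into N2 (the canonical cryptographic
#'   relation: both true edges carry zero pairwise TE).
#' * `"md_solver"` — a delay-and-compare circuit that stores the first
#'   stimulus frame in memory neurons, compares it with the second, and
#'   scores perfectly on the motion-detection task.
#' * `"sl_solver"` — a Jeffress-style circuit: two delay lines (one per
#'   ear) feeding five coincidence detectors on the output neurons, and
#'   scoring perfectly on the sound-localization task.
#' * `"dup_gate"` — the MD solver with one gate duplicated exactly, so
#'   either copy can be knocked out without losing fitness.
#' * `"vestigial"` — a single pass-through gate whose second input never
#'   affects the output, so the influence map must drop that edge.
#'
#' @param name Fixture name.
#' @return A list with `brain` (a [markov_brain()]) and `expected`, a
#'   list of stored expectations (`edges`: two-column matrix of 0-based
#'   source/destination pairs where applicable; `md_fitness` /
#'   `sl_fitness` for the solvers).
#' @export
build_named_fixture <- function(name) {
  fx <- fixture_specs()
  if (!name %in% names(fx)) {
    stop("Unknown fixture '", name, "'. Available: ",
         paste(names(fx), collapse = ", "), call. = FALSE)
  }
  fx[[name]]()
}

#' @rdname build_named_fixture
#' @export
fixture_names <- function() names(fixture_specs())

gn <- function(in1, in2, out, tt) c(in1, in2, out, tt)

fixture_specs <- function() {
  cat <- gate_name_table()
  specs <- list()

  for (k in seq_len(16)) {
    id <- cat$id[k]
    tt <- cat$tt[[k]]
    local({
      tt_k <- tt
      specs[[paste0("gate_", id)]] <<- function() {
        b <- markov_brain(rbind(gn(0L, 1L, 2L, tt_k)),
                          sensory_ids = integer(0))
        cls <- classify_gate(tt_k)
        edges <- switch(cls,
          constant = cbind(integer(0), integer(0)),
          dyadic = {
            dep_x <- any(apply_tt(tt_k, 0L, 0:1) != apply_tt(tt_k, 1L, 0:1))
            cbind(if (dep_x) 0L else 1L, 2L)
          },
          cbind(c(0L, 1L), c(2L, 2L))
        )
        list(brain = b, expected = list(edges = edges))
      }
      specs[[paste0("gate_", id, "_fb")]] <<- function() {
        b <- markov_brain(rbind(gn(1L, 2L, 2L, tt_k)),
                          sensory_ids = integer(0))
        list(brain = b, expected = list())
      }
    })
  }

  specs$xor_pair <- function() {
    b <- markov_brain(rbind(gn(0L, 1L, 2L, c(0L, 1L, 1L, 0L))),
                      sensory_ids = integer(0))
    list(brain = b, expected = list(edges = cbind(c(0L, 1L), c(2L, 2L))))
  }

  specs$vestigial <- function() {
    # pass-through of N0; N1 is wired in but never matters
    b <- markov_brain(rbind(gn(0L, 1L, 2L, c(0L, 0L, 1L, 1L))),
                      sensory_ids = integer(0))
    list(brain = b, expected = list(edges = cbind(0L, 2L)))
  }

  specs$md_solver <- function() {
    list(brain = md_solver_brain(), expected = list(md_fitness = 1))
  }

  specs$dup_gate <- function() {
    b <- md_solver_brain()
    b$genes <- rbind(b$genes, b$genes[1, ])
    rownames(b$genes) <- NULL
    list(brain = b, expected = list(md_fitness = 1, duplicated = c(1L, nrow(b$genes))))
  }

  specs$sl_solver <- function() {
    list(brain = sl_solver_brain(), expected = list(sl_fitness = 1))
  }

  specs
}

# Delay-and-compare motion detector. Memory neurons N2, N3 hold the
# first frame; at the second update a bank of comparison gates computes
# the direction predicates from (old frame, new frame); at the third
# update the output pair N14 (PD detector) and N15 (not-ND detector) is
# assembled so the output sum codes ND = 0, stationary = 1, PD = 2.
md_solver_brain <- function() {
  COPY  <- c(0L, 0L, 1L, 1L)  # first input
  ANDN  <- c(0L, 0L, 1L, 0L)  # in1 AND NOT in2
  NOR   <- c(1L, 0L, 0L, 0L)
  AND   <- c(0L, 0L, 0L, 1L)
  NOT1  <- c(1L, 1L, 0L, 0L)  # NOT in1
  genes <- rbind(
    gn(0L, 0L, 2L, COPY),    # N2  <- a (previous frame after next update)
    gn(1L, 1L, 3L, COPY),    # N3  <- b
    gn(2L, 0L, 4L, ANDN),    # N4  <- a1 & !a2   (at update 2)
    gn(1L, 1L, 5L, COPY),    # N5  <- b2
    gn(2L, 3L, 6L, NOR),     # N6  <- !a1 & !b1
    gn(0L, 1L, 7L, ANDN),    # N7  <- a2 & !b2
    gn(3L, 2L, 8L, ANDN),    # N8  <- b1 & !a1
    gn(0L, 0L, 9L, COPY),    # N9  <- a2
    gn(3L, 3L, 10L, COPY),   # N10 <- b1
    gn(2L, 2L, 11L, COPY),   # N11 <- a1
    gn(4L, 5L, 14L, AND),    # PD term (a1 & !a2) & b2
    gn(6L, 7L, 14L, AND),    # PD term (!a1 & !b1) & (a2 & !b2)
    gn(10L, 10L, 15L, NOT1), # !ND term !b1
    gn(9L, 9L, 15L, NOT1),   # !ND term !a2
    gn(11L, 5L, 15L, AND)    # !ND term a1 & b2
  )
  markov_brain(genes, sensory_ids = c(0L, 1L), output_ids = c(14L, 15L))
}

# Jeffress-style sound localizer: COPY chains N0->N2->N4 and
# N1->N3->N5 delay each ear's pulse by one and two steps; at the final
# update the five AND gates fire one coincidence detector per lag.
sl_solver_brain <- function() {
  COPY <- c(0L, 0L, 1L, 1L)
  AND  <- c(0L, 0L, 0L, 1L)
  genes <- rbind(
    gn(0L, 0L, 2L, COPY),
    gn(1L, 1L, 3L, COPY),
    gn(2L, 2L, 4L, COPY),
    gn(3L, 3L, 5L, COPY),
    gn(0L, 5L, 11L, AND),   # lag -2: left now, right two steps ago
    gn(2L, 5L, 12L, AND),   # lag -1
    gn(4L, 5L, 13L, AND),   # lag  0
    gn(4L, 3L, 14L, AND),   # lag +1
    gn(4L, 1L, 15L, AND)    # lag +2: left two steps ago, right now
  )
  markov_brain(genes, sensory_ids = c(0L, 1L), output_ids = 11:15)
}
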