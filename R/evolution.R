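#' Genetic-algorithm configuration
#'
#' Defaults: populations of 100 genomes evolved for up to 10,000
#' generations (stopping early once fitness is perfect) in 20 replicate
#' populations, tournament selection (size 2) on a graded per-trial
#' score with one elite, per-site point-mutation rate 0.01 (connection
#' ids are resampled, truth-table bits flipped), per-genome gene
#' duplication/insertion rate 0.1 and deletion rate 0.02, and initial
#' genomes of 8-12 random genes.
#'
#' @param population_size Genomes per population.
#' @param generations Generations per replicate.
#' @param replicates Independent replicate populations.
#' @param point_rate Per-site point-mutation probability (a gene has 7
#'   sites: two input ids, one output id, four truth-table bits).
#' @param insertion_rate Per-genome probability of duplicating a random
#'   gene (a fresh random gene if the genome is empty).
#' @param deletion_rate Per-genome probability of deleting a random gene.
#' @param init_genes Length-2 integer range for initial gene counts.
#' @param tournament_size Tournament size (ties go to the first-drawn
#'   contestant).
#' @param elitism Number of elites copied unchanged (ties broken by
#'   earliest index).
#' @param n_neurons Neurons per brain.
#' @param seed Master seed; replicate seeds are derived from it by
#'   drawing `replicates` integers from the seeded R generator.
#' @param stop_when_perfect Stop a replicate once maximum fitness reaches
#'   1 (the elite is preserved, so the champion is unchanged; only the
#'   trace is shortened).
#' @param shaped_selection Select on the graded per-trial score (partial
#'   credit for near-correct outputs) instead of the raw
#'   fraction-correct fitness. Reported fitness, traces and the
#'   perfect-fitness criterion always use the exact fraction correct.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 100L, generations = 10000L,
                             replicates = 20L, point_rate = 0.01,
                             insertion_rate = 0.1, deletion_rate = 0.02,
                             init_genes = c(8L, 12L), tournament_size = 2L,
                             elitism = 1L, n_neurons = 16L, seed = 1L,
                             stop_when_perfect = TRUE,
                             shaped_selection = TRUE) {
  cfg <- list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    replicates = as.integer(replicates),
    point_rate = point_rate,
    insertion_rate = insertion_rate,
    deletion_rate = deletion_rate,
    init_genes = as.integer(init_genes),
    tournament_size = as.integer(tournament_size),
    elitism = as.integer(elitism),
    n_neurons = as.integer(n_neurons),
    seed = as.integer(seed),
    stop_when_perfect = isTRUE(stop_when_perfect),
    shaped_selection = isTRUE(shaped_selection)
  )
  rates <- c(cfg$point_rate, cfg$insertion_rate, cfg$deletion_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("Mutation rates must lie in [0, 1].", call. = FALSE)
  }
  if (cfg$generations < 1L || cfg$population_size < 2L || cfg$replicates < 1L) {
    stop("Need generations >= 1, population_size >= 2, replicates >= 1.",
         call. = FALSE)
  }
  if (length(cfg$init_genes) != 2L || any(cfg$init_genes < 0L)) {
    stop("`init_genes` must be a non-negative range c(lo, hi).", call. = FALSE)
  }
  class(cfg) <- "evolution_config"
  cfg
}

#' Read an evolution configuration from a JSON file
#'
#' Any field of [evolution_config()] may be given; the rest keep their
#' defaults.
#'
#' @param path Path to a JSON file.
#' @return An `evolution_config`.
#' @export
read_evolution_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(evolution_config, obj)
}

random_gene <- function(n_neurons) {
  cat <- gate_name_table()
  c(sample.int(n_neurons, 2L, replace = TRUE) - 1L,
    sample.int(n_neurons, 1L) - 1L,
    cat$tt[[sample.int(16L, 1L)]])
}

random_genome <- function(config) {
  n <- sample(config$init_genes[1]:config$init_genes[2], 1L)
  g <- do.call(rbind, c(lapply(seq_len(n), function(i) {
    random_gene(config$n_neurons)
  }), list(matrix(integer(0), 0, 7))))
  colnames(g) <- gene_cols
  g
}

#' Mutate a genome
#'
#' Applies, in order: per-site point mutations (input and output ids are
#' resampled uniformly; truth-table bits are flipped), then gene
#' duplication/insertion, then gene deletion, at the configured rates.
#' Uses the session RNG.
#'
#' @param genes Gene matrix (see [markov_brain()]).
#' @param config An [evolution_config()].
#' @return A mutated gene matrix that decodes to a valid brain.
#' @export
mutate_genome <- function(genes, config) {
  n_gene <- nrow(genes)
  if (n_gene > 0L && config$point_rate > 0) {
    hit <- matrix(stats::runif(n_gene * 7L) < config$point_rate, n_gene, 7L)
    for (col in 1:3) {
      idx <- which(hit[, col])
      if (length(idx)) {
        genes[idx, col] <- sample.int(config$n_neurons, length(idx),
                                      replace = TRUE) - 1L
      }
    }
    flips <- hit[, 4:7, drop = FALSE]
    if (any(flips)) {
      block <- genes[, 4:7, drop = FALSE]
      block[flips] <- 1L - block[flips]
      genes[, 4:7] <- block
    }
  }
  if (stats::runif(1) < config$insertion_rate) {
    new_gene <- if (nrow(genes) > 0L) {
      genes[sample.int(nrow(genes), 1L), ]
    } else {
      random_gene(config$n_neurons)
    }
    genes <- rbind(genes, new_gene)
    rownames(genes) <- NULL
  }
  if (nrow(genes) > 0L && stats::runif(1) < config$deletion_rate) {
    genes <- genes[-sample.int(nrow(genes), 1L), , drop = FALSE]
  }
  genes
}

# Batch version of mutate_genome() over a whole population: one RNG draw
# per mutation class instead of per genome. Same per-site and per-genome
# rates as mutate_genome().
mutate_population <- function(pop, config) {
  sizes <- vapply(pop, nrow, integer(1))
  all <- do.call(rbind, pop)
  n_rows <- nrow(all)
  if (n_rows > 0L && config$point_rate > 0) {
    hit <- matrix(stats::runif(n_rows * 7L) < config$point_rate, n_rows, 7L)
    for (col in 1:3) {
      idx <- which(hit[, col])
      if (length(idx)) {
        all[idx, col] <- sample.int(config$n_neurons, length(idx),
                                    replace = TRUE) - 1L
      }
    }
    flips <- hit[, 4:7, drop = FALSE]
    if (any(flips)) {
      block <- all[, 4:7, drop = FALSE]
      block[flips] <- 1L - block[flips]
      all[, 4:7] <- block
    }
  }
  ins <- stats::runif(length(pop)) < config$insertion_rate
  del <- stats::runif(length(pop)) < config$deletion_rate
  idx_by_genome <- split(seq_len(n_rows),
                         factor(rep.int(seq_along(pop), sizes),
                                levels = seq_along(pop)))
  lapply(seq_along(pop), function(p) {
    m <- all[idx_by_genome[[p]], , drop = FALSE]
    if (ins[p]) {
      new_gene <- if (nrow(m) > 0L) m[sample.int(nrow(m), 1L), ]
                  else random_gene(config$n_neurons)
      m <- rbind(m, new_gene)
      rownames(m) <- NULL
    }
    if (del[p] && nrow(m) > 0L) {
      m <- m[-sample.int(nrow(m), 1L), , drop = FALSE]
    }
    m
  })
}

task_eval_args <- function(task) {
  code <- if (task$name == "md") task$trials$code else task$trials$label
  list(
    schedule = as.integer(task$schedule),
    n_trials = dim(task$schedule)[1],
    n_updates = dim(task$schedule)[2],
    sensors = task$sensors,
    outputs = task$outputs,
    code = as.integer(code),
    task_type = if (task$name == "md") 0L else 1L
  )
}

eval_population <- function(pop, args, n_neurons) {
  cpp_eval_population(pop, args$schedule, args$n_trials, args$n_updates,
                      args$sensors, args$outputs, args$code, args$task_type,
                      n_neurons)
}

ga_run <- function(task, config, seed, seed_genomes = NULL) {
  set.seed(seed)
  args <- task_eval_args(task)
  p <- config$population_size
  pop <- lapply(seq_len(p), function(i) random_genome(config))
  for (i in seq_along(seed_genomes)) pop[[i]] <- seed_genomes[[i]]
  trace <- numeric(0)
  repeat {
    scores <- eval_population(pop, args, config$n_neurons)
    fit <- scores$fitness
    sel <- if (config$shaped_selection) scores$shaped else scores$fitness
    gen <- length(trace) + 1L
    trace[gen] <- max(fit)
    done <- gen >= config$generations ||
      (config$stop_when_perfect && max(fit) >= 1)
    if (done) break
    # elites ranked by exact fitness (selection score breaking ties), so
    # maximum fitness is non-decreasing across generations
    ord <- order(fit, sel, decreasing = TRUE)
    elites <- ord[seq_len(config$elitism)]
    n_off <- p - config$elitism
    contenders <- matrix(sample.int(p, n_off * config$tournament_size,
                                    replace = TRUE),
                         nrow = n_off)
    winners <- contenders[, 1L]
    for (t in seq_len(config$tournament_size - 1L)) {
      challenger <- contenders[, t + 1L]
      better <- sel[challenger] > sel[winners]
      winners[better] <- challenger[better]
    }
    pop <- c(pop[elites], mutate_population(pop[winners], config))
  }
  best <- which.max(fit)
  list(seed = seed, trace = trace, champion = pop[[best]],
       fitness = fit[best])
}

#' Evolve Markov Brains on a task
#'
#' Runs the genetic algorithm independently in each replicate population
#' (seeds derived from the master seed) and keeps the highest-fitness
#' genome of the final generation of each replicate, with the
#' per-generation max-fitness trace. Fully deterministic given the
#' configuration.
#'
#' @param task A task from [md_task()] or [sl_task()].
#' @param config An [evolution_config()].
#' @param seed_genomes Optional list of gene matrices injected into the
#'   initial population of every replicate (e.g. to resume from known
#'   circuits).
#' @return An object of class `mb_evolution`: a list with the config,
#'   the task's sensor/output ids, and one entry per replicate holding
#'   `seed`, `trace`, `champion` (gene matrix) and `fitness`.
#' @export
evolve <- function(task, config = evolution_config(), seed_genomes = NULL) {
  stopifnot(inherits(config, "evolution_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$replicates)
  runs <- lapply(seeds, function(s) ga_run(task, config, s, seed_genomes))
  structure(
    list(task_name = task$name, sensors = task$sensors,
         outputs = task$outputs, n_neurons = config$n_neurons,
         config = config, replicates = runs),
    class = "mb_evolution"
  )
}

#' @export
print.mb_evolution <- function(x, ...) {
  fits <- vapply(x$replicates, `[[`, numeric(1), "fitness")
  cat("<mb_evolution> task '", x$task_name, "': ", length(fits),
      " replicates, ", sum(fits >= 1), " perfect (max fitness ",
      format(max(fits)), ")\n", sep = "")
  invisible(x)
}

#' Tidy and summarise evolution results
#'
#' `tidy()` returns the per-generation max-fitness traces in long form;
#' `glance()` one row of cohort summaries.
#'
#' @param x An `mb_evolution` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mb_evolution
#' @export
tidy.mb_evolution <- function(x, ...) {
  purrr::imap_dfr(x$replicates, function(r, i) {
    tibble::tibble(replicate = i, generation = seq_along(r$trace),
                   max_fitness = r$trace)
  })
}

#' @rdname tidy.mb_evolution
#' @method glance mb_evolution
#' @export
glance.mb_evolution <- function(x, ...) {
  fits <- vapply(x$replicates, `[[`, numeric(1), "fitness")
  tibble::tibble(
    task = x$task_name,
    replicates = length(fits),
    n_perfect = sum(fits >= 1),
    mean_fitness = mean(fits),
    max_fitness = max(fits)
  )
}

#' Extract champion brains from an evolution result
#'
#' @param results An `mb_evolution` object.
#' @param require_perfect Keep only champions with fitness exactly 1.
#' @return A list of [markov_brain()] objects (sensor and output ids
#'   taken from the evolved task).
#' @export
best_brains <- function(results, require_perfect = TRUE) {
  keep <- vapply(results$replicates, function(r) {
    !require_perfect || r$fitness >= 1
  }, logical(1))
  lapply(results$replicates[keep], function(r) {
    markov_brain(r$champion, n_neurons = results$n_neurons,
                 sensory_ids = results$sensors,
                 output_ids = results$outputs)
  })
}
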