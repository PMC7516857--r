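tiny_cfg <- function(...) {
  args <- list(population_size = 20L, generations = 5L, replicates = 2L,
               seed = 5L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(evolution_config, args)
}

test_that("configuration validation rejects invalid settings", {
  expect_error(evolution_config(point_rate = 1.5), "rates")
  expect_error(evolution_config(generations = 0), "generations")
  expect_error(evolution_config(init_genes = c(-1, 4)), "init_genes")
  expect_s3_class(evolution_config(), "evolution_config")
})

test_that("mutation respects its rates and is reproducible", {
  g <- random_brain(5, seed = 1)$genes
  cfg0 <- evolution_config(point_rate = 0, insertion_rate = 0,
                           deletion_rate = 0)
  expect_identical(mutate_genome(g, cfg0), g)
  cfg_del <- evolution_config(point_rate = 0, insertion_rate = 0,
                              deletion_rate = 1)
  expect_equal(nrow(mutate_genome(g, cfg_del)), 4L)
  cfg <- evolution_config()
  set.seed(99); m1 <- mutate_genome(g, cfg)
  set.seed(99); m2 <- mutate_genome(g, cfg)
  expect_identical(m1, m2)
  # mutants always decode to a valid brain
  set.seed(100)
  for (i in 1:20) {
    g <- mutate_genome(g, cfg)
    expect_s3_class(markov_brain(g), "markov_brain")
  }
})

test_that("batch population mutation matches the per-genome operator distributionally", {
  cfg <- evolution_config(point_rate = 0.2, insertion_rate = 0,
                          deletion_rate = 0)
  pop <- lapply(1:400, function(i) random_brain(6, seed = i)$genes)
  set.seed(42)
  mut <- teflow:::mutate_population(pop, cfg)
  changed <- mean(mapply(function(a, b) mean(a != b), pop, mut))
  # a resampled id is unchanged with prob 1/16; a flipped bit always changes
  expected <- 0.2 * (3 * 15 / 16 + 4) / 7
  expect_equal(changed, expected, tolerance = 0.1)
})

test_that("a population seeded with a perfect circuit reports it immediately", {
  solver <- build_named_fixture("md_solver")$brain
  res <- evolve(md_task(), tiny_cfg(generations = 1L),
                seed_genomes = list(solver$genes))
  expect_true(all(vapply(res$replicates, `[[`, numeric(1), "fitness") == 1))
  expect_equal(res$replicates[[1]]$trace[1], 1)
  champ <- best_brains(res)[[1]]
  expect_equal(md_evaluate(champ)$fitness, 1)
})

test_that("identical seeds give identical lineages and champions", {
  r1 <- evolve(md_task(), tiny_cfg())
  r2 <- evolve(md_task(), tiny_cfg())
  expect_identical(lapply(r1$replicates, `[[`, "champion"),
                   lapply(r2$replicates, `[[`, "champion"))
  expect_identical(tidy(r1), tidy(r2))
})

test_that("elitism keeps the max-fitness trace non-decreasing", {
  res <- evolve(md_task(), tiny_cfg(generations = 60L, seed = 8L))
  for (r in res$replicates) {
    expect_true(all(diff(r$trace) >= 0))
  }
  # champions re-evaluated from scratch reproduce their reported fitness
  for (b in best_brains(res, require_perfect = FALSE)) {
    expect_true(md_evaluate(b)$fitness %in% ((0:16) / 16))
  }
  fits <- vapply(res$replicates, `[[`, numeric(1), "fitness")
  re_fits <- vapply(best_brains(res, require_perfect = FALSE),
                    function(b) md_evaluate(b)$fitness, numeric(1))
  expect_equal(re_fits, fits)
})

test_that("best_brains filters to perfect champions", {
  fake <- structure(list(
    task_name = "md", sensors = c(0L, 1L), outputs = c(14L, 15L),
    n_neurons = 16L, config = evolution_config(),
    replicates = list(
      list(seed = 1, trace = 1, champion = random_brain(3, seed = 1)$genes,
           fitness = 1),
      list(seed = 2, trace = 0.5, champion = random_brain(3, seed = 2)$genes,
           fitness = 0.5)
    )
  ), class = "mb_evolution")
  expect_length(best_brains(fake), 1L)
  expect_length(best_brains(fake, require_perfect = FALSE), 2L)
  fake$replicates[[1]]$fitness <- 0.9
  expect_length(best_brains(fake), 0L)
})

test_that("glance and config files round-trip", {
  res <- evolve(md_task(), tiny_cfg())
  g <- glance(res)
  expect_equal(g$replicates, 2L)
  expect_true(g$max_fitness <= 1)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(population_size = 30, generations = 7),
                       path, auto_unbox = TRUE)
  cfg <- read_evolution_config(path)
  expect_equal(cfg$population_size, 30L)
  expect_equal(cfg$generations, 7L)
  expect_equal(cfg$replicates, 20L)
})

test_that("C++ task evaluation agrees with the reference simulator", {
  task_md <- md_task()
  task_sl <- sl_task()
  args_md <- teflow:::task_eval_args(task_md)
  args_sl <- teflow:::task_eval_args(task_sl)
  set.seed(31)
  pop <- lapply(1:30, function(i) {
    random_brain(sample(1:12, 1), seed = i * 7)$genes
  })
  fast_md <- teflow:::eval_population(pop, args_md, 16L)$fitness
  fast_sl <- teflow:::eval_population(pop, args_sl, 16L)$fitness
  slow_md <- vapply(pop, function(g) {
    evaluate_task(markov_brain(g), task_md)$fitness
  }, numeric(1))
  slow_sl <- vapply(pop, function(g) {
    evaluate_task(markov_brain(g), task_sl)$fitness
  }, numeric(1))
  expect_equal(fast_md, slow_md)
  expect_equal(fast_sl, slow_sl)
})
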