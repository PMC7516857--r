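test_that("knockout removes one gate and is reversible", {
  md <- build_named_fixture("md_solver")$brain
  mut <- knockout_gate(md, 3)
  expect_equal(nrow(mut$genes), nrow(md$genes) - 1L)
  restored <- mut
  restored$genes <- rbind(mut$genes[1:2, , drop = FALSE],
                          md$genes[3, , drop = FALSE],
                          mut$genes[-(1:2), , drop = FALSE])
  expect_equal(logic_table(restored), logic_table(md))
})

test_that("knockout assay separates essential from redundant gates", {
  dup <- build_named_fixture("dup_gate")
  b <- dup$brain
  assay <- knockout_assay(b, md_task())
  pair <- dup$expected$duplicated
  # either copy of the duplicated gate can go
  expect_false(any(assay$essential[pair]))
  expect_equal(assay$mutant_fitness[pair], c(1, 1))
  # the PD detector gates are essential in the intact solver
  md <- build_named_fixture("md_solver")$brain
  ess <- essential_gates(md, md_task())
  expect_true(11 %in% ess)  # first PD output gate
  expect_true(all(evaluate_task(knockout_gate(md, 11), md_task())$fitness < 1))
  expect_equal(essential_gates(markov_brain(matrix(integer(0), 0, 7)),
                               md_task()), integer(0))
})

test_that("gate composition counts types per brain and deduplicates exact copies", {
  # AND + identical AND copy + XOR
  genes <- rbind(
    c(2, 3, 4, 0, 0, 0, 1),
    c(2, 3, 4, 0, 0, 0, 1),
    c(2, 3, 5, 0, 1, 1, 0)
  )
  b <- markov_brain(genes)
  comp <- gate_composition(list(b), dedup = TRUE)
  expect_equal(comp$count[comp$id == "AND"], 1)
  expect_equal(comp$count[comp$id == "XOR"], 1)
  expect_equal(sum(comp$count), 2)
  comp2 <- gate_composition(list(b), dedup = FALSE)
  expect_equal(comp2$count[comp2$id == "AND"], 2)
  # cohort of two known brains gives exact expected means
  b2 <- markov_brain(rbind(c(2, 3, 4, 0, 0, 0, 1)))
  cohort <- gate_composition(list(b, b2))
  means <- tapply(cohort$count, cohort$id, mean)
  expect_equal(unname(means["AND"]), 1)
  expect_equal(unname(means["XOR"]), 0.5)
})

test_that("theoretical misestimate sums the analytic per-gate errors", {
  # essential gates XOR, AND, COPY, all feedforward
  genes <- rbind(
    c(2, 3, 4, 0, 1, 1, 0),   # XOR
    c(2, 3, 5, 0, 0, 0, 1),   # AND
    c(2, 2, 6, 0, 0, 1, 1)    # COPY
  )
  b <- markov_brain(genes)
  rep <- theoretical_misestimate(b, essential = 1:3)
  expect_equal(round(rep$misestimate_bits, 2), 1.19)
  expect_equal(round(rep$correct_bits, 2), 1.62)
  # per-gate normalisation recovers the totals
  expect_equal(rep$misestimate_per_gate * rep$n_essential,
               rep$misestimate_bits, tolerance = 1e-12)
  expect_equal(rep$correct_per_gate * rep$n_essential, rep$correct_bits,
               tolerance = 1e-12)
  # no essential gates
  rep0 <- theoretical_misestimate(b, essential = integer(0))
  expect_equal(rep0$misestimate_bits, 0)
  expect_equal(rep0$correct_bits, 0)
})

test_that("feedback gates use the feedback columns of the catalog", {
  # AND feedback loop: output among its own inputs
  b <- markov_brain(rbind(c(3, 4, 4, 0, 0, 0, 1)))
  rep <- theoretical_misestimate(b, essential = 1L)
  tab <- gate_table()
  and_row <- tab[tab$id == "AND", ]
  expect_equal(rep$misestimate_bits, and_row$te_error_fb)
  expect_equal(rep$correct_bits,
               and_row$te_y_fb + and_row$processed_fb - and_row$te_error_fb)
  # XOR feedback: the whole bit is misattributed
  bx <- markov_brain(rbind(c(3, 4, 4, 0, 1, 1, 0)))
  expect_equal(theoretical_misestimate(bx, essential = 1L)$misestimate_bits, 1)
  expect_equal(theoretical_misestimate(bx, essential = 1L)$correct_bits, 0)
})

test_that("cohort summaries compute normal-theory confidence intervals", {
  df <- tibble::tibble(a = c(1, 2, 3, 4))
  s <- cohort_summary(df)
  expect_equal(s$mean, 2.5)
  se <- sd(df$a) / 2
  expect_equal(s$se, se)
  expect_equal(s$ci_hi - s$ci_lo, 2 * 1.96 * se)
})
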