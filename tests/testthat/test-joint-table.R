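and_ff_joint <- function() analytic_joint(c(0L, 0L, 0L, 1L), "feedforward")
xor_ff_joint <- function() analytic_joint(c(0L, 1L, 1L, 0L), "feedforward")
xor_fb_joint <- function() analytic_joint(c(0L, 1L, 1L, 0L), "feedback")

test_that("constructor enforces the probability-table invariants", {
  states <- expand.grid(x = 0:1, y = 0:1)
  expect_s3_class(joint_table(states, rep(0.25, 4)), "joint_table")
  expect_error(joint_table(states, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(joint_table(states, c(-0.1, 0.5, 0.3, 0.3)), "non-negative")
  expect_error(joint_table(data.frame(x = c(0, 2)), c(0.5, 0.5)), "0 or 1")
  jt <- joint_table(states, rep(0.25, 4))
  expect_error(entropy(jt, "nope"), "nope")
  expect_error(entropy(jt, character(0)), "at least one")
})

test_that("entropy matches hand values for uniform, AND-output and degenerate marginals", {
  jt <- joint_table(expand.grid(x = 0:1), c(0.5, 0.5))
  expect_equal(entropy(jt, "x"), 1)
  # output of AND on uniform inputs is Bernoulli(1/4)
  expect_equal(round(entropy(and_ff_joint(), "z1"), 2), 0.81)
  degenerate <- joint_table(expand.grid(x = 0:1, y = 0:1),
                            c(1, 0, 0, 0))
  expect_equal(entropy(degenerate, c("x", "y")), 0)
})

test_that("mutual information: copy, one-time pad, and AND obfuscation", {
  copy <- joint_table(data.frame(x = c(0, 1), z = c(0, 1)), c(0.5, 0.5))
  expect_equal(mutual_information(copy, "x", "z"), 1)
  expect_equal(mutual_information(xor_ff_joint(), "x", "z1"), 0)
  expect_equal(round(mutual_information(and_ff_joint(), "x", "z1"), 2), 0.31)
  expect_error(mutual_information(copy, "x", "x"), "disjoint")
})

test_that("co-information is -1 for XOR, -0.19 for AND, 0 for copy-plus-bystander", {
  expect_equal(co_information(xor_ff_joint(), "x", "y", "z1"), -1)
  expect_equal(round(co_information(and_ff_joint(), "x", "y", "z1"), 2),
               -0.19)
  copy_bystander <- joint_table(
    expand.grid(x = 0:1, y = 0:1) |> transform(z = x),
    rep(0.25, 4)
  )
  expect_equal(co_information(copy_bystander, "x", "y", "z"), 0)
})

test_that("co-information is symmetric under permutations of its arguments", {
  set.seed(11)
  for (rep in 1:25) {
    jt <- random_joint_table(c("a", "b", "c"))
    vals <- c(
      co_information(jt, "a", "b", "c"),
      co_information(jt, "b", "c", "a"),
      co_information(jt, "c", "a", "b"),
      co_information(jt, "b", "a", "c")
    )
    expect_lt(max(vals) - min(vals), 1e-9)
  }
})

test_that("chain identity links plain and conditional transfer entropy", {
  # TE(y->z) = TE(y->z | x) + I(x:y:z1 | z) on arbitrary joints
  set.seed(12)
  for (rep in 1:25) {
    jt <- random_joint_table(c("x", "y", "z", "z1"))
    lhs <- conditional_mutual_information(jt, "y", "z1", "z")
    rhs <- conditional_mutual_information(jt, "y", "z1", c("z", "x")) +
      co_information(jt, "x", "y", "z1", cond = "z")
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("entropy decompositions hold on random joints satisfying their preconditions", {
  set.seed(13)
  for (rep in 1:100) {
    expect_lt(abs(decomposition_residual(random_feedforward_joint(),
                                         "feedforward")), 1e-9)
    expect_lt(abs(decomposition_residual(random_feedback_joint(),
                                         "feedback")), 1e-9)
    expect_lt(abs(decomposition_residual(random_joint_table(c("x", "y", "z", "z1")),
                                         "general")), 1e-9)
  }
  expect_equal(decomposition_residual(xor_ff_joint(), "feedforward"), 0,
               tolerance = 1e-12)
  expect_equal(decomposition_residual(xor_fb_joint(), "feedback"), 0,
               tolerance = 1e-12)
})

test_that("information measures agree with an independent direct-summation oracle", {
  set.seed(14)
  for (rep in 1:10) {
    jt <- random_joint_table(c("a", "b", "c"))
    df <- as.data.frame(jt)
    expect_equal(entropy(jt, c("a", "b")), oracle_entropy(df, c("a", "b")),
                 tolerance = 1e-12)
    expect_equal(mutual_information(jt, "a", "b"),
                 max(oracle_cmi(df, "a", "b"), 0), tolerance = 1e-12)
    expect_equal(conditional_mutual_information(jt, "a", "b", "c"),
                 max(oracle_cmi(df, "a", "b", "c"), 0), tolerance = 1e-12)
  }
})

test_that("joint tables round-trip through JSON", {
  set.seed(15)
  jt <- random_joint_table(c("x", "y", "z"))
  path <- withr::local_tempfile(fileext = ".json")
  write_joint_table(jt, path)
  back <- read_joint_table(path)
  expect_equal(jt_variables(back), jt_variables(jt))
  merged <- dplyr::inner_join(as.data.frame(jt), as.data.frame(back),
                              by = c("x", "y", "z"))
  expect_equal(merged$p.x, merged$p.y, tolerance = 1e-12)
})
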