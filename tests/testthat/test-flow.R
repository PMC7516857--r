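test_that("TE matrix recovers a copy relation and stays blind to XOR", {
  copy <- build_named_fixture("gate_COPY_X")$brain
  te <- te_matrix(exhaustive_recording(copy, neurons = 0:2))
  expect_equal(te["N0", "N2"], 1)
  expect_equal(te["N1", "N2"], 0)
  xorb <- build_named_fixture("xor_pair")$brain
  te2 <- te_matrix(exhaustive_recording(xorb, neurons = 0:2))
  expect_equal(te2["N0", "N2"], 0)
  expect_equal(te2["N1", "N2"], 0)
  # yet the output carries a full bit: the cryptographic failure mode
  truth <- influence_map(xorb)
  det <- score_detection(te2, truth, 0)
  expect_equal(det$hits, 0L)
  expect_equal(det$misses, 2L)
})

test_that("a gateless brain yields an all-zero TE matrix", {
  silent <- markov_brain(matrix(integer(0), 0, 7), sensory_ids = integer(0))
  te <- te_matrix(exhaustive_recording(silent, neurons = 0:1))
  expect_true(all(te == 0))
})

test_that("te_matrix agrees with the single-pair estimators", {
  b <- build_named_fixture("gate_NAND")$brain
  rec <- exhaustive_recording(b, neurons = 0:2)
  te <- te_matrix(rec, include_self = TRUE)
  for (i in 0:2) {
    for (j in 0:2) {
      expected <- if (i == j) processed_information(rec, i)
                  else transfer_entropy(rec, i, j)
      expect_equal(te[i + 1, j + 1], expected, tolerance = 1e-12)
    }
  }
})

test_that("detection counts follow the confusion-matrix definitions", {
  te <- matrix(0, 4, 4)
  truth <- matrix(0L, 4, 4)
  truth[1, 2] <- 1L; truth[2, 3] <- 1L        # two true edges
  te[1, 2] <- 0.4                              # one detected
  te[3, 1] <- 0.2                              # one false alarm
  class(truth) <- c("influence_map", class(truth))
  det <- score_detection(te, truth, 0)
  expect_equal(det$hits, 1L)
  expect_equal(det$misses, 1L)
  expect_equal(det$false_alarms, 1L)
  expect_equal(det$hit_rate, 0.5)
  expect_equal(det$false_alarm_rate, 1 / 10)   # 12 off-diagonal cells - 2 edges
  # nothing exceeds a threshold of 1
  det1 <- score_detection(te, truth, 1)
  expect_equal(det1$hits + det1$false_alarms, 0L)
  # truth recovered exactly when TE mirrors it
  te_oracle <- truth * 0.7
  class(te_oracle) <- "matrix"
  det2 <- score_detection(te_oracle, truth, 0)
  expect_equal(det2$hits, 2L)
  expect_equal(det2$misses + det2$false_alarms, 0L)
})

test_that("the ROC staircase is monotone and anchored", {
  set.seed(41)
  te <- matrix(runif(64), 8, 8)
  truth <- matrix(rbinom(64, 1, 0.2), 8, 8)
  roc <- roc_curve(te, truth)
  expect_s3_class(roc, "te_roc")
  expect_equal(nrow(roc), 101L)
  # thresholds descending; rates non-decreasing along the curve
  expect_true(all(diff(roc$threshold) <= 0))
  expect_true(all(diff(roc$hit_rate) >= 0))
  expect_true(all(diff(roc$false_alarm_rate) >= 0))
  two <- roc_curve(te, truth, thresholds = c(0, 1))
  expect_equal(nrow(two), 2L)
  expect_equal(two$hit_rate[1], 0)
  expect_equal(two$false_alarm_rate[1], 0)
  # perfectly separated classes reach the (0, 1) corner
  te_sep <- truth * 0.9 + 0.01
  diag(te_sep) <- 0
  roc_sep <- roc_curve(te_sep, truth)
  expect_true(any(roc_sep$hit_rate == 1 & roc_sep$false_alarm_rate == 0))
})

test_that("binormal fit reduces to chance for coinciding classes and saturates for separated ones", {
  vals <- c(0.1, 0.2, 0.3, 0.4)
  fit <- fit_gaussian_roc(vals, vals)
  x <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(fit$fun(x) - x)), 1e-9)
  expect_equal(fit$fun(0.5), 0.5)
  fit2 <- fit_gaussian_roc(c(0.9, 0.91, 0.92), c(0.01, 0.02, 0.03))
  expect_gt(fit2$fun(0.05), 0.999)
  expect_equal(glance(fit2)$auc, 1, tolerance = 1e-6)
  expect_error(fit_gaussian_roc(c(0.5, 0.5), c(0.1, 0.2)), "variance")
  expect_error(fit_gaussian_roc(numeric(0), c(0.1)), "non-empty")
})

test_that("end-to-end flow analysis wires recording, TE, truth and scoring together", {
  b <- build_named_fixture("sl_solver")$brain
  fa <- flow_analysis(b, sl_task())
  expect_s3_class(fa$te, "te_matrix")
  expect_s3_class(fa$truth, "influence_map")
  expect_equal(fa$detection$hits + fa$detection$misses, fa$detection$n_edges)
  expect_equal(fa$roc$hits[nrow(fa$roc)], fa$detection$hits)
  split <- te_values_by_truth(fa$te, fa$truth)
  expect_equal(length(split$edge), fa$detection$n_edges)
  expect_equal(length(split$nonedge), fa$detection$n_nonedges)
})

test_that("tidy and autoplot methods return the documented shapes", {
  b <- build_named_fixture("gate_AND")$brain
  te <- te_matrix(exhaustive_recording(b, neurons = 0:2))
  td <- tidy(te)
  expect_equal(nrow(td), 256L)
  expect_equal(td$te[td$source == 0 & td$destination == 2], te["N0", "N2"])
  truth <- influence_map(b)
  expect_equal(sum(tidy(truth)$edge), sum(truth))
  expect_s3_class(autoplot(te), "ggplot")
  expect_s3_class(autoplot(truth), "ggplot")
  roc <- roc_curve(te, truth, thresholds = c(0, 0.5, 1))
  fit <- fit_gaussian_roc(c(0.2, 0.3, 0.4), c(0, 0.05, 0.1))
  expect_s3_class(autoplot(roc, fit = fit), "ggplot")
  comp <- gate_composition(list(b))
  expect_s3_class(plot_gate_composition(comp), "ggplot")
})
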