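# Condition construction, paired statistics and the single-trial lineup.

test_that("condition selections activate exactly one unit per feature pair
           with the stated rules", {
  st <- std_stimuli()
  sel_cons <- vosim:::condition_selection(similar_condition(), st, 1:64)
  expect_equal(dim(sel_cons), c(6L, 64L))
  expect_true(all(sel_cons[c(1, 3, 5), ] + sel_cons[c(2, 4, 6), ] == 1))
  # consistent selection equals the item's own verbal vector
  expect_equal(unname(sel_cons), unname(st$verbal))
  # inconsistent selection is the within-pair complement
  sel_inc <- vosim:::condition_selection(irrelevant_condition(), st, 1:64)
  expect_equal(unname(sel_inc), unname(1 - st$verbal))
  # graded k = 3 reproduces the consistent (similar-condition) clamps
  sel_g3 <- vosim:::condition_selection(graded_condition(3, 3), st, 1:64)
  expect_equal(sel_g3, sel_cons)
  # graded k = 0 reproduces the inconsistent clamps
  sel_g0 <- vosim:::condition_selection(graded_condition(0, 0), st, 1:64)
  expect_equal(sel_g0, sel_inc)
  # graded k = 2: each item has exactly 2 of its 3 correct units active,
  # resampled identically under the same seed
  sel_g2 <- vosim:::condition_selection(graded_condition(2, 2, seed = 9), st, 1:64)
  hits <- colSums(sel_g2 * st$verbal)
  expect_true(all(hits == 2))
  sel_g2b <- vosim:::condition_selection(graded_condition(2, 2, seed = 9), st, 1:64)
  expect_identical(sel_g2, sel_g2b)
})

test_that("a selection activating two units in one pair is rejected", {
  st <- std_stimuli()
  bad <- matrix(0, 6, 64)
  bad[1, ] <- 1; bad[2, ] <- 1; bad[3, ] <- 1
  cond <- condition_spec("bad", "consistent", selection = bad)
  expect_error(vosim:::condition_selection(cond, st, 1:64), "one unit per")
})

test_that("paired t against control matches the closed form and handles the
           zero-variance path", {
  as_result <- function(acc) {
    structure(list(per_model = data.frame(model_id = 1:5, accuracy = acc)),
              class = "condition_result")
  }
  control <- as_result(c(0.65, 0.60, 0.70, 0.65, 0.65))
  # hand-computed oracle for differences 0.15 0.10 0.20 0.15 0.15
  cond <- as_result(control$per_model$accuracy - c(0.15, 0.10, 0.20, 0.15, 0.15))
  res <- paired_t_vs_control(cond, control)
  d <- c(0.15, 0.10, 0.20, 0.15, 0.15)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-10)
  expect_equal(res$df, 4L)
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-10)
  # agreement with stats::t.test as an independent check
  tt <- t.test(control$per_model$accuracy, cond$per_model$accuracy,
               paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # identical accuracies: t = 0, p = 1
  res0 <- paired_t_vs_control(control, control)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # constant non-zero differences: signed infinity
  resinf <- paired_t_vs_control(as_result(control$per_model$accuracy - 0.1),
                                control)
  expect_equal(resinf$t, Inf)
  expect_equal(resinf$p, 0)
})

test_that("lineup success is certain for disjoint distributions and near
           chance for exchangeable ones", {
  fx <- make_micro_instance("overlap_distributions", seed = 4)
  res <- single_trial_lineup(fx$disjoint, n_distractors = 7, repetitions = 500)
  expect_equal(res$proportion, 1)
  expect_error(single_trial_lineup(fx$disjoint, n_distractors = 40),
               "exceeds")
  # exchangeable pool: proportion near 1/8 (chance for 8 alternatives)
  set.seed(99)
  big <- data.frame(old = rep(c(TRUE, FALSE), each = 20000),
                    polarity = runif(40000))
  res8 <- single_trial_lineup(big, n_distractors = 7, repetitions = 20000)
  expect_lt(abs(res8$proportion - 1 / 8), 0.015)
})

test_that("experiment suite on micro stimuli runs end to end and is
           reproducible", {
  run_suite <- function() {
    run_experiment_suite(
      stim_seed = 5, model_seeds = 21:22,
      config = training_config("reduced", reps_per_item_per_task = 5L,
                               eval_interval = 2L,
                               pretrain_accuracy_threshold = 0.01,
                               max_pretrain_epochs = 60L),
      lineup_repetitions = 200L, verbose = FALSE)
  }
  s1 <- run_suite()
  expect_s3_class(s1, "experiment_suite")
  expect_equal(nrow(s1$summary), 6L)
  expect_true(all(c("control", "similar", "dissimilar", "irrelevant",
                    "graded_2v1", "graded_1v0") %in% s1$summary$condition))
  expect_true(all(s1$summary$accuracy >= 0 & s1$summary$accuracy <= 1))
  expect_equal(s1$control$hit, 1)  # hits 100% by criterion construction
  expect_equal(vapply(s1$t_tests, function(x) x$df, integer(1)),
               c(similar = 1L, dissimilar = 1L, irrelevant = 1L,
                 graded_2v1 = 1L, graded_1v0 = 1L))
  s2 <- run_suite()
  expect_equal(s1$summary, s2$summary)
})
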