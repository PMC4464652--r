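## Verbalization experiment harness: condition definitions, condition runs,
## graded description accuracy, cross-model paired t-tests, and the
## single-trial lineup procedure.

#' Define a verbalization condition
#'
#' A condition specifies, separately for old (trained) and new (untrained)
#' test items, which verbal units are externally activated before
#' recognition, and whether the external verbal input is maintained during
#' the recognition phase or removed at retinotopic onset. Selection rules:
#' `"consistent"` activates the item's own three labels, `"inconsistent"`
#' the within-pair opposite label for every feature, and `"graded"`
#' activates exactly `k` features' correct labels (seeded per item) with
#' the remaining features flipped within their pair.
#'
#' @param name Condition label.
#' @param rule_old,rule_new Selection rule for old / new items.
#' @param k_old,k_new Number of correctly described features (graded rule).
#' @param maintain Keep the verbal clamp during recognition (`TRUE`) or
#'   remove it at retinotopic onset (`FALSE`).
#' @param pre_cycles Length of the verbalization phase before retinotopic
#'   onset.
#' @param seed Seed for the graded rule's per-item feature sampling.
#' @param selection Optional explicit 6 x 64 0/1 selection matrix overriding
#'   the rules.
#' @return A list of class `condition_spec`.
#' @export
condition_spec <- function(name,
                           rule_old = c("consistent", "inconsistent", "graded"),
                           rule_new = rule_old,
                           k_old = 3L, k_new = 3L,
                           maintain = TRUE, pre_cycles = 10L, seed = 1L,
                           selection = NULL) {
  rule_old <- match.arg(rule_old)
  rule_new <- match.arg(rule_new, c("consistent", "inconsistent", "graded"))
  structure(list(name = name, rule_old = rule_old, rule_new = rule_new,
                 k_old = as.integer(k_old), k_new = as.integer(k_new),
                 maintain = isTRUE(maintain), pre_cycles = as.integer(pre_cycles),
                 seed = as.integer(seed), selection = selection),
            class = "condition_spec")
}

#' Standard conditions
#'
#' `similar_condition()`: consistent verbal units for every item, maintained
#' (high target-distractor similarity). `dissimilar_condition()`: consistent
#' for old items, within-pair-opposite for new items, maintained (low
#' similarity). `irrelevant_condition()`: within-pair-opposite units for
#' every item, removed at retinotopic onset (verbalization of an unrelated
#' face). `graded_condition(k_old, k_new)`: exactly `k` correct features.
#'
#' @param seed Seed for graded feature sampling.
#' @param k_old,k_new Correct feature counts for the graded condition.
#' @return A [condition_spec()].
#' @export
similar_condition <- function() {
  condition_spec("similar", "consistent", "consistent", maintain = TRUE)
}

#' @rdname similar_condition
#' @export
dissimilar_condition <- function() {
  condition_spec("dissimilar", "consistent", "inconsistent", maintain = TRUE)
}

#' @rdname similar_condition
#' @export
irrelevant_condition <- function() {
  condition_spec("irrelevant", "inconsistent", "inconsistent",
                 maintain = FALSE)
}

#' @rdname similar_condition
#' @export
graded_condition <- function(k_old, k_new = k_old, seed = 1L) {
  condition_spec(sprintf("graded_k%d_k%d", k_old, k_new),
                 "graded", "graded", k_old = k_old, k_new = k_new,
                 maintain = TRUE, seed = seed)
}

# Correct verbal unit indices (1-based within the 6-unit layer) of one spec
# row: eyes, nose, lips.
correct_units <- function(spec) {
  c(1L + spec$eye_label, 3L + spec$nose_label, 5L + spec$lip_label)
}

# Within-pair opposite of a unit index.
opposite_unit <- function(u) ifelse(u %% 2L == 1L, u + 1L, u - 1L)

# 6 x length(items) 0/1 matrix of externally activated verbal units for a
# condition. Graded feature identities are sampled per item from the
# condition's seed (deterministic across models).
condition_selection <- function(condition, stimuli, items) {
  if (!is.null(condition$selection)) {
    sel <- condition$selection[, items, drop = FALSE]
    validate_selection(sel)
    return(sel)
  }
  set.seed(condition$seed)
  all_sel <- vapply(seq_len(nrow(stimuli$specs)), function(i) {
    spec <- stimuli$specs[i, ]
    rule <- if (spec$trained) condition$rule_old else condition$rule_new
    k <- if (spec$trained) condition$k_old else condition$k_new
    cu <- correct_units(spec)
    units <- switch(rule,
      consistent = cu,
      inconsistent = opposite_unit(cu),
      graded = {
        ok <- seq_len(3) %in% sample.int(3, k)
        ifelse(ok, cu, opposite_unit(cu))
      })
    v <- numeric(6); v[units] <- 1; v
  }, numeric(6))
  sel <- all_sel[, items, drop = FALSE]
  validate_selection(sel)
  sel
}

validate_selection <- function(sel) {
  pair_sums <- sel[c(1, 3, 5), , drop = FALSE] + sel[c(2, 4, 6), , drop = FALSE]
  if (any(pair_sums != 1))
    stop("verbal selection must activate exactly one unit per feature pair")
  invisible(sel)
}

#' Run one verbalization condition across model instances
#'
#' For every item and model, runs the two-phase trial (verbal units
#' soft-clamped for the verbalization phase, then retinotopic onset with the
#' clamp maintained or removed), measures mean visual-image polarity at the
#' 10th post-onset cycle, judges old/new with the frozen control criterion,
#' and aggregates across models.
#'
#' @param condition A [condition_spec()].
#' @param models List of `face_model`s.
#' @param stimuli A `stimulus_set`.
#' @param criterion The frozen control [select_criterion()].
#' @param params A [network_params()].
#' @return A list of class `condition_result`: `name`, `samples`,
#'   `per_model`, `accuracy`, `hit`, `correct_rejection`, `se`.
#' @export
run_condition <- function(condition, models, stimuli, criterion,
                          params = network_params()) {
  samples <- polarity_distribution(models, stimuli, condition, params)
  judged <- judge_old_new(samples, criterion)
  structure(c(list(name = if (is.null(condition)) "control" else condition$name,
                   samples = samples), judged),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("Condition '%s': accuracy %.1f%% (SE %.3f), hits %.1f%%, CR %.1f%%\n",
              x$name, 100 * x$accuracy, x$se, 100 * x$hit,
              100 * x$correct_rejection))
  invisible(x)
}

#' Paired t-test of a condition against control
#'
#' Two-sided paired t on per-model accuracies (`control - condition`;
#' positive t = accuracy drop), df = number of model instances minus one.
#' With zero variance of the differences, t is reported as signed infinity
#' (p ~ 0) or 0 (p = 1) when the mean difference is also zero.
#'
#' @param condition,control `condition_result`s over the same model
#'   instances.
#' @return List `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_vs_control <- function(condition, control) {
  stopifnot(identical(condition$per_model$model_id,
                      control$per_model$model_id))
  d <- control$per_model$accuracy - condition$per_model$accuracy
  n <- length(d)
  stopifnot(n >= 2)
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1L, p = p, mean_diff = m)
}

#' Graded description-accuracy distributions
#'
#' Runs the graded condition for every description accuracy level k in
#' 0, 1, 2, 3 correct features (0%, 33.3%, 66.7%, 100%), for all items, and
#' returns the polarity distributions. Old/new accuracy for a pairing of an
#' old-item level `k_old` with a new-item level `k_new` is computed by
#' [graded_pair_accuracy()].
#'
#' @param models List of `face_model`s.
#' @param stimuli A `stimulus_set`.
#' @param seed Seed for per-item feature sampling.
#' @param params A [network_params()].
#' @return A list of class `graded_result`: `distributions` (list `k0`-`k3`
#'   of polarity sample data.frames).
#' @export
run_graded_accuracy <- function(models, stimuli, seed = 1L,
                                params = network_params()) {
  distributions <- lapply(0:3, function(k) {
    cond <- graded_condition(k, k, seed = seed)
    polarity_distribution(models, stimuli, cond, params)
  })
  names(distributions) <- paste0("k", 0:3)
  structure(list(distributions = distributions), class = "graded_result")
}

#' @rdname run_graded_accuracy
#' @param graded A `graded_result`.
#' @param k_old,k_new Description accuracy level (0-3 correct features) for
#'   old and new items.
#' @param criterion The frozen control criterion.
#' @return `graded_pair_accuracy`: a `condition_result` combining the old
#'   items of level `k_old` with the new items of level `k_new`.
#' @export
graded_pair_accuracy <- function(graded, k_old, k_new, criterion) {
  d_old <- graded$distributions[[paste0("k", k_old)]]
  d_new <- graded$distributions[[paste0("k", k_new)]]
  samples <- rbind(d_old[d_old$old, ], d_new[!d_new$old, ])
  judged <- judge_old_new(samples, criterion)
  structure(c(list(name = sprintf("graded old k=%d vs new k=%d", k_old, k_new),
                   samples = samples), judged),
            class = "condition_result")
}

#' Single-trial lineup test
#'
#' Emulates the N-alternative forced-choice lineup: each repetition samples
#' one old item and `n_distractors` new items (without replacement) from a
#' model's polarity samples and scores a success when the old item's
#' polarity is strictly maximal (ties count as failures and are tallied).
#'
#' @param samples Polarity samples for one model/condition (data.frame with
#'   `old`, `polarity`).
#' @param n_distractors Number of new-item distractors (7 emulates the
#'   classic eight-alternative lineup).
#' @param repetitions Monte-Carlo repetitions.
#' @param seed RNG seed.
#' @return A list of class `lineup_result`: `proportion`, `se` (Monte-Carlo),
#'   `ties`, `n_distractors`, `repetitions`.
#' @export
single_trial_lineup <- function(samples, n_distractors = 7L,
                                repetitions = 10000L, seed = 1L) {
  old_pol <- samples$polarity[samples$old]
  new_pol <- samples$polarity[!samples$old]
  if (n_distractors > length(new_pol))
    stop("n_distractors exceeds the number of new-item samples")
  set.seed(seed)
  targets <- old_pol[sample.int(length(old_pol), repetitions, replace = TRUE)]
  best_new <- vapply(seq_len(repetitions), function(i) {
    max(new_pol[sample.int(length(new_pol), n_distractors)])
  }, numeric(1))
  success <- targets > best_new
  p <- mean(success)
  structure(list(proportion = p,
                 se = sqrt(p * (1 - p) / repetitions),
                 ties = sum(targets == best_new),
                 n_distractors = as.integer(n_distractors),
                 repetitions = as.integer(repetitions)),
            class = "lineup_result")
}

#' Run the full experiment suite
#'
#' Generates the stimulus set, trains the model instances, fits the control
#' criterion, and runs all simulations: control old/new recognition,
#' nearest-neighbour recognition accuracy on trained and untrained faces,
#' the similar/dissimilar/irrelevant verbalization conditions with paired
#' t-tests against control, the graded description-accuracy levels with the
#' two diagnostic pairings, and a single-trial lineup.
#'
#' @param stim_seed Seed for the stimulus set (trained/untrained split).
#' @param model_seeds Integer seeds, one per model instance (default 5
#'   instances derived from `stim_seed`).
#' @param config A [training_config()].
#' @param params A [network_params()].
#' @param sd Retinotopic smoothing width.
#' @param graded_seed Seed for graded feature sampling.
#' @param lineup_repetitions Monte-Carlo repetitions of the lineup test.
#' @param verbose Print progress messages.
#' @return A list of class `experiment_suite`: `stimuli`, `models`,
#'   `criterion`, per-condition `condition_result`s, `t_tests`, `graded`,
#'   `lineup`, `nn_accuracy`, and a `summary` data.frame.
#' @export
run_experiment_suite <- function(stim_seed = 1L,
                                 model_seeds = stim_seed + 1:5,
                                 config = training_config("reduced"),
                                 params = network_params(),
                                 sd = 0.2,
                                 graded_seed = stim_seed + 100L,
                                 lineup_repetitions = 10000L,
                                 verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  say("Building stimulus set (seed ", stim_seed, ")")
  stimuli <- build_stimulus_set(seed = stim_seed, sd = sd)
  mask <- derive_connectivity(stimuli)
  models <- lapply(seq_along(model_seeds), function(i) {
    say("Training model instance ", i, "/", length(model_seeds),
        " (seed ", model_seeds[i], ")")
    train_model(stimuli, seed = model_seeds[i], config = config,
                params = params, mask = mask)
  })
  old_items <- item_ids(stimuli, TRUE)
  new_items <- item_ids(stimuli, FALSE)

  say("Scoring nearest-neighbour recognition")
  nn_trained <- mean(vapply(models, visual_accuracy, numeric(1),
                            stimuli = stimuli, items = old_items,
                            params = params))
  nn_untrained <- mean(vapply(models, visual_accuracy, numeric(1),
                              stimuli = stimuli, items = new_items,
                              params = params))

  say("Control condition and criterion")
  control_samples <- polarity_distribution(models, stimuli, NULL, params)
  criterion <- select_criterion(control_samples)
  control <- structure(c(list(name = "control", samples = control_samples),
                         judge_old_new(control_samples, criterion)),
                       class = "condition_result")

  conds <- list(similar = similar_condition(),
                dissimilar = dissimilar_condition(),
                irrelevant = irrelevant_condition())
  results <- lapply(conds, function(cn) {
    say("Condition: ", cn$name)
    run_condition(cn, models, stimuli, criterion, params)
  })

  say("Graded description accuracy")
  graded <- run_graded_accuracy(models, stimuli, seed = graded_seed,
                                params = params)
  graded_21 <- graded_pair_accuracy(graded, 2, 1, criterion)
  graded_10 <- graded_pair_accuracy(graded, 1, 0, criterion)

  all_results <- c(list(control = control), results,
                   list(graded_2v1 = graded_21, graded_1v0 = graded_10))
  t_tests <- lapply(all_results[-1], paired_t_vs_control, control = control)

  say("Single-trial lineup")
  lineup <- single_trial_lineup(
    results$similar$samples[results$similar$samples$model_id == 1, ],
    n_distractors = 7L, repetitions = lineup_repetitions,
    seed = stim_seed + 200L)

  summary <- data.frame(
    condition = names(all_results),
    accuracy = vapply(all_results, function(r) r$accuracy, numeric(1)),
    hit = vapply(all_results, function(r) r$hit, numeric(1)),
    correct_rejection = vapply(all_results, function(r) r$correct_rejection,
                               numeric(1)),
    se = vapply(all_results, function(r) r$se, numeric(1)),
    t_vs_control = c(NA, vapply(t_tests, function(x) x$t, numeric(1))),
    p_vs_control = c(NA, vapply(t_tests, function(x) x$p, numeric(1))),
    row.names = NULL)

  structure(list(stimuli = stimuli, models = models, criterion = criterion,
                 control = control, similar = results$similar,
                 dissimilar = results$dissimilar,
                 irrelevant = results$irrelevant, graded = graded,
                 graded_2v1 = graded_21, graded_1v0 = graded_10,
                 t_tests = t_tests, lineup = lineup,
                 nn_accuracy = c(trained = nn_trained,
                                 untrained = nn_untrained),
                 summary = summary),
            class = "experiment_suite")
}

#' @export
print.experiment_suite <- function(x, ...) {
  cat("Verbal overshadowing experiment suite (",
      length(x$models), " model instances)\n", sep = "")
  cat(sprintf("Nearest-neighbour recognition: trained %.1f%%, untrained %.1f%%\n",
              100 * x$nn_accuracy["trained"], 100 * x$nn_accuracy["untrained"]))
  df <- x$summary
  df$accuracy <- sprintf("%.1f%%", 100 * df$accuracy)
  df$hit <- sprintf("%.1f%%", 100 * df$hit)
  df$correct_rejection <- sprintf("%.1f%%", 100 * df$correct_rejection)
  print(df, digits = 3)
  invisible(x)
}
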