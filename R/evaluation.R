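## Scoring: nearest-neighbour classification, task accuracies, polarity
## (familiarity), criterion-based old/new judgment, and MDS of hidden
## trajectories.

#' Nearest-neighbour classification of a visual-image output
#'
#' Classifies an output vector over the connected visual-image units as the
#' item whose target vector lies at the smallest Euclidean distance. Ties
#' are broken by the lowest item id and flagged in the `tie` attribute.
#'
#' @param output Numeric vector over the connected visual units.
#' @param stimuli A `stimulus_set`.
#' @param mask A `connectivity_mask` for `stimuli`.
#' @return The winning item id, with attribute `tie` (logical).
#' @export
nearest_neighbor_classify <- function(output, stimuli, mask) {
  targets <- stimuli$images[mask$vis, , drop = FALSE]
  d2 <- colSums((targets - output)^2)
  win <- which(d2 == min(d2))
  structure(stimuli$specs$item_id[win[1]], tie = length(win) > 1L)
}

# Final-cycle visual outputs for a batch of recognition trials (noise off).
# condition = NULL gives the plain control visual-recognition trial.
final_visual_outputs <- function(weights, stimuli, items,
                                 params = network_params(),
                                 condition = NULL, selection = NULL) {
  weights <- model_weights(weights)
  inp <- connected_inputs(stimuli, weights$mask)
  if (is.null(condition)) {
    eval_visual_cpp(weights, inp$RET, items, params, NULL)
  } else {
    eval_visual_cpp(weights, inp$RET, items, params, selection,
                    pre_cycles = condition$pre_cycles,
                    maintain = condition$maintain)
  }
}

#' Nearest-neighbour visual recognition accuracy
#'
#' Presents each item's retinotopic input, reads the visual-image output at
#' the end of the trial, and scores it correct when the nearest target (by
#' Euclidean distance over connected units) is the item's own.
#'
#' @param weights A `weight_set` or `face_model`.
#' @param stimuli A `stimulus_set`.
#' @param items Item ids to test.
#' @param params A [network_params()].
#' @return Proportion correct.
#' @export
visual_accuracy <- function(weights, stimuli, items,
                            params = network_params()) {
  weights <- model_weights(weights)
  out <- final_visual_outputs(weights, stimuli, items, params)
  targets <- stimuli$images[weights$mask$vis, , drop = FALSE]
  pred <- vapply(seq_along(items), function(k) {
    d2 <- colSums((targets - out[, k])^2)
    which.min(d2)
  }, integer(1))
  mean(stimuli$specs$item_id[pred] == items)
}

#' Verbalization accuracy
#'
#' Runs a verbalization trial per item (retinotopic input, noise off) and
#' scores it correct when, within each of the three verbal label pairs, the
#' correct unit is the more active one at the final cycle (equivalently:
#' the item's label triple is the nearest of the 8 possible triples).
#'
#' @inheritParams visual_accuracy
#' @return Proportion correct.
#' @export
verbal_accuracy <- function(weights, stimuli, items,
                            params = network_params()) {
  weights <- model_weights(weights)
  mask <- weights$mask
  correct <- vapply(items, function(it) {
    trial <- make_trial("verbalization", it, stimuli, mask, params)
    traj <- run_trial(weights, trial, params)
    a <- layer_traj(traj, "verb")[, traj$n_cycles + 1L]
    target <- stimuli$verbal[mask$verb, it]
    all(vapply(c(1, 3, 5), function(p) {
      which.max(a[p:(p + 1)]) == which.max(target[p:(p + 1)])
    }, logical(1)))
  }, logical(1))
  mean(correct)
}

#' Mental imagery accuracy
#'
#' Soft-clamps the verbal layer to the item's label vector (no retinotopic
#' input), reads the visual-image output at the final cycle, and scores by
#' the nearest-neighbour criterion against all target images. Because every
#' label triple is shared by several faces, this one-to-many mapping cannot
#' reach 100%.
#'
#' @inheritParams visual_accuracy
#' @return Proportion of items whose own target is the nearest.
#' @export
imagery_accuracy <- function(weights, stimuli, items,
                             params = network_params()) {
  weights <- model_weights(weights)
  mask <- weights$mask
  targets <- stimuli$images[mask$vis, , drop = FALSE]
  correct <- vapply(items, function(it) {
    trial <- make_trial("imagery", it, stimuli, mask, params)
    traj <- run_trial(weights, trial, params)
    a <- layer_traj(traj, "vis")[, traj$n_cycles + 1L]
    d2 <- colSums((targets - a)^2)
    stimuli$specs$item_id[which.min(d2)] == it
  }, logical(1))
  mean(correct)
}

## ---- polarity ------------------------------------------------------------

#' Polarity of an activation value
#'
#' One minus the binary entropy of the activation:
#' `a * log2(a) + (1 - a) * log2(1 - a) + 1`, with the convention
#' `0 * log2(0) = 0`. Ranges from 0 (activation at 0.5, maximally
#' ambiguous) to 1 (activation at 0 or 1, maximally confident), and is
#' symmetric about 0.5. Used as the familiarity axis of old/new decisions.
#'
#' @param a Activation value(s) in `[0, 1]`.
#' @return Polarity value(s) in `[0, 1]`.
#' @export
polarity <- function(a) {
  if (any(a < 0 | a > 1)) stop("activation outside [0, 1]")
  term <- function(x) ifelse(x == 0, 0, x * log2(x))
  term(a) + term(1 - a) + 1
}

#' Measure per-item polarity under a condition
#'
#' Runs the (possibly two-phase) recognition trial for each item with noise
#' disabled, reads the visual-image activations at the 10th cycle after
#' retinotopic onset, and returns the mean polarity over connected units.
#'
#' @param model A `face_model` or `weight_set` (with mask).
#' @param stimuli A `stimulus_set`.
#' @param condition A [condition_spec()], or `NULL` for the control
#'   condition (no verbalization).
#' @param items Item ids (default: all 64).
#' @param params A [network_params()].
#' @param model_id Identifier recorded in the output.
#' @return A data.frame: `model_id`, `item_id`, `old`, `condition`,
#'   `polarity`.
#' @export
measure_item_polarity <- function(model, stimuli, condition = NULL,
                                  items = stimuli$specs$item_id,
                                  params = network_params(), model_id = 1L) {
  weights <- model_weights(model)
  selection <- if (!is.null(condition))
    condition_selection(condition, stimuli, items)
  out <- final_visual_outputs(weights, stimuli, items, params,
                              condition, selection)
  pol <- colMeans(polarity(out))
  data.frame(model_id = model_id, item_id = items,
             old = stimuli$specs$trained[items],
             condition = if (is.null(condition)) "control" else condition$name,
             polarity = pol)
}

#' Polarity distribution across model instances
#'
#' [measure_item_polarity()] applied to each model, row-bound.
#'
#' @param models List of `face_model`s.
#' @inheritParams measure_item_polarity
#' @return A data.frame of polarity samples (one row per model x item).
#' @export
polarity_distribution <- function(models, stimuli, condition = NULL,
                                  params = network_params()) {
  do.call(rbind, lapply(seq_along(models), function(m) {
    measure_item_polarity(models[[m]], stimuli, condition,
                          params = params, model_id = m)
  }))
}

## ---- old/new decision ----------------------------------------------------

#' Fit the old/new decision criterion on the control condition
#'
#' Sets, per model instance, the threshold infinitesimally below that
#' instance's minimum old-item polarity, so the hit rate is 100% by
#' construction and the correct-rejection rate is emergent. The criterion is
#' then frozen and reused unchanged across verbalization conditions.
#'
#' @param control Control-condition polarity samples from
#'   [polarity_distribution()].
#' @param eps Offset below the minimum old-item polarity.
#' @return A `decision_criterion`: data.frame `model_id`, `threshold`, with
#'   attribute `provenance`.
#' @export
select_criterion <- function(control, eps = 1e-8) {
  per_model <- do.call(rbind, lapply(split(control, control$model_id),
    function(d) {
      old_pol <- d$polarity[d$old]
      if (max(d$polarity) == min(d$polarity))
        warning("degenerate polarity distribution (all values equal)")
      data.frame(model_id = d$model_id[1], threshold = min(old_pol) - eps)
    }))
  rownames(per_model) <- NULL
  structure(per_model, class = c("decision_criterion", "data.frame"),
            provenance = unique(control$condition))
}

#' Criterion-based old/new judgment
#'
#' Judges an item "old" when its mean polarity exceeds the (frozen) model's
#' threshold. Accuracy is the unweighted mean of the hit rate and the
#' correct-rejection rate.
#'
#' @param samples Polarity samples from [polarity_distribution()].
#' @param criterion A [select_criterion()] result.
#' @return List with `per_model` (data.frame: hit, correct_rejection,
#'   accuracy per model), `accuracy` (mean across models), and `se`
#'   (standard error across models).
#' @export
judge_old_new <- function(samples, criterion) {
  per_model <- do.call(rbind, lapply(split(samples, samples$model_id),
    function(d) {
      thr <- criterion$threshold[criterion$model_id == d$model_id[1]]
      stopifnot(length(thr) == 1L)
      hit <- mean(d$polarity[d$old] > thr)
      cr <- mean(d$polarity[!d$old] <= thr)
      data.frame(model_id = d$model_id[1], hit = hit,
                 correct_rejection = cr, accuracy = (hit + cr) / 2)
    }))
  rownames(per_model) <- NULL
  n <- nrow(per_model)
  list(per_model = per_model,
       accuracy = mean(per_model$accuracy),
       hit = mean(per_model$hit),
       correct_rejection = mean(per_model$correct_rejection),
       se = if (n > 1) sd(per_model$accuracy) / sqrt(n) else NA_real_)
}

## ---- MDS of hidden trajectories -----------------------------------------

#' Classical MDS projection of hidden-layer trajectories
#'
#' Pools the per-cycle hidden-layer activation snapshots of several trials
#' and embeds them by classical (metric) multidimensional scaling on
#' pairwise Euclidean distances. Axis signs are fixed deterministically
#' (largest-magnitude coordinate positive per axis).
#'
#' @param trajectories List of matrices (cycles x hidden units), e.g.
#'   `t(layer_traj(traj, "hidden"))`.
#' @param k Target dimensionality (default 3). If fewer positive
#'   eigenvalues exist the embedding is reduced with a warning.
#' @return List with `points` (rows = pooled snapshots, `k` columns),
#'   `trajectory` (index of the source trajectory per row), and `eig`.
#' @export
project_mds <- function(trajectories, k = 3L) {
  pts <- do.call(rbind, trajectories)
  idx <- rep(seq_along(trajectories),
             vapply(trajectories, nrow, integer(1)))
  if (k > nrow(pts) - 1L) {
    warning("only ", nrow(pts) - 1L,
            " dimensions available for ", nrow(pts), " points")
    k <- nrow(pts) - 1L
  }
  mds <- stats::cmdscale(stats::dist(pts), k = k, eig = TRUE)
  npos <- sum(mds$eig > sqrt(.Machine$double.eps) * max(abs(mds$eig)))
  if (npos < k) {
    warning("only ", npos, " positive eigenvalues; returning ", npos,
            " dimensions")
    k <- npos
  }
  coords <- mds$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  list(points = coords, trajectory = idx, eig = mds$eig)
}
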