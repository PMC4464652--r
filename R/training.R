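## Training curriculum: visual-recognition pre-training to above-chance
## accuracy, then fully interleaved training of the three tasks.

TASK_CODES <- c(visual_recognition = 1L, verbalization = 2L, imagery = 3L)

#' Training configuration
#'
#' The `"full"` profile reproduces the standard curriculum (3000 repetitions
#' per item per task after pre-training); the `"reduced"` profile is a
#' desk-scale run (2000 repetitions) that preserves the qualitative result
#' pattern at a fraction of the cost.
#'
#' @param profile `"full"` or `"reduced"`.
#' @param reps_per_item_per_task Overrides the profile's repetition count.
#' @param pretrain_accuracy_threshold Pre-training stops at the first
#'   evaluation whose nearest-neighbour accuracy on the trained items
#'   exceeds this.
#' @param eval_interval Epochs between pre-training accuracy checks.
#' @param max_pretrain_epochs Per-attempt epoch cap for pre-training.
#' @param max_restarts With stochastic gradient descent from random weights
#'   a minority of initializations fall into a collapsed attractor (one
#'   item-independent hidden pattern) and never discriminate items; such
#'   attempts are detected by the per-attempt epoch cap and restarted from a
#'   seed derived deterministically from the instance seed, at most this
#'   many times before aborting.
#' @return A list of class `training_config`.
#' @export
training_config <- function(profile = c("full", "reduced"),
                            reps_per_item_per_task = NULL,
                            pretrain_accuracy_threshold = 0.5,
                            eval_interval = 25L,
                            max_pretrain_epochs = 600L,
                            max_restarts = 8L) {
  profile <- match.arg(profile)
  if (is.null(reps_per_item_per_task))
    reps_per_item_per_task <- if (profile == "full") 3000L else 2000L
  stopifnot(reps_per_item_per_task >= 1,
            pretrain_accuracy_threshold > 0, pretrain_accuracy_threshold < 1)
  structure(list(profile = profile,
                 reps_per_item_per_task = as.integer(reps_per_item_per_task),
                 pretrain_accuracy_threshold = pretrain_accuracy_threshold,
                 eval_interval = as.integer(eval_interval),
                 max_pretrain_epochs = as.integer(max_pretrain_epochs),
                 max_restarts = as.integer(max_restarts)),
            class = "training_config")
}

#' Pre-train visual recognition to above-chance accuracy
#'
#' Runs epochs of visual-recognition training over the trained items (order
#' reshuffled each epoch, one weight update per trial), evaluating
#' nearest-neighbour accuracy (noise disabled) every `eval_interval` epochs,
#' and stops at the first evaluation exceeding the accuracy threshold.
#' An attempt that does not reach the threshold within
#' `max_pretrain_epochs` epochs is treated as a collapsed initialization and
#' restarted from a deterministically derived seed (at most `max_restarts`
#' times); the attempt number is recorded in the log.
#'
#' @param weights A `weight_set` (fresh or checkpointed).
#' @param stimuli A `stimulus_set`.
#' @param config A [training_config()].
#' @param params A [network_params()].
#' @return List with `weights` and a `log` data.frame (attempt, epoch,
#'   accuracy).
#' @export
pretrain_visual <- function(weights, stimuli, config = training_config(),
                            params = network_params()) {
  inp <- connected_inputs(stimuli, weights$mask)
  train_items <- item_ids(stimuli, trained = TRUE)
  log <- data.frame(attempt = integer(), epoch = integer(),
                    accuracy = numeric())
  base_seed <- weights$init_seed
  for (attempt in seq_len(max(1L, config$max_restarts))) {
    if (attempt > 1L) {
      weights <- init_network(weights$mask, params,
                              seed = base_seed + 1000L * (attempt - 1L))
    }
    epoch <- 0L
    while (epoch < config$max_pretrain_epochs) {
      for (i in seq_len(config$eval_interval)) {
        deck <- sample(train_items)
        res <- train_schedule_cpp(weights, inp$RET, inp$VIS, inp$VERB,
                                  deck, rep(1L, length(deck)), params,
                                  use_noise = TRUE)
        weights[names(res$weights)] <- res$weights
        epoch <- epoch + 1L
      }
      acc <- visual_accuracy(weights, stimuli, train_items, params)
      log <- rbind(log, data.frame(attempt = attempt, epoch = epoch,
                                   accuracy = acc))
      if (acc > config$pretrain_accuracy_threshold)
        return(list(weights = weights, log = log))
    }
  }
  stop("pre-training did not exceed ", config$pretrain_accuracy_threshold,
       " accuracy within ", config$max_pretrain_epochs, " epochs in any of ",
       config$max_restarts, " attempts (last accuracy ",
       tail(log$accuracy, 1), ")")
}

#' Interleaved training of the three tasks
#'
#' Presents (item, task) training trials in a single seeded shuffled deck in
#' which every trained item occurs exactly `reps_per_item_per_task` times in
#' each of the three tasks, updating the weights after every trial.
#'
#' @inheritParams pretrain_visual
#' @return List with `weights` and a `log` data.frame of per-block mean
#'   error and mean stop cycle.
#' @export
train_interleaved <- function(weights, stimuli, config = training_config(),
                              params = network_params()) {
  inp <- connected_inputs(stimuli, weights$mask)
  train_items <- item_ids(stimuli, trained = TRUE)
  reps <- config$reps_per_item_per_task
  deck_items <- rep(train_items, times = 3L * reps)
  deck_tasks <- rep(rep(1:3, each = length(train_items)), times = reps)
  ord <- sample.int(length(deck_items))
  deck_items <- deck_items[ord]
  deck_tasks <- deck_tasks[ord]
  res <- train_schedule_cpp(weights, inp$RET, inp$VIS, inp$VERB,
                            deck_items, deck_tasks, params, use_noise = TRUE)
  weights[names(res$weights)] <- res$weights
  blk <- (seq_along(deck_items) - 1L) %/% 1000L + 1L
  log <- data.frame(block = sort(unique(blk)),
                    mean_error = as.numeric(tapply(res$error, blk, mean)),
                    mean_stop_cycle = as.numeric(tapply(res$stop_cycle, blk,
                                                        mean)))
  counts <- table(deck_items, deck_tasks)
  stopifnot(all(counts == reps))
  list(weights = weights, log = log)
}

#' Train one model instance end to end
#'
#' Initializes a weight set from the seed, pre-trains visual recognition to
#' above-chance accuracy, then runs the interleaved three-task curriculum.
#' All randomness (initial weights, trial order, hidden noise) derives from
#' the seed, so the same seed reproduces the same model bit-exactly.
#'
#' @param stimuli A `stimulus_set`.
#' @param seed Integer seed for this model instance.
#' @param config A [training_config()].
#' @param params A [network_params()].
#' @param mask Optional precomputed `connectivity_mask`.
#' @return A list of class `face_model`: `weights`, `params`, `config`,
#'   `seed`, `pretrain_log`, `train_log`.
#' @export
train_model <- function(stimuli, seed = 1L, config = training_config(),
                        params = network_params(), mask = NULL) {
  if (is.null(mask)) mask <- derive_connectivity(stimuli)
  weights <- init_network(mask, params, seed = seed)
  pre <- pretrain_visual(weights, stimuli, config, params)
  fin <- train_interleaved(pre$weights, stimuli, config, params)
  structure(list(weights = fin$weights, params = params, config = config,
                 seed = as.integer(seed), pretrain_log = pre$log,
                 train_log = fin$log),
            class = "face_model")
}

#' @export
print.face_model <- function(x, ...) {
  cat(sprintf(paste0("Trained face model (seed %d): %s profile, %d reps/item",
                     "/task; pre-training %d epochs (final accuracy %.2f)\n"),
              x$seed, x$config$profile, x$config$reps_per_item_per_task,
              max(x$pretrain_log$epoch), tail(x$pretrain_log$accuracy, 1)))
  invisible(x)
}

# Accept either a face_model or a raw weight_set wherever weights are needed.
model_weights <- function(x) {
  if (inherits(x, "face_model")) x$weights else x
}
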