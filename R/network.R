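## Network construction, activation dynamics and single-trial training.

#' Network hyperparameters
#'
#' Collects every fixed parameter of the activation dynamics, clamping,
#' error function and learning rule. Defaults are the model's standard
#' operating point: net inputs are time-averaged with rate 0.1, units are
#' logistic, external verbal input is blended in with gain 0.5, trials run
#' 10 cycles per phase with early stopping once every target-layer unit is
#' within 0.5 of its target, cross-entropy error with a 0.1 zero-error
#' radius, learning rate 0.05, weight decay 1e-8, zero momentum, batch size
#' 1, and Gaussian noise (SD 0.2) on the hidden layer's summed input during
#' training.
#'
#' @param n_hidden Hidden layer size.
#' @param integration_rate Time-averaging rate of the net input.
#' @param clamp_gain Soft-clamp gain for external verbal input.
#' @param cycles_per_phase Cycles the network settles per trial phase.
#' @param early_stop_threshold Output-target difference below which a
#'   training trial ends early (0, the default, disables early stopping so
#'   trials always run the full cycle count; 0.5 is the classic loose
#'   criterion).
#' @param zero_error_radius Output-target difference below which a unit
#'   back-propagates no error derivative.
#' @param error_start_cycle First cycle of a target phase on which error is
#'   injected (the early-stop comparison always runs from cycle 1).
#' @param error_aggregation `"mean"` averages the cross-entropy over the
#'   error-injected cycles of a trial (so the per-trial gradient magnitude
#'   does not scale with the number of cycles); `"sum"` accumulates it.
#' @param learning_rate,weight_decay,momentum,batch_size Learning rule
#'   parameters (momentum and batch size are fixed at 0 and 1; they are kept
#'   as explicit fields so the operating point is fully recorded).
#' @param hidden_input_noise_sd SD of the Gaussian noise added to the hidden
#'   layer's summed input during training.
#' @param init_weight_range Scale of the symmetric uniform weight
#'   initialization; each projection's half-width is this value divided by
#'   the square root of its fan-in (see [init_network()]).
#' @param epsilon_guard Guard inside logarithms of the cross-entropy.
#' @return A list of class `network_params`.
#' @export
network_params <- function(n_hidden = 20L,
                           integration_rate = 0.1,
                           clamp_gain = 0.5,
                           cycles_per_phase = 10L,
                           early_stop_threshold = 0,
                           zero_error_radius = 0.1,
                           error_start_cycle = 2L,
                           error_aggregation = c("mean", "sum"),
                           learning_rate = 0.05,
                           weight_decay = 1e-8,
                           momentum = 0,
                           batch_size = 1L,
                           hidden_input_noise_sd = 0.2,
                           init_weight_range = 1.0,
                           epsilon_guard = 1e-7) {
  error_aggregation <- match.arg(error_aggregation)
  stopifnot(integration_rate >= 0, clamp_gain >= 0, cycles_per_phase >= 1,
            zero_error_radius >= 0, hidden_input_noise_sd >= 0,
            momentum == 0, batch_size == 1L)
  structure(as.list(environment()), class = "network_params")
}

#' Derive the sparse connectivity mask from a stimulus set
#'
#' A peripheral unit is connected to the hidden layer only when its external
#' input/target value varies across the items of the set; constant units
#' (e.g., background pixels white in every face) receive no connections.
#'
#' @param stimuli A `stimulus_set`.
#' @param tol Variation below this is treated as constant.
#' @return A list of class `connectivity_mask` with logical vectors `ret`,
#'   `vis`, `verb`.
#' @export
derive_connectivity <- function(stimuli, tol = 1e-12) {
  varies <- function(m) {
    apply(m, 1, function(x) max(x) - min(x) > tol)
  }
  structure(list(ret = varies(stimuli$retinotopic),
                 vis = varies(stimuli$images),
                 verb = varies(stimuli$verbal)),
            class = "connectivity_mask")
}

# Stimulus matrices restricted to connected units (one item per column).
connected_inputs <- function(stimuli, mask) {
  list(RET = stimuli$retinotopic[mask$ret, , drop = FALSE],
       VIS = stimuli$images[mask$vis, , drop = FALSE],
       VERB = stimuli$verbal[mask$verb, , drop = FALSE])
}

#' Initialize a weight set
#'
#' Samples weights i.i.d. uniform and symmetric about zero, with each
#' projection's range scaled by the inverse square root of its fan-in
#' (`init_weight_range / sqrt(n_source_units)`), so every projection —
#' the 6-unit verbal layer as much as the thousands-of-units retinotopic
#' layer — contributes net input of comparable magnitude at the start of
#' training. Biases are uniform in `[-init_weight_range, init_weight_range]`.
#' Weights exist only between the hidden layer and connected peripheral
#' units.
#'
#' @param mask A `connectivity_mask` (or an integer list for micro networks:
#'   `list(nr=, nv=, nl=)`).
#' @param params A [network_params()].
#' @param seed Integer seed; the same seed yields an identical weight set.
#' @return A list of class `weight_set` holding the six weight matrices
#'   (`W_rh`, `W_vh`, `W_lh` peripheral-to-hidden; `W_hr`, `W_hv`, `W_hl`
#'   hidden-to-peripheral), the four bias vectors, layer sizes, and the mask.
#' @export
init_network <- function(mask, params = network_params(), seed = 1L) {
  if (inherits(mask, "connectivity_mask")) {
    nr <- sum(mask$ret); nv <- sum(mask$vis); nl <- sum(mask$verb)
  } else {
    nr <- mask$nr; nv <- mask$nv; nl <- mask$nl
  }
  nh <- params$n_hidden
  set.seed(seed)
  r <- params$init_weight_range
  draw <- function(n, m, fan) {
    matrix(runif(n * m, -r / sqrt(fan), r / sqrt(fan)), n, m)
  }
  w <- list(
    W_rh = draw(nr, nh, nr), W_vh = draw(nv, nh, nv), W_lh = draw(nl, nh, nl),
    W_hr = draw(nh, nr, nh), W_hv = draw(nh, nv, nh), W_hl = draw(nh, nl, nh),
    b_h = runif(nh, -r, r), b_r = runif(nr, -r, r),
    b_v = runif(nv, -r, r), b_l = runif(nl, -r, r),
    mask = if (inherits(mask, "connectivity_mask")) mask else NULL,
    dims = list(nr = nr, nv = nv, nl = nl, nh = nh),
    init_seed = as.integer(seed)
  )
  class(w) <- "weight_set"
  w
}

#' @export
print.weight_set <- function(x, ...) {
  d <- x$dims
  cat(sprintf(paste0("Weight set: retinotopic %d, visual image %d, verbal %d",
                     " <-> hidden %d (bidirectional, biases on all)\n"),
              d$nr, d$nv, d$nl, d$nh))
  invisible(x)
}

#' Soft-clamp a unit's output toward an external input
#'
#' `output + gain * (external - output)`: a convex blend of the internally
#' computed output and the external input.
#'
#' @param output Internally computed activation(s).
#' @param external External input value(s).
#' @param gain Blend gain in `[0, 1]`.
#' @return Clamped activation(s).
#' @export
soft_clamp <- function(output, external, gain = 0.5) {
  output + gain * (external - output)
}

#' Construct a trial specification
#'
#' Builds the phase structure of one trial. Visual recognition: retinotopic
#' input hard-clamped, visual-image target. Verbalization: retinotopic input
#' hard-clamped, verbal target. Mental imagery: the verbal layer
#' soft-clamped to the item's label vector, no retinotopic input,
#' visual-image target. Recognition after verbalization: a verbalization
#' phase (selected verbal units soft-clamped to 1.0 for one phase) followed
#' by a recognition phase in which the retinotopic input is presented and
#' the verbal clamp is maintained or removed.
#'
#' @param task One of `"visual_recognition"`, `"verbalization"`,
#'   `"imagery"`, `"recognition_after_verbalization"`.
#' @param item Item id (column) in `stimuli`.
#' @param stimuli A `stimulus_set`.
#' @param mask A `connectivity_mask` for `stimuli`.
#' @param params A [network_params()].
#' @param train_flag If `TRUE`, the item must belong to the trained half and
#'   the trial carries a target for learning.
#' @param verbal_selection For `recognition_after_verbalization`: 0/1 vector
#'   over the 6 verbal units marking which are externally activated.
#' @param maintain For `recognition_after_verbalization`: keep the verbal
#'   clamp during the recognition phase (`TRUE`) or remove it at retinotopic
#'   onset (`FALSE`).
#' @return A list of class `trial_spec` with elements `task`, `item`,
#'   `phases`, `train_flag`.
#' @export
make_trial <- function(task, item, stimuli, mask, params = network_params(),
                       train_flag = FALSE, verbal_selection = NULL,
                       maintain = TRUE) {
  task <- match.arg(task, c("visual_recognition", "verbalization", "imagery",
                            "recognition_after_verbalization"))
  if (train_flag && !stimuli$specs$trained[item])
    stop("training trial requested for an untrained item")
  inp <- connected_inputs(stimuli, mask)
  n <- params$cycles_per_phase
  no_target <- list(target_layer = 0L, target = NULL)
  phase <- function(...) {
    p <- list(n_cycles = n, ret_ext = NULL, verb_mask = NULL, verb_ext = NULL,
              target_layer = 0L, target = NULL)
    p[names(list(...))] <- list(...)
    p
  }
  phases <- switch(task,
    visual_recognition = list(phase(ret_ext = inp$RET[, item],
                                    target_layer = if (train_flag) 1L else 0L,
                                    target = if (train_flag) inp$VIS[, item])),
    verbalization = list(phase(ret_ext = inp$RET[, item],
                               target_layer = if (train_flag) 2L else 0L,
                               target = if (train_flag) inp$VERB[, item])),
    imagery = list(phase(verb_mask = inp$VERB[, item],
                         verb_ext = rep(1, nrow(inp$VERB)),
                         target_layer = if (train_flag) 1L else 0L,
                         target = if (train_flag) inp$VIS[, item])),
    recognition_after_verbalization = {
      if (is.null(verbal_selection))
        stop("verbal_selection required for recognition after verbalization")
      if (train_flag)
        stop("the two-phase trial is an evaluation trial, not a training trial")
      sel <- as.numeric(verbal_selection)
      ones <- rep(1, length(sel))
      list(phase(verb_mask = sel, verb_ext = ones),
           if (maintain) phase(ret_ext = inp$RET[, item], verb_mask = sel,
                               verb_ext = ones)
           else phase(ret_ext = inp$RET[, item]))
    })
  structure(list(task = task, item = item, phases = phases,
                 train_flag = train_flag),
            class = "trial_spec")
}

#' Run one trial of the network
#'
#' Settles the network over the trial's phases. Each cycle performs one
#' synchronous update: net inputs are time-averaged
#' (`s_t = s_{t-1} + rate * (input_t - s_{t-1})`), activations are logistic
#' in the net input, then soft-clamped layers are blended toward their
#' external input and hard-clamped layers are overwritten by it. Net inputs
#' persist across phase boundaries (no reset). When a target is active, the
#' phase ends early once every target-layer unit is within the early-stop
#' threshold of its target.
#'
#' @param weights A `weight_set`.
#' @param trial A [make_trial()] spec, or a raw list of phases.
#' @param params A [network_params()].
#' @param noise Draw Gaussian hidden-input noise (training-style) if `TRUE`.
#' @param gradient Also compute the BPTT gradient.
#' @return A `trajectory`: list with `S`, `A` (units x cycles+1; column 1 is
#'   the initial state), `stop_cycles` per phase, `phase_of_cycle`,
#'   `n_cycles`, `error`, `dims`, and `gradient` when requested.
#' @export
run_trial <- function(weights, trial, params = network_params(),
                      noise = FALSE, gradient = FALSE) {
  phases <- if (inherits(trial, "trial_spec")) trial$phases else trial
  out <- run_trial_cpp(weights, phases, params, noise, gradient)
  out$dims <- weights$dims
  class(out) <- "trajectory"
  out
}

#' Extract one layer's activations from a trajectory
#'
#' @param traj A `trajectory` from [run_trial()].
#' @param layer `"ret"`, `"vis"`, `"verb"` or `"hidden"`.
#' @param what `"A"` (activations) or `"S"` (net inputs).
#' @return Matrix units x (cycles + 1); column 1 is the initial state.
#' @export
layer_traj <- function(traj, layer = c("vis", "ret", "verb", "hidden"),
                       what = c("A", "S")) {
  layer <- match.arg(layer); what <- match.arg(what)
  d <- traj$dims
  idx <- switch(layer,
    ret = seq_len(d$nr),
    vis = d$nr + seq_len(d$nv),
    verb = d$nr + d$nv + seq_len(d$nl),
    hidden = d$nr + d$nv + d$nl + seq_len(d$nh))
  traj[[what]][idx, , drop = FALSE]
}

#' Cross-entropy error with a zero-error radius
#'
#' Error summed over target units, with outputs guarded away from 0 and 1
#' inside the logarithms. Units whose output lies within the zero-error
#' radius of the target contribute zero gradient (but their error is still
#' reported).
#'
#' @param output,target Aligned activation vectors; targets in `[0, 1]`.
#' @param zero_error_radius Radius below which a unit's gradient is zeroed.
#' @param guard Epsilon guard inside the logarithms.
#' @return List with `error` (scalar) and `gradient` (per-unit d error /
#'   d output).
#' @export
compute_error <- function(output, target, zero_error_radius = 0.1,
                          guard = 1e-7) {
  stopifnot(length(output) == length(target), all(target >= 0 & target <= 1))
  ag <- pmin(pmax(output, guard), 1 - guard)
  err <- sum(-target * log(ag) - (1 - target) * log(1 - ag))
  grad <- (ag - target) / (ag * (1 - ag))
  grad[abs(output - target) <= zero_error_radius] <- 0
  list(error = err, gradient = grad)
}

#' One backpropagation-through-time weight update
#'
#' Runs the trial, backpropagates the per-cycle cross-entropy (injected from
#' the first cycle of the target phase through the stop cycle) through the
#' unrolled dynamics, and applies
#' `w <- w - learning_rate * gradient - weight_decay * w`. Momentum is zero,
#' so the update is independent of any previous update.
#'
#' @param weights A `weight_set`.
#' @param trial A training [make_trial()] spec.
#' @param params A [network_params()].
#' @param noise Hidden-input noise during the forward pass.
#' @return List with the updated `weights`, the `gradient`, and the
#'   forward `trajectory`.
#' @export
apply_bptt_update <- function(weights, trial, params = network_params(),
                              noise = FALSE) {
  traj <- run_trial(weights, trial, params, noise = noise, gradient = TRUE)
  g <- traj$gradient
  upd <- weights
  for (nm in c("W_rh", "W_vh", "W_lh", "W_hr", "W_hv", "W_hl",
               "b_h", "b_r", "b_v", "b_l")) {
    upd[[nm]] <- weights[[nm]] - params$learning_rate * g[[nm]] -
      params$weight_decay * weights[[nm]]
  }
  list(weights = upd, gradient = g, trajectory = traj)
}

#' Save / load a weight set
#'
#' Round-trips a `weight_set` bit-exactly through an RDS file.
#' @param weights A `weight_set`.
#' @param path File path.
#' @return `save_weight_set` invisibly returns `path`; `load_weight_set`
#'   returns the `weight_set`.
#' @export
save_weight_set <- function(weights, path) {
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_weight_set
#' @export
load_weight_set <- function(path) readRDS(path)
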