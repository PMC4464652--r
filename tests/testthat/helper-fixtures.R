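# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

std_stimuli <- function() cached("stimuli", function() build_stimulus_set(seed = 11))
std_mask <- function() cached("mask", function() derive_connectivity(std_stimuli()))

# Flattened 1-based pixel indices of a feature's row band.
region_idx <- function(rows) {
  unlist(lapply(rows, function(r) ((r - 1) * 60 + 1):((r - 1) * 60 + 60)))
}

# Maximum relative disagreement between the BPTT gradient and central finite
# differences over every weight and bias of a micro fixture.
max_grad_rel_error <- function(fx, h = 1e-5) {
  g <- run_trial(fx$weights, fx$phases, fx$params, gradient = TRUE)$gradient
  loss <- function(w) run_trial(w, fx$phases, fx$params)$error
  worst <- 0
  for (nm in c("W_rh", "W_vh", "W_lh", "W_hr", "W_hv", "W_hl",
               "b_h", "b_r", "b_v", "b_l")) {
    for (i in seq_along(fx$weights[[nm]])) {
      wp <- fx$weights; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- fx$weights; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (loss(wp) - loss(wm)) / (2 * h)
      worst <- max(worst, abs(g[[nm]][i] - fd) / max(1, abs(fd)))
    }
  }
  worst
}

# Desk-scale training of the 4-item micro stimulus set; cached across tests.
smoke_model <- function() {
  cached("smoke_model", function() {
    st <- make_micro_instance("four_item_stimuli", seed = 5)
    mask <- derive_connectivity(st)
    params <- network_params()
    config <- training_config("reduced", reps_per_item_per_task = 400L,
                              eval_interval = 10L)
    model <- train_model(st, seed = 3, config = config, params = params,
                         mask = mask)
    list(stimuli = st, mask = mask, params = params, model = model)
  })
}

# The scaled-down replication suite: 64 faces, 5 model instances, reduced
# repetitions. Built once and shared by the acceptance tests.
replication_suite <- function() {
  cached("replication_suite", function() {
    run_experiment_suite(stim_seed = 11, model_seeds = 11 + 1:5,
                         config = training_config("reduced"),
                         lineup_repetitions = 5000L, verbose = FALSE)
  })
}
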