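## Deterministic micro-instances for testing every stage without full-scale
## training: hand-checkable micro networks, a 4-item stimulus subset, and
## canned polarity distributions.

#' Build a deterministic test fixture
#'
#' * `"gradient_check"`: a micro network (3 retinotopic, 3 visual, 2 verbal,
#'   3 hidden units) plus a trial with a retinotopic clamp, a partial verbal
#'   soft clamp and a visual target, and parameters with the zero-error
#'   radius, early stopping and noise disabled — small enough for central
#'   finite-difference gradient oracles.
#' * `"four_item_stimuli"`: a 4-face subset of the factorial set (items
#'   whose subordinate type triples are (0,0,0), (1,1,1), (2,2,2), (3,3,3)),
#'   all marked trained. Items 1-2 share one verbal label triple and items
#'   3-4 the other, so mental imagery is a one-to-many mapping.
#' * `"overlap_distributions"`: canned old/new polarity samples, as a list
#'   with `disjoint` (all old polarities above all new) and `exchangeable`
#'   (old and new drawn from the identical distribution) data.frames of
#'   32 + 32 samples each.
#'
#' Every fixture regenerates bit-identically from `(kind, seed)`.
#'
#' @param kind One of `"gradient_check"`, `"four_item_stimuli"`,
#'   `"overlap_distributions"`.
#' @param seed Integer seed.
#' @return The fixture (see above).
#' @export
make_micro_instance <- function(kind = c("gradient_check",
                                         "four_item_stimuli",
                                         "overlap_distributions"),
                                seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    gradient_check = micro_gradient_fixture(seed),
    four_item_stimuli = micro_four_item_stimuli(seed),
    overlap_distributions = micro_overlap_distributions(seed))
}

micro_gradient_fixture <- function(seed) {
  params <- network_params(n_hidden = 3L, cycles_per_phase = 4L,
                           early_stop_threshold = 0,  # never stops early
                           zero_error_radius = 0,
                           hidden_input_noise_sd = 0,
                           init_weight_range = 0.5)
  weights <- init_network(list(nr = 3L, nv = 3L, nl = 2L), params,
                          seed = seed)
  set.seed(seed + 1L)
  phases <- list(list(n_cycles = params$cycles_per_phase,
                      ret_ext = runif(3),
                      verb_mask = c(1, 0), verb_ext = c(1, 0),
                      target_layer = 1L,
                      target = round(runif(3))))
  list(weights = weights, phases = phases, params = params)
}

micro_four_item_stimuli <- function(seed) {
  full <- build_stimulus_set(seed = seed)
  # subordinate triples (0,0,0), (1,1,1), (2,2,2), (3,3,3)
  pick <- vapply(0:3, function(t) {
    with(full$specs,
         item_id[eye_type == t & nose_type == t & lip_type == t])
  }, integer(1))
  specs <- full$specs[pick, ]
  specs$item_id <- seq_along(pick)
  specs$trained <- TRUE
  rownames(specs) <- NULL
  structure(list(specs = specs,
                 images = full$images[, pick, drop = FALSE],
                 retinotopic = full$retinotopic[, pick, drop = FALSE],
                 verbal = full$verbal[, pick, drop = FALSE],
                 seed = as.integer(seed), sd = full$sd,
                 glyph_version = full$glyph_version),
            class = "stimulus_set")
}

micro_overlap_distributions <- function(seed) {
  set.seed(seed)
  disjoint <- data.frame(
    model_id = 1L, item_id = 1:64, old = rep(c(TRUE, FALSE), each = 32),
    condition = "canned_disjoint",
    polarity = c(runif(32, 0.8, 1.0), runif(32, 0.0, 0.5)))
  exchangeable <- data.frame(
    model_id = 1L, item_id = 1:64, old = rep(c(TRUE, FALSE), each = 32),
    condition = "canned_exchangeable",
    polarity = runif(64, 0.2, 0.9))
  list(disjoint = disjoint, exchangeable = exchangeable)
}
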