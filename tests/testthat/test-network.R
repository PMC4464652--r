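# Activation dynamics, clamping, connectivity, error and BPTT updates.

# A bias-only network: every weight zero, so a hidden unit with bias b gets
# the constant summed input b.
bias_only_net <- function(b_h1 = 1) {
  p <- network_params(n_hidden = 2L, init_weight_range = 0,
                      hidden_input_noise_sd = 0)
  w <- init_network(list(nr = 2L, nv = 2L, nl = 2L), p, seed = 1)
  w$b_h <- c(b_h1, 0)
  list(w = w, p = p)
}

free_phase <- function(n = 10L, ...) {
  p <- list(n_cycles = n, ret_ext = NULL, verb_mask = NULL, verb_ext = NULL,
            target_layer = 0L, target = NULL)
  p[names(list(...))] <- list(...)
  list(p)
}

test_that("net input converges geometrically to a constant summed input", {
  net <- bias_only_net(b_h1 = 1)
  traj <- run_trial(net$w, free_phase(10L), net$p)
  s <- layer_traj(traj, "hidden", "S")[1, ]
  expect_equal(s[2], 0.1)                      # one step from s0 = 0
  expect_equal(s[11], 1 - 0.9^10)              # ten steps
  expect_equal(diff(1 - s[-1]) / (1 - s[2:10]) * -1, rep(0.1, 9),
               tolerance = 1e-12)              # ratio 0.9 per cycle
  # unclamped activations stay strictly inside (0, 1)
  expect_true(all(traj$A[, -1] > 0 & traj$A[, -1] < 1))
})

test_that("soft clamping is a convex blend of output and external input", {
  expect_equal(soft_clamp(0.2, 1.0), 0.6)
  expect_equal(soft_clamp(0.8, 0.0), 0.4)
  expect_equal(soft_clamp(0.5, 0.5), 0.5)
  a <- runif(50); e <- runif(50)
  out <- soft_clamp(a, e)
  expect_true(all(out >= pmin(a, e) & out <= pmax(a, e)))
})

test_that("clamped layers match their external input at every cycle, and the
           soft-clamped trajectory follows the blend rule", {
  net <- bias_only_net()
  ret <- c(0.3, 0.9)
  traj <- run_trial(net$w, free_phase(10L, ret_ext = ret), net$p)
  A_ret <- layer_traj(traj, "ret")
  expect_true(all(A_ret[, -1] == ret))
  # soft clamp: output = sigmoid(s) + 0.5 * (1 - sigmoid(s))
  traj2 <- run_trial(net$w, free_phase(10L, verb_mask = c(1, 0),
                                       verb_ext = c(1, 0)), net$p)
  A_l <- layer_traj(traj2, "verb")
  S_l <- layer_traj(traj2, "verb", "S")
  intl <- 1 / (1 + exp(-S_l[1, -1]))
  expect_equal(A_l[1, -1], intl + 0.5 * (1 - intl))
  expect_equal(A_l[2, -1], 1 / (1 + exp(-S_l[2, -1])))  # unmasked unit free
})

test_that("connectivity links only units whose values vary across items", {
  st <- std_stimuli()
  mask <- std_mask()
  expect_true(all(mask$verb))                        # each label used by 32
  constant_pixels <- apply(st$images, 1, function(x) all(x == x[1]))
  expect_identical(unname(mask$vis), unname(!constant_pixels))
  # toy 2-item set differing in one pixel
  toy <- list(retinotopic = cbind(c(0, 1, 0.5), c(0, 0, 0.5)),
              images = cbind(c(1, 1, 0), c(1, 0, 0)),
              verbal = cbind(c(1, 0), c(0, 1)))
  m <- derive_connectivity(toy)
  expect_equal(which(m$ret), 2L)
  expect_equal(which(m$vis), 2L)
})

test_that("weight initialization is seed-deterministic and mask-shaped", {
  p <- network_params()
  m <- std_mask()
  w1 <- init_network(m, p, seed = 4)
  w2 <- init_network(m, p, seed = 4)
  expect_identical(w1, w2)
  expect_false(identical(w1$W_rh, init_network(m, p, seed = 5)$W_rh))
  expect_equal(dim(w1$W_rh), c(sum(m$ret), p$n_hidden))
  expect_equal(dim(w1$W_hv), c(p$n_hidden, sum(m$vis)))
  w0 <- init_network(m, network_params(init_weight_range = 0), seed = 4)
  expect_true(all(w0$W_vh == 0) && all(w0$b_h == 0))
})

test_that("cross-entropy error and the zero-error radius behave as specified", {
  # exact match on binary targets: zero error, zero gradient
  r <- compute_error(c(0, 1, 1), c(0, 1, 1))
  expect_equal(r$error, 0, tolerance = 1e-6)
  expect_equal(r$gradient, c(0, 0, 0))
  # output 0.5 against target 1: error ln 2
  expect_equal(compute_error(0.5, 1)$error, log(2))
  # inside the radius: no gradient, error still counted
  r2 <- compute_error(0.95, 1, zero_error_radius = 0.1)
  expect_equal(r2$gradient, 0)
  expect_gt(r2$error, 0)
  r3 <- compute_error(0.95, 1, zero_error_radius = 0.01)
  expect_lt(r3$gradient, 0)
  expect_error(compute_error(0.5, 1.2), "target")
})

test_that("trials stop early once all target units are within threshold", {
  net <- bias_only_net()
  p05 <- net$p
  p05$early_stop_threshold <- 0.5
  # free-running outputs sit at 0.5, so a 0.5 target is met at cycle 1
  ph <- free_phase(10L, target_layer = 1L, target = c(0.5, 0.5))
  traj <- run_trial(net$w, ph, p05)
  expect_equal(traj$stop_cycles, 1L)
  # unreachable target: all 10 cycles run
  ph2 <- free_phase(10L, target_layer = 1L, target = c(1, 1))
  traj2 <- run_trial(net$w, ph2, p05)
  expect_equal(traj2$stop_cycles, 10L)
  # no target, or early stopping disabled: full cycle count
  expect_equal(run_trial(net$w, free_phase(10L), p05)$stop_cycles, 10L)
  expect_equal(run_trial(net$w, ph, net$p)$stop_cycles, 10L)
})

test_that("the trajectory's reported error matches compute_error on stored
           activations", {
  fx <- make_micro_instance("gradient_check", seed = 2)
  traj <- run_trial(fx$weights, fx$phases, fx$params)
  A_v <- layer_traj(traj, "vis")
  target <- fx$phases[[1]]$target
  es <- fx$params$error_start_cycle
  cycles <- which(traj$phase_of_cycle == 1)
  cycles <- cycles[cycles - 1 >= es]  # column 1 is the initial state
  per_cycle <- vapply(cycles, function(cc) {
    compute_error(A_v[, cc], target, fx$params$zero_error_radius)$error
  }, numeric(1))
  err <- if (fx$params$error_aggregation == "mean") mean(per_cycle)
         else sum(per_cycle)
  expect_equal(traj$error, err, tolerance = 1e-10)
})

test_that("BPTT gradients match central finite differences on micro networks", {
  for (seed in c(2, 7)) {
    fx <- make_micro_instance("gradient_check", seed = seed)
    expect_lt(max_grad_rel_error(fx), 1e-6)
  }
})

test_that("a zero gradient leaves only the weight-decay term in the update", {
  fx <- make_micro_instance("gradient_check", seed = 3)
  # move every target inside the zero-error radius of nothing: use radius 1
  fx$params$zero_error_radius <- 1
  res <- apply_bptt_update(fx$weights, fx$phases, fx$params)
  expect_equal(max(abs(res$gradient$W_rh)), 0)
  expect_equal(res$weights$W_rh,
               fx$weights$W_rh * (1 - fx$params$weight_decay))
})

test_that("training updates are momentum-free and seed-reproducible", {
  st <- make_micro_instance("four_item_stimuli", seed = 5)
  mask <- derive_connectivity(st)
  p <- network_params()
  w <- init_network(mask, p, seed = 9)
  trial <- make_trial("visual_recognition", 1, st, mask, p, train_flag = TRUE)
  # same state in, same update out, irrespective of a different prior update
  u1 <- apply_bptt_update(w, trial, p)
  u2 <- apply_bptt_update(u1$weights, trial, p)
  u2b <- apply_bptt_update(u1$weights, trial, p)
  expect_identical(u2$weights, u2b$weights)
  # single-trial C++ schedule equals the R-level single update
  inp <- vosim:::connected_inputs(st, mask)
  res <- vosim:::train_schedule_cpp(w, inp$RET, inp$VIS, inp$VERB,
                                    1L, 1L, p, use_noise = FALSE)
  expect_equal(res$weights$W_rh, u1$weights$W_rh, tolerance = 1e-12)
  expect_equal(res$weights$b_v, u1$weights$b_v, tolerance = 1e-12)
})

test_that("weight sets round-trip bit-exactly through checkpoints", {
  w <- init_network(list(nr = 3L, nv = 2L, nl = 2L),
                    network_params(n_hidden = 4L), seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_weight_set(w, path)
  expect_identical(load_weight_set(path), w)
})
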