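# Nearest-neighbour scoring, polarity, criterion-based old/new judgment,
# and MDS of hidden trajectories.

test_that("nearest-neighbour classification returns the closest target and
           logs ties", {
  st <- std_stimuli()
  mask <- std_mask()
  out <- st$images[mask$vis, 17]
  expect_equal(as.integer(nearest_neighbor_classify(out, st, mask)), 17L)
  # equidistant toy case: two identical targets tie, lowest item id wins
  toy <- list(images = cbind(c(1, 0, 1), c(0, 1, 1), c(1, 0, 1)),
              specs = data.frame(item_id = 1:3))
  toy_mask <- list(vis = rep(TRUE, 3))
  win <- nearest_neighbor_classify(c(1, 0, 1), toy, toy_mask)
  expect_equal(as.integer(win), 1L)
  expect_true(attr(win, "tie"))
})

test_that("polarity follows the entropy formula with its conventions", {
  expect_equal(polarity(0.5), 0)
  expect_equal(polarity(1), 1)
  expect_equal(polarity(0), 1)
  expect_equal(polarity(0.9), 0.9 * log2(0.9) + 0.1 * log2(0.1) + 1)
  expect_equal(round(polarity(0.9), 4), 0.5310)
  a <- seq(0, 1, by = 0.01)
  expect_equal(polarity(a), polarity(1 - a))          # symmetry
  expect_true(all(polarity(a) >= 0 & polarity(a) <= 1))
  expect_error(polarity(1.01), "outside")
  expect_error(polarity(-0.2), "outside")
})

test_that("criterion selection sits just below the minimum old polarity so
           hits are 100% by construction", {
  fx <- make_micro_instance("overlap_distributions", seed = 2)
  crit <- select_criterion(fx$disjoint)
  old_min <- min(fx$disjoint$polarity[fx$disjoint$old])
  expect_lt(crit$threshold, old_min)
  expect_gt(crit$threshold, old_min - 1e-6)
  judged <- judge_old_new(fx$disjoint, crit)
  expect_equal(judged$hit, 1)
  expect_equal(judged$correct_rejection, 1)  # disjoint: all new below
  # degenerate distribution warns
  degen <- fx$disjoint
  degen$polarity <- 0.7
  expect_warning(select_criterion(degen), "degenerate")
})

test_that("old/new accuracy is the unweighted mean of hit and correct
           rejection rates", {
  # engineered samples: hits 100%, correct rejections 30% -> accuracy 65%
  samples <- data.frame(
    model_id = 1L, item_id = 1:20, old = rep(c(TRUE, FALSE), each = 10),
    condition = "x",
    polarity = c(rep(0.96, 10), rep(0.99, 7), rep(0.5, 3)))
  crit <- data.frame(model_id = 1L, threshold = 0.95)
  class(crit) <- c("decision_criterion", "data.frame")
  judged <- judge_old_new(samples, crit)
  expect_equal(judged$hit, 1)
  expect_equal(judged$correct_rejection, 0.3)
  expect_equal(judged$accuracy, 0.65)
  # threshold above everything: all judged new -> accuracy 0.5
  crit$threshold <- 2
  expect_equal(judge_old_new(samples, crit)$accuracy, 0.5)
  # threshold below everything: all judged old -> accuracy 0.5
  crit$threshold <- -Inf
  expect_equal(judge_old_new(samples, crit)$accuracy, 0.5)
})

test_that("hit and false-alarm rates are non-increasing in the threshold,
           and identical distributions give accuracy 0.5 exactly", {
  set.seed(31)
  pol <- runif(64)
  samples <- data.frame(model_id = 1L, item_id = 1:64,
                        old = rep(c(TRUE, FALSE), 32), condition = "x",
                        polarity = pol)
  rates <- t(vapply(seq(0, 1, by = 0.05), function(thr) {
    crit <- data.frame(model_id = 1L, threshold = thr)
    j <- judge_old_new(samples, crit)
    c(hit = j$hit, fa = 1 - j$correct_rejection)
  }, numeric(2)))
  expect_true(all(diff(rates[, "hit"]) <= 0))
  expect_true(all(diff(rates[, "fa"]) <= 0))
  # identical old and new polarity values: accuracy exactly 0.5 at any
  # threshold
  same <- data.frame(model_id = 1L, item_id = 1:40,
                     old = rep(c(TRUE, FALSE), each = 20), condition = "x",
                     polarity = rep(runif(20), 2))
  for (thr in c(0.2, 0.5, 0.9)) {
    crit <- data.frame(model_id = 1L, threshold = thr)
    expect_equal(judge_old_new(same, crit)$accuracy, 0.5)
  }
})

test_that("classical MDS preserves known geometry deterministically", {
  # identical trajectories map to identical coordinates
  tr <- matrix(runif(40), 10, 4)
  res <- project_mds(list(tr, tr), k = 2)
  expect_equal(res$points[1:10, ], res$points[11:20, ])
  expect_equal(res$trajectory, rep(1:2, each = 10))
  # three collinear points: distances preserved, embedding collinear
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(7, 0, 0))
  res3 <- suppressWarnings(project_mds(list(pts), k = 3))
  d <- as.matrix(dist(res3$points))
  expect_equal(d[1, 2], 3, tolerance = 1e-8)
  expect_equal(d[1, 3], 7, tolerance = 1e-8)
  expect_equal(d[2, 3], 4, tolerance = 1e-8)
  if (ncol(res3$points) > 1) {
    expect_lt(max(abs(res3$points[, -1])), 1e-8)
  }
  # deterministic sign convention: repeated runs agree
  res3b <- suppressWarnings(project_mds(list(pts), k = 3))
  expect_identical(res3$points, res3b$points)
})
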