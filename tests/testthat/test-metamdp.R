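params_t1 <- tiny_params()  # Fixate-MAP defaults: cost 0.01, scale 3, k 200

test_that("belief initialization gives the uninformative prior", {
  s <- manual_scene(matrix(rnorm(8), 4))
  b <- init_beliefs(s, params_t1, seed = 1)
  expect_true(all(b$J == 0.01))
  expect_equal(unique(as.vector(1 / b$J)), 100)
  expect_equal(b$f_target, s$features[s$target_index, ])
  # Monte-Carlo check of the stated mean-jitter law
  means <- vapply(seq_len(10000), function(i)
    init_beliefs(s, params_t1)$F[1, 1], numeric(1))
  expect_lt(abs(mean(means)), 0.001)
  expect_equal(sd(means), 0.01, tolerance = 0.05)
})

test_that("identical beliefs give a uniform posterior (symmetry)", {
  s <- manual_scene(matrix(c(0.5, 0.5), 2, 1))
  b <- init_beliefs(s, params_t1, seed = 1)
  b$F[] <- 0
  expect_equal(target_posterior(b), c(0.5, 0.5))
})

test_that("the foveal kernel matches its closed form", {
  locs <- rbind(c(0, 0, 1),
                c(0, 0, 1),            # aligned
                c(1, 0, 0),            # orthogonal
                c(sin(10 * pi / 180), 0, cos(10 * pi / 180)))  # 10 degrees
  g <- attention_mask(locs, 1L, params_t1)
  expect_equal(g[1], 3)
  expect_equal(g[2], 3)
  expect_equal(g[3], 3 * exp(-200))
  expect_false(any(is.nan(g)))
  expect_true(all(g >= 0))
  # hand-computed scalar at 10 degrees of misalignment
  expect_equal(g[4], 3 * exp((cos(10 * pi / 180) - 1) * 200), tolerance = 1e-12)
  expect_error(attention_mask(rbind(c(0, 0, 2)), 1L, params_t1), "unit-norm")
})

test_that("measurements follow the stated noise law", {
  s <- manual_scene(matrix(c(1, -1, 0.5, 2), 2))
  # near-infinite precision pins the measurement to the latent state
  m <- withr::with_seed(1, sample_measurement(s, c(1e8, 1e8), params_t1))
  expect_lt(max(abs(m$X - s$features)), 1e-3)
  # precision at the floor is information-free: the update is a no-op
  b <- init_beliefs(s, params_t1, seed = 2)
  m0 <- sample_measurement(s, c(1e-13, 1e-13), params_t1)
  expect_true(all(m0$J_meas == 0))
  b2 <- update_beliefs(b, m0)
  expect_equal(b2$F, b$F)
  expect_equal(b2$J, b$J)
  expect_equal(b2$p, b$p)
  # empirical variance of X - A at g = 4
  xs <- withr::with_seed(3, vapply(seq_len(20000), function(i)
    sample_measurement(s, c(4, 4), params_t1)$X[1, 1], numeric(1)))
  expect_equal(var(xs - s$features[1, 1]), 0.25, tolerance = 0.02)
})

test_that("the Bayesian update matches direct conjugate arithmetic", {
  s <- manual_scene(matrix(0, 1, 1), target_index = 1L)
  b <- init_beliefs(s, params_t1, seed = 1)
  b$F[] <- 0
  m <- structure(list(X = matrix(1, 1, 1), J_meas = matrix(3, 1, 1)),
                 class = "measurement")
  b2 <- update_beliefs(b, m)
  expect_equal(b2$F[1, 1], 3 / 3.01, tolerance = 1e-12)
  expect_equal(b2$J[1, 1], 3.01, tolerance = 1e-12)
  expect_error(update_beliefs(b, structure(list(X = matrix(1, 1, 1),
                                                J_meas = matrix(-1, 1, 1)),
                                           class = "measurement")),
               "non-negative")
})

test_that("sequential updates equal the one-shot precision-weighted merge", {
  withr::with_seed(42, {
    for (case in 1:20) {
      n <- sample(2:4, 1)
      nf <- sample(1:3, 1)
      s <- manual_scene(matrix(rnorm(n * nf), n), target_index = 1L)
      b0 <- init_beliefs(s, params_t1)
      k <- sample(2:5, 1)
      Xs <- replicate(k, matrix(rnorm(n * nf), n), simplify = FALSE)
      Js <- replicate(k, matrix(rexp(n * nf), n), simplify = FALSE)
      b_seq <- b0
      for (i in seq_len(k))
        b_seq <- update_beliefs(b_seq, structure(list(X = Xs[[i]], J_meas = Js[[i]]),
                                                 class = "measurement"))
      merged <- merge_measurements(b0$F, b0$J, Xs, Js)
      expect_equal(b_seq$F, merged$F, tolerance = 1e-10)
      expect_equal(b_seq$J, merged$J, tolerance = 1e-10)
      # order invariance (conjugacy)
      perm <- sample(k)
      b_perm <- b0
      for (i in perm)
        b_perm <- update_beliefs(b_perm, structure(list(X = Xs[[i]], J_meas = Js[[i]]),
                                                   class = "measurement"))
      expect_equal(b_perm$F, b_seq$F, tolerance = 1e-10)
    }
  })
})

test_that("the target posterior matches the quadrature oracle on random beliefs", {
  withr::with_seed(7, {
    worst <- 0
    for (case in 1:30) {
      n <- sample(2:3, 1)
      nf <- sample(1:2, 1)
      F <- matrix(rnorm(n * nf), n)
      J <- matrix(rexp(n * nf, rate = 0.3), n)
      ft <- rnorm(nf)
      b <- structure(list(F = F, J = J, f_target = ft,
                          phantom_mask = rep(FALSE, n)),
                     class = "belief_state")
      p <- target_posterior(b)
      q <- quad_target_posterior(F, J, ft)
      worst <- max(worst, max(abs(p - q)))
    }
    expect_lt(worst, 1e-6)
  })
})

test_that("the posterior honors certainty limits and phantom zeroing", {
  # object 1 pinned at the target features, object 2 pinned far away
  b <- structure(list(F = matrix(c(1, 5), 2, 1), J = matrix(1e8, 2, 1),
                      f_target = 1, phantom_mask = c(FALSE, FALSE)),
                 class = "belief_state")
  expect_equal(target_posterior(b), c(1, 0), tolerance = 1e-6)
  # phantoms carry exactly zero mass
  b2 <- structure(list(F = matrix(0, 3, 1), J = matrix(0.01, 3, 1),
                       f_target = 0, phantom_mask = c(FALSE, FALSE, TRUE)),
                  class = "belief_state")
  p <- target_posterior(b2)
  expect_identical(p[3], 0)
  expect_equal(sum(p), 1)
  b3 <- b2
  b3$phantom_mask <- rep(TRUE, 3)
  expect_error(target_posterior(b3), "all objects are phantoms")
})

test_that("step rewards implement the cost and terminal payoff", {
  s <- manual_scene(matrix(c(2, -2), 2, 1), target_index = 1L)
  b <- init_beliefs(s, params_t1, seed = 1)
  out <- withr::with_seed(2, metamdp_step(s, b, 1L, params_t1))
  expect_equal(out$reward, -0.01)
  expect_false(out$done)
  # terminal action with mass on the target
  b$F <- s$features
  b$J <- matrix(100, 2, 1)
  b$p <- target_posterior(b)
  done <- metamdp_step(s, b, 0L, params_t1)
  expect_true(done$done)
  expect_equal(done$reward, 1)
  expect_identical(done$info$report, 1L)
  # terminal action with argmax on a distractor earns nothing
  s2 <- manual_scene(matrix(c(2, -2), 2, 1), target_index = 2L)
  b2 <- init_beliefs(s2, params_t1, seed = 1)
  b2$F <- s2$features
  b2$J <- matrix(100, 2, 1)
  b2$f_target <- 2  # beliefs (mistakenly) match the distractor's features
  b2$p <- target_posterior(b2)
  done2 <- metamdp_step(s2, b2, 0L, params_t1)
  expect_true(done2$done)
  expect_equal(done2$reward, 0)
  expect_identical(done2$info$report, 1L)
  # phantom fixation is illegal
  sp <- pad_with_phantoms(s, 4L)
  bp <- init_beliefs(sp, params_t1, seed = 1)
  expect_error(metamdp_step(sp, bp, 3L, params_t1), "phantom")
})

test_that("argmax ties at termination break toward the lowest index", {
  s <- manual_scene(matrix(c(0, 0), 2, 1), target_index = 1L)
  b <- init_beliefs(s, params_t1, seed = 1)
  b$F[] <- 0
  b$p <- target_posterior(b)  # exactly (0.5, 0.5)
  out <- metamdp_step(s, b, 0L, params_t1)
  expect_identical(out$info$report, 1L)
})

test_that("episodes keep their books: returns, budgets, reproducibility", {
  s <- manual_scene(matrix(rnorm(12, sd = 2), 6), target_index = 3L)
  tr <- run_episode(s, fixate_map_policy(), params_t1, seed = 9)
  expect_identical(tr, run_episode(s, fixate_map_policy(), params_t1, seed = 9))
  expect_equal(tr$return, tr$reward_final - 0.01 * tr$n_fixations)
  expect_equal(tr$return, sum(tr$rewards))
  if (tr$n_fixations > 0)
    expect_equal(rowSums(tr$posteriors), rep(1, tr$n_fixations))
  # indistinguishable objects + strict threshold + unit budget -> timeout
  s0 <- manual_scene(matrix(0, 3, 1))
  p0 <- tiny_params(theta = 0.999, budget = 1L)
  tr0 <- run_episode(s0, fixate_map_policy(), p0, seed = 1)
  expect_identical(tr0$termination, "budget")
  expect_identical(tr0$report, NA_integer_)
  expect_equal(tr0$reward_final, 0)
  expect_error(meta_mdp_params(theta = 0.9, fixation_budget = 0L),
               "positive integer")
  # precision only accumulates
  s1 <- manual_scene(matrix(rnorm(4), 4, 1))
  b <- init_beliefs(s1, params_t1, seed = 2)
  withr::with_seed(3, {
    for (i in 1:5) {
      b2 <- metamdp_step(s1, b, sample(4, 1), params_t1)$belief
      expect_true(all(b2$J >= b$J))
      b <- b2
    }
  })
})

test_that("harder discrimination lengthens search on average", {
  mean_len <- function(sim) {
    scenes <- small_ensemble(n_scenes = 6L, n_objects = 6L, n_features = 2L,
                             seed = 400L, similarity = sim)
    traces <- simulate_policy(scenes, fixate_map_policy(), tiny_params(0.8),
                              reps = 25L, seed = 5)
    mean(vapply(traces, `[[`, numeric(1), "n_fixations"))
  }
  expect_gte(mean_len(0.9), mean_len(0))
})

test_that("episode traces round-trip through JSONL", {
  scenes <- small_ensemble(n_scenes = 2L, n_objects = 5L)
  traces <- simulate_policy(scenes, fixate_map_policy(), tiny_params(0.8),
                            reps = 2L, seed = 3)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_traces(traces, f, scene_ids = sprintf("s%d", attr(traces, "scene_index")))
  back <- read_traces(f)
  expect_length(back, length(traces))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$fixations, traces[[i]]$fixations)
    expect_identical(back[[i]]$termination, traces[[i]]$termination)
    expect_equal(back[[i]]$return, traces[[i]]$return)
    expect_identical(back[[i]]$report, traces[[i]]$report)
  }
})
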