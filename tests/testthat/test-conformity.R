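test_that("initialization wires the canonical experiment", {
  init <- init_state(conformity_config(seed = 1))
  st <- init$state
  expect_length(st$scores, 500)
  expect_equal(nrow(init$network$edges), 2500)
  expect_identical(st$behavior, st$scores > 0)
  expect_true(all(st$range_low <= st$scores & st$scores <= st$range_high))

  # equal conformism bounds: every range has width exactly 2r
  cfg <- conformity_config(conformism_low = 0.4, conformism_high = 0.4,
                           seed = 2)
  st2 <- init_state(cfg)$state
  expect_equal(st2$range_high - st2$range_low, rep(0.8, 500))
  expect_equal((st2$range_high + st2$range_low) / 2, st2$scores)
})

test_that("the theta-step rule moves, rejects and flips as specified", {
  # two agents linked to each other; seed 1 selects agent 1 first
  adj <- list(2L, 1L)

  # contact doing the behavior: score moves up by theta
  st <- make_conformity_state(c(0.10, 0.5), c(-0.5, 0), c(0.5, 1))
  set.seed(1)
  out <- learning_step(st, adj, step_size = 0.02)
  expect_equal(out$scores[1], 0.12)

  # proposed move leaves the permissible range: score unchanged
  st <- make_conformity_state(c(0.49, 0.5), c(-0.5, 0), c(0.5, 1))
  set.seed(1)
  out <- learning_step(st, adj, step_size = 0.02)
  expect_equal(out$scores[1], 0.49)
  # ... unless clamping to the boundary is requested
  set.seed(1)
  out <- learning_step(st, adj, step_size = 0.02, clamp_to_boundary = TRUE)
  expect_equal(out$scores[1], 0.5)

  # crossing zero flips the behavior (contact not doing the behavior)
  st <- make_conformity_state(c(0.01, -1), c(-0.5, -2), c(0.5, 0))
  expect_true(st$behavior[1])
  set.seed(1)
  out <- learning_step(st, adj, step_size = 0.02)
  expect_equal(out$scores[1], -0.01)
  expect_false(out$behavior[1])
})

test_that("theta = 0 leaves scores untouched over any horizon", {
  cfg <- conformity_config(network_config = small_world_config(50, 4, 0.2),
                           score_field_config = score_field_config(50),
                           step_size = 0, n_periods = 5000, seed = 3)
  res <- run_learning(cfg)
  expect_identical(res$final_scores, res$initial_scores)
})

test_that("compiled learning loop matches the pure-R step driver bit-for-bit", {
  cfg <- conformity_config(network_config = small_world_config(30, 4, 0.2),
                           score_field_config = score_field_config(30, smoothness = 5),
                           n_periods = 400, convergence_window = Inf, seed = 42)
  compiled <- run_learning(cfg)

  set.seed(42)
  cfg_stream <- cfg
  cfg_stream$seed <- NULL
  init <- init_state(cfg_stream)
  st <- init$state
  adj <- as_adjacency_list(init$network)
  for (t in 1:400) st <- learning_step(st, adj, cfg$step_size)

  expect_identical(st$scores, compiled$final_scores)
  expect_identical(st$behavior, compiled$final_scores > 0)
})

test_that("scores stay in range, behavior tracks sign, runs are reproducible", {
  for (s in 1:5) {
    cfg <- conformity_config(network_config = small_world_config(50, 4, 0.3),
                             score_field_config = score_field_config(50),
                             n_periods = 10000, seed = s)
    res <- run_learning(cfg)
    expect_true(all(res$final_scores >= res$range_low &
                    res$final_scores <= res$range_high))
    expect_true(all(res$pro_fraction_trajectory >= 0 &
                    res$pro_fraction_trajectory <= 1))
    expect_identical(run_learning(cfg)$final_scores, res$final_scores)
  }
})

test_that("a unanimous population with positive ranges never flips", {
  cfg <- conformity_config(
    network_config = small_world_config(40, 4, 0.2),
    score_field_config = score_field_config(40, amplitude = 0.1, mean_level = 2),
    conformism_low = 0.2, conformism_high = 0.5,
    n_periods = 20000, convergence_window = Inf, seed = 6)
  init <- init_state(cfg)
  expect_true(all(init$state$scores > 0))
  expect_true(all(init$state$range_low > 0))
  res <- run_learning(cfg)
  expect_true(all(res$final_scores > 0))
  expect_true(all(res$pro_fraction_trajectory == 1))
})

test_that("polarization metrics summarize initial vs final scores", {
  x <- c(-0.2, 0.1, 0.4)
  same <- polarization_metrics(x, x)
  expect_equal(same$variance_ratio, 1)
  expect_equal(same$fraction_anti_final, mean(x < 0))

  lo <- c(-1, -1, -1); hi <- c(1, 1, 1)
  atboundary <- polarization_metrics(x, hi, lo, hi)
  expect_equal(atboundary$fraction_anti_final, 0)
  expect_equal(atboundary$fraction_strongly_pro, 1)
  expect_equal(atboundary$fraction_strongly_anti, 0)

  expect_error(polarization_metrics(1:3, 1:4), "equal length")
})
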