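test_that("initial populations carry the canonical compartment counts", {
  st <- init_population(contagion_config(seed = 1))
  counts <- tabulate(st$compartment + 1L, nbins = 4)
  expect_equal(counts, c(900, 90, 10, 0))  # unsus, sus, inf, rec
  expect_equal(st$recovery_prob[st$compartment == 2L], rep(0.05, 10))
  expect_equal(st$recovery_prob[st$compartment != 2L], rep(0, 990))

  # boundary: every susceptible starts infected
  st2 <- init_population(contagion_config(n_population = 50, n_susceptible = 5,
                                          n_infected_initial = 5, seed = 2))
  expect_equal(sum(st2$compartment == 1L), 0)
  expect_equal(sum(st2$compartment == 2L), 5)

  expect_error(contagion_config(n_susceptible = 5, n_infected_initial = 6),
               "n_infected_initial")
})

test_that("interaction rules produce the printed arithmetic", {
  cfg <- contagion_config()
  # believer meets believer: both recovery probabilities x0.9
  st <- make_contagion_state(c(2L, 2L, 0L))
  out <- interact(st, 1, 2, cfg)
  expect_equal(out$recovery_prob[1:2], c(0.045, 0.045))
  expect_identical(out$compartment, st$compartment)

  # ... unless recovery probabilities are held constant
  out <- interact(st, 1, 2, contagion_config(constant_recovery = TRUE))
  expect_equal(out$recovery_prob[1:2], c(0.05, 0.05))

  # susceptible meets infected: infection, recovery prob reset
  st <- make_contagion_state(c(1L, 2L, 0L), c(0, 0.02, 0))
  out <- interact(st, 1, 2, cfg)
  expect_equal(out$compartment[1], 2L)
  expect_equal(out$recovery_prob[1], 0.05)
  expect_equal(out$compartment[2], 2L)  # the believer is unaffected

  # failed challenge under cumulative influence: 5% -> 5.5%
  st <- make_contagion_state(c(2L, 0L))
  set.seed(1)  # first uniform 0.266 > 0.05: recovery fails
  out <- interact(st, 1, 2, contagion_config(cumulative_influence = TRUE))
  expect_equal(out$compartment[1], 2L)
  expect_equal(out$recovery_prob[1], 0.055)
  # without the cumulative switch a failed challenge changes nothing
  set.seed(1)
  out <- interact(st, 1, 2, cfg)
  expect_equal(out$recovery_prob[1], 0.05)

  # successful challenge: believer recovers (force with prob 1)
  st <- make_contagion_state(c(2L, 3L), c(1, 0))
  out <- interact(st, 1, 2, cfg)
  expect_equal(out$compartment[1], 3L)

  # susceptible meets recovered: no rule fires
  st <- make_contagion_state(c(1L, 3L))
  expect_identical(interact(st, 1, 2, cfg), st)

  expect_error(interact(st, 2, 2, cfg), "differ")
})

test_that("matching is assortative for believers and uniform otherwise", {
  st <- make_contagion_state(c(rep(2L, 10), rep(1L, 20), rep(0L, 70)))

  set.seed(1)
  pairs <- replicate(3000, match_pair(st, assortative_prob = 0.5))
  expect_true(all(pairs[1, ] != pairs[2, ]))

  # m = 1: a believer's partner is always another believer
  set.seed(2)
  for (k in 1:500) {
    ij <- match_pair(st, assortative_prob = 1)
    if (st$compartment[ij[1]] == 2L)
      expect_equal(st$compartment[ij[2]], 2L)
  }

  # m = 0.5: about half of believers' partners are believers (plus the
  # uniform branch's small believer share)
  inf_i <- pairs[, st$compartment[pairs[1, ]] == 2L, drop = FALSE]
  frac_inf_partner <- mean(st$compartment[inf_i[2, ]] == 2L)
  p_expected <- 0.5 + 0.5 * 9 / 99
  expect_lt(abs(frac_inf_partner - p_expected), 0.1)

  # sole believer: assortative draw falls back to uniform-over-others
  solo <- make_contagion_state(c(2L, rep(0L, 9)))
  set.seed(3)
  for (k in 1:50) {
    ij <- match_pair(solo, assortative_prob = 1)
    expect_true(ij[2] != ij[1])
  }
})

test_that("compiled contagion loop matches the pure-R driver bit-for-bit", {
  cfg <- contagion_config(n_population = 60, n_susceptible = 20,
                          n_infected_initial = 5, n_periods = 3000, seed = 11)
  compiled <- run_contagion(cfg)

  set.seed(11)
  cfg_stream <- cfg
  cfg_stream$seed <- NULL
  st <- init_population(cfg_stream)
  for (t in 1:3000) {
    ij <- match_pair(st, cfg$assortative_prob)
    st <- interact(st, ij[1], ij[2], cfg)
    if (!any(st$compartment == 2L)) break
  }
  expect_identical(st$compartment, compiled$final_state$compartment)
  expect_identical(st$recovery_prob, compiled$final_state$recovery_prob)
})

test_that("trajectories conserve compartments and are reproducible", {
  for (s in 1:5) {
    cfg <- small_contagion_config(seed = s)
    res <- run_contagion(cfg)
    tr <- res$trajectory
    # unsusceptible constant; S + I + R = initial susceptible pool
    expect_true(all(tr$susceptible + tr$infected + tr$recovered == 20))
    expect_true(all(tr$infected <= cfg$n_susceptible))
    # one-directional flows: S never grows, R never shrinks
    expect_true(all(diff(tr$susceptible) <= 0))
    expect_true(all(diff(tr$recovered) >= 0))
    # time axis: one tick per unit of mean interactions per individual
    expect_equal(tr$time, seq(0, by = 1, length.out = nrow(tr)))
    # final snapshot agrees with the last tick
    expect_equal(sum(res$final_state$compartment == 2L),
                 tr$infected[nrow(tr)])
    expect_identical(run_contagion(cfg)$trajectory, tr)
  }
})

test_that("extinction is absorbing and recorded in mean-interaction units", {
  cfg <- contagion_config(n_population = 100, n_susceptible = 10,
                          n_infected_initial = 2, recovery_prob_initial = 0.5,
                          assortative_prob = 0, constant_recovery = TRUE,
                          n_periods = 50000, seed = 4)
  res <- run_contagion(cfg)
  expect_false(is.na(res$extinction_time))
  expect_true(res$equilibrium_reached)
  tr <- res$trajectory
  gone <- which(tr$infected == 0)
  expect_gt(length(gone), 0)
  after <- seq(min(gone), nrow(tr))
  expect_true(all(tr$infected[after] == 0))
  expect_equal(length(unique(tr$recovered[after])), 1)
  expect_gte(res$extinction_time, 0)
  expect_lte(res$extinction_time, 2 * cfg$n_periods / cfg$n_population)
})

test_that("assortativity sweeps pair replicates across the grid", {
  cfg <- small_contagion_config(seed = 21)
  sw <- sweep_assortativity(c(0.2, 0.5), replicates = 4, cfg)
  expect_equal(nrow(sw), 8)
  expect_equal(sw$seed[sw$m == 0.2], sw$seed[sw$m == 0.5])  # paired

  one <- sweep_assortativity(0.5, 1, cfg)
  cfg1 <- cfg
  cfg1$seed <- child_seed(21, 1)
  ref <- run_contagion(cfg1)
  expect_equal(one$final_infected,
               ref$trajectory$infected[nrow(ref$trajectory)])

  expect_error(sweep_assortativity(c(-0.1, 0.5), 2, cfg), "\\[0, 1\\]")
})
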