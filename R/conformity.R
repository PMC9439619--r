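#' Conformity social-learning configuration
#'
#' Agents sit on a small-world network and hold a real-valued score: their
#' propensity to do a behavior. A positive score means the agent does the
#' behavior. Each agent also has a permissible score range — wide ranges
#' mean conformist agents whose scores social influence can move far. In
#' each period one random agent observes one random social contact and
#' nudges its own score by `step_size` toward the contact's behavior, but
#' only if the nudge stays within the agent's range.
#'
#' Defaults follow the canonical experiment: N = 500 agents, each linked to
#' its 5 nearest neighbors per side (k = 10); initial scores smooth on the
#' ring with a moderately positive majority and a 20% anti-behavior
#' minority; `step_size` is 1% of the score-field amplitude (many small
#' steps over many periods); conformism half-ranges uniform on
#' \[0.25, 1.5\] times the amplitude; `n_periods = 500 * N` so each agent
#' is updated about 500 times.
#'
#' @param network_config a [small_world_config()]; its `rewiring_prob` is
#'   the knob the canonical experiments vary (0.1, 0.2, 0.3).
#' @param score_field_config a [score_field_config()]; its `n_nodes` must
#'   match the network's.
#' @param step_size positive learning step (theta).
#' @param conformism_low,conformism_high bounds of the uniform distribution
#'   of per-agent half-ranges.
#' @param n_periods positive integer number of asynchronous periods.
#' @param convergence_window early stop after this many consecutive periods
#'   without a behavior flip (`Inf` disables; default `50 * N`).
#' @param clamp_to_boundary if `TRUE`, an out-of-range update is truncated
#'   to the range boundary instead of rejected (off by default: the
#'   literal rule rejects moves that would leave the range).
#' @param seed master seed for the whole run (network, scores, ranges,
#'   learning), or `NULL` to use the current RNG stream.
#' @return A list of class `"conformity_config"`.
#' @examples
#' conformity_config(rewiring_prob = 0.1, seed = 1)
#' @param rewiring_prob shortcut overriding `network_config$rewiring_prob`.
#' @export
conformity_config <- function(network_config = small_world_config(500, 10, 0.1),
                              score_field_config = crowdsim::score_field_config(network_config$n_nodes),
                              step_size = 0.01 * score_field_config$amplitude,
                              conformism_low = 0.25 * score_field_config$amplitude,
                              conformism_high = 1.5 * score_field_config$amplitude,
                              n_periods = 500L * network_config$n_nodes,
                              convergence_window = 50L * network_config$n_nodes,
                              clamp_to_boundary = FALSE,
                              rewiring_prob = NULL,
                              seed = NULL) {
  stopifnot(inherits(network_config, "small_world_config"),
            inherits(score_field_config, "score_field_config"))
  if (!is.null(rewiring_prob)) {
    check_scalar(rewiring_prob, "rewiring_prob", lower = 0, upper = 1)
    network_config$rewiring_prob <- rewiring_prob
  }
  if (score_field_config$n_nodes != network_config$n_nodes)
    stop_bad("score field and network must have the same number of nodes")
  check_scalar(step_size, "step_size", lower = 0)
  check_scalar(conformism_low, "conformism_low", lower = 0, strict_lower = TRUE)
  check_scalar(conformism_high, "conformism_high", lower = conformism_low)
  check_scalar(n_periods, "n_periods", "integerish", lower = 1)
  if (!identical(convergence_window, Inf))
    check_scalar(convergence_window, "convergence_window", "integerish", lower = 1)
  check_flag(clamp_to_boundary, "clamp_to_boundary")
  if (!is.null(seed)) check_scalar(seed, "seed", "integerish")
  structure(
    list(network_config = network_config,
         score_field_config = score_field_config,
         step_size = step_size,
         conformism_low = conformism_low, conformism_high = conformism_high,
         n_periods = as.integer(n_periods),
         convergence_window = convergence_window,
         clamp_to_boundary = clamp_to_boundary,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "conformity_config"
  )
}

#' Initialize a conformity simulation
#'
#' Seeds the RNG (if `config$seed` is set), builds the small-world network,
#' draws the correlated initial score field, then draws each agent's
#' conformism half-range `r_i ~ Uniform(conformism_low, conformism_high)`
#' and sets the permissible range `[score_i - r_i, score_i + r_i]`, which
#' always contains the initial score. Behavior is `score > 0`.
#'
#' @param config a [conformity_config()].
#' @return A list with `state` (class `"conformity_state"`: `scores`,
#'   `range_low`, `range_high`, `behavior`) and `network`
#'   (`"crowd_network"`).
#' @examples
#' init <- init_state(conformity_config(seed = 1))
#' all(init$state$behavior == (init$state$scores > 0))
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "conformity_config"))
  maybe_seed(config$seed)
  net_cfg <- config$network_config
  net_cfg$seed <- NULL           # share the run's RNG stream
  network <- small_world_network(net_cfg)
  sf_cfg <- config$score_field_config
  sf_cfg$seed <- NULL
  scores <- generate_correlated_scores(sf_cfg)
  n <- net_cfg$n_nodes
  half_range <- runif(n, config$conformism_low, config$conformism_high)
  state <- structure(
    list(scores = scores,
         range_low = scores - half_range,
         range_high = scores + half_range,
         behavior = scores > 0),
    class = "conformity_state"
  )
  list(state = state, network = network)
}

#' One asynchronous learning period
#'
#' Reference (pure R) implementation of a single period, drawing from the
#' global RNG in the same order as the compiled loop used by
#' [run_learning()]: one uniform picks the agent, one uniform picks one of
#' its contacts (isolated agents skip their turn and consume only the first
#' draw). The agent's score moves by `step_size` toward the contact's
#' behavior if and only if the move stays inside the agent's permissible
#' range (or is clamped to the boundary when `clamp_to_boundary` is set);
#' behavior is then recomputed as `score > 0`.
#'
#' @param state a `"conformity_state"`.
#' @param adjacency adjacency list from [as_adjacency_list()].
#' @param step_size positive step (theta).
#' @param clamp_to_boundary see [conformity_config()].
#' @return The updated `"conformity_state"`.
#' @export
learning_step <- function(state, adjacency, step_size,
                          clamp_to_boundary = FALSE) {
  n <- length(state$scores)
  i <- 1L + as.integer(floor(runif(1) * n))
  contacts <- adjacency[[i]]
  if (!length(contacts)) return(state)
  j <- contacts[1L + as.integer(floor(runif(1) * length(contacts)))]
  dir <- if (state$behavior[j]) 1 else -1
  proposed <- state$scores[i] + dir * step_size
  if (proposed >= state$range_low[i] && proposed <= state$range_high[i]) {
    state$scores[i] <- proposed
  } else if (clamp_to_boundary) {
    state$scores[i] <- min(max(proposed, state$range_low[i]), state$range_high[i])
  }
  state$behavior[i] <- state$scores[i] > 0
  state
}

#' Run the conformity learning process
#'
#' Simulates `n_periods` asynchronous single-agent updates (compiled inner
#' loop; bit-identical to looping [learning_step()] under the same seed).
#' The pro-behavior fraction is snapshotted every `N` periods. The run
#' stops early once no behavior flip has occurred for `convergence_window`
#' consecutive periods.
#'
#' @param config a [conformity_config()].
#' @return An object of class `"conformity_sim"`: `initial_scores`,
#'   `final_scores`, `range_low`, `range_high`, `pro_fraction_trajectory`
#'   (value at period 0 and every `N` periods), `periods_run`,
#'   `polarization` (see [polarization_metrics()]), `network`, `config`.
#' @examples
#' \donttest{
#' res <- run_learning(conformity_config(rewiring_prob = 0.3, seed = 1))
#' res$polarization$fraction_anti_final
#' }
#' @export
run_learning <- function(config) {
  stopifnot(inherits(config, "conformity_config"))
  init <- init_state(config)
  state <- init$state
  adjacency <- as_adjacency_list(init$network)
  window <- if (identical(config$convergence_window, Inf)) -1L
            else as.integer(config$convergence_window)
  fit <- cpp_run_learning(state$scores, state$range_low, state$range_high,
                          adjacency, config$step_size, config$n_periods,
                          length(state$scores), window,
                          config$clamp_to_boundary)
  pol <- polarization_metrics(init$state$scores, fit$scores,
                              state$range_low, state$range_high)
  structure(
    list(initial_scores = init$state$scores,
         final_scores = fit$scores,
         range_low = state$range_low,
         range_high = state$range_high,
         pro_fraction_trajectory = fit$pro_fraction,
         periods_run = fit$periods_run,
         polarization = pol,
         network = init$network,
         config = config),
    class = "conformity_sim"
  )
}

#' @export
print.conformity_sim <- function(x, ...) {
  p <- x$polarization
  cat(sprintf(
    paste0("<conformity_sim> N = %d, p = %g: anti share %.1f%% -> %.1f%%, ",
           "score variance ratio %.2f (%d periods)\n"),
    length(x$final_scores), x$config$network_config$rewiring_prob,
    100 * mean(x$initial_scores < 0), 100 * p$fraction_anti_final,
    p$variance_ratio, x$periods_run))
  invisible(x)
}

#' @export
plot.conformity_sim <- function(x, ...) {
  n <- length(x$initial_scores)
  plot(seq_len(n) - 1L, x$initial_scores, type = "l", col = "grey50",
       xlab = "agent (ring position)", ylab = "score",
       ylim = range(x$range_low, x$range_high), ...)
  points(seq_len(n) - 1L, x$final_scores, pch = 16, cex = 0.4)
  abline(h = 0, lty = 2)
  legend("topright", c("initial", "final"), lty = c(1, NA),
         pch = c(NA, 16), col = c("grey50", "black"), bty = "n")
  invisible(x)
}

#' Polarization summary of a learning run
#'
#' Operationalizes the visual initial-vs-final score comparison:
#' `fraction_anti_final` (share of final scores below zero), the
#' final/initial score variance ratio, and — when per-agent ranges are
#' supplied — the shares of agents whose final score sits within 10% of
#' the upper (`fraction_strongly_pro`) or lower (`fraction_strongly_anti`)
#' boundary of their permissible range.
#'
#' @param initial_scores,final_scores equal-length numeric vectors.
#' @param range_low,range_high optional per-agent range bounds; without
#'   them the "strongly" shares are `NA`.
#' @return A list with `fraction_anti_final`, `variance_ratio`,
#'   `fraction_strongly_pro`, `fraction_strongly_anti`,
#'   `variance_initial`, `variance_final`.
#' @examples
#' polarization_metrics(c(-0.1, 0.2), c(-0.1, 0.2))
#' @export
polarization_metrics <- function(initial_scores, final_scores,
                                 range_low = NULL, range_high = NULL) {
  if (length(initial_scores) != length(final_scores))
    stop_bad("`initial_scores` and `final_scores` must have equal length")
  v0 <- var(initial_scores)
  v1 <- var(final_scores)
  out <- list(
    fraction_anti_final = mean(final_scores < 0),
    variance_ratio = v1 / v0,
    fraction_strongly_pro = NA_real_,
    fraction_strongly_anti = NA_real_,
    variance_initial = v0,
    variance_final = v1
  )
  if (!is.null(range_low) && !is.null(range_high)) {
    if (length(range_low) != length(final_scores) ||
        length(range_high) != length(final_scores))
      stop_bad("range bounds must match the score vectors in length")
    width <- range_high - range_low
    out$fraction_strongly_pro <- mean(final_scores >= range_high - 0.1 * width)
    out$fraction_strongly_anti <- mean(final_scores <= range_low + 0.1 * width)
  }
  out
}
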