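#' Belief-contagion configuration
#'
#' Modified SIR model of conspiracy-belief spread in a well-mixed population
#' with biased (assortative) matching. Compartments: unsusceptible (will
#' never believe), susceptible, infected (believes), recovered (abandoned
#' the belief). In each period one individual is drawn; if infected, with
#' probability `assortative_prob` its partner is drawn among the other
#' believers, otherwise uniformly among everyone else. The matched pair then
#' interacts:
#' \itemize{
#'   \item susceptible x infected: the susceptible becomes infected, with
#'     recovery probability reset to `recovery_prob_initial`;
#'   \item non-susceptible (incl. recovered) x infected: the infected
#'     recovers with its current recovery probability; under
#'     `cumulative_influence`, a failed attempt multiplies that probability
#'     by `influence_factor` (capped at 1);
#'   \item infected x infected: both recovery probabilities are multiplied
#'     by `reinforcement_factor` (skipped under `constant_recovery`).
#' }
#' Defaults are the canonical baseline: N = 1000, 100 susceptible of whom
#' 10 start infected, `m = 0.5`, initial recovery probability 0.05,
#' reinforcement factor 0.9, influence factor 1.1, and
#' `n_periods = 250 * N` (500 mean interactions per individual — long
#' enough that the baseline plateaus with its persistent believer core and
#' the burnout scenarios actually reach extinction rather than being cut
#' off with a handful of straggler believers).
#'
#' @param n_population positive integer (N).
#' @param n_susceptible number initially able to believe (S0, includes the
#'   initially infected).
#' @param n_infected_initial number believing at the start (I0).
#' @param assortative_prob probability `m` that a believer's partner is
#'   another believer.
#' @param recovery_prob_initial initial per-believer recovery probability.
#' @param reinforcement_factor multiplicative decay of recovery probability
#'   on believer-believer contact, in (0, 1\].
#' @param influence_factor multiplicative growth (>= 1) of recovery
#'   probability after a failed challenge, used when `cumulative_influence`.
#' @param cumulative_influence logical, scenario switch (Simulation-4 rule).
#' @param constant_recovery logical, scenario switch disabling reinforcement
#'   (Simulation-3 rule).
#' @param n_periods positive integer number of pairwise interactions (T).
#' @param seed integer seed or `NULL`.
#' @return A list of class `"contagion_config"`.
#' @examples
#' contagion_config(seed = 1)
#' @export
contagion_config <- function(n_population = 1000, n_susceptible = 100,
                             n_infected_initial = 10, assortative_prob = 0.5,
                             recovery_prob_initial = 0.05,
                             reinforcement_factor = 0.9,
                             influence_factor = 1.1,
                             cumulative_influence = FALSE,
                             constant_recovery = FALSE,
                             n_periods = 250L * n_population,
                             seed = NULL) {
  check_scalar(n_population, "n_population", "integerish", lower = 2)
  check_scalar(n_susceptible, "n_susceptible", "integerish", lower = 1)
  check_scalar(n_infected_initial, "n_infected_initial", "integerish", lower = 1)
  if (!(n_infected_initial <= n_susceptible && n_susceptible <= n_population))
    stop_bad("need n_infected_initial <= n_susceptible <= n_population")
  check_scalar(assortative_prob, "assortative_prob", lower = 0, upper = 1)
  check_scalar(recovery_prob_initial, "recovery_prob_initial", lower = 0, upper = 1)
  check_scalar(reinforcement_factor, "reinforcement_factor",
               lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(influence_factor, "influence_factor", lower = 1)
  check_flag(cumulative_influence, "cumulative_influence")
  check_flag(constant_recovery, "constant_recovery")
  check_scalar(n_periods, "n_periods", "integerish", lower = 1)
  if (!is.null(seed)) check_scalar(seed, "seed", "integerish")
  structure(
    list(n_population = as.integer(n_population),
         n_susceptible = as.integer(n_susceptible),
         n_infected_initial = as.integer(n_infected_initial),
         assortative_prob = assortative_prob,
         recovery_prob_initial = recovery_prob_initial,
         reinforcement_factor = reinforcement_factor,
         influence_factor = influence_factor,
         cumulative_influence = cumulative_influence,
         constant_recovery = constant_recovery,
         n_periods = as.integer(n_periods),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "contagion_config"
  )
}

# compartment codes shared by R and C++ code
UNSUSCEPTIBLE <- 0L; SUSCEPTIBLE <- 1L; INFECTED <- 2L; RECOVERED <- 3L

#' Initialize a contagion population
#'
#' Assigns compartments uniformly at random: `n_infected_initial` infected
#' (each with recovery probability `recovery_prob_initial`),
#' `n_susceptible - n_infected_initial` susceptible, the remainder
#' unsusceptible; nobody starts recovered.
#'
#' @param config a [contagion_config()].
#' @return A `"contagion_state"`: integer `compartment` vector (0
#'   unsusceptible, 1 susceptible, 2 infected, 3 recovered) and numeric
#'   `recovery_prob` (meaningful while infected).
#' @examples
#' st <- init_population(contagion_config(seed = 1))
#' table(st$compartment)
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "contagion_config"))
  maybe_seed(config$seed)
  n <- config$n_population
  comp <- rep(UNSUSCEPTIBLE, n)
  perm <- sample.int(n)
  comp[perm[seq_len(config$n_infected_initial)]] <- INFECTED
  if (config$n_susceptible > config$n_infected_initial)
    comp[perm[(config$n_infected_initial + 1L):config$n_susceptible]] <- SUSCEPTIBLE
  rp <- rep(0, n)
  rp[comp == INFECTED] <- config$recovery_prob_initial
  structure(list(compartment = comp, recovery_prob = rp),
            class = "contagion_state")
}

#' Match a pair of individuals
#'
#' Reference (pure R) implementation of one matching, drawing from the
#' global RNG in the same order as the compiled loop: one uniform picks
#' `i`; if `i` is infected a second uniform decides assortative vs uniform
#' matching and a third picks the partner; if `i` is uninfected the second
#' uniform picks the partner directly. Assortative partners are drawn
#' uniformly over the other infected individuals in ascending-index order;
#' if `i` is the sole believer the draw falls back to uniform-over-others.
#'
#' @param state a `"contagion_state"`.
#' @param assortative_prob probability `m`.
#' @return Integer vector `c(i, j)` (1-based, `i != j`).
#' @export
match_pair <- function(state, assortative_prob) {
  n <- length(state$compartment)
  i <- 1L + as.integer(floor(runif(1) * n))
  draw_other <- function() {
    j <- 1L + as.integer(floor(runif(1) * (n - 1L)))
    if (j >= i) j + 1L else j
  }
  if (state$compartment[i] == INFECTED) {
    u <- runif(1)
    others <- setdiff(which(state$compartment == INFECTED), i)
    if (u < assortative_prob && length(others)) {
      j <- others[1L + as.integer(floor(runif(1) * length(others)))]
    } else {
      j <- draw_other()
    }
  } else {
    j <- draw_other()
  }
  c(i, j)
}

#' Apply one pairwise interaction
#'
#' Reference (pure R) implementation of the three state-update rules (see
#' [contagion_config()]); exactly one rule fires per interaction, and both
#' individuals' states may change — the drawn individual has no privileged
#' role beyond matching. The global RNG is consumed only by the recovery
#' attempt of the challenge rule.
#'
#' @param state a `"contagion_state"`.
#' @param i,j distinct 1-based indices.
#' @param config a [contagion_config()] (rates and scenario switches).
#' @return The updated `"contagion_state"`.
#' @examples
#' cfg <- contagion_config(seed = 1)
#' st <- init_population(cfg)
#' inf <- which(st$compartment == 2L)
#' st2 <- interact(st, inf[1], inf[2], cfg)
#' st2$recovery_prob[inf[1:2]]  # 0.05 * 0.9 = 0.045
#' @export
interact <- function(state, i, j, config) {
  if (i == j) stop_bad("`i` and `j` must differ")
  ci <- state$compartment[i]; cj <- state$compartment[j]
  inf_i <- ci == INFECTED; inf_j <- cj == INFECTED
  if (inf_i && inf_j) {
    if (!config$constant_recovery) {
      state$recovery_prob[c(i, j)] <-
        state$recovery_prob[c(i, j)] * config$reinforcement_factor
    }
  } else if (inf_i || inf_j) {
    b <- if (inf_i) i else j          # the believer
    o <- if (inf_i) cj else ci        # the other's compartment
    if (o == SUSCEPTIBLE) {
      s <- if (inf_i) j else i
      state$compartment[s] <- INFECTED
      state$recovery_prob[s] <- config$recovery_prob_initial
    } else {                           # unsusceptible or recovered: challenge
      if (runif(1) < state$recovery_prob[b]) {
        state$compartment[b] <- RECOVERED
        state$recovery_prob[b] <- 0
      } else if (config$cumulative_influence) {
        state$recovery_prob[b] <-
          min(1, state$recovery_prob[b] * config$influence_factor)
      }
    }
  }
  state
}

#' Run the belief contagion
#'
#' Simulates `n_periods` sequential match-and-interact events (compiled
#' inner loop; bit-identical to looping [match_pair()] + [interact()] under
#' the same seed). Compartment counts are sampled every `n_population / 2`
#' periods, i.e. once per unit of the time axis "mean interactions per
#' individual" (= 2 x periods / N). The run stops once no believer remains
#' (the state is then absorbing) and the trajectory is padded constant to
#' the full horizon.
#'
#' @param config a [contagion_config()].
#' @return An object of class `"belief_contagion"`: `trajectory` data frame
#'   (`time`, `susceptible`, `infected`, `recovered`), `final_state`
#'   (`"contagion_state"`), `ever_infected` logical vector,
#'   `extinction_time` (mean-interactions units; `NA` if believers remain),
#'   `equilibrium_reached` per the operational rule (no believers, or all
#'   believer recovery probabilities below 1e-9 with no compartment change
#'   for `50 * N` periods), and `config`.
#' @examples
#' \donttest{
#' res <- run_contagion(contagion_config(seed = 1))
#' tail(res$trajectory, 1)
#' }
#' @export
run_contagion <- function(config) {
  stopifnot(inherits(config, "contagion_config"))
  state <- init_population(config)
  n <- config$n_population
  fit <- cpp_run_contagion(state$compartment, state$recovery_prob,
                           config$assortative_prob,
                           config$recovery_prob_initial,
                           config$reinforcement_factor,
                           config$influence_factor,
                           config$cumulative_influence,
                           config$constant_recovery,
                           config$n_periods, n)
  traj <- data.frame(time = fit$time, susceptible = fit$susceptible,
                     infected = fit$infected, recovered = fit$recovered)
  final_state <- structure(
    list(compartment = fit$compartment, recovery_prob = fit$recovery_prob),
    class = "contagion_state")
  extinction_time <- if (fit$extinction_period >= 0)
    2 * fit$extinction_period / n else NA_real_
  structure(
    list(trajectory = traj, final_state = final_state,
         ever_infected = fit$ever_infected,
         extinction_time = extinction_time,
         equilibrium_reached = fit$equilibrium_reached,
         config = config),
    class = "belief_contagion"
  )
}

#' @export
print.belief_contagion <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf(
    paste0("<belief_contagion> N = %d, m = %g: final S/I/R = %d/%d/%d",
           " at t = %g mean interactions%s\n"),
    x$config$n_population, x$config$assortative_prob,
    last$susceptible, last$infected, last$recovered, last$time,
    if (!is.na(x$extinction_time))
      sprintf(" (belief extinct at t = %g)", x$extinction_time) else ""))
  invisible(x)
}

#' @export
plot.belief_contagion <- function(x, ...) {
  tr <- x$trajectory
  matplot(tr$time, tr[, c("susceptible", "infected", "recovered")],
          type = "l", lty = 1, lwd = 2,
          col = c("steelblue", "firebrick", "darkgreen"),
          xlab = "mean interactions per individual", ylab = "count", ...)
  legend("right", c("susceptible", "infected", "recovered"), lty = 1,
         lwd = 2, col = c("steelblue", "firebrick", "darkgreen"), bty = "n")
  invisible(x)
}

#' Sweep the assortative-matching probability
#'
#' Runs replicated contagions across a grid of `m` values. Replicate `r`
#' uses [child_seed()]`(master, r)` for every `m`, so runs are paired
#' across the grid by replicate.
#'
#' @param m_grid vector of probabilities in \[0, 1\].
#' @param replicates positive integer.
#' @param config a [contagion_config()] template; `assortative_prob` is
#'   overridden by the grid and `seed` acts as master seed (default 1).
#' @return A data frame of class `"contagion_sweep"`: columns `m`,
#'   `replicate`, `seed`, `final_infected`, `final_recovered`,
#'   `extinction_time`.
#' @examples
#' \donttest{
#' sw <- sweep_assortativity(c(0.2, 0.5), 3, contagion_config(seed = 1))
#' aggregate(final_infected ~ m, sw, mean)
#' }
#' @export
sweep_assortativity <- function(m_grid, replicates = 30,
                                config = contagion_config()) {
  stopifnot(inherits(config, "contagion_config"))
  if (!length(m_grid) || any(m_grid < 0) || any(m_grid > 1))
    stop_bad("`m_grid` values must lie in [0, 1]")
  check_scalar(replicates, "replicates", "integerish", lower = 1)
  master <- config$seed %||% 1L
  rows <- list()
  for (m in m_grid) {
    for (r in seq_len(replicates)) {
      s <- child_seed(master, r)
      cfg <- config
      cfg$assortative_prob <- m
      cfg$seed <- s
      res <- run_contagion(cfg)
      last <- res$trajectory[nrow(res$trajectory), ]
      rows[[length(rows) + 1L]] <- data.frame(
        m = m, replicate = r, seed = s,
        final_infected = last$infected,
        final_recovered = last$recovered,
        extinction_time = res$extinction_time)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contagion_sweep", "data.frame")
  out
}
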