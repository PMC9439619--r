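#' Panic-buying cascade configuration
#'
#' Each consumer gets a panic threshold, expressed in panic-fraction units:
#' the consumer starts panic buying once the fraction of the population
#' already panic buying reaches their threshold. Base thresholds are drawn
#' from `Normal(threshold_mean, threshold_sd)` and divided by the product's
#' visibility `v`, so conspicuous products (large `v`) shrink every
#' threshold. The default calibration sets `threshold_sd` so that
#' `pnorm(-threshold_mean / threshold_sd) = 0.10`: about 10% of consumers
#' hold a threshold at or below zero and panic from the outset, regardless
#' of `v`.
#'
#' @param n_consumers positive integer population size.
#' @param visibility positive real, product visibility `v`.
#' @param threshold_mean base normal mean (default 0.35).
#' @param threshold_sd base normal sd; default `threshold_mean / qnorm(0.9)`
#'   (about 0.2731) which fixes the 10% initial-trigger share.
#' @param seed integer seed or `NULL`.
#' @return A list of class `"panic_config"`.
#' @examples
#' panic_config(visibility = 1, seed = 1)
#' @export
panic_config <- function(n_consumers = 1000, visibility = 1,
                         threshold_mean = 0.35,
                         threshold_sd = threshold_mean / qnorm(0.9),
                         seed = NULL) {
  check_scalar(n_consumers, "n_consumers", "integerish", lower = 1)
  check_scalar(visibility, "visibility", lower = 0, strict_lower = TRUE)
  check_scalar(threshold_mean, "threshold_mean")
  check_scalar(threshold_sd, "threshold_sd", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) check_scalar(seed, "seed", "integerish")
  structure(
    list(n_consumers = as.integer(n_consumers), visibility = visibility,
         threshold_mean = threshold_mean, threshold_sd = threshold_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "panic_config"
  )
}

new_panic_population <- function(thresholds) {
  structure(list(thresholds = as.numeric(thresholds),
                 panicking = as.numeric(thresholds) <= 0),
            class = "panic_population")
}

#' Draw a population of visibility-scaled panic thresholds
#'
#' `threshold_i = z_i / visibility` with
#' `z_i ~ Normal(threshold_mean, threshold_sd)`; consumers with a threshold
#' at or below zero are panicking from round 0. Scaling by a positive
#' visibility preserves signs, so the initial panic set does not depend on
#' `v`.
#'
#' @param config a [panic_config()].
#' @return A `"panic_population"`: list with numeric `thresholds` (in
#'   panic-fraction units) and logical `panicking`.
#' @examples
#' pop <- draw_thresholds(panic_config(seed = 1))
#' mean(pop$panicking)  # about 0.10
#' @export
draw_thresholds <- function(config) {
  stopifnot(inherits(config, "panic_config"))
  maybe_seed(config$seed)
  z <- rnorm(config$n_consumers, config$threshold_mean, config$threshold_sd)
  new_panic_population(z / config$visibility)
}

#' One synchronous cascade round
#'
#' Every non-panicking consumer whose threshold is at or below the current
#' panicking fraction starts panicking; panic is absorbing (no reversal).
#'
#' @param population a `"panic_population"`.
#' @return The updated `"panic_population"`.
#' @examples
#' pop <- draw_thresholds(panic_config(n_consumers = 3, seed = 1))
#' cascade_step(pop)
#' @export
cascade_step <- function(population) {
  stopifnot(inherits(population, "panic_population"))
  frac <- mean(population$panicking)
  population$panicking <- population$panicking | (population$thresholds <= frac)
  population
}

cascade_from_population <- function(population) {
  frac <- mean(population$panicking)
  trajectory <- frac
  repeat {
    population <- cascade_step(population)
    new_frac <- mean(population$panicking)
    if (new_frac == frac) break
    trajectory <- c(trajectory, new_frac)
    frac <- new_frac
  }
  list(population = population, trajectory = trajectory)
}

#' Run a panic-buying cascade to equilibrium
#'
#' Draws thresholds under `config`, then iterates synchronous best-response
#' rounds ([cascade_step()]) until the panicking fraction stops changing.
#' Because each joining round adds at least one consumer, equilibrium is
#' reached in at most `n_consumers` rounds.
#'
#' @param config a [panic_config()].
#' @return An object of class `"panic_cascade"`: list with
#'   `fraction_trajectory` (nondecreasing; initial fraction first, one value
#'   per joining round thereafter), `equilibrium_fraction`,
#'   `rounds_to_equilibrium`, `initial_fraction` and `config`.
#' @examples
#' res <- run_cascade(panic_config(visibility = 2, seed = 1))
#' res$equilibrium_fraction
#' @export
run_cascade <- function(config) {
  stopifnot(inherits(config, "panic_config"))
  pop <- draw_thresholds(config)
  run <- cascade_from_population(pop)
  traj <- run$trajectory
  structure(
    list(fraction_trajectory = traj,
         equilibrium_fraction = traj[length(traj)],
         rounds_to_equilibrium = length(traj) - 1L,
         initial_fraction = traj[1L],
         config = config),
    class = "panic_cascade"
  )
}

#' @export
print.panic_cascade <- function(x, ...) {
  cat(sprintf(
    "<panic_cascade> v = %g, n = %d: %.1f%% panic initially -> %.1f%% at equilibrium (%d joining rounds)\n",
    x$config$visibility, x$config$n_consumers,
    100 * x$initial_fraction, 100 * x$equilibrium_fraction,
    x$rounds_to_equilibrium))
  invisible(x)
}

#' Analytic equilibrium of the panic cascade
#'
#' In the large-population limit the equilibrium panicking fraction `f`
#' solves `f = pnorm((visibility * f - threshold_mean) / threshold_sd)`.
#' Starting from the initial trigger share `f0 = pnorm(-mean/sd)`, the
#' iteration is monotone nondecreasing (the map is increasing in `f`) and
#' converges to the smallest fixed point at or above `f0` — the same point
#' the synchronous cascade reaches. Serves as an independent oracle for the
#' simulator.
#'
#' @param visibility positive real.
#' @param threshold_mean,threshold_sd base normal parameters (defaults as in
#'   [panic_config()]).
#' @param tol convergence tolerance (default 1e-10).
#' @return Equilibrium fraction in \[0, 1\].
#' @examples
#' analytic_fixed_point(0.2)  # low visibility: stays near the 10% trigger
#' analytic_fixed_point(2.0)  # high visibility: near-total cascade
#' @export
analytic_fixed_point <- function(visibility, threshold_mean = 0.35,
                                 threshold_sd = threshold_mean / qnorm(0.9),
                                 tol = 1e-10) {
  check_scalar(visibility, "visibility", lower = 0, strict_lower = TRUE)
  check_scalar(threshold_sd, "threshold_sd", lower = 0, strict_lower = TRUE)
  f <- pnorm(-threshold_mean / threshold_sd)
  repeat {
    f_new <- pnorm((visibility * f - threshold_mean) / threshold_sd)
    if (abs(f_new - f) < tol) return(f_new)
    f <- f_new
  }
}

#' Sweep product visibility
#'
#' Runs independent cascades across a grid of visibility levels, with fresh
#' thresholds per replicate. Replicate seeds derive from `config$seed` via
#' [child_seed()] with a running counter (grid-major order: all replicates
#' of the first `v`, then the second, ...), so the whole sweep is
#' reproducible from the single master seed.
#'
#' @param v_grid ordered vector of positive visibility levels.
#' @param replicates positive integer replicates per level.
#' @param config a [panic_config()] template; its `visibility` is
#'   overridden by the grid and its `seed` acts as master seed (default 1
#'   if `NULL`).
#' @return A data frame of class `"panic_sweep"` with columns `v`,
#'   `replicate`, `seed`, `initial_fraction`, `equilibrium_fraction`,
#'   `rounds`.
#' @examples
#' sw <- sweep_visibility(c(0.2, 1, 2), replicates = 2, panic_config(seed = 1))
#' aggregate(equilibrium_fraction ~ v, sw, mean)
#' @export
sweep_visibility <- function(v_grid, replicates = 5, config = panic_config()) {
  stopifnot(inherits(config, "panic_config"))
  if (!length(v_grid) || any(v_grid <= 0))
    stop_bad("`v_grid` must be a nonempty vector of positive visibilities")
  check_scalar(replicates, "replicates", "integerish", lower = 1)
  master <- config$seed %||% 1L
  rows <- vector("list", length(v_grid) * replicates)
  counter <- 0L
  for (v in v_grid) {
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      s <- child_seed(master, counter)
      cfg <- config
      cfg$visibility <- v
      cfg$seed <- s
      res <- run_cascade(cfg)
      rows[[counter]] <- data.frame(
        v = v, replicate = r, seed = s,
        initial_fraction = res$initial_fraction,
        equilibrium_fraction = res$equilibrium_fraction,
        rounds = res$rounds_to_equilibrium)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("panic_sweep", "data.frame")
  out
}

#' @export
plot.panic_sweep <- function(x, ...) {
  plot(x$v, x$equilibrium_fraction, pch = 16, cex = 0.5,
       col = grDevices::grey(0.3, 0.5),
       xlab = "visibility v", ylab = "equilibrium panic fraction",
       ylim = c(0, 1), ...)
  agg <- aggregate(equilibrium_fraction ~ v, as.data.frame(x), mean)
  lines(agg$v, agg$equilibrium_fraction, lwd = 2)
  invisible(x)
}
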