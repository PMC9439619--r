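# shared fixtures built in code

# population with hand-picked thresholds (panic-fraction units)
make_population <- function(thresholds) {
  crowdsim:::new_panic_population(thresholds)
}

# minimal conformity state for single-step rule tests
make_conformity_state <- function(scores, range_low, range_high) {
  structure(list(scores = scores, range_low = range_low,
                 range_high = range_high, behavior = scores > 0),
            class = "conformity_state")
}

# minimal contagion state: comp codes 0 unsus, 1 sus, 2 inf, 3 rec
make_contagion_state <- function(compartment, recovery_prob = NULL) {
  rp <- recovery_prob %||% ifelse(compartment == 2L, 0.05, 0)
  structure(list(compartment = as.integer(compartment), recovery_prob = rp),
            class = "contagion_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small, fast contagion config for property tests
small_contagion_config <- function(..., seed) {
  contagion_config(n_population = 100, n_susceptible = 20,
                   n_infected_initial = 5, n_periods = 20000, seed = seed, ...)
}

# ring neighbors of a node (0-based) in a crowd_network
neighbors_of <- function(net, node) {
  e <- net$edges
  sort(c(e[e[, 1] == node, 2], e[e[, 2] == node, 1]))
}
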