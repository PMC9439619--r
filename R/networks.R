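#' Small-world network configuration
#'
#' Parameters of the Watts-Strogatz construction: a ring lattice with
#' `n_nodes` nodes and `degree` links per node, each lattice link rewired
#' independently with probability `rewiring_prob`.
#'
#' @param n_nodes positive integer, number of nodes (N).
#' @param degree even positive integer, links per node (k); must be < N.
#' @param rewiring_prob probability in \[0, 1\] of rewiring each lattice
#'   link (p).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return A list of class `"small_world_config"`.
#' @examples
#' small_world_config(500, 10, 0.1, seed = 1)
#' @export
small_world_config <- function(n_nodes, degree, rewiring_prob, seed = NULL) {
  check_scalar(n_nodes, "n_nodes", "integerish", lower = 3)
  check_scalar(degree, "degree", "integerish", lower = 2)
  if (degree %% 2 != 0)
    stop_bad("`degree` must be even: each node has degree/2 neighbors per side")
  if (degree >= n_nodes)
    stop_bad("`degree` must be smaller than `n_nodes`")
  check_scalar(rewiring_prob, "rewiring_prob", lower = 0, upper = 1)
  if (!is.null(seed)) check_scalar(seed, "seed", "integerish")
  structure(
    list(n_nodes = as.integer(n_nodes), degree = as.integer(degree),
         rewiring_prob = rewiring_prob,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "small_world_config"
  )
}

new_network <- function(n_nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges)) {
    edges <- cbind(from = pmin(edges[, 1L], edges[, 2L]),
                   to   = pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "crowd_network")
}

#' @export
print.crowd_network <- function(x, ...) {
  cat(sprintf("<crowd_network> %d nodes, %d undirected edges (0-based indices)\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Generate a ring lattice
#'
#' Links every node to its `degree/2` nearest neighbors on each side of the
#' ring. Node indices are 0-based (node 0 .. N-1), matching the edge-list
#' file format.
#'
#' @param config a [small_world_config()] (its `rewiring_prob` is ignored
#'   here; see [rewire()]).
#' @return A `"crowd_network"`: list with `n_nodes` and an `edges` matrix of
#'   0-based unordered pairs, lexicographically sorted.
#' @examples
#' net <- generate_ring_lattice(small_world_config(8, 4, 0))
#' nrow(net$edges)  # 8 * 4 / 2 = 16
#' @export
generate_ring_lattice <- function(config) {
  stopifnot(inherits(config, "small_world_config"))
  n <- config$n_nodes
  half <- config$degree %/% 2L
  from <- rep(0:(n - 1L), each = half)
  off <- rep(seq_len(half), times = n)
  to <- (from + off) %% n
  new_network(n, cbind(from, to))
}

#' Rewire a ring lattice into a small-world network
#'
#' Watts-Strogatz rewiring: every lattice edge is independently selected
#' with probability `rewiring_prob`; a selected edge `(i, i+d)` keeps its
#' anchor `i` and its clockwise endpoint is replaced by a uniformly random
#' node. Candidate targets producing a self-loop or a duplicate edge are
#' rejected and redrawn, so the edge count is exactly preserved. Edges are
#' visited in the standard order: all offset-1 edges around the ring, then
#' offset-2, and so on.
#'
#' @param network a freshly generated ring lattice from
#'   [generate_ring_lattice()].
#' @param rewiring_prob probability in \[0, 1\].
#' @param degree the lattice degree used to generate `network` (needed to
#'   recover the visiting order); defaults to the mean degree.
#' @return A `"crowd_network"` with the same node and edge counts.
#' @examples
#' cfg <- small_world_config(8, 4, 0.2, seed = 1)
#' net <- rewire(generate_ring_lattice(cfg), 0.2)
#' @export
rewire <- function(network, rewiring_prob, degree = NULL) {
  stopifnot(inherits(network, "crowd_network"))
  check_scalar(rewiring_prob, "rewiring_prob", lower = 0, upper = 1)
  n <- network$n_nodes
  degree <- as.integer(degree %||% (2L * nrow(network$edges) / n))
  half <- degree %/% 2L
  # adjacency as a list of 1-based-position integer vectors over 0-based ids
  adj <- vector("list", n)
  for (i in 0:(n - 1L)) adj[[i + 1L]] <- ((i + c(seq_len(half), -seq_len(half))) %% n)
  if (rewiring_prob > 0) {
    for (off in seq_len(half)) {
      for (i in 0:(n - 1L)) {
        if (runif(1) >= rewiring_prob) next
        old <- (i + off) %% n
        # detach clockwise endpoint, redraw until no self-loop/duplicate
        adj[[i + 1L]] <- setdiff(adj[[i + 1L]], old)
        adj[[old + 1L]] <- setdiff(adj[[old + 1L]], i)
        repeat {
          cand <- as.integer(floor(runif(1) * n))
          if (cand != i && !(cand %in% adj[[i + 1L]])) break
        }
        adj[[i + 1L]] <- c(adj[[i + 1L]], cand)
        adj[[cand + 1L]] <- c(adj[[cand + 1L]], i)
      }
    }
  }
  deg <- lengths(adj)
  from <- rep(0:(n - 1L), deg)
  to <- unlist(adj, use.names = FALSE)
  keep <- from < to
  new_network(n, cbind(from[keep], to[keep]))
}

#' Generate a small-world network in one call
#'
#' Convenience wrapper: seeds the RNG (if `config$seed` is set), builds the
#' ring lattice and rewires it.
#'
#' @inheritParams generate_ring_lattice
#' @return A `"crowd_network"`.
#' @export
small_world_network <- function(config) {
  stopifnot(inherits(config, "small_world_config"))
  maybe_seed(config$seed)
  rewire(generate_ring_lattice(config), config$rewiring_prob,
         degree = config$degree)
}

#' Adjacency list of a network
#'
#' @param network a `"crowd_network"`.
#' @return A list of length `n_nodes`; element `i` holds the 1-based indices
#'   of the neighbors of node `i - 1`, sorted ascending. Used by the
#'   learning simulator.
#' @export
as_adjacency_list <- function(network) {
  stopifnot(inherits(network, "crowd_network"))
  n <- network$n_nodes
  adj <- vector("list", n)
  e <- network$edges
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1L] + 1L; b <- e[k, 2L] + 1L
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) if (is.null(v)) integer() else sort(v))
}

#' Correlated initial score field configuration
#'
#' Scores represent per-agent propensities to do a behavior; agents with
#' positive scores do it. Neighboring nodes on the ring get correlated
#' scores via circular moving-average smoothing of Gaussian white noise:
#' `score = amplitude * MA(noise, smoothness) + mean_level`. The smoothed
#' noise has marginal sd `amplitude / sqrt(smoothness)`, so the default
#' `mean_level = amplitude * qnorm(1 - anti_fraction_target) /
#' sqrt(smoothness)` makes the expected share of negative (anti-behavior)
#' scores equal `anti_fraction_target` exactly.
#'
#' @param n_nodes positive integer.
#' @param anti_fraction_target intended share of initially negative scores,
#'   in (0, 0.5): the anti-behavior group must be a minority. Default 0.20.
#' @param smoothness positive integer moving-average window (spatial
#'   correlation length on the ring, in nodes). `1` gives uncorrelated
#'   white noise. Default 10, one neighborhood width under the canonical
#'   k = 10 lattice.
#' @param amplitude nonnegative scale of the noise field; `0` collapses all
#'   scores to `mean_level`.
#' @param mean_level average propensity; default derived from
#'   `anti_fraction_target` as above. Must be positive when the target is
#'   below one half (otherwise the target is unattainable).
#' @param seed integer seed or `NULL`.
#' @return A list of class `"score_field_config"`.
#' @examples
#' score_field_config(500, anti_fraction_target = 0.25)
#' @export
score_field_config <- function(n_nodes, anti_fraction_target = 0.20,
                               smoothness = 10, amplitude = 1,
                               mean_level = NULL, seed = NULL) {
  check_scalar(n_nodes, "n_nodes", "integerish", lower = 1)
  check_scalar(anti_fraction_target, "anti_fraction_target",
               lower = 0, upper = 0.5, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(smoothness, "smoothness", "integerish", lower = 1)
  check_scalar(amplitude, "amplitude", lower = 0)
  if (is.null(mean_level)) {
    mean_level <- amplitude * qnorm(1 - anti_fraction_target) / sqrt(smoothness)
  } else {
    check_scalar(mean_level, "mean_level")
    if (mean_level <= 0 && amplitude >= 0)
      stop_bad("`anti_fraction_target` < 0.5 is unattainable with nonpositive `mean_level`")
  }
  if (!is.null(seed)) check_scalar(seed, "seed", "integerish")
  structure(
    list(n_nodes = as.integer(n_nodes),
         anti_fraction_target = anti_fraction_target,
         smoothness = as.integer(smoothness), amplitude = amplitude,
         mean_level = mean_level,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "score_field_config"
  )
}

#' Generate spatially correlated initial scores on a ring
#'
#' Draws Gaussian white noise, smooths it with a circular moving average of
#' window `smoothness`, scales by `amplitude` and shifts by `mean_level`.
#' Adjacent nodes are positively correlated for `smoothness > 1`
#' (correlation `(w-1)/w` for window `w`), producing contiguous runs of
#' like-minded agents on the ring.
#'
#' @param config a [score_field_config()].
#' @return Numeric vector of length `n_nodes`, one score per node (node
#'   order = ring order).
#' @examples
#' s <- generate_correlated_scores(score_field_config(500, seed = 1))
#' mean(s < 0)  # close to the 0.20 target
#' @export
generate_correlated_scores <- function(config) {
  stopifnot(inherits(config, "score_field_config"))
  maybe_seed(config$seed)
  n <- config$n_nodes
  w <- config$smoothness
  noise <- rnorm(n)
  sm <- if (w == 1L) noise else
    as.numeric(stats::filter(noise, rep(1 / w, w), method = "convolution",
                             sides = 2, circular = TRUE))
  config$amplitude * sm + config$mean_level
}

#' Write / read a network as a plain-text edge list
#'
#' Tab-separated 0-based node-index pairs, one edge per line, smaller index
#' first, lines lexicographically sorted; a header comment `#n_nodes=N`
#' carries the node count (and is the whole body for an empty edge set).
#'
#' @param network a `"crowd_network"`.
#' @param path file path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   returns a `"crowd_network"`. Round-tripping is the identity.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' net <- generate_ring_lattice(small_world_config(3, 2, 0))
#' write_edge_list(net, f)
#' identical(read_edge_list(f)$edges, net$edges)
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "crowd_network"))
  e <- network$edges
  lines <- c(sprintf("#n_nodes=%d", network$n_nodes),
             if (nrow(e)) sprintf("%d\t%d", e[, 1L], e[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  head_line <- grep("^#n_nodes=", lines, value = TRUE)
  if (length(head_line) != 1L)
    stop_bad("edge list must carry exactly one '#n_nodes=N' header comment")
  n <- suppressWarnings(as.integer(sub("^#n_nodes=", "", head_line)))
  if (is.na(n) || n < 1L) stop_bad("malformed '#n_nodes=' header")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(new_network(n, matrix(integer(), ncol = 2L)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_bad("malformed edge-list line: expected two tab-separated indices")
  from <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  to <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(from) || anyNA(to))
    stop_bad("malformed edge-list line: non-integer index")
  if (any(from < 0L) || any(to < 0L) || any(from >= n) || any(to >= n))
    stop_bad("edge-list index out of range [0, n_nodes)")
  if (any(from == to)) stop_bad("edge list contains a self-loop")
  net <- new_network(n, cbind(from, to))
  if (anyDuplicated(net$edges)) stop_bad("edge list contains a duplicate edge")
  net
}
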