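test_that("ring lattice links each node to degree/2 neighbors per side", {
  net <- generate_ring_lattice(small_world_config(8, 4, 0))
  expect_equal(nrow(net$edges), 16)  # N * k / 2
  expect_equal(neighbors_of(net, 0), c(1, 2, 6, 7))

  # canonical N = 500, k = 10 construction: node 100 <-> 95..99, 101..105
  big <- generate_ring_lattice(small_world_config(500, 10, 0))
  expect_equal(neighbors_of(big, 100), c(95:99, 101:105))
  expect_equal(nrow(big$edges), 2500)

  # smallest valid ring is the triangle
  tri <- generate_ring_lattice(small_world_config(3, 2, 0))
  expect_equal(nrow(tri$edges), 3)
  expect_equal(tri$edges[, "from"], c(0L, 0L, 1L), ignore_attr = TRUE)

  expect_error(small_world_config(8, 3, 0), "even")
  expect_error(small_world_config(8, 8, 0), "smaller")
})

test_that("rewiring preserves edge count, avoids self-loops and duplicates", {
  cfg <- small_world_config(500, 10, 0)
  lat <- generate_ring_lattice(cfg)

  # p = 0 reproduces the lattice bit-exactly under any seed
  set.seed(99)
  expect_identical(rewire(lat, 0), lat)

  for (p in c(0.1, 0.5, 1)) {
    set.seed(p * 100)
    net <- rewire(lat, p)
    expect_equal(nrow(net$edges), 2500)
    expect_true(all(net$edges[, 1] != net$edges[, 2]))
    expect_equal(anyDuplicated(net$edges), 0)
    expect_true(all(net$edges >= 0 & net$edges < 500))
  }

  # p = 1 leaves essentially no lattice edge in place
  set.seed(5)
  full <- rewire(lat, 1)
  key <- function(e) paste(e[, 1], e[, 2])
  retained <- mean(key(full$edges) %in% key(lat$edges))
  expect_lt(retained, 0.05)
})

test_that("p = 0.1 rewires about one link per agent on average", {
  cfg <- small_world_config(500, 10, 0)
  lat <- generate_ring_lattice(cfg)
  key <- function(e) paste(e[, 1], e[, 2])
  set.seed(42)
  rewired <- replicate(20, sum(!key(rewire(lat, 0.1)$edges) %in% key(lat$edges)))
  # expectation ~250 of 2500 edges = 1 per agent (binomial sd ~15)
  expect_gt(mean(rewired), 220)
  expect_lt(mean(rewired), 280)
})

test_that("rewiring destroys clustering (small-world premise)", {
  skip_if_not_installed("igraph")
  to_igraph <- function(net)
    igraph::graph_from_edgelist(net$edges + 1L, directed = FALSE)
  cfg <- small_world_config(500, 10, 0)
  lat <- generate_ring_lattice(cfg)
  cc0 <- igraph::transitivity(to_igraph(lat), type = "global")
  set.seed(7)
  cc1 <- mean(replicate(20, {
    igraph::transitivity(to_igraph(rewire(lat, 1)), type = "global")
  }))
  expect_gt(cc0, 0.5)   # ring lattice with k = 10 clusters heavily
  expect_gt(cc0, cc1 * 5)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- small_world_config(200, 6, 0.3, seed = 123)
  expect_identical(small_world_network(cfg), small_world_network(cfg))
  sf <- score_field_config(200, seed = 123)
  expect_identical(generate_correlated_scores(sf),
                   generate_correlated_scores(sf))
})

test_that("correlated score fields have the advertised structure", {
  # smoothness = 1: pure white noise, adjacent scores uncorrelated
  s1 <- generate_correlated_scores(
    score_field_config(5000, smoothness = 1, seed = 1))
  expect_lt(abs(cor(s1[-5000], s1[-1])), 0.05)

  # smoothness > 1: strictly positive adjacent correlation
  s10 <- generate_correlated_scores(
    score_field_config(5000, smoothness = 10, seed = 1))
  expect_gt(cor(s10[-5000], s10[-1]), 0.5)

  # amplitude = 0 collapses to the constant mean level
  s0 <- generate_correlated_scores(
    score_field_config(100, amplitude = 0, mean_level = 0.3, seed = 1))
  expect_equal(s0, rep(0.3, 100))

  # negative-score share matches the target in expectation:
  # 1000 seeded draws at N = 500, target 0.25 -> mean count within 125 +- 10
  set.seed(2024)
  cfg <- score_field_config(500, anti_fraction_target = 0.25)
  counts <- replicate(1000, sum(generate_correlated_scores(cfg) < 0))
  expect_gt(mean(counts), 115)
  expect_lt(mean(counts), 135)

  # negative scores come in contiguous runs on the ring, not salt-and-pepper
  set.seed(3)
  s <- generate_correlated_scores(score_field_config(500))
  runs <- rle(s < 0)
  expect_gt(mean(runs$lengths[runs$values]), 2)

  # an anti minority needs a positive mean level
  expect_error(score_field_config(100, mean_level = -0.1), "unattainable")
})

test_that("edge lists round-trip and reject malformed input", {
  tri <- generate_ring_lattice(small_world_config(3, 2, 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(tri, f)
  expect_equal(readLines(f), c("#n_nodes=3", "0\t1", "0\t2", "1\t2"))
  expect_identical(read_edge_list(f), tri)

  # arbitrary rewired network round-trips too
  set.seed(8)
  net <- rewire(generate_ring_lattice(small_world_config(50, 4, 0)), 0.4)
  write_edge_list(net, f)
  expect_identical(read_edge_list(f), net)

  # empty edge set: header-only body
  empty <- crowdsim:::new_network(4, matrix(integer(), ncol = 2))
  write_edge_list(empty, f)
  expect_equal(readLines(f), "#n_nodes=4")
  expect_identical(read_edge_list(f), empty)

  writeLines(c("#n_nodes=6", "5\t5"), f)
  expect_error(read_edge_list(f), "self-loop")
  writeLines(c("#n_nodes=6", "5\t6"), f)
  expect_error(read_edge_list(f), "out of range")
  writeLines(c("#n_nodes=6", "1\t2\t3"), f)
  expect_error(read_edge_list(f), "malformed")
  writeLines(c("#n_nodes=6", "a\tb"), f)
  expect_error(read_edge_list(f), "malformed")
})
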