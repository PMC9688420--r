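check_all_metrics <- function(a) {
  dfw <- oracle_fw(a)
  expect_equal(distance_matrix(a), dfw)
  cc <- clustering_coefficient(a)
  expect_equal(cc$nodal, oracle_cp_nodal(a))
  expect_equal(cc$cp, mean(oracle_cp_nodal(a)))
  expect_equal(nodal_global_efficiency(a), oracle_enod(a))
  expect_equal(global_efficiency(a), oracle_eglob(a))
  expect_equal(nodal_local_efficiency(a), oracle_eloc_nodal(a))
  expect_equal(local_efficiency(a), mean(oracle_eloc_nodal(a)))
  if (any(is.finite(dfw[row(dfw) != col(dfw)])))
    expect_equal(as.numeric(characteristic_path_length(a)), oracle_lp(a))
}

test_that("hand-checkable graphs give textbook metric values", {
  tri <- graph_from_code(3, 7)                      # triangle
  expect_equal(distance_matrix(tri)[upper.tri(tri)], rep(1, 3))
  expect_equal(clustering_coefficient(tri)$cp, 1)
  expect_equal(as.numeric(characteristic_path_length(tri)), 1)
  expect_equal(nodal_local_efficiency(tri), rep(1, 3))

  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)  # 1-2-3
  expect_equal(distance_matrix(path3)[1, 3], 2)
  expect_equal(as.numeric(characteristic_path_length(path3)), 4 / 3)

  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- 1; star4 <- star4 + t(star4)
  expect_equal(clustering_coefficient(star4)$cp, 0)
  expect_equal(global_efficiency(star4), 0.75)      # (3*1 + 3*0.5)/6
  expect_equal(nodal_global_efficiency(star4), c(1, 2/3, 2/3, 2/3))
  expect_equal(nodal_local_efficiency(star4)[1], 0) # leaves mutually unreachable

  empty4 <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty4), 0)
  expect_equal(local_efficiency(empty4), 0)
  expect_error(characteristic_path_length(empty4), "no reachable")

  full5 <- 1 - diag(5)
  expect_equal(as.numeric(characteristic_path_length(full5)), 1)
  expect_equal(global_efficiency(full5), 1)
  expect_equal(local_efficiency(full5), 1)
})

test_that("metrics match brute-force oracles on enumerated and random graphs", {
  # exhaustive up to n = 4 here; the acceptance suite extends this to all
  # n <= 5 plus sampled n = 6, 7 and 200 random graphs up to n = 20
  for (n in 2:4)
    for (code in 0:(2^(n * (n - 1) / 2) - 1))
      check_all_metrics(graph_from_code(n, code))
  for (b in 1:20) {
    n <- sample(8:20, 1)
    check_all_metrics(rand_graph(n, runif(1, 0.1, 0.7), seed = b))
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (b in 1:25) {
    a <- rand_graph(15, 0.3, seed = 100 + b)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(distance_matrix(a),
                 unname(igraph::distances(g)))
    expect_equal(global_efficiency(a), igraph::global_efficiency(g))
    lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    deg1 <- rowSums(a) == 1
    expect_equal(clustering_coefficient(a)$nodal[!deg1], lc[!deg1])
  }
})

test_that("metric identities and bounds hold on random graphs", {
  for (b in 1:30) {
    a <- rand_graph(sample(5:20, 1), runif(1, 0.1, 0.8), seed = 200 + b)
    expect_equal(mean(nodal_global_efficiency(a)), global_efficiency(a))
    cc <- clustering_coefficient(a)
    expect_true(all(cc$nodal >= 0 & cc$nodal <= 1))
    expect_true(all(nodal_global_efficiency(a) >= 0 &
                      nodal_global_efficiency(a) <= 1))
    expect_true(all(nodal_local_efficiency(a) >= 0 &
                      nodal_local_efficiency(a) <= 1))
  }
})

test_that("including the index node in its neighborhood inflates degree-1 scores", {
  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- 1; star4 <- star4 + t(star4)
  # leaves: neighborhood {leaf, hub} fully connected under the inclusive variant
  expect_equal(nodal_local_efficiency(star4, include_self = TRUE)[2:4],
               rep(1, 3))
  expect_equal(nodal_local_efficiency(star4)[2:4], rep(0, 3))
})

test_that("random rewiring preserves degrees and edge count, destroys clustering", {
  lat <- ring_lattice(24, 3)
  net <- net_of(lat)
  dropped <- logical(0)
  for (b in 1:40) {
    r <- random_reference(net, n_swaps_per_edge = 10, seed = b)
    expect_equal(rowSums(r$adjacency), rowSums(lat))
    expect_equal(sum(r$adjacency), sum(lat))
    expect_true(all(diag(r$adjacency) == 0))
    expect_true(isSymmetric(r$adjacency))
    dropped[b] <- clustering_coefficient(r)$cp < clustering_coefficient(lat)$cp
  }
  expect_gte(mean(dropped), 0.95)
})

test_that("rewiring is seeded and degenerate inputs warn", {
  net <- net_of(rand_graph(12, 0.4, seed = 9))
  expect_identical(random_reference(net, seed = 5), random_reference(net, seed = 5))
  one_edge <- matrix(0, 4, 4); one_edge[1, 2] <- one_edge[2, 1] <- 1
  expect_warning(random_reference(net_of(one_edge)), "fewer than 2 edges")
})

test_that("self-normalization gives unit small-world indices", {
  net <- net_of(rand_graph(15, 0.35, seed = 3))
  sw <- small_world(net, n_random = 1, n_swaps_per_edge = 0)
  expect_identical(sw$gamma, 1)
  expect_identical(sw$lambda, 1)
  expect_identical(sw$sigma, 1)
})

test_that("sigma equals gamma over lambda to machine precision", {
  net <- net_of(rand_graph(20, 0.3, seed = 11))
  sw <- small_world(net, n_random = 5, seed = 2)
  expect_identical(sw$sigma, sw$gamma / sw$lambda)
})

test_that("hub detection applies the mean-plus-one-SD rule", {
  expect_identical(detect_hubs(c(1, 1, 1, 1)), integer(0))
  v <- c(0, 0, 0, 10)    # mean 2.5, sd ~4.33 -> only node 4 exceeds 6.83
  expect_identical(detect_hubs(v), 4L)
  expect_identical(detect_hubs(v + 100), detect_hubs(v))
})
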