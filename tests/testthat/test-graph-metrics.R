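complete_graph <- function(n, w) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}

test_that("hand-computed examples of all four metrics", {
  w4 <- complete_graph(4, 0.5)
  expect_equal(average_degree(w4), 1.5)
  expect_equal(clustering_coefficient(w4), 1)
  dm4 <- distance_matrix(w4)
  expect_true(all(dm4[row(dm4) != col(dm4)] == 2))
  expect_equal(characteristic_path_length(dm4), 2)
  expect_equal(global_efficiency(dm4), 0.5)
  m <- network_metrics(w4)
  expect_equal(unlist(m), c(D = 1.5, CC = 1, CPL = 2, GE = 0.5))

  # two nodes, one edge
  w2 <- matrix(c(0, 0.8, 0.8, 0), 2)
  expect_equal(average_degree(w2), 0.8)

  # 3-node chain, unit weights, no direct 1-3 edge
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 1
  w3[2, 3] <- w3[3, 2] <- 1
  dm3 <- distance_matrix(w3)
  expect_equal(dm3[1, 3], 2)
  expect_equal(characteristic_path_length(dm3), 4 / 3)
  expect_equal(global_efficiency(dm3), 5 / 6)

  # star graph has no triangles
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.7
  expect_equal(clustering_coefficient(star), 0)

  # zero matrix
  z <- matrix(0, 4, 4)
  expect_equal(average_degree(z), 0)
  expect_equal(clustering_coefficient(z), 0)
  dmz <- distance_matrix(z)
  expect_warning(cpl <- characteristic_path_length(dmz), "disconnected")
  expect_equal(cpl, Inf)
  expect_equal(global_efficiency(dmz), 0)
})

test_that("disconnected pairs give Inf CPL with warning, finite-pairs option", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 0.5
  dm <- distance_matrix(w)
  expect_warning(cpl <- characteristic_path_length(dm), "disconnected")
  expect_equal(cpl, Inf)
  expect_equal(characteristic_path_length(dm, finite_pairs = TRUE),
               mean(c(1, 1, 2, 2)))
})

test_that("Dijkstra distances match Floyd-Warshall on random 19-node graphs", {
  set.seed(20)
  for (k in 1:25) {
    w <- random_weight_matrix(19, density = stats::runif(1, 0.2, 1))
    expect_equal(distance_matrix(w), oracle_floyd_warshall(w),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("weighted clustering matches triple enumeration", {
  set.seed(21)
  for (k in 1:10) {
    w <- random_weight_matrix(6, density = 0.8)
    expect_equal(clustering_coefficient(w), oracle_clustering(w),
                 tolerance = 1e-12)
  }
})

test_that("binary clustering option reproduces the unweighted definition", {
  # 4-cycle plus one chord: nodes on the chord close one triangle each
  a <- matrix(0, 4, 4)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- a[edges[r, 2], edges[r, 1]] <- 1
  }
  # nodes 1 and 3: k = 3, two closed pairs among three -> 2/3
  # nodes 2 and 4: k = 2, single neighbor pair closed -> 1
  expect_equal(clustering_coefficient(a, weighted = FALSE), 5 / 6)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(22)
  w <- random_weight_matrix(10, density = 0.8)
  m0 <- suppressWarnings(network_metrics(w))
  for (k in 1:5) {
    p <- sample(10)
    mp <- suppressWarnings(network_metrics(w[p, p]))
    expect_equal(mp, m0, tolerance = 1e-12)
  }
})

test_that("metrics scale as k*D, CC, CPL/k, k*GE under weight scaling", {
  set.seed(23)
  w <- random_weight_matrix(8, density = 1)
  k <- 3.7
  m1 <- network_metrics(w)
  m2 <- network_metrics(k * w)
  expect_equal(m2$D, k * m1$D, tolerance = 1e-12)
  expect_equal(m2$CC, m1$CC, tolerance = 1e-12)
  expect_equal(m2$CPL, m1$CPL / k, tolerance = 1e-12)
  expect_equal(m2$GE, k * m1$GE, tolerance = 1e-12)
})

test_that("GE * CPL = 1 exactly on uniform complete graphs", {
  for (n in c(3, 7, 19)) {
    for (w in c(0.2, 0.5, 0.9)) {
      m <- network_metrics(complete_graph(n, w))
      expect_equal(m$GE * m$CPL, 1, tolerance = 1e-12)
    }
  }
})

test_that("invalid weight matrices are rejected", {
  expect_error(average_degree(matrix(-1, 3, 3)), "non-negative")
  asym <- matrix(runif(9), 3)
  expect_error(average_degree(asym), "symmetric")
})
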