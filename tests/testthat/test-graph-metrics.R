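# Degree, clustering, path length, local efficiency, null model and
# small-worldness.

test_that("closed-form values on canonical graphs", {
  k5 <- gen_ring_lattice(5, 4)  # complete K5
  expect_equal(unname(mean_degree(k5)$degrees), rep(4, 5))
  expect_equal(mean_degree(k5)$mean_degree, 4)
  expect_equal(clustering_coef(k5)$mean, 1)
  expect_equal(characteristic_path_length(k5)$mean, 1)
  expect_equal(local_efficiency(k5)$mean, 1)

  empty <- matrix(0L, 6, 6)
  expect_equal(mean_degree(empty)$mean_degree, 0)
  expect_error(characteristic_path_length(empty), class = "plvnet_no_paths")

  star <- matrix(0L, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1L
  expect_equal(clustering_coef(star)$mean, 0)
  expect_equal(local_efficiency(star)$mean, 0)

  # path graph 1-2-3: pair distances {1, 1, 2}
  p3 <- matrix(0L, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1L
  pl <- characteristic_path_length(p3)
  expect_equal(sort(pl$distances[upper.tri(pl$distances)]), c(1, 1, 2))
  expect_equal(pl$mean, mean(c(mean(c(1, 2)), mean(c(1, 1)),
                               mean(c(2, 1)))))
  expect_equal(pl$n_unreachable_pairs, 0)
})

test_that("disconnected components: reachable-pair convention", {
  two_tri <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    two_tri[e[1], e[2]] <- two_tri[e[2], e[1]] <- 1L
  pl <- characteristic_path_length(two_tri)
  expect_equal(pl$mean, 1)                       # within-component distances
  expect_equal(pl$n_unreachable_pairs, 9)        # 3 x 3 cross pairs
  expect_equal(clustering_coef(two_tri)$mean, 1)
})

test_that("metrics match brute-force oracles on 500 random small graphs", {
  for (s in 1:500) {
    n <- 4 + (s %% 4)                            # 4..7 nodes
    a <- random_graph(n, 0.15 + 0.7 * ((s * 37) %% 97) / 97, seed = s)
    expect_equal(clustering_coef(a)$per_node, bf_clustering(a),
                 tolerance = 1e-12)
    if (sum(a) > 0) {
      expect_equal(characteristic_path_length(a)$mean, bf_path_length(a),
                   tolerance = 1e-12)
    }
    expect_equal(local_efficiency(a)$mean, bf_local_efficiency(a),
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on moderate random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    a <- random_graph(12, 0.35, seed = 100 + s)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    ci[igraph::degree(g) <= 1] <- 0
    expect_equal(clustering_coef(a)$per_node, ci, tolerance = 1e-12)
    D <- igraph::distances(g)
    expect_equal(unname(characteristic_path_length(a)$distances), unname(D))
  }
})

test_that("on connected graphs, adding an edge never increases path length", {
  # (on disconnected graphs the reachable-pairs convention can raise the
  # mean when a new edge joins two components at a large distance)
  for (s in 1:40) {
    a <- random_graph(10, 0.45, seed = 200 + s)
    if (sum(a) == 0) next
    if (characteristic_path_length(a)$n_unreachable_pairs > 0) next
    l0 <- characteristic_path_length(a)$mean
    free <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (!nrow(free)) next
    pick <- free[1 + (s %% nrow(free)), ]
    a[pick[1], pick[2]] <- a[pick[2], pick[1]] <- 1L
    expect_lte(characteristic_path_length(a)$mean, l0 + 1e-12)
  }
})

test_that("null ensemble preserves degrees exactly and is seeded", {
  a <- gen_ws_smallworld(32, 6, 0.2, seed = 1)
  nulls <- null_ensemble(a, 20, seed = 2)
  for (b in nulls) {
    expect_equal(sort(rowSums(b)), sort(rowSums(a)))
    expect_equal(sum(b) / 2, sum(a) / 2)
    expect_equal(b, t(b))
    expect_true(all(diag(b) == 0))
  }
  expect_identical(null_ensemble(a, 5, seed = 3), null_ensemble(a, 5, seed = 3))
  expect_false(identical(null_ensemble(a, 1, seed = 4)[[1]],
                         null_ensemble(a, 1, seed = 5)[[1]]))
})

test_that("randomization destroys lattice clustering", {
  a <- gen_ring_lattice(64, 8)
  nulls <- null_ensemble(a, 30, seed = 7)
  c_rand <- mean(sapply(nulls, function(b) clustering_coef(b)$mean))
  expect_lt(c_rand, clustering_coef(a)$mean)
})

test_that("small-worldness: self-comparison, fixtures and ER reference", {
  k6 <- matrix(1L, 6, 6) - diag(6)  # complete: no legal swap exists
  expect_warning(nulls <- null_ensemble(k6, 10, seed = 1), "no legal")
  sw <- small_worldness(k6, nulls)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$S, 1)

  ws <- gen_ws_smallworld(64, 8, 0.1, seed = 11)
  sw2 <- small_worldness(ws, null_ensemble(ws, 50, seed = 12))
  expect_gt(sw2$gamma, 1)
  expect_gt(sw2$S, 1)

  # an ER graph is statistically its own null family: S scatters around 1
  # (individual 64-node draws fluctuate by ~10-20 %, so the band is asserted
  # on the ensemble mean and on the bulk of the replicates)
  s_vals <- sapply(1:20, function(s) {
    er <- gen_er_random(64, 0.125, seed = 300 + s)
    small_worldness(er, null_ensemble(er, 50, seed = 400 + s))$S
  })
  expect_gt(mean(s_vals), 0.8)
  expect_lt(mean(s_vals), 1.2)
  expect_gte(mean(s_vals > 0.8 & s_vals < 1.2), 0.8)

  expect_error(small_worldness(ws, list()), "non-empty")
})

test_that("graph_metrics bundles all measures consistently", {
  a <- gen_ws_smallworld(20, 4, 0.2, seed = 3)
  gm <- graph_metrics(a)
  expect_equal(gm$mean_degree, 4)
  expect_equal(gm$clustering, clustering_coef(a)$mean)
  expect_equal(gm$path_length, characteristic_path_length(a)$mean)
  expect_equal(gm$local_efficiency, local_efficiency(a)$mean)
  expect_output(print(gm), "Graph metrics")
})
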