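test_that("Onnela clustering matches closed-form values on small motifs", {
  eq_tri <- triangle_net(1, 1, 1)
  expect_equal(unname(onnela_clustering(eq_tri)$per_node), rep(1, 3))

  path3 <- triangle_net(1, 0, 1)   # A-B, B-C only
  expect_equal(unname(onnela_clustering(path3)$per_node), rep(0, 3))

  tri <- triangle_net(w12 = 1, w13 = 0.125, w23 = 1)  # node B joins unit edges
  cl <- onnela_clustering(tri)$per_node
  expect_equal(unname(cl[2]), (1 * 1 * 0.125)^(1 / 3))
  expect_equal(unname(cl[2]), 0.5)

  allzero <- connectome(matrix(0, 4, 4))
  expect_equal(onnela_clustering(allzero)$mean, 0)
})

test_that("path length uses Dijkstra on inverse weights", {
  two <- connectome(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(path_length(two), 2)

  tri <- triangle_net(w12 = 1, w13 = 0.25, w23 = 1)
  # d(A,C) = 2 via B since 1 + 1 < 4; L = (1 + 1 + 2) / 3
  expect_equal(path_length(tri), 4 / 3)

  disc <- connectome(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_warning(L <- path_length(disc), "disconnected")
  expect_identical(L, Inf)
})

test_that("equivalent regular network fills subdiagonals in descending order", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 4; m[1, 3] <- 3; m[1, 4] <- 2; m[2, 3] <- 1
  net <- connectome(m + t(m))
  reg <- equivalent_regular(net)
  # ring offset-1 edges (1,2),(2,3),(3,4),(1,4) receive 4,3,2,1;
  # opposite-offset edges (1,3),(2,4) receive the zeros
  expect_equal(reg[1, 2], 4)
  expect_equal(reg[2, 3], 3)
  expect_equal(reg[3, 4], 2)
  expect_equal(reg[1, 4], 1)
  expect_equal(reg[1, 3], 0)
  expect_equal(reg[2, 4], 0)
  # weight multiset conserved
  expect_equal(sort(reg[upper.tri(reg)]), sort(unclass(net)[upper.tri(net)]))
  # a lattice is its own regular null
  lat <- plant_connectome(16, "lattice", seed = 3)
  expect_equal(unclass(equivalent_regular(lat)), unclass(lat),
               ignore_attr = TRUE)
})

test_that("random nulls conserve the weight multiset and average correctly", {
  net <- plant_connectome(8, "random", seed = 5)
  ens <- equivalent_random(net, n_nulls = 20, seed = 2)
  for (nb in ens$nets[1:5]) {
    expect_equal(sort(nb[upper.tri(nb)]), sort(unclass(net)[upper.tri(net)]))
  }
  # constant-weight complete network: every null identical to the input
  const <- connectome(matrix(0.4, 5, 5) - diag(0.4, 5))
  ens_c <- equivalent_random(const, n_nulls = 5, seed = 1)
  for (nb in ens_c$nets) expect_equal(unclass(nb), unclass(const),
                                      ignore_attr = TRUE)
  # ensemble-mean clustering approaches an independent permutation oracle
  small <- plant_connectome(5, "random", seed = 9)
  ens_s <- equivalent_random(small, n_nulls = 100, seed = 3)
  pairs <- gammanet:::upper_pairs(5)
  vals <- unclass(small)[pairs]
  set.seed(77)
  oracle <- replicate(2000, {
    w <- matrix(0, 5, 5)
    w[pairs] <- sample(vals)
    onnela_clustering(connectome(w + t(w)))$mean
  })
  se <- sd(oracle) / sqrt(100)
  expect_lt(abs(mean(ens_s$stats$clustering) - mean(oracle)), 2.5 * se)
})

test_that("small-world propensity follows the deviation arithmetic", {
  mk <- function(dc, dl) 1 - sqrt((dc^2 + dl^2) / 2)
  expect_equal(mk(0, 0), 1)
  expect_equal(mk(1, 1), 0)
  expect_equal(mk(0.6, 0.8), 1 - sqrt(0.5))
  lat <- plant_connectome(16, "lattice", seed = 3)
  s <- swp(lat, n_nulls = 20, seed = 1)
  expect_equal(s$delta_c, 0)            # lattice is its own regular null
  expect_equal(s$swp, 1 - sqrt((s$delta_c^2 + s$delta_l^2) / 2))
  expect_true(s$swp >= 0 && s$swp <= 1)
})

test_that("degenerate null brackets set deviations to zero with a warning", {
  const <- connectome(matrix(0.4, 6, 6) - diag(0.4, 6))
  # both the clustering and the path-length bracket degenerate here
  expect_warning(expect_warning(s <- swp(const, n_nulls = 5, seed = 1),
                                "Degenerate"), "Degenerate")
  expect_equal(s$delta_c, 0)
  expect_equal(s$delta_l, 0)
  expect_equal(s$swp, 1)
})

test_that("betweenness matches hand counts and a brute-force oracle", {
  path3 <- triangle_net(1, 0, 1)   # A-B-C chain
  b <- betweenness_centrality(path3, n_nulls = 0)
  expect_equal(unname(b$per_node), c(0, 1, 0))
  expect_equal(b$global, 1 / 3)

  complete <- connectome(matrix(1, 4, 4) - diag(1, 4))
  expect_equal(unname(betweenness_centrality(complete, n_nulls = 0)$per_node),
               rep(0, 4))

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  bs <- betweenness_centrality(connectome(star), n_nulls = 0)
  expect_equal(unname(bs$per_node[1]), 6)  # C(4,2) pairs through the hub
  expect_equal(bs$global, 6 / 5)

  for (seed in 1:5) {
    net <- plant_connectome(6, "random", seed = seed)
    got <- betweenness_centrality(net, n_nulls = 0)$per_node
    expect_equal(unname(got), unname(betweenness_bruteforce(net)),
                 tolerance = 1e-10)
  }
})

test_that("eigenvector centrality is symmetric, scale-free and block-dominant", {
  ring <- matrix(0, 6, 6)
  for (i in 1:6) ring[i, i %% 6 + 1] <- 1
  ring <- pmax(ring, t(ring))
  ev <- eigenvector_centrality(connectome(ring))
  expect_equal(unname(ev$per_node), rep(1 / sqrt(6), 6))

  net <- plant_connectome(8, "random", seed = 2)
  e1 <- eigenvector_centrality(net)$per_node
  e2 <- eigenvector_centrality(connectome(unclass(net) * 7))$per_node
  expect_equal(e1, e2)

  blocks <- matrix(0.05, 8, 8)
  blocks[1:4, 1:4] <- 0.9
  diag(blocks) <- 0
  eb <- eigenvector_centrality(connectome(blocks))$per_node
  expect_true(min(eb[1:4]) > max(eb[5:8]))
})

test_that("rich-club curve is exact on equal weights and detects planted clubs", {
  # equal-weight sparse network with degree variation
  set.seed(10)
  m <- matrix(0, 10, 10)
  p <- gammanet:::upper_pairs(10)
  keep <- sample(nrow(p), 28)
  m[p[keep, ]] <- 0.5
  net <- connectome(m + t(m))
  rc <- rich_club(net, n_nulls = 10, seed = 1)
  ok <- !is.na(rc$phi_obs)
  expect_true(all(abs(rc$phi_obs[ok] - 1) < 1e-12))
  expect_true(all(abs(rc$phi_norm[!is.na(rc$phi_norm)] - 1) < 1e-12))

  planted <- plant_connectome(24, "rich_club", seed = 4)
  rcp <- rich_club(planted, n_nulls = 25, seed = 2)
  expect_gt(max(rcp$phi_norm, na.rm = TRUE), 1)

  # phi_obs is a ratio against the strongest weights: bounded by 1
  for (seed in 1:5) {
    sp <- plant_connectome(12, "rich_club", seed = seed)
    rcs <- rich_club(sp, n_nulls = 2, seed = 1)
    expect_true(all(rcs$phi_obs <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("weighted rewiring preserves degrees, weights and connectedness", {
  net <- plant_connectome(16, "rich_club", seed = 6)
  set.seed(3)
  for (i in 1:5) {
    rw <- gammanet:::rewire_weighted(net)
    expect_equal(sort(rw[upper.tri(rw)]), sort(unclass(net)[upper.tri(net)]))
    expect_equal(rowSums(unclass(rw) > 0), rowSums(unclass(net) > 0))
    g <- igraph::graph_from_adjacency_matrix(unclass(rw) > 0,
                                             mode = "undirected")
    expect_true(igraph::is_connected(g))
  }
})

test_that("proportional thresholding keeps the strongest edges", {
  net <- plant_connectome(10, "random", seed = 8)
  th <- threshold_proportional(net, 0.3)
  vals <- unclass(net)[upper.tri(net)]
  kept <- unclass(th)[upper.tri(th)]
  expect_equal(sum(kept > 0), ceiling(0.3 * length(vals)))
  expect_equal(sort(kept[kept > 0], decreasing = TRUE),
               sort(vals, decreasing = TRUE)[seq_len(sum(kept > 0))],
               tolerance = 1e-12)
})

test_that("network_topology aggregates all fields consistently", {
  net <- plant_connectome(12, "small_world", seed = 11)
  res <- suppressWarnings(network_topology(net, n_nulls = 10, seed = 2))
  expect_s3_class(res, "topology_result")
  expect_equal(res$swp, 1 - sqrt((res$delta_c^2 + res$delta_l^2) / 2))
  expect_true(res$clustering_mean >= 0 && res$clustering_mean <= 1)
  expect_true(res$betweenness_norm > 0)
})
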