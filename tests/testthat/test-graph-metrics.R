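K4 <- graph_fixtures$complete(4)
star5 <- graph_fixtures$star(5)
path4 <- graph_fixtures$path(4)
path3 <- graph_fixtures$path(3)
tri_pendant <- graph_fixtures$tri_pendant

test_that("clustering coefficient matches hand counts", {
  expect_equal(clustering_coefficient(K4), 1)
  expect_equal(clustering_coefficient(star5), 0)
  expect_equal(clustering_coefficient(tri_pendant), (1 / 3 + 1 + 1 + 0) / 4)
  expect_equal(unname(clustering_coefficient(tri_pendant, per_node = TRUE)),
               c(1 / 3, 1, 1, 0))
})

test_that("characteristic path length averages finite pairs and reports the rest", {
  expect_equal(as.numeric(characteristic_path_length(K4)), 1)
  expect_equal(as.numeric(characteristic_path_length(path4)),
               mean(c(1, 2, 3, 1, 2, 1)))
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1
  two_edges[3, 4] <- two_edges[4, 3] <- 1
  lp <- characteristic_path_length(two_edges)
  expect_equal(as.numeric(lp), 1)
  expect_equal(attr(lp, "unreachable_pairs"), 4L)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no edges")
})

test_that("efficiencies match their definitions", {
  expect_equal(global_efficiency(K4), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(global_efficiency(path3), mean(c(1, 1, 1 / 2)))

  expect_equal(local_efficiency(K4), 1)
  expect_equal(local_efficiency(star5), 0)
  expect_equal(local_efficiency(tri_pendant), (1 / 3 + 1 + 1 + 0) / 4)

  expect_equal(unname(nodal_efficiency(star5))[1], 1)
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(unname(nodal_efficiency(iso))[3], 0)
  expect_equal(unname(nodal_efficiency(path3))[1], mean(c(1, 1 / 2)))
})

test_that("betweenness is the normalized fraction of shortest paths", {
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(K4)), rep(0, 4))
  expect_equal(unname(betweenness_centrality(star5)), c(1, 0, 0, 0, 0))
})

test_that("degree is the row sum", {
  expect_equal(unname(node_degree(graph_fixtures$complete(17))), rep(16L, 17))
  expect_equal(unname(node_degree(matrix(0, 5, 5))), rep(0L, 5))
  expect_equal(unname(node_degree(tri_pendant)), c(3L, 2L, 2L, 1L))
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(11)
  for (i in 1:120) {
    n <- sample(3:7, 1)
    adj <- random_adjacency(n)
    expect_equal(mean(oracle_clustering(adj)), clustering_coefficient(adj))
    o <- oracle_lp(adj)
    if (!is.na(o$lp)) {
      lp <- characteristic_path_length(adj)
      expect_equal(as.numeric(lp), o$lp)
      expect_equal(attr(lp, "unreachable_pairs"), as.integer(o$unreachable))
    }
    expect_equal(global_efficiency(adj), oracle_eglobal(adj))
    expect_equal(local_efficiency(adj), mean(oracle_local_eff(adj)))
    expect_equal(unname(nodal_efficiency(adj)), oracle_nodal_eff(adj))
    expect_equal(unname(betweenness_centrality(adj)), oracle_betweenness(adj))
  }
})

test_that("metrics agree with igraph on larger random graphs", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (i in 1:25) {
    n <- sample(8:17, 1)
    adj <- random_adjacency(n, p_edge = runif(1, 0.25, 0.7))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    # clustering: igraph local transitivity is NaN for degree < 2, our
    # convention scores those nodes 0
    tr <- igraph::transitivity(g, type = "local", isolates = "zero")
    expect_equal(clustering_coefficient(adj), mean(tr))
    expect_equal(as.numeric(characteristic_path_length(adj)),
                 igraph::mean_distance(g))
    bn <- igraph::betweenness(g, normalized = TRUE)
    expect_equal(unname(betweenness_centrality(adj)), unname(bn))
    d <- igraph::distances(g)
    inv <- 1 / d[upper.tri(d)]
    expect_equal(global_efficiency(adj), mean(ifelse(is.finite(inv), inv, 0)))
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:17, 1)
    adj <- random_adjacency(n)
    perm <- sample(n)
    padj <- adj[perm, perm]
    expect_equal(clustering_coefficient(padj), clustering_coefficient(adj))
    expect_equal(global_efficiency(padj), global_efficiency(adj))
    expect_equal(local_efficiency(padj), local_efficiency(adj))
    if (sum(adj) > 0) {
      expect_equal(as.numeric(characteristic_path_length(padj)),
                   as.numeric(characteristic_path_length(adj)))
    }
    expect_equal(unname(betweenness_centrality(padj)),
                 unname(betweenness_centrality(adj))[perm])
    expect_equal(unname(nodal_efficiency(padj)),
                 unname(nodal_efficiency(adj))[perm])
  }
})

test_that("global efficiency is monotone under edge addition", {
  set.seed(14)
  for (i in 1:20) {
    adj <- random_adjacency(10, p_edge = 0.3)
    e0 <- global_efficiency(adj)
    empty <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(empty)) next
    pick <- empty[sample(nrow(empty), 1), ]
    adj[pick[1], pick[2]] <- adj[pick[2], pick[1]] <- 1
    expect_gte(global_efficiency(adj), e0)
  }
})

test_that("rewiring preserves degrees, keeps edge counts and breaks clustering", {
  set.seed(15)
  # modular fixture: two dense blocks weakly linked -> strongly clustered
  blocks <- matrix(0, 17, 17)
  blocks[1:8, 1:8] <- 1; blocks[9:17, 9:17] <- 1
  diag(blocks) <- 0
  blocks[8, 9] <- blocks[9, 8] <- 1
  cp0 <- clustering_coefficient(blocks)
  cps <- replicate(100, {
    rw <- rewire_preserving_degree(blocks)
    expect_equal(rowSums(rw), rowSums(blocks), ignore_attr = TRUE)
    expect_equal(sum(rw) / 2, sum(blocks) / 2)
    clustering_coefficient(rw)
  })
  expect_lt(mean(cps), cp0)

  # any seed, any graph: degree sequence is the defining invariant
  for (i in 1:10) {
    adj <- random_adjacency(12, p_edge = 0.4)
    rw <- rewire_preserving_degree(adj, seed = i)
    expect_equal(rowSums(rw), rowSums(adj), ignore_attr = TRUE)
  }

  # the complete graph admits no legal swap and is returned unchanged
  K6 <- graph_fixtures$complete(6)
  expect_warning(rw6 <- rewire_preserving_degree(K6), "swaps")
  expect_equal(unclass(rw6), K6, ignore_attr = TRUE)
})

test_that("normalized metrics behave as ratios and detect small worlds", {
  set.seed(16)
  adj <- random_adjacency(17, n_edges = 40)
  # zero swap budget: the ensemble is the graph itself
  nm0 <- normalized_metrics(adj, n_random = 1, swap_mult = 0)
  expect_equal(nm0$gamma, 1)
  expect_equal(nm0$lambda, 1)
  expect_equal(nm0$sigma, 1)

  nm <- normalized_metrics(adj, n_random = 20, seed = 1)
  expect_equal(nm$sigma, nm$gamma / nm$lambda)

  # clustered ring lattice: Gamma and Sigma clearly above 1
  rl <- ring_lattice(17, 2)
  nml <- normalized_metrics(rl, n_random = 100, seed = 2)
  expect_gt(nml$gamma, 1)
  expect_gt(nml$sigma, 1)

  # a star graph's rewired ensemble has zero clustering -> Gamma undefined
  expect_error(normalized_metrics(graph_fixtures$star(6), n_random = 5,
                                  seed = 3),
               "Gamma")
})

test_that("global_metrics bundles the individual metrics coherently", {
  set.seed(17)
  adj <- random_adjacency(12, p_edge = 0.5)
  gm <- global_metrics(adj, n_random = 10, seed = 4)
  expect_equal(gm$Cp, clustering_coefficient(adj))
  expect_equal(gm$Lp, as.numeric(characteristic_path_length(adj)))
  expect_equal(gm$Eglobal, global_efficiency(adj))
  expect_equal(gm$Elocal, local_efficiency(adj))
  expect_equal(gm$Sigma, gm$Gamma / gm$Lambda)
})

test_that("malformed adjacency matrices are rejected", {
  expect_error(clustering_coefficient(matrix(0.5, 3, 3)), "binary")
  bad <- matrix(0, 3, 3); bad[1, 2] <- 1
  expect_error(clustering_coefficient(bad), "symmetric")
  d <- diag(3)
  expect_error(clustering_coefficient(d), "diagonal")
})
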