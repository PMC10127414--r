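test_that("correlation matrix entries follow the Pearson formula and zeroing rule", {
  nodes <- c("n1", "n2", "n3")
  V <- cbind(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10), c(5, 4, 3, 2, 1))
  co <- volume_cohort(A = V, nodes = nodes)
  net <- covariance_matrix(co, nodes, group = "A")
  expect_equal(net$R["n1", "n2"], 1)            # identical up to scale
  expect_equal(net$R["n1", "n3"], -1)           # exactly anticorrelated
  expect_equal(net$R_plus["n1", "n3"], 0)       # negatives zeroed
  expect_equal(diag(net$R_plus), rep(1, 3), ignore_attr = TRUE)

  # hand Pearson on a 5-subject, 3-node fixture
  set.seed(2)
  V2 <- matrix(rnorm(15), 5, 3)
  co2 <- volume_cohort(A = V2, nodes = nodes)
  R <- covariance_matrix(co2, nodes, group = "A")$R
  hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(R["n1", "n2"], hand(V2[, 1], V2[, 2]))
  expect_equal(R["n2", "n3"], hand(V2[, 2], V2[, 3]))

  expect_error(covariance_matrix(co2[1:3, ], nodes), "4 subjects")
  co2$n2 <- 7
  expect_error(covariance_matrix(co2, nodes), "n2")
})

test_that("R_plus is invariant to monotone affine rescaling of volumes", {
  set.seed(4)
  nodes <- default_node_set()
  V <- mvn_volumes(30)
  co <- volume_cohort(A = V, nodes = nodes)
  R1 <- covariance_matrix(co, nodes)$R_plus
  V2 <- sweep(sweep(V, 2, runif(17, 0.5, 3), "*"), 2, rnorm(17, 50), "+")
  co2 <- volume_cohort(A = V2, nodes = nodes)
  R2 <- covariance_matrix(co2, nodes)$R_plus
  expect_equal(R1, R2, tolerance = 1e-12)
})

test_that("sparsity grid has exact decimal handling", {
  g <- sparsity_grid()
  expect_length(g, 33)
  expect_equal(g[1], 0.18)
  expect_equal(g[33], 0.50)
  expect_true(all(diff(g) > 0))
  expect_equal(sparsity_grid(0.3, 0.3, 0.01), 0.3)
  expect_equal(sparsity_grid(0.10, 0.20, 0.05), c(0.10, 0.15, 0.20))
  expect_error(sparsity_grid(0.1, 0.2, 0.03), "divide")
})

test_that("binarization keeps the k strongest edges with the fixed tie rule", {
  set.seed(5)
  nodes <- default_node_set()
  co <- volume_cohort(A = mvn_volumes(40), nodes = nodes)
  net <- covariance_matrix(co, nodes)

  adj <- binarize_at_sparsity(net, 0.18)
  expect_equal(sum(adj) / 2, floor(0.18 * 136))
  expect_equal(sum(adj) / 2, 24)
  expect_true(all(adj %in% c(0, 1)))
  expect_equal(adj, t(adj))
  expect_equal(diag(adj), rep(0, 17), ignore_attr = TRUE)

  # support equals a brute-force sort-and-cut oracle (fuzz)
  for (i in 1:100) {
    p <- sample(4:17, 1)
    W <- matrix(runif(p * p, -0.5, 1), p, p)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    W <- pmax(W, 0)
    s <- runif(1, 0.05, 1)
    adj <- suppressWarnings(binarize_at_sparsity(W, s))
    k <- floor(s * p * (p - 1) / 2 + 1e-9)
    ut <- which(upper.tri(W), arr.ind = TRUE)
    ord <- order(-W[ut], ut[, 1], ut[, 2])
    keep <- ord[seq_len(min(k, sum(W[ut] > 0)))]
    oracle <- matrix(0, p, p)
    oracle[ut[keep, , drop = FALSE]] <- 1
    oracle <- oracle + t(oracle)
    expect_equal(unclass(adj), oracle, ignore_attr = TRUE)
  }
})

test_that("edge sets are nested across increasing sparsity", {
  set.seed(6)
  co <- volume_cohort(A = mvn_volumes(40), nodes = default_node_set())
  net <- covariance_matrix(co)
  grid <- sparsity_grid()
  prev <- binarize_at_sparsity(net, grid[1])
  for (s in grid[-1]) {
    cur <- binarize_at_sparsity(net, s)
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("binarization never manufactures edges from zero weights", {
  p <- 8
  W <- matrix(0, p, p)
  diag(W) <- 1
  # only 5 positive pairs available
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.8
  W[2, 3] <- W[3, 2] <- 0.7
  W[4, 5] <- W[5, 4] <- 0.6
  W[6, 7] <- W[7, 6] <- 0.5
  expect_warning(adj <- binarize_at_sparsity(W, 0.9), "5 positive")
  expect_equal(sum(adj) / 2, 5)
  expect_equal(attr(adj, "achieved_edges"), 5)
  expect_gt(attr(adj, "requested_edges"), 5)
})

test_that("strongest-fraction edge list agrees with binarization support", {
  set.seed(7)
  nodes <- default_node_set()
  co <- volume_cohort(A = mvn_volumes(50), nodes = nodes)
  net <- covariance_matrix(co, nodes)
  el <- strongest_fraction_edges(net, 0.25)
  expect_equal(nrow(el), 34)
  expect_true(all(diff(el$weight) <= 0))
  adj <- binarize_at_sparsity(net, 0.25)
  sup <- matrix_edge_list(adj)
  key <- function(d) paste(pmin(d$node_i, d$node_j), pmax(d$node_i, d$node_j))
  expect_setequal(key(el), key(sup))

  # single strongest edge on a 3-node network
  W3 <- matrix(c(1, .9, .2, .9, 1, .5, .2, .5, 1), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  e1 <- strongest_fraction_edges(W3, 1 / 3)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$weight, 0.9)
})

test_that("residualized covariance removes covariate-driven correlation", {
  set.seed(8)
  n <- 60
  nodes <- c("x1", "x2", "x3", "x4")
  tiv <- rnorm(n)
  V <- matrix(rnorm(n * 4, sd = 0.3), n, 4) + 2 * tiv  # common TIV drive
  co <- volume_cohort(A = V, nodes = nodes)
  co$tiv <- tiv
  co$age <- rnorm(n); co$sex <- sample(c("M", "F"), n, TRUE)
  co$education <- rnorm(n)
  plain <- covariance_matrix(co, nodes)
  res <- covariance_matrix(co, nodes, residualize = TRUE)
  expect_gt(min(plain$R[upper.tri(plain$R)]), 0.9)
  expect_lt(max(abs(res$R[upper.tri(res$R)])), 0.5)
})
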