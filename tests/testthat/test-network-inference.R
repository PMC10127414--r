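fast_config <- function(...) {
  analysis_config(n_perm = 99, n_random = 2, ...)
}

test_that("curve AUC matches closed forms and a refinement oracle", {
  grid <- sparsity_grid()
  expect_equal(curve_auc(rep(2, 33), grid), 0.32 * 2)
  lin <- (grid - 0.18) / 0.32
  expect_equal(curve_auc(lin, grid), 0.16)

  # piecewise-linear input: trapezoid equals a fine Riemann refinement
  set.seed(21)
  v <- cumsum(rnorm(33))
  fine_x <- seq(0.18, 0.50, length.out = 20001)
  fine_v <- approx(grid, v, xout = fine_x)$y
  riemann <- sum((fine_v[-1] + fine_v[-length(fine_v)]) / 2 * diff(fine_x))
  expect_equal(curve_auc(v, grid), riemann, tolerance = 1e-12)

  # step-sum convention: sum of values times the constant step
  expect_equal(curve_auc(v, grid, method = "step_sum"), sum(v) * 0.01)

  expect_error(curve_auc(c(1, NA, 3), grid[1:3]), "missing")
  expect_error(curve_auc(1, 0.2), "2 grid points")
})

test_that("metric curves evaluate the full grid deterministically", {
  set.seed(22)
  co <- volume_cohort(A = mvn_volumes(40), nodes = default_node_set())
  cfg <- fast_config(seed = 5)
  cur1 <- metric_curves(co, "A", config = cfg)
  cur2 <- metric_curves(co, "A", config = cfg)
  expect_identical(cur1$global, cur2$global)
  expect_identical(cur1$auc, cur2$auc)
  expect_equal(ncol(cur1$global), 33)
  expect_equal(dim(cur1$nodal_efficiency), c(17, 33))
  expect_equal(cur1$auc[["Sigma"]],
               curve_auc(cur1$global["Sigma", ], cur1$grid))
  # requested edge counts follow floor(s * 136); achieved never exceeds them
  expect_equal(cur1$requested_edges, as.integer(floor(cur1$grid * 136 + 1e-9)))
  expect_true(all(cur1$achieved_edges <= cur1$requested_edges))
})

test_that("an all-positive equicorrelated network saturates at full sparsity", {
  set.seed(23)
  nodes <- paste0("n", 1:6)
  base <- rnorm(40)
  V <- sapply(1:6, function(i) base + rnorm(40, sd = 0.2))
  co <- volume_cohort(A = V, nodes = nodes)
  cfg <- analysis_config(sparsity_min = 0.5, sparsity_max = 1, sparsity_step = 0.25,
                         n_perm = 9, n_random = 1, seed = 1)
  cur <- metric_curves(co, "A", nodes, cfg)
  # last grid point: complete graph
  expect_equal(unname(cur$global["Cp", 3]), 1)
  expect_equal(unname(cur$global["Lp", 3]), 1)
  expect_equal(cur$achieved_edges[3], 15)
})

test_that("the permutation chain is reproducible and respects its bounds", {
  set.seed(24)
  co <- volume_cohort(A = mvn_volumes(20), B = mvn_volumes(20),
                      nodes = default_node_set())
  cfg <- fast_config(seed = 7)
  r1 <- permutation_test_auc(co, c("A", "B"), config = cfg)
  r2 <- permutation_test_auc(co, c("A", "B"), config = cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / (cfg$n_perm + 1)))
  expect_true(all(r1$p <= 1))

  # label swap flips the difference and leaves p unchanged
  r3 <- permutation_test_auc(co, c("B", "A"), config = cfg)
  expect_equal(r3$p, r1$p)
  expect_equal(r3$diff, -r1$diff)
  expect_equal(r3$auc_A, r1$auc_B)
})

test_that("duplicated groups give zero differences and p = 1", {
  set.seed(25)
  V <- mvn_volumes(25)
  co <- volume_cohort(A = V, B = V, nodes = default_node_set())
  cfg <- fast_config(seed = 9)
  r <- permutation_test_auc(co, c("A", "B"), config = cfg)
  # the deterministic part of the chain gives exactly zero differences;
  # Gamma/Lambda/Sigma carry independent random-ensemble noise per group
  det <- r$metric %in% c("Cp", "Lp", "Eglobal", "Elocal")
  expect_equal(r$diff[det], rep(0, 4), tolerance = 1e-12)
  expect_equal(r$p[det], rep(1, 4))

  nod <- nodal_permutation_fdr(co, c("A", "B"), config = cfg)
  expect_equal(nod$diff, rep(0, 17), tolerance = 1e-12)
  expect_equal(nod$p, rep(1, 17))
  expect_true(all(nod$q >= nod$p))
})

test_that("nodal FDR adjustment follows BH across 17 nodes", {
  p <- c(0.001, rep(0.9, 16))
  q <- fdr_adjust(p)
  expect_equal(q[1], 0.001 * 17)
  expect_equal(q[1], 0.017)
  expect_true(all(q >= p))
})

test_that("null permutation p-values are uniform (KS check)", {
  set.seed(26)
  cfg <- analysis_config(n_perm = 99, n_random = 1, swap_mult = 0, seed = 0)
  pvals <- replicate(500, {
    co <- volume_cohort(A = mvn_volumes(15), B = mvn_volumes(15),
                        nodes = default_node_set())
    cfg$seed <- sample.int(1e6, 1)
    permutation_test_auc(co, c("A", "B"), config = cfg,
                         metrics = "Cp")$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("reused random ensembles remain a valid (deterministic) option", {
  set.seed(27)
  co <- volume_cohort(A = mvn_volumes(20), B = mvn_volumes(20),
                      nodes = default_node_set())
  cfg <- analysis_config(n_perm = 49, n_random = 3, seed = 11,
                         reuse_random_ensembles = TRUE)
  r1 <- permutation_test_auc(co, c("A", "B"), config = cfg)
  r2 <- permutation_test_auc(co, c("A", "B"), config = cfg)
  expect_identical(r1, r2)
  expect_true(all(is.finite(r1$diff[r1$metric %in% c("Gamma", "Lambda")])))
})
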