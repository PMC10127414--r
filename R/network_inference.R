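.scn_global_metric_names <- c("Cp", "Lp", "Eglobal", "Elocal", "Gamma",
                              "Lambda", "Sigma")

.group_volumes <- function(cohort, group, nodes, residualize = FALSE,
                           covariates = NULL) {
  sub <- cohort[as.character(cohort$group) %in% group, , drop = FALSE]
  absent <- setdiff(nodes, names(sub))
  if (length(absent)) {
    stop("cohort is missing node column(s): ", paste(absent, collapse = ", "))
  }
  V <- as.matrix(sub[, nodes])
  if (nrow(V) < 4) {
    stop("group '", paste(group, collapse = "+"),
         "' has fewer than 4 subjects")
  }
  if (isTRUE(residualize)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(sub[, covariates]))
    V <- apply(V, 2, function(v) stats::resid(stats::lm.fit(mm, v)))
  }
  V
}

#' Area under a metric-versus-sparsity curve
#'
#' Integrates a metric curve over the sparsity grid.  `"trapezoid"` uses the
#' trapezoidal rule; `"step_sum"` sums the values times the constant grid
#' step (the convention of some network toolboxes).
#'
#' @param values Metric values, one per grid point (no missing values).
#' @param grid Increasing sparsity fractions, length >= 2.
#' @param method `"trapezoid"` (default) or `"step_sum"`.
#' @return Scalar AUC in units of metric x sparsity-fraction.
#' @export
curve_auc <- function(values, grid, method = c("trapezoid", "step_sum")) {
  method <- match.arg(method)
  if (length(values) != length(grid)) {
    stop("values and grid must have equal length")
  }
  if (length(grid) < 2) stop("at least 2 grid points are required")
  if (anyNA(values)) stop("metric curve contains missing values")
  if (method == "trapezoid") {
    pracma::trapz(grid, values)
  } else {
    step <- (grid[length(grid)] - grid[1]) / (length(grid) - 1)
    sum(values) * step
  }
}

#' Metric curves across the sparsity grid for one group
#'
#' Builds the group's structural covariance network, binarizes it at every
#' sparsity of the grid, computes all global metrics (with random-network
#' normalization) and the nodal metrics, and integrates each curve into its
#' AUC.
#'
#' @param cohort Cohort tibble.
#' @param group Group label(s) defining the subset.
#' @param nodes Node columns (default 17-node set).
#' @param config An [analysis_config()]; the master seed drives the
#'   random-network ensembles.
#' @return An `"scn_curves"` object: sparsity `grid`, `global` (7 x S metric
#'   matrix), `nodal_efficiency` / `degree` / `betweenness` (node x S),
#'   `auc` (named global AUCs), `nodal_auc` (node x 3), edge-count
#'   diagnostics, and `unreachable_pairs` per sparsity.
#' @export
metric_curves <- function(cohort, group, nodes = default_node_set(),
                          config = analysis_config()) {
  validate_config(config)
  grid <- sparsity_grid(config$sparsity_min, config$sparsity_max,
                        config$sparsity_step)
  if (length(grid) < 2) stop("AUC needs at least two sparsity values")
  V <- .group_volumes(cohort, group, nodes, config$residualize_edges,
                      config$covariates)
  set.seed(config$seed)
  res <- cpp_group_curves(V, grid, config$n_random, config$swap_mult,
                          config$attempt_mult, TRUE, TRUE, TRUE, TRUE, TRUE)
  rownames(res$nodal_efficiency) <- nodes
  rownames(res$degree) <- nodes
  rownames(res$betweenness) <- nodes
  trap <- config$auc == "trapezoid"
  auc <- apply(res$global, 1, curve_auc, grid = grid, method = config$auc)
  nodal_auc <- cbind(
    nodal_efficiency = apply(res$nodal_efficiency, 1, curve_auc, grid = grid,
                             method = config$auc),
    degree = apply(res$degree, 1, curve_auc, grid = grid, method = config$auc),
    betweenness = apply(res$betweenness, 1, curve_auc, grid = grid,
                        method = config$auc))
  structure(list(group = paste(group, collapse = "+"), nodes = nodes,
                 grid = grid, global = res$global,
                 nodal_efficiency = res$nodal_efficiency,
                 degree = res$degree, betweenness = res$betweenness,
                 auc = auc, nodal_auc = nodal_auc,
                 requested_edges = res$requested_edges,
                 achieved_edges = res$achieved_edges,
                 unreachable_pairs = res$unreachable_pairs,
                 n_subjects = nrow(V)),
            class = "scn_curves")
}

#' @export
print.scn_curves <- function(x, ...) {
  cat("Metric curves: group ", x$group, " (n = ", x$n_subjects, ", ",
      length(x$grid), " sparsities ", min(x$grid), "-", max(x$grid), ")\n",
      sep = "")
  cat("  AUC: ", paste(sprintf("a%s=%.3f", names(x$auc), x$auc),
                       collapse = ", "), "\n", sep = "")
  short <- sum(x$achieved_edges < x$requested_edges)
  if (short) cat("  note: ", short, " sparsity level(s) short of positive edges\n")
  invisible(x)
}

.run_perm_engine <- function(cohort, groups, nodes, config,
                             do_norm = TRUE, do_gamma = TRUE,
                             do_local = TRUE, do_betw = TRUE,
                             do_nodal = TRUE) {
  if (length(groups) != 2) stop("exactly two groups are required")
  validate_config(config)
  grid <- sparsity_grid(config$sparsity_min, config$sparsity_max,
                        config$sparsity_step)
  # canonical internal order makes the test invariant to label swapping
  ord <- order(as.character(groups))
  g1 <- groups[ord[1]]; g2 <- groups[ord[2]]
  resid <- config$residualize_edges
  if (resid) {
    # residualize on the pooled two-group sample so permuted relabellings
    # stay consistent
    pooled <- cohort[as.character(cohort$group) %in% groups, , drop = FALSE]
    mm <- stats::model.matrix(~ ., data = as.data.frame(pooled[, config$covariates]))
    for (nd in nodes) {
      pooled[[nd]] <- stats::resid(stats::lm.fit(mm, pooled[[nd]]))
    }
    cohort <- pooled
  }
  V1 <- .group_volumes(cohort, g1, nodes, FALSE)
  V2 <- .group_volumes(cohort, g2, nodes, FALSE)
  set.seed(config$seed)
  eng <- cpp_perm_test(V1, V2, grid, config$n_perm, config$n_random,
                       config$swap_mult, config$attempt_mult,
                       do_norm, do_gamma, do_local, do_betw, do_nodal,
                       config$auc == "trapezoid",
                       config$reuse_random_ensembles)
  list(engine = eng, g1 = g1, g2 = g2, flipped = ord[1] != 1L)
}

.perm_p <- function(obs, null) {
  ok <- is.finite(null)
  (1 + sum(abs(null[ok]) >= abs(obs))) / (1 + sum(ok))
}

#' Permutation test on AUC differences of global network metrics
#'
#' Pools the subjects of two groups, randomly reassigns them (preserving
#' group sizes) `n_perm` times, and re-runs the entire chain — correlation,
#' negative zeroing, sparsity binarization, metrics, random-network
#' normalization, AUC — for every relabelling.  The two-tailed p-value is
#' `(1 + #{|diff_perm| >= |diff_obs|}) / (1 + n_perm)`, so it is never
#' smaller than `1/(n_perm + 1)` and is invariant to swapping the group
#' labels.
#'
#' @param cohort Cohort tibble.
#' @param groups Character vector of exactly two group labels; the reported
#'   difference is `groups[1] - groups[2]`.
#' @param nodes Node columns.
#' @param config An [analysis_config()] (n_perm, n_random, grid, AUC rule,
#'   seed).
#' @param metrics Global metrics to report (default all seven).
#' @return Tibble with one row per metric: `metric`, `auc_A`, `auc_B`,
#'   `diff`, `p`, `n_perm`, plus the group labels in the `"groups"`
#'   attribute.
#' @export
permutation_test_auc <- function(cohort, groups, nodes = default_node_set(),
                                 config = analysis_config(),
                                 metrics = .scn_global_metric_names) {
  metrics <- match.arg(metrics, .scn_global_metric_names, several.ok = TRUE)
  run <- .run_perm_engine(cohort, groups, nodes, config,
                          do_norm = any(c("Gamma", "Lambda", "Sigma") %in%
                                          metrics),
                          do_gamma = any(c("Gamma", "Sigma") %in% metrics),
                          do_local = "Elocal" %in% metrics,
                          do_betw = FALSE, do_nodal = FALSE)
  eng <- run$engine
  sign_flip <- if (run$flipped) -1 else 1
  rows <- lapply(metrics, function(m) {
    oA <- eng$auc_A[[m]]; oB <- eng$auc_B[[m]]
    if (!is.finite(oA) || !is.finite(oB)) {
      return(tibble::tibble(metric = m, auc_A = NA_real_, auc_B = NA_real_,
                            diff = NA_real_, p = NA_real_,
                            n_perm = config$n_perm))
    }
    d <- oA - oB
    p <- .perm_p(d, eng$null_global[, m])
    tibble::tibble(metric = m,
                   auc_A = if (run$flipped) oB else oA,
                   auc_B = if (run$flipped) oA else oB,
                   diff = sign_flip * d, p = p, n_perm = config$n_perm)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "groups") <- groups
  out
}

#' Nodal permutation tests with FDR across nodes
#'
#' Applies the AUC permutation test per node to a nodal metric
#' (nodal efficiency, betweenness or degree) and adjusts the per-node
#' p-values across the node set with Benjamini-Hochberg FDR.
#'
#' @inheritParams permutation_test_auc
#' @param metric `"nodal_efficiency"`, `"betweenness"` or `"degree"`.
#' @return Tibble with `node`, `auc_A`, `auc_B`, `diff`, `p`, `q`.
#' @export
nodal_permutation_fdr <- function(cohort, groups, nodes = default_node_set(),
                                  config = analysis_config(),
                                  metric = c("nodal_efficiency",
                                             "betweenness", "degree")) {
  metric <- match.arg(metric)
  # nodal metrics need no random-network normalization
  run <- .run_perm_engine(cohort, groups, nodes, config,
                          do_norm = FALSE, do_gamma = FALSE,
                          do_local = FALSE,
                          do_betw = metric == "betweenness",
                          do_nodal = TRUE)
  eng <- run$engine
  sign_flip <- if (run$flipped) -1 else 1
  if (metric == "betweenness") {
    oA <- eng$betweenness_auc_A[, 1]; oB <- eng$betweenness_auc_B[, 1]
    null <- eng$null_betweenness
  } else {
    col <- if (metric == "nodal_efficiency") 1 else 2
    oA <- eng$nodal_auc_A[, col]; oB <- eng$nodal_auc_B[, col]
    null <- if (metric == "nodal_efficiency") eng$null_nodal_efficiency
            else eng$null_degree
  }
  d <- oA - oB
  p <- vapply(seq_along(nodes), function(i) .perm_p(d[i], null[, i]),
              numeric(1))
  out <- tibble::tibble(node = nodes,
                        auc_A = if (run$flipped) oB else oA,
                        auc_B = if (run$flipped) oA else oB,
                        diff = sign_flip * d, p = p,
                        q = fdr_adjust(p, config$fdr_method))
  attr(out, "groups") <- groups
  attr(out, "metric") <- metric
  out
}
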