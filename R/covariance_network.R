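#' Group-level structural covariance network
#'
#' Correlates every pair of node volumes across the subjects of one group,
#' yielding the symmetric `R` matrix; negative correlations are set to zero
#' (`R_plus`), following the convention that negative structural covariance
#' is not interpretable as connectivity.  Optionally the volumes are first
#' residualized on covariates.
#'
#' @param cohort Cohort tibble.
#' @param nodes Character vector of node columns (default: the 17-node set).
#' @param group Optional group label to subset on; `NULL` uses all rows.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @param residualize If `TRUE`, each node is residualized on `covariates`
#'   before correlating.
#' @param covariates Covariate columns used when `residualize = TRUE`.
#' @return An `"scn_network"` object: list with `group`, `nodes`, `R`,
#'   `R_plus`, `n_subjects`, `method`, `residualized`.
#' @export
covariance_matrix <- function(cohort, nodes = default_node_set(),
                              group = NULL,
                              method = c("pearson", "spearman"),
                              residualize = FALSE,
                              covariates = c("sex", "age", "education", "tiv")) {
  method <- match.arg(method)
  validate_node_set(nodes)
  if (!is.null(group)) {
    cohort <- cohort[as.character(cohort$group) %in% group, , drop = FALSE]
  }
  absent <- setdiff(nodes, names(cohort))
  if (length(absent)) {
    stop("cohort is missing node column(s): ", paste(absent, collapse = ", "))
  }
  n <- nrow(cohort)
  if (n < 4) stop("at least 4 subjects are required to correlate volumes")
  V <- as.matrix(cohort[, nodes])
  const <- nodes[apply(V, 2, stats::sd) == 0]
  if (length(const)) {
    stop("constant volume column(s): ", paste(const, collapse = ", "))
  }
  if (isTRUE(residualize)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(cohort[, covariates]))
    V <- apply(V, 2, function(v) stats::resid(stats::lm.fit(mm, v)))
  }
  R <- stats::cor(V, method = method)
  R_plus <- pmax(R, 0)
  diag(R_plus) <- 1
  structure(list(group = if (is.null(group)) "all" else paste(group, collapse = "+"),
                 nodes = nodes, R = R, R_plus = R_plus, n_subjects = n,
                 method = method, residualized = isTRUE(residualize)),
            class = "scn_network")
}

#' @export
print.scn_network <- function(x, ...) {
  cat("Structural covariance network: group ", x$group, " (n = ",
      x$n_subjects, ", ", length(x$nodes), " nodes, ", x$method,
      if (x$residualized) ", residualized" else "", ")\n", sep = "")
  off <- x$R[upper.tri(x$R)]
  cat("  correlations: median ", signif(stats::median(off), 3),
      ", negative ", sum(off < 0), "/", length(off), "\n", sep = "")
  invisible(x)
}

.as_weight_matrix <- function(network) {
  if (inherits(network, "scn_network")) network$R_plus
  else as.matrix(network)
}

#' Sparsity grid
#'
#' Inclusive arithmetic grid of sparsity fractions with exact decimal
#' handling (the defaults give exactly 33 values 0.18, 0.19, ..., 0.50).
#'
#' @param min,max,step Grid bounds and increment; `step` must divide
#'   `max - min` to within 1e-8.  A single-point grid (`min == max`) is
#'   allowed.
#' @return Numeric vector of sparsity fractions.
#' @export
sparsity_grid <- function(min = 0.18, max = 0.50, step = 0.01) {
  if (min > max) stop("require min <= max")
  if (min == max) return(min)
  if (step <= 0) stop("step must be positive")
  n <- (max - min) / step
  if (abs(n - round(n)) > 1e-8) {
    stop("step does not divide the sparsity range: (", max, " - ", min,
         ") / ", step, " is not an integer")
  }
  round(min + step * seq(0, round(n)), 10)
}

.edge_order <- function(W) {
  p <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  # enumeration in lexicographic (i, j) order
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  w <- W[ut]
  # stable sort: weight descending, ties by (i, j)
  ord <- order(-w)
  list(pairs = ut[ord, , drop = FALSE], weights = w[ord])
}

#' Binarize a covariance network at a sparsity level
#'
#' Retains the `k = floor(sparsity * N(N-1)/2)` strongest positive edges of
#' `R_plus`, with ties at the cutoff broken by the fixed lexicographic
#' node-pair order.  Zero-weight (or negative, already zeroed) edges are
#' never retained even if `k` demands them; the achieved edge count is
#' recorded in the `"achieved_edges"` attribute and a warning is emitted
#' when it falls short.
#'
#' @param network `"scn_network"` or a non-negative weight matrix.
#' @param sparsity Fraction of possible edges to retain, in (0, 1].
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and attributes
#'   `"requested_edges"` / `"achieved_edges"`.
#' @export
binarize_at_sparsity <- function(network, sparsity) {
  if (!(sparsity > 0 && sparsity <= 1)) stop("sparsity must lie in (0, 1]")
  W <- .as_weight_matrix(network)
  p <- nrow(W)
  M <- p * (p - 1) / 2
  k <- floor(sparsity * M + 1e-9)
  eo <- .edge_order(W)
  pos <- eo$weights > 0
  k_eff <- min(k, sum(pos))
  adj <- matrix(0, p, p, dimnames = dimnames(W))
  if (k_eff > 0) {
    sel <- eo$pairs[seq_len(k_eff), , drop = FALSE]
    adj[sel] <- 1
    adj[sel[, c(2, 1), drop = FALSE]] <- 1
  }
  if (k_eff < k) {
    warning("only ", k_eff, " positive edges available at sparsity ",
            sparsity, " (requested ", k, ")")
  }
  attr(adj, "requested_edges") <- k
  attr(adj, "achieved_edges") <- k_eff
  adj
}

#' Strongest fraction of network edges
#'
#' Edge list of the top `fraction` of possible connections by weight (for
#' example the 25% strongest connections for visualization), sorted by
#' descending weight.
#'
#' @param network `"scn_network"` or weight matrix.
#' @param fraction Fraction of possible edges, in (0, 1].
#' @return Tibble with `node_i`, `node_j`, `weight`.
#' @export
strongest_fraction_edges <- function(network, fraction = 0.25) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must lie in (0, 1]")
  W <- .as_weight_matrix(network)
  p <- nrow(W)
  M <- p * (p - 1) / 2
  k <- floor(fraction * M + 1e-9)
  eo <- .edge_order(W)
  keep <- seq_len(min(k, sum(eo$weights > 0)))
  nm <- rownames(W) %||% as.character(seq_len(p))
  tibble::tibble(node_i = nm[eo$pairs[keep, 1]],
                 node_j = nm[eo$pairs[keep, 2]],
                 weight = eo$weights[keep])
}

#' Export an adjacency or weight matrix as an edge list
#'
#' @param mat Symmetric matrix (weights or 0/1).
#' @param keep_zero Keep zero entries? Default drops them.
#' @return Tibble with `node_i`, `node_j`, `weight` over the upper triangle.
#' @export
matrix_edge_list <- function(mat, keep_zero = FALSE) {
  mat <- as.matrix(mat)
  nm <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  w <- mat[ut]
  keep <- if (keep_zero) rep(TRUE, length(w)) else w != 0
  tibble::tibble(node_i = nm[ut[keep, 1]], node_j = nm[ut[keep, 2]],
                 weight = w[keep])
}
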