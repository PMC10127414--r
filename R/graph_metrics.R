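# User-facing graph metrics on binary undirected adjacency matrices.  The
# computations run in compiled code (see src/); these wrappers validate the
# input and attach names.

.check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  if (any(is.na(adj))) stop("adjacency matrix must not contain NA")
  if (!all(adj %in% c(0, 1))) stop("adjacency matrix must be binary (0/1)")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency matrix must be symmetric")
  adj
}

.node_names <- function(adj) rownames(adj) %||% as.character(seq_len(nrow(adj)))

#' Clustering coefficient
#'
#' Per-node clustering coefficient (edges among neighbours divided by
#' d(d-1)/2; zero for degree < 2) and, by default, its unweighted mean over
#' all nodes (Cp).
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @param per_node Return the per-node vector instead of the mean.
#' @return Scalar Cp, or a named per-node vector.
#' @export
clustering_coefficient <- function(adj, per_node = FALSE) {
  adj <- .check_adjacency(adj)
  v <- cpp_clustering(adj)
  if (per_node) stats::setNames(v, .node_names(adj)) else mean(v)
}

#' Characteristic path length
#'
#' Mean breadth-first shortest-path length over all pairs of distinct nodes
#' with a finite distance.  The number of unreachable (unordered) pairs is
#' returned in the `"unreachable_pairs"` attribute; an empty graph (no
#' finite pair) is an error.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar Lp with attribute `"unreachable_pairs"`.
#' @export
characteristic_path_length <- function(adj) {
  adj <- .check_adjacency(adj)
  ps <- cpp_path_stats(adj)
  if (ps$finite_pairs == 0) {
    stop("no finite node pair: the graph has no edges")
  }
  structure(ps$lp, unreachable_pairs = as.integer(ps$unreachable_pairs))
}

#' Global efficiency
#'
#' Mean of 1/d(i,j) over all distinct node pairs, with 1/Inf = 0 for
#' unreachable pairs (so the empty graph has efficiency 0).
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(adj) {
  adj <- .check_adjacency(adj)
  cpp_path_stats(adj)$eglobal
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbours (zero for fewer than two neighbours); Elocal is the mean over
#' all nodes.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar Elocal, or a named per-node vector.
#' @export
local_efficiency <- function(adj, per_node = FALSE) {
  adj <- .check_adjacency(adj)
  v <- cpp_local_efficiency(adj)
  if (per_node) stats::setNames(v, .node_names(adj)) else mean(v)
}

#' Nodal efficiency
#'
#' For node i, the mean of 1/d(i,j) over all other nodes j (1/Inf = 0).
#'
#' @inheritParams clustering_coefficient
#' @return Named per-node vector in \[0, 1\].
#' @export
nodal_efficiency <- function(adj) {
  adj <- .check_adjacency(adj)
  stats::setNames(cpp_path_stats(adj)$nodal_efficiency, .node_names(adj))
}

#' Betweenness centrality
#'
#' Fraction of all shortest paths passing through each node: the Brandes
#' accumulation of sigma_st(v)/sigma_st over source-target pairs, normalized
#' by (N-1)(N-2)/2 for undirected graphs.
#'
#' @inheritParams clustering_coefficient
#' @return Named per-node vector in \[0, 1\].
#' @export
betweenness_centrality <- function(adj) {
  adj <- .check_adjacency(adj)
  stats::setNames(cpp_betweenness(adj), .node_names(adj))
}

#' Node degree
#'
#' @inheritParams clustering_coefficient
#' @return Named integer vector of row sums.
#' @export
node_degree <- function(adj) {
  adj <- .check_adjacency(adj)
  stats::setNames(as.integer(rowSums(adj)), .node_names(adj))
}

#' Degree-preserving rewiring (Maslov-Sneppen double-edge swaps)
#'
#' Randomizes a graph while exactly preserving its degree sequence by
#' repeated double-edge swaps.  The budget is `n_swap_multiplier` successful
#' swaps per edge; if the attempt cap (`attempt_multiplier` times the swap
#' budget) is exhausted first — e.g. for a complete graph, which admits no
#' legal swap — the graph is returned as-is with a warning and the achieved
#' count in the `"achieved_swaps"` attribute.
#'
#' @inheritParams clustering_coefficient
#' @param n_swap_multiplier Successful-swap budget per edge (default 10).
#' @param attempt_multiplier Attempt cap as a multiple of the swap budget.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return Rewired adjacency matrix with attributes `"achieved_swaps"` and
#'   `"target_swaps"`.
#' @export
rewire_preserving_degree <- function(adj, n_swap_multiplier = 10,
                                     attempt_multiplier = 100, seed = NULL) {
  adj <- .check_adjacency(adj)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_rewire(adj, n_swap_multiplier, attempt_multiplier)
  out <- res$adjacency
  dimnames(out) <- dimnames(adj)
  if (res$achieved_swaps < res$target_swaps) {
    warning("rewiring achieved ", res$achieved_swaps, " of ",
            res$target_swaps, " swaps before the attempt cap")
  }
  attr(out, "achieved_swaps") <- res$achieved_swaps
  attr(out, "target_swaps") <- res$target_swaps
  out
}

#' Small-world normalization: Gamma, Lambda, Sigma
#'
#' Normalizes Cp and Lp by their means over an ensemble of `n_random`
#' degree-preserving random networks: `Gamma = Cp / mean(Cp_random)`,
#' `Lambda = Lp / mean(Lp_random)`, `Sigma = Gamma / Lambda`.  The ensemble
#' is generated as a single edge-swap Markov chain seeded from the current
#' RNG state: `swap_mult * E` successful swaps of burn-in before the first
#' member, then `swap_mult * E / 10` further swaps between members, so each
#' member is marginally a fully rewired network.
#'
#' @inheritParams rewire_preserving_degree
#' @param n_random Ensemble size (default 100).
#' @param swap_mult Burn-in swap budget per edge (default 10; 0 keeps the
#'   graph unchanged, so the triple degenerates to 1).
#' @return List with `gamma`, `lambda`, `sigma`, `cp`, `lp`,
#'   `mean_cp_random`, `mean_lp_random`.
#' @export
normalized_metrics <- function(adj, n_random = 100, swap_mult = 10,
                               attempt_multiplier = 100, seed = NULL) {
  adj <- .check_adjacency(adj)
  if (n_random < 1) stop("n_random must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_normalized_metrics(adj, as.integer(n_random), swap_mult,
                                attempt_multiplier)
  if (!is.finite(res$mean_cp_random) || res$mean_cp_random == 0) {
    stop("mean clustering of the random ensemble is zero; Gamma is undefined")
  }
  if (!is.finite(res$mean_lp_random) || res$mean_lp_random == 0) {
    stop("mean path length of the random ensemble is zero; Lambda is undefined")
  }
  res
}

#' All global metrics of a binary graph
#'
#' @inheritParams normalized_metrics
#' @return List with `Cp`, `Lp`, `Eglobal`, `Elocal`, `Gamma`, `Lambda`,
#'   `Sigma`, `unreachable_pair_count`.
#' @export
global_metrics <- function(adj, n_random = 100, swap_mult = 10, seed = NULL) {
  adj <- .check_adjacency(adj)
  if (!is.null(seed)) set.seed(seed)
  ps <- cpp_path_stats(adj)
  nm <- normalized_metrics(adj, n_random = n_random, swap_mult = swap_mult)
  list(Cp = mean(cpp_clustering(adj)),
       Lp = ps$lp,
       Eglobal = ps$eglobal,
       Elocal = mean(cpp_local_efficiency(adj)),
       Gamma = nm$gamma, Lambda = nm$lambda, Sigma = nm$sigma,
       unreachable_pair_count = as.integer(ps$unreachable_pairs))
}
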