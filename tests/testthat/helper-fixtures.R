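# Cohort fixtures built in code.

# minimal cohort carrying only group labels and node volumes, for network
# and permutation tests that do not need the clinical columns
volume_cohort <- function(..., nodes = default_node_set()) {
  groups <- list(...)
  stopifnot(!is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    V <- groups[[g]]
    colnames(V) <- nodes
    dplyr::bind_cols(tibble::tibble(group = g), tibble::as_tibble(V))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%04d", seq_len(nrow(out)))),
                   out)
}

# multivariate normal volumes with exchangeable correlation rho
mvn_volumes <- function(n, p = 17, rho = 0.4, mean = 100, sd = 10) {
  Sig <- matrix(rho, p, p)
  diag(Sig) <- 1
  MASS::mvrnorm(n, rep(mean, p), Sig * sd^2)
}

# two-group spec over the standard four-group defaults, restricted to the
# SCD subgroups, with optional null equalization.  `nodes_only` restricts
# the ROI set to the 17 network nodes (faster generation for calibration
# loops); `ring_decay` additionally uses the structured distance-decay base
# correlation that makes covariance-strength differences visible to
# thresholded network topology.
two_group_spec <- function(nG = 40, nB = 40, strength = c(1, 1),
                           null_groups = TRUE, seed = NULL, followup = FALSE,
                           conversion = c(0, 0), nodes_only = FALSE,
                           ring_decay = FALSE) {
  groups <- c("G-SCD", "B-SCD")
  fu <- list(prob = c("G-SCD" = as.numeric(followup),
                      "B-SCD" = as.numeric(followup)),
             interval = matrix(c(536, 163.5, 539, 168.6), 2, 2, byrow = TRUE,
                               dimnames = list(groups, c("mean", "sd"))))
  extra <- list()
  if (nodes_only || ring_decay) {
    nodes <- default_node_set()
    extra$roi_means <- scnet:::scn_roi_means[groups, nodes]
    extra$roi_sds <- scnet:::scn_roi_sds[groups, nodes]
    if (ring_decay) extra$base_correlation <- ring_decay_correlation(nodes)
  }
  do.call(cohort_spec,
          c(list(group_sizes = stats::setNames(c(nG, nB), groups),
                 covariance_strength = stats::setNames(strength, groups),
                 followup_params = fu,
                 conversion_probs = stats::setNames(conversion, groups),
                 null_groups = null_groups, seed = seed),
            extra))
}
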