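#' Scale the off-diagonal entries of a correlation matrix
#'
#' Multiplies every off-diagonal entry by `factor` (clipping to \[-1, 1\]) and
#' leaves the unit diagonal untouched.  Used to induce group differences in
#' covariance strength while preserving the correlation structure's shape.
#'
#' @param correlation Symmetric correlation matrix with unit diagonal.
#' @param factor Non-negative scalar multiplier.
#' @return The rescaled correlation matrix.  An error is raised if the result
#'   is not positive semidefinite.
#' @examples
#' r <- matrix(0.6, 3, 3); diag(r) <- 1
#' scale_offdiagonal(r, 0.5)
#' @export
scale_offdiagonal <- function(correlation, factor) {
  stopifnot(is.matrix(correlation), nrow(correlation) == ncol(correlation))
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10))) {
    stop("correlation matrix must be symmetric")
  }
  if (any(abs(diag(correlation) - 1) > 1e-10)) {
    stop("correlation matrix must have a unit diagonal")
  }
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor < 0) {
    stop("factor must be a single non-negative number")
  }
  out <- correlation * factor
  out <- pmin(pmax(out, -1), 1)
  diag(out) <- 1
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("rescaled correlation matrix is not positive semidefinite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")")
  }
  out
}

#' Ring distance-decay correlation matrix
#'
#' Builds a structured correlation matrix in which the correlation between
#' two nodes decays linearly with their distance on a ring:
#' `r_ij = near - decay * d(i, j)` with `d` the circular distance.  Uniformly
#' rescaling an *exchangeable* correlation leaves the ranking of sample
#' correlations — and therefore every sparsity-thresholded network —
#' unchanged in distribution; a structured pattern like this one is what
#' makes group differences in covariance strength visible to network
#' topology, so it is the natural base for power studies of the permutation
#' test.
#'
#' @param nodes Node names (length defines the ring size).
#' @param near Correlation of adjacent nodes (before scaling).
#' @param decay Decrease in correlation per step of ring distance.
#' @return Symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @export
ring_decay_correlation <- function(nodes = default_node_set(), near = 0.66,
                                   decay = 0.052) {
  p <- length(nodes)
  idx <- seq_len(p)
  d <- outer(idx, idx, function(i, j) pmin(abs(i - j), p - abs(i - j)))
  R <- near - decay * d
  diag(R) <- 1
  dimnames(R) <- list(nodes, nodes)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("near/decay combination is not positive semidefinite")
  }
  R
}

.default_base_correlation <- function(rois = scn_all_rois,
                                      nodes = default_node_set(),
                                      r_node = 0.4, r_other = 0.2) {
  p <- length(rois)
  R <- matrix(r_other, p, p, dimnames = list(rois, rois))
  idx <- match(nodes, rois)
  idx <- idx[!is.na(idx)]
  R[idx, idx] <- r_node
  diag(R) <- 1
  R
}

#' Specification of a synthetic cohort
#'
#' Bundles every parameter of the synthetic cohort generator: group sizes,
#' per-group ROI volume means and SDs, the inter-ROI correlation matrix and a
#' per-group multiplier on its off-diagonal, demographic and cognitive
#' parameters, navigation distance-error parameters, and follow-up conversion
#' probabilities.  Defaults reproduce the group-level summary statistics of
#' the reference cohort (77 controls, 40/40 navigation-split subjective
#' cognitive decline subjects, 23 MCI patients).
#'
#' @param group_sizes Named integer vector of subjects per group.  Names must
#'   be a subset of `c("NC", "G-SCD", "B-SCD", "MCI")` unless all parameter
#'   tables are supplied explicitly.
#' @param roi_means,roi_sds Numeric group-by-ROI matrices (mm^3).
#' @param base_correlation Symmetric positive-semidefinite correlation matrix
#'   over the ROIs (unit diagonal).  Default: exchangeable 0.4 among the 17
#'   network nodes, 0.2 elsewhere.
#' @param covariance_strength Named per-group scalar multiplier applied to the
#'   off-diagonal of `base_correlation` (via [scale_offdiagonal()]).
#' @param covariate_params,navigation_params,cognitive_params,followup_params
#'   Optional overrides of the reference demographic, navigation, cognitive
#'   and follow-up parameter lists; see `scnet:::scn_covariate_reference` and
#'   friends for the expected shapes.
#' @param conversion_probs Named per-group probability of conversion to MCI
#'   among subjects with follow-up.
#' @param null_groups If `TRUE`, every per-group parameter (ROI means/SDs,
#'   covariates, navigation, cognition) is replaced by the first group's
#'   values so that, at equal `covariance_strength`, group labels are
#'   exchangeable — a null configuration for calibration studies.
#' @param seed Optional integer seed making [generate_cohort()] fully
#'   reproducible.
#' @return An object of class `"cohort_spec"`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(group_sizes = scn_group_sizes,
                        roi_means = NULL, roi_sds = NULL,
                        base_correlation = NULL,
                        covariance_strength = NULL,
                        covariate_params = NULL,
                        navigation_params = NULL,
                        cognitive_params = NULL,
                        followup_params = NULL,
                        conversion_probs = NULL,
                        null_groups = FALSE,
                        seed = NULL) {
  if (is.null(names(group_sizes))) {
    stop("group_sizes must be a named vector")
  }
  groups <- names(group_sizes)

  pick_rows <- function(m) {
    missing_g <- setdiff(groups, rownames(m))
    if (length(missing_g)) {
      stop("no default parameters for group(s) ",
           paste(missing_g, collapse = ", "),
           "; supply explicit parameter tables")
    }
    m[groups, , drop = FALSE]
  }
  pick <- function(v) {
    missing_g <- setdiff(groups, names(v))
    if (length(missing_g)) {
      stop("no default parameters for group(s) ",
           paste(missing_g, collapse = ", "))
    }
    v[groups]
  }

  if (is.null(roi_means)) roi_means <- pick_rows(scn_roi_means)
  if (is.null(roi_sds)) roi_sds <- pick_rows(scn_roi_sds)
  if (is.null(base_correlation)) {
    base_correlation <- .default_base_correlation(colnames(roi_means))
  }
  if (is.null(covariance_strength)) {
    covariance_strength <- stats::setNames(rep(1, length(groups)), groups)
  }
  if (is.null(covariate_params)) {
    covariate_params <- list(
      age = pick_rows(scn_covariate_reference$age),
      education = pick_rows(scn_covariate_reference$education),
      tiv = pick_rows(scn_covariate_reference$tiv),
      sex_male = pick(scn_covariate_reference$sex_male),
      scanner_tx = pick(scn_covariate_reference$scanner_tx),
      scdq = pick_rows(scn_covariate_reference$scdq),
      mmse = pick_rows(scn_covariate_reference$mmse))
  }
  if (is.null(navigation_params)) {
    navigation_params <- list(
      error = pick_rows(scn_navigation_reference$error),
      trial_sd = scn_navigation_reference$trial_sd,
      n_trials = scn_navigation_reference$n_trials)
  }
  if (is.null(cognitive_params)) {
    cognitive_params <- list(
      domains = lapply(scn_domain_reference, pick_rows),
      tests = scn_test_reference)
  }
  if (is.null(followup_params)) {
    followup_params <- list(
      prob = pick(scn_followup_reference$prob),
      interval = pick_rows(scn_followup_reference$interval))
  }
  if (is.null(conversion_probs)) {
    conversion_probs <- pick(scn_followup_reference$conversion)
  }

  if (isTRUE(null_groups)) {
    ref <- groups[1]
    eq_rows <- function(m) {
      m[] <- rep(m[ref, ], each = nrow(m))
      m
    }
    roi_means <- eq_rows(roi_means)
    roi_sds <- eq_rows(roi_sds)
    for (nm in c("age", "education", "tiv", "scdq", "mmse")) {
      covariate_params[[nm]] <- eq_rows(covariate_params[[nm]])
    }
    covariate_params$sex_male[] <- covariate_params$sex_male[[ref]]
    covariate_params$scanner_tx[] <- covariate_params$scanner_tx[[ref]]
    navigation_params$error <- eq_rows(navigation_params$error)
    cognitive_params$domains <- lapply(cognitive_params$domains, eq_rows)
  }

  spec <- structure(list(
    group_sizes = group_sizes,
    groups = groups,
    roi_means = roi_means,
    roi_sds = roi_sds,
    base_correlation = base_correlation,
    covariance_strength = covariance_strength,
    covariate_params = covariate_params,
    navigation_params = navigation_params,
    cognitive_params = cognitive_params,
    followup_params = followup_params,
    conversion_probs = conversion_probs,
    seed = seed), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the structural invariants of a [cohort_spec()]: group sizes of at
#' least 2, strictly positive ROI SDs, a symmetric positive-semidefinite base
#' correlation with unit diagonal (also after per-group off-diagonal
#' scaling), and conversion probabilities inside \[0, 1\].
#'
#' @param spec A `"cohort_spec"` object.
#' @return `spec`, invisibly; errors name the offending component.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$group_sizes < 2)) {
    stop("every group must have at least 2 subjects")
  }
  if (any(spec$roi_sds <= 0)) {
    stop("roi_sds must be strictly positive")
  }
  if (!identical(dim(spec$roi_means), dim(spec$roi_sds))) {
    stop("roi_means and roi_sds must have identical dimensions")
  }
  R <- spec$base_correlation
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10))) {
    stop("base_correlation must be symmetric")
  }
  if (any(abs(diag(R) - 1) > 1e-10)) {
    stop("base_correlation must have a unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("base_correlation is not positive semidefinite")
  }
  for (g in spec$groups) {
    Rg <- spec$base_correlation * spec$covariance_strength[[g]]
    diag(Rg) <- 1
    evg <- eigen(Rg, symmetric = TRUE, only.values = TRUE)$values
    if (min(evg) < -1e-8) {
      stop("scaled correlation for group '", g,
           "' is not positive semidefinite")
    }
  }
  if (any(spec$conversion_probs < 0 | spec$conversion_probs > 1)) {
    stop("conversion_probs must lie in [0, 1]")
  }
  if (any(spec$followup_params$prob < 0 | spec$followup_params$prob > 1)) {
    stop("follow-up probabilities must lie in [0, 1]")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  groups: ",
      paste(sprintf("%s (n=%d)", x$groups, x$group_sizes), collapse = ", "),
      "\n", sep = "")
  cat("  ROIs: ", ncol(x$roi_means), "\n", sep = "")
  cat("  covariance strength: ",
      paste(sprintf("%s=%.2f", x$groups, x$covariance_strength),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$seed)) cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
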