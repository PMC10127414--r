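#' Generate a synthetic cohort
#'
#' Draws a subject-level table with the statistical structure the downstream
#' analyses assume: per-group ROI volumes from a multivariate normal with the
#' group's mean/SD vectors and (off-diagonal-scaled) correlation matrix,
#' demographic covariates, per-trial navigation distance errors (a latent
#' subject-level error plus trial noise), raw cognitive test scores driven by
#' latent domain levels, and Bernoulli follow-up conversion outcomes.
#'
#' Volumes must be positive: subjects with any non-positive sampled volume
#' are redrawn, up to 100 attempts each (the defaults place all means at
#' least 5 SDs above zero, so truncation bias is negligible).
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A tibble with one row per subject: `subject_id`, `group`, the
#'   covariates (`age`, `sex`, `education`, `tiv`, `scanner`), `scdq`,
#'   `mmse`, raw cognitive test scores, 8 egocentric and 8 allocentric
#'   navigation trial errors, one volume column per ROI (canonical names),
#'   and `followup_outcome` / `followup_days` (NA when no follow-up).
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 1))
#' table(cohort$group)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  if (!is.null(seed)) set.seed(seed)

  rois <- colnames(spec$roi_means)
  tests <- spec$cognitive_params$tests
  nav <- spec$navigation_params
  n_trials <- nav$n_trials

  per_group <- lapply(spec$groups, function(g) {
    n <- spec$group_sizes[[g]]
    cp <- spec$covariate_params

    # ROI volumes: multivariate normal on the raw mm^3 scale
    Rg <- scale_offdiagonal(spec$base_correlation,
                            spec$covariance_strength[[g]])
    sds <- spec$roi_sds[g, ]
    Sigma <- Rg * tcrossprod(sds)
    mu <- spec$roi_means[g, ]
    vols <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
    if (n == 1) vols <- matrix(vols, nrow = 1)
    for (attempt in seq_len(100)) {
      bad <- which(apply(vols, 1, function(r) any(r <= 0)))
      if (!length(bad)) break
      vols[bad, ] <- MASS::mvrnorm(length(bad), mu = mu, Sigma = Sigma)
    }
    if (any(vols <= 0)) {
      stop("failed to draw positive volumes for group '", g,
           "' within 100 attempts; check roi_means/roi_sds")
    }
    colnames(vols) <- rois

    # demographics
    age <- stats::rnorm(n, cp$age[g, "mean"], cp$age[g, "sd"])
    education <- stats::rnorm(n, cp$education[g, "mean"], cp$education[g, "sd"])
    tiv <- stats::rnorm(n, cp$tiv[g, "mean"], cp$tiv[g, "sd"])
    sex <- ifelse(stats::runif(n) < cp$sex_male[[g]], "M", "F")
    scanner <- ifelse(stats::runif(n) < cp$scanner_tx[[g]], "TX", "CX")
    scdq <- stats::rnorm(n, cp$scdq[g, "mean"], cp$scdq[g, "sd"])
    mmse <- pmin(stats::rnorm(n, cp$mmse[g, "mean"], cp$mmse[g, "sd"]), 30)

    # navigation: latent subject error level + trial noise, 8 trials per
    # subtask
    latent_nav <- stats::rnorm(n, nav$error[g, "mean"], nav$error[g, "sd"])
    trial_mat <- matrix(
      stats::rnorm(n * 2 * n_trials, mean = latent_nav, sd = nav$trial_sd),
      nrow = n)
    colnames(trial_mat) <- c(paste0("ego_trial_", seq_len(n_trials)),
                             paste0("allo_trial_", seq_len(n_trials)))

    # cognitive tests: latent domain level -> raw scores on each test scale
    domain_latent <- lapply(spec$cognitive_params$domains, function(m) {
      stats::rnorm(n, m[g, "mean"], m[g, "sd"])
    })
    test_mat <- sapply(seq_len(nrow(tests)), function(k) {
      d <- domain_latent[[tests$domain[k]]]
      tests$base[k] + tests$slope[k] * d + stats::rnorm(n, 0, tests$resid[k])
    })
    if (n == 1) test_mat <- matrix(test_mat, nrow = 1)
    colnames(test_mat) <- tests$test

    # follow-up
    has_fu <- stats::runif(n) < spec$followup_params$prob[[g]]
    converted <- has_fu & (stats::runif(n) < spec$conversion_probs[[g]])
    outcome <- ifelse(has_fu,
                      ifelse(converted, "converter", "nonconverter"),
                      NA_character_)
    days <- ifelse(has_fu,
                   as.integer(round(stats::rnorm(
                     n, spec$followup_params$interval[g, "mean"],
                     spec$followup_params$interval[g, "sd"]))),
                   NA_integer_)

    out <- tibble::tibble(
      group = g, age = age, sex = sex, education = education, tiv = tiv,
      scanner = scanner, scdq = scdq, mmse = mmse)
    out <- dplyr::bind_cols(out, tibble::as_tibble(test_mat),
                            tibble::as_tibble(trial_mat),
                            tibble::as_tibble(vols))
    out$followup_outcome <- outcome
    out$followup_days <- days
    out
  })

  cohort <- dplyr::bind_rows(per_group)
  cohort <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(nrow(cohort)))),
    cohort)
  cohort$group <- factor(cohort$group, levels = spec$groups)
  cohort
}
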