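.mean_sd <- function(x) {
  sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
}

.posthoc_codes <- c("NC vs G-SCD" = "a", "NC vs B-SCD" = "b",
                    "NC vs MCI" = "c", "G-SCD vs B-SCD" = "d",
                    "G-SCD vs MCI" = "e", "B-SCD vs MCI" = "f")

.posthoc_string <- function(lsd, alpha) {
  sig <- lsd$contrast[lsd$p < alpha]
  if (!length(sig)) return("")
  sig <- gsub(" - ", " vs ", sig)
  sig <- gsub("[()]", "", sig)
  codes <- .posthoc_codes[sig]
  if (anyNA(codes)) paste(sig, collapse = "; ")
  else paste(sort(codes), collapse = "")
}

#' Follow-up comparison between two groups
#'
#' Builds the conversion contingency table of subjects with follow-up and
#' compares the two groups: Fisher's exact test on outcome
#' (converter/nonconverter) and on sex, pooled-variance t tests on age,
#' education and follow-up interval.
#'
#' @param cohort Cohort tibble with `followup_outcome` / `followup_days`.
#' @param groups Two group labels (default `"G-SCD"` vs `"B-SCD"`).
#' @param alpha Significance level used for flagging.
#' @return Tibble with one row per variable: group summaries, statistic
#'   (where defined), p-value and test name.  The conversion table itself is
#'   attached as attribute `"contingency"`.
#' @export
compare_followup <- function(cohort, groups = c("G-SCD", "B-SCD"),
                             alpha = 0.05) {
  if (length(groups) != 2) stop("exactly two groups are required")
  if (!"followup_outcome" %in% names(cohort)) {
    stop("cohort has no followup_outcome column")
  }
  fu <- cohort[as.character(cohort$group) %in% groups &
                 !is.na(cohort$followup_outcome), , drop = FALSE]
  gl <- factor(as.character(fu$group), levels = groups)
  if (any(table(gl) == 0)) {
    stop("no follow-up outcomes available for group(s): ",
         paste(groups[table(gl) == 0], collapse = ", "))
  }
  sub1 <- fu[gl == groups[1], ]
  sub2 <- fu[gl == groups[2], ]

  conv <- rbind(converter = c(sum(sub1$followup_outcome == "converter"),
                              sum(sub2$followup_outcome == "converter")),
                nonconverter = c(sum(sub1$followup_outcome == "nonconverter"),
                                 sum(sub2$followup_outcome == "nonconverter")))
  colnames(conv) <- groups
  fisher_outcome <- fisher_exact_two_tailed(t(conv))

  sex_tab <- rbind(M = c(sum(sub1$sex == "M"), sum(sub2$sex == "M")),
                   F = c(sum(sub1$sex == "F"), sum(sub2$sex == "F")))
  fisher_sex <- fisher_exact_two_tailed(t(sex_tab))

  trow <- function(variable, v1, v2) {
    ht <- two_sample_t(v1, v2)
    tibble::tibble(variable = variable, group_A = .mean_sd(v1),
                   group_B = .mean_sd(v2),
                   statistic = unname(ht$statistic), p = ht$p.value,
                   test = "two-sample t")
  }
  out <- dplyr::bind_rows(
    trow("Age", sub1$age, sub2$age),
    tibble::tibble(variable = "Sex (male/female)",
                   group_A = paste0(sex_tab["M", 1], "/", sex_tab["F", 1]),
                   group_B = paste0(sex_tab["M", 2], "/", sex_tab["F", 2]),
                   statistic = NA_real_, p = fisher_sex$p.value,
                   test = "Fisher exact"),
    trow("Education", sub1$education, sub2$education),
    tibble::tibble(variable = "Outcome (converters/nonconverters)",
                   group_A = paste0(conv[1, 1], "/", conv[2, 1]),
                   group_B = paste0(conv[1, 2], "/", conv[2, 2]),
                   statistic = NA_real_, p = fisher_outcome$p.value,
                   test = "Fisher exact"),
    trow("Interval (days)", sub1$followup_days, sub2$followup_days))
  out$significant <- !is.na(out$p) & out$p < alpha
  names(out)[names(out) == "group_A"] <- groups[1]
  names(out)[names(out) == "group_B"] <- groups[2]
  attr(out, "contingency") <- conv
  out
}

.demographics_table <- function(cohort, composites, alpha) {
  groups <- levels(droplevels(factor(cohort$group)))
  g <- factor(as.character(cohort$group), levels = groups)
  num_row <- function(variable, v) {
    ht <- oneway_anova(v, g)
    row <- tibble::as_tibble(as.list(stats::setNames(
      tapply(v, g, .mean_sd), groups)))
    dplyr::bind_cols(tibble::tibble(variable = variable), row,
                     tibble::tibble(statistic = unname(ht$statistic),
                                    p = ht$p.value, test = "one-way ANOVA"))
  }
  count_row <- function(variable, fct, label_levels) {
    tab <- table(factor(fct, levels = label_levels), g)
    ht <- chi_square_test(tab)
    cells <- apply(tab, 2, paste, collapse = "/")
    row <- tibble::as_tibble(as.list(cells))
    dplyr::bind_cols(tibble::tibble(variable = variable), row,
                     tibble::tibble(statistic = unname(ht$statistic),
                                    p = ht$p.value, test = "chi-square"))
  }
  comp <- composites[match(cohort$subject_id, composites$subject_id), ]
  out <- dplyr::bind_rows(
    num_row("Age", cohort$age),
    count_row("Sex (male/female)", cohort$sex, c("M", "F")),
    num_row("Education years", cohort$education),
    count_row("MRI (TX/CX)", cohort$scanner, c("TX", "CX")),
    if ("scdq" %in% names(cohort)) num_row("SCD-Q", cohort$scdq),
    if ("mmse" %in% names(cohort)) num_row("MMSE", cohort$mmse),
    num_row("Memory function", comp$memory),
    num_row("Language function", comp$language),
    num_row("Executive function", comp$executive),
    if ("navigation" %in% names(comp))
      num_row("Navigation distance errors", comp$navigation),
    num_row("TIV", cohort$tiv))
  out$significant <- out$p < alpha
  out
}

.volumetrics_table <- function(cohort, rois, config) {
  groups <- levels(droplevels(factor(cohort$group)))
  g <- factor(as.character(cohort$group), levels = groups)
  covs <- as.data.frame(cohort[, config$covariates])
  rows <- lapply(rois, function(roi) {
    v <- cohort[[roi]]
    anc <- ancova_group_effect(v, g, covs)
    lsd <- lsd_posthoc(anc)
    row <- tibble::as_tibble(as.list(stats::setNames(
      tapply(v, g, .mean_sd), groups)))
    dplyr::bind_cols(
      tibble::tibble(roi = roi), row,
      tibble::tibble(F = unname(anc$statistic), p = anc$p.value,
                     posthoc = .posthoc_string(lsd, config$alpha)))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- fdr_adjust(out$p, config$fdr_method)
  out$significant <- out$q < config$alpha
  out
}

.correlation_table <- function(cohort, nodes, composites, config) {
  covs <- as.data.frame(cohort[, config$covariates])
  comp <- composites[match(cohort$subject_id, composites$subject_id), ]
  domains <- setdiff(names(comp), "subject_id")
  grid <- expand.grid(node = nodes, domain = domains,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    pc <- partial_correlation(cohort[[grid$node[k]]],
                              comp[[grid$domain[k]]], covs)
    tibble::tibble(node = grid$node[k], domain = grid$domain[k],
                   r = unname(pc$statistic), p = pc$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- fdr_adjust(out$p, config$fdr_method)
  out$significant <- out$q < config$alpha
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or ingest) a cohort, compute
#' composite scores, split the SCD subjects by the configured score,
#' produce the demographic/clinical comparison table, the covariate-adjusted
#' volumetric tables for the subcortical nuclei and the basal
#' forebrain/hippocampal subfields, partial-correlation tables, the
#' per-group covariance networks (matrices, edge lists, strongest-25%
#' connections, metric curves and AUCs), permutation inference for every
#' group pair (global metrics plus nodal efficiency with FDR), and the
#' follow-up conversion comparison.  All tables and a JSON run log are
#' written to `out_dir`.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory.
#' @param input Path to a cohort CSV, or a cohort tibble.  When `NULL`, a
#'   cohort is simulated from `spec`.
#' @param spec A [cohort_spec()] used when `input` is `NULL`.
#' @param nodes Node set for the covariance network.
#' @param contrasts List of group pairs for network inference; default every
#'   pair of groups present.
#' @return A run manifest: per-stage status, warnings, result tables and
#'   file paths (invisibly).
#' @export
run_pipeline <- function(config = analysis_config(), out_dir,
                         input = NULL, spec = NULL,
                         nodes = default_node_set(), contrasts = NULL) {
  validate_config(config)
  stages <- list()
  warns <- character()
  results <- list()
  note <- function(stage, w) {
    warns <<- c(warns, paste0("[", stage, "] ", w))
  }
  run_stage <- function(name, fn) {
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        stages[[name]] <<- paste("failed:", conditionMessage(e))
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        note(name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    stages[[name]] <<- "ok"
    res
  }

  cohort <- run_stage("cohort", function() {
    if (is.null(input)) {
      if (is.null(spec)) spec <- cohort_spec(seed = config$seed)
      generate_cohort(spec)
    } else if (is.character(input)) {
      read_cohort(input, nodes = nodes)
    } else {
      validate_cohort(input, nodes = nodes)
    }
  })

  composites <- run_stage("composites", function() composite_zscores(cohort))

  cohort <- run_stage("grouping", function() {
    scdish <- as.character(cohort$group) %in% c("SCD", "G-SCD", "B-SCD")
    if (sum(scdish) >= 2) {
      split_scd_by_score(cohort, score = config$grouping_score)
    } else cohort
  })
  # recompute composites in case grouping reordered nothing but be explicit
  groups_present <- levels(droplevels(factor(cohort$group)))

  results$demographics <- run_stage("demographics", function() {
    .demographics_table(cohort, composites, config$alpha)
  })

  present_rois <- function(rois) intersect(rois, names(cohort))
  if (length(present_rois(scn_subcortical_nuclei))) {
    results$subcortical_volumes <- run_stage("volumetrics_nuclei", function() {
      .volumetrics_table(cohort, present_rois(scn_subcortical_nuclei), config)
    })
  }
  if (length(present_rois(scn_bf_subfields))) {
    results$basal_forebrain_subfields <- run_stage("volumetrics_bf", function() {
      .volumetrics_table(cohort, present_rois(scn_bf_subfields), config)
    })
  }
  if (length(present_rois(scn_hc_subfields))) {
    results$hippocampal_subfields <- run_stage("volumetrics_hc", function() {
      .volumetrics_table(cohort, present_rois(scn_hc_subfields), config)
    })
  }

  results$partial_correlations <- run_stage("correlations", function() {
    .correlation_table(cohort, nodes, composites, config)
  })

  networks <- run_stage("networks", function() {
    lapply(stats::setNames(groups_present, groups_present), function(g) {
      covariance_matrix(cohort, nodes, group = g,
                        residualize = config$residualize_edges,
                        covariates = config$covariates)
    })
  })
  curves <- run_stage("curves", function() {
    lapply(stats::setNames(groups_present, groups_present), function(g) {
      metric_curves(cohort, g, nodes, config)
    })
  })
  results$global_auc <- dplyr::bind_rows(lapply(groups_present, function(g) {
    dplyr::bind_cols(tibble::tibble(group = g),
                     tibble::as_tibble(as.list(curves[[g]]$auc)))
  }))
  for (g in groups_present) {
    tag <- unname(sanitize_names(g))
    results[[paste0("correlation_matrix_", tag)]] <- networks[[g]]$R
    results[[paste0("correlation_matrix_plus_", tag)]] <- networks[[g]]$R_plus
    results[[paste0("edge_list_plus_", tag)]] <-
      matrix_edge_list(networks[[g]]$R_plus)
    results[[paste0("top_edges_", tag)]] <-
      strongest_fraction_edges(networks[[g]], 0.25)
  }

  if (is.null(contrasts)) {
    contrasts <- utils::combn(groups_present, 2, simplify = FALSE)
  }
  perm <- run_stage("inference", function() {
    glob <- list(); nod <- list()
    for (pr in contrasts) {
      key <- paste(pr, collapse = " vs ")
      pt <- permutation_test_auc(cohort, pr, nodes, config)
      pt$contrast <- key
      glob[[key]] <- pt
      np <- nodal_permutation_fdr(cohort, pr, nodes, config,
                                  metric = "nodal_efficiency")
      np$contrast <- key
      nod[[key]] <- np
    }
    list(global = dplyr::bind_rows(glob), nodal = dplyr::bind_rows(nod))
  })
  results$network_permutation_global <- perm$global
  results$network_permutation_nodal <- perm$nodal

  if ("followup_outcome" %in% names(cohort) &&
      all(c("G-SCD", "B-SCD") %in% groups_present) &&
      any(!is.na(cohort$followup_outcome))) {
    results$followup <- run_stage("followup", function() {
      compare_followup(cohort, c("G-SCD", "B-SCD"), alpha = config$alpha)
    })
  }

  manifest <- run_stage("report", function() {
    write_report_tables(results, out_dir, config = config, warnings = warns)
  })
  manifest$stages <- stages
  manifest$results <- results
  manifest$cohort <- cohort
  invisible(manifest)
}
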