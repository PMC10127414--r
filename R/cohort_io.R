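#' Write a cohort table to CSV
#'
#' Writes one row per subject with a header row, UTF-8, full numeric
#' precision (values survive a write/read round trip bit-for-bit).
#'
#' @param cohort Cohort tibble (as returned by [generate_cohort()] or
#'   [read_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a delimited subject table, checks it against the schema, and
#' normalizes column order (identifier and covariates first, then ROI volumes
#' in node-set order, then everything else).  All violations are collected
#' and reported together; the function never silently coerces.
#'
#' Validation rules: required columns present; unique `subject_id`; ROI
#' volume columns numeric, non-missing and strictly positive.  Missing
#' follow-up outcomes are allowed; missing cells in other non-volume columns
#' are recorded in the `"missing_cells"` attribute.
#'
#' @param path CSV file path.
#' @param nodes Character vector of ROI volume columns that must be present
#'   (default: the 17 network nodes).
#' @param required_covariates Additional required columns.
#' @return A validated cohort tibble with attribute `"missing_cells"`.
#' @export
read_cohort <- function(path, nodes = default_node_set(),
                        required_covariates = c("group", "age", "sex",
                                                "education", "tiv")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  # base read.csv parses doubles with correctly-rounded strtod, so the
  # shortest-representation values written by write_cohort round-trip exactly
  cohort <- utils::read.csv(path, check.names = FALSE,
                            na.strings = c("", "NA"),
                            stringsAsFactors = FALSE)
  if ("followup_outcome" %in% names(cohort) &&
      is.logical(cohort$followup_outcome)) {
    cohort$followup_outcome <- as.character(cohort$followup_outcome)
  }
  validate_cohort(cohort, nodes = nodes,
                  required_covariates = required_covariates)
}

#' Validate an in-memory cohort table
#'
#' @inheritParams read_cohort
#' @param cohort Data frame to validate.
#' @return The cohort (as tibble, columns reordered), with missing-cell
#'   bookkeeping in `attr(, "missing_cells")`.
#' @export
validate_cohort <- function(cohort, nodes = default_node_set(),
                            required_covariates = c("group", "age", "sex",
                                                    "education", "tiv")) {
  validate_node_set(nodes)
  cohort <- tibble::as_tibble(cohort)
  problems <- character()

  required <- c("subject_id", required_covariates, nodes)
  absent <- setdiff(required, names(cohort))
  if (length(absent)) {
    problems <- c(problems,
                  paste0("missing required column(s): ",
                         paste(absent, collapse = ", ")))
  }

  if ("subject_id" %in% names(cohort)) {
    dup <- unique(cohort$subject_id[duplicated(cohort$subject_id)])
    if (length(dup)) {
      problems <- c(problems,
                    paste0("duplicate subject id(s): ",
                           paste(dup, collapse = ", ")))
    }
  }

  for (nd in intersect(nodes, names(cohort))) {
    v <- cohort[[nd]]
    if (!is.numeric(v)) {
      problems <- c(problems,
                    paste0("volume column '", nd, "' is not numeric"))
    } else {
      if (anyNA(v)) {
        problems <- c(problems,
                      paste0("volume column '", nd, "' has missing values"))
      }
      if (any(v <= 0, na.rm = TRUE)) {
        problems <- c(problems,
                      paste0("volume column '", nd,
                             "' has non-positive values (volumes must be positive)"))
      }
    }
  }

  if (length(problems)) {
    stop("cohort validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  # normalized column order: id, covariates, volumes (node order), rest
  lead <- c("subject_id", required_covariates)
  rest <- setdiff(names(cohort), c(lead, nodes))
  cohort <- cohort[, c(lead, rest[!rest %in% c("followup_outcome", "followup_days")],
                       nodes,
                       intersect(c("followup_outcome", "followup_days"),
                                 names(cohort)))]

  soft_cols <- setdiff(names(cohort),
                       c(nodes, "followup_outcome", "followup_days"))
  miss <- lapply(soft_cols, function(cl) {
    i <- which(is.na(cohort[[cl]]))
    if (length(i)) tibble::tibble(subject_id = cohort$subject_id[i],
                                  column = cl) else NULL
  })
  attr(cohort, "missing_cells") <- dplyr::bind_rows(miss)
  cohort
}

#' Analysis configuration
#'
#' Central configuration for the network/statistics pipeline: covariates
#' used for adjustment, the sparsity grid, random-network and permutation
#' counts, significance level, FDR method, AUC integration rule and seeds.
#'
#' @param covariates Covariate columns for adjusted analyses.
#' @param sparsity_min,sparsity_max,sparsity_step Sparsity grid: fractions of
#'   retained edges; defaults 0.18–0.50 in steps of 0.01 (33 values).
#' @param n_random Number of degree-preserving random networks used to
#'   normalize Cp and Lp (Gamma/Lambda).
#' @param n_perm Number of label permutations for group inference.
#' @param alpha Two-tailed significance level.
#' @param fdr_method Multiplicity correction passed to [stats::p.adjust()].
#' @param auc AUC integration rule: `"trapezoid"` (default) or `"step_sum"`
#'   (values times grid step, the convention of some network toolboxes).
#' @param swap_mult Successful double-edge-swap budget per random network, as
#'   a multiple of the edge count.
#' @param attempt_mult Attempt cap for rewiring, as a multiple of the swap
#'   budget.
#' @param residualize_edges If `TRUE`, node volumes are residualized on the
#'   covariates before computing covariance-network edges.
#' @param reuse_random_ensembles If `TRUE`, permutation tests reuse the
#'   observed groups' random-network normalization denominators instead of
#'   re-deriving an ensemble for every permutation.
#' @param grouping_score Score used to split SCD subjects:
#'   `"navigation"` (default), `"memory"`, `"language"` or `"executive"`.
#' @param seed Master seed for all stochastic stages.
#' @return A validated list of class `"scn_config"`.
#' @export
analysis_config <- function(covariates = c("sex", "age", "education", "tiv"),
                            sparsity_min = 0.18, sparsity_max = 0.50,
                            sparsity_step = 0.01,
                            n_random = 100L, n_perm = 1000L,
                            alpha = 0.05, fdr_method = "BH",
                            auc = c("trapezoid", "step_sum"),
                            swap_mult = 10, attempt_mult = 100,
                            residualize_edges = FALSE,
                            reuse_random_ensembles = FALSE,
                            grouping_score = c("navigation", "memory",
                                               "language", "executive"),
                            seed = 1L) {
  cfg <- list(
    covariates = covariates,
    sparsity_min = sparsity_min, sparsity_max = sparsity_max,
    sparsity_step = sparsity_step,
    n_random = as.integer(n_random), n_perm = as.integer(n_perm),
    alpha = alpha, fdr_method = fdr_method,
    auc = match.arg(auc),
    swap_mult = swap_mult, attempt_mult = attempt_mult,
    residualize_edges = isTRUE(residualize_edges),
    reuse_random_ensembles = isTRUE(reuse_random_ensembles),
    grouping_score = match.arg(grouping_score),
    seed = as.integer(seed))
  class(cfg) <- "scn_config"
  validate_config(cfg)
  cfg
}

#' @rdname analysis_config
#' @param config An `"scn_config"` object to validate.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "scn_config"))
  with(config, {
    if (!(sparsity_min > 0 && sparsity_min < sparsity_max &&
          sparsity_max <= 1)) {
      stop("require 0 < sparsity_min < sparsity_max <= 1")
    }
    if (sparsity_step <= 0) stop("sparsity_step must be positive")
    if (n_random < 1) stop("n_random must be at least 1")
    if (n_perm < 1) stop("n_perm must be at least 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  })
  # the grid itself must be constructible
  sparsity_grid(config$sparsity_min, config$sparsity_max,
                config$sparsity_step)
  invisible(config)
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns an `"scn_config"`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config An `"scn_config"` object.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write result tables and a machine-readable run log
#'
#' Writes each element of `results` (data frames as delimited tables,
#' matrices as square CSVs with row names) under filesystem-safe names, plus
#' a JSON run log echoing the configuration, seeds, package/R versions and
#' any collected warnings.
#'
#' @param results Named list of data frames / matrices; may be empty.
#' @param out_dir Output directory (created if needed).
#' @param config Optional `"scn_config"` echoed into the log.
#' @param warnings Character vector of warnings to record.
#' @return Manifest list (`files`, `log`, `warnings`), invisibly.
#' @export
write_report_tables <- function(results = list(), out_dir, config = NULL,
                                warnings = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    fn <- file.path(out_dir, paste0(unname(sanitize_names(nm)), ".csv"))
    if (is.matrix(x)) {
      df <- tibble::as_tibble(x, rownames = "name", .name_repair = "minimal")
      readr::write_csv(df, fn, na = "")
    } else {
      readr::write_csv(tibble::as_tibble(x), fn, na = "")
    }
    files <- c(files, fn)
  }
  log <- list(
    package = "scnet",
    version = as.character(utils::packageVersion("scnet")),
    r_version = R.version.string,
    config = if (!is.null(config)) unclass(config) else NULL,
    files = basename(files),
    warnings = warnings)
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  manifest <- list(files = files, log = log_path, warnings = warnings)
  invisible(manifest)
}
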