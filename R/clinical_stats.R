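#' Default mapping of cognitive tests to domains
#'
#' Memory: the five AVLT subscores; executive: TMT-A, TMT-B (completion
#' times, higher is worse), SDMT, CDT; language: AFT, BNT.  Navigation is
#' handled separately from the per-trial distance errors.
#'
#' @return Data frame with columns `test`, `domain`, `higher_is_better`.
#' @export
default_domain_map <- function() {
  scn_test_reference[, c("test", "domain", "higher_is_better")]
}

.nav_trial_columns <- function(cohort) {
  grep("^(ego|allo)_trial_[0-9]+$", names(cohort), value = TRUE)
}

#' Per-subject cognitive composite z-scores
#'
#' Each raw test score is standardized over the reference sample (all
#' subjects in `cohort`; mean 0, SD 1 with the n-1 denominator), sign-flipped
#' where a higher raw score means worse performance, and averaged within its
#' domain.  The navigation composite is the standardized per-subject mean
#' distance error over all egocentric and allocentric trials and is *not*
#' sign-flipped: higher means worse navigation.
#'
#' @param cohort Cohort tibble.
#' @param domain_map Data frame mapping tests to domains (see
#'   [default_domain_map()]).
#' @return Tibble with `subject_id` and one composite column per domain
#'   (including `navigation` when trial columns are present).
#' @export
composite_zscores <- function(cohort, domain_map = default_domain_map()) {
  absent <- setdiff(domain_map$test, names(cohort))
  if (length(absent)) {
    stop("cohort is missing mapped test column(s): ",
         paste(absent, collapse = ", "))
  }
  zscore <- function(v, name) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("test '", name, "' has zero variance; z-scores are undefined")
    }
    (v - mean(v)) / s
  }
  out <- tibble::tibble(subject_id = cohort$subject_id)
  for (dom in unique(domain_map$domain)) {
    rows <- domain_map[domain_map$domain == dom, ]
    zs <- sapply(seq_len(nrow(rows)), function(k) {
      z <- zscore(cohort[[rows$test[k]]], rows$test[k])
      if (rows$higher_is_better[k]) z else -z
    })
    if (is.null(dim(zs))) zs <- matrix(zs, ncol = nrow(rows))
    out[[dom]] <- rowMeans(zs)
  }
  trials <- .nav_trial_columns(cohort)
  if (length(trials)) {
    mean_err <- rowMeans(as.matrix(cohort[, trials]))
    out$navigation <- zscore(mean_err, "navigation distance error")
  }
  out
}

#' Split SCD subjects into good and bad performers
#'
#' Ranks SCD subjects by a performance score and labels the better half
#' `"G-SCD"` and the worse half `"B-SCD"` (symmetric median split).  For the
#' default navigation score, *lower* mean distance error is better; for the
#' cognitive composites (`"memory"`, `"language"`, `"executive"`), higher is
#' better.  Ties spanning the boundary are resolved by stable input order and
#' reported via a warning.  An odd number of SCD subjects requires an
#' explicit `odd` rule.
#'
#' @param cohort Cohort tibble; SCD subjects are rows whose `group` is one of
#'   `scd_labels`.
#' @param score `"navigation"`, `"memory"`, `"language"`, `"executive"`, or a
#'   numeric vector (one value per SCD subject, higher = better).
#' @param scd_labels Group labels identifying SCD subjects.
#' @param odd For an odd SCD count: `"error"` (default), or assign the
#'   middle subject to the `"good"` or `"bad"` half.
#' @return The cohort with `group` relabeled to `"G-SCD"` / `"B-SCD"` for SCD
#'   subjects (factor levels preserved/extended).
#' @export
split_scd_by_score <- function(cohort,
                               score = c("navigation", "memory", "language",
                                         "executive"),
                               scd_labels = c("SCD", "G-SCD", "B-SCD"),
                               odd = c("error", "good", "bad")) {
  odd <- match.arg(odd)
  is_scd <- as.character(cohort$group) %in% scd_labels
  n_scd <- sum(is_scd)
  if (n_scd < 2) stop("fewer than 2 SCD subjects to split")

  if (is.numeric(score)) {
    if (length(score) != n_scd) {
      stop("numeric score must have one value per SCD subject (",
           n_scd, ")")
    }
    goodness <- score
  } else {
    score <- match.arg(score)
    if (score == "navigation") {
      # rank directly on the mean distance error (lower = better); the
      # ranking is identical to the standardized composite's
      trials <- .nav_trial_columns(cohort)
      if (!length(trials)) stop("cohort has no navigation trial columns")
      goodness <- -rowMeans(as.matrix(cohort[is_scd, trials]))
    } else {
      comps <- composite_zscores(cohort[is_scd, , drop = FALSE])
      goodness <- comps[[score]]
    }
  }
  if (anyNA(goodness)) stop("split score contains missing values")

  if (n_scd %% 2 == 1 && odd == "error") {
    stop("odd number of SCD subjects (", n_scd,
         "); set `odd` to 'good' or 'bad' to place the middle subject")
  }
  n_good <- if (n_scd %% 2 == 0) n_scd / 2 else
    (n_scd - 1) / 2 + as.integer(odd == "good")

  # stable rank: order by decreasing goodness, ties by input order
  ord <- order(-goodness)
  good_idx <- ord[seq_len(n_good)]
  boundary_val <- goodness[ord[n_good]]
  if (n_good < n_scd && any(goodness[ord[(n_good + 1):n_scd]] == boundary_val)) {
    tied <- which(goodness == boundary_val)
    warning("tie at the median-split boundary (score ", signif(boundary_val, 6),
            "); resolved by stable input order for subject(s): ",
            paste(cohort$subject_id[is_scd][tied], collapse = ", "))
  }

  labels <- rep("B-SCD", n_scd)
  labels[good_idx] <- "G-SCD"
  new_group <- as.character(cohort$group)
  new_group[is_scd] <- labels
  lev <- unique(c(setdiff(levels(factor(cohort$group)), scd_labels),
                  "G-SCD", "B-SCD"))
  # keep a canonical ordering when the standard labels are in play
  canonical <- c("NC", "G-SCD", "B-SCD", "MCI")
  if (all(unique(new_group) %in% canonical)) lev <- intersect(canonical, unique(new_group))
  cohort$group <- factor(new_group, levels = lev)
  cohort
}

.scn_test <- function(method, statistic, df = NULL, p.value, ...) {
  structure(list(method = method, statistic = statistic, df = df,
                 p.value = p.value, ...),
            class = "scn_test")
}

#' @export
print.scn_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic)) {
    cat("  ", names(x$statistic) %||% "statistic", " = ",
        signif(unname(x$statistic), 5), sep = "")
  }
  if (!is.null(x$df)) cat(", df = ", paste(x$df, collapse = ", "), sep = "")
  cat(", p = ", format.pval(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-way analysis of variance
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @return `"scn_test"` with the F statistic, (k-1, N-k) degrees of freedom,
#'   p-value and group means.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  wvar <- tapply(values, groups, stats::var)
  if (max(wvar) <= .Machine$double.eps * max(1, mean(values)^2)) {
    stop("zero within-group variance; the F statistic is undefined")
  }
  fit <- stats::lm(values ~ groups)
  a <- stats::anova(fit)
  .scn_test("One-way ANOVA",
            statistic = c(F = a[1, "F value"]),
            df = c(a[1, "Df"], a["Residuals", "Df"]),
            p.value = a[1, "Pr(>F)"],
            group_means = tapply(values, groups, mean))
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic without continuity correction, as used for
#' sex-by-group and scanner-by-group contingency tables.
#'
#' @param table Integer matrix of counts (at least 2 x 2).
#' @return `"scn_test"` with the chi-square statistic, df = (r-1)(c-1), and
#'   p-value.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin; expected counts are undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .scn_test("Pearson chi-square test (no continuity correction)",
            statistic = c(`X-squared` = unname(ht$statistic)),
            df = unname(ht$parameter), p.value = ht$p.value,
            expected = ht$expected)
}

#' Fisher's exact test, two-tailed
#'
#' Exact two-tailed p for a 2 x 2 table.  The default rule sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a relative
#' tolerance of 1e-7); `rule = "doubling"` instead doubles the smaller
#' one-sided tail (capped at 1).
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @param rule `"sum_small_p"` (default) or `"doubling"`.
#' @return `"scn_test"` with the exact p-value and the odds-ratio estimate.
#' @export
fisher_exact_two_tailed <- function(table, rule = c("sum_small_p", "doubling")) {
  rule <- match.arg(rule)
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stop("table must be 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (rule == "sum_small_p") {
    ht <- stats::fisher.test(table)
    p <- ht$p.value
    or <- unname(ht$estimate)
  } else {
    x <- table[1, 1]
    m <- sum(table[1, ])   # first row total
    n <- sum(table[2, ])
    k <- sum(table[, 1])   # first column total
    lower <- stats::phyper(x, k, m + n - k, m)
    upper <- stats::phyper(x - 1, k, m + n - k, m, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    or <- suppressWarnings(unname(stats::fisher.test(table)$estimate))
  }
  .scn_test(paste0("Fisher's exact test (two-tailed, ", rule, ")"),
            statistic = NULL, p.value = min(p, 1), odds_ratio = or)
}

#' Pooled-variance two-sample t test
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return `"scn_test"` with t, df = nA + nB - 2 and the two-tailed p.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  sp2 <- (stats::var(a) * (length(a) - 1) + stats::var(b) * (length(b) - 1)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled variance; the t statistic is undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  .scn_test("Two-sample t test (pooled variance)",
            statistic = c(t = unname(ht$statistic)),
            df = unname(ht$parameter), p.value = ht$p.value,
            estimate = unname(diff(rev(ht$estimate))))
}

#' One-way ANCOVA for a group effect with covariate adjustment
#'
#' Least-squares fit of the response on group indicators plus covariates; the
#' group F statistic is the increment test
#' `F = ((SSE_reduced - SSE_full)/(k-1)) / MSE_full`, where the reduced model
#' drops the group factor.  Covariate-adjusted group means are evaluated at
#' the covariate means (via \pkg{emmeans}).
#'
#' @param values Numeric response (e.g. an ROI volume).
#' @param groups Group labels.
#' @param covariates Data frame of covariates (possibly zero columns, in
#'   which case the test reduces to [oneway_anova()]).
#' @param adjusted_means Compute covariate-adjusted group means (needed for
#'   [lsd_posthoc()]); disable in large simulation loops where only the
#'   omnibus F/p are used.
#' @return `"scn_test"` (class also `"scn_ancova"`) with F, df, p, the
#'   adjusted means, and the underlying `lm` fit.
#' @export
ancova_group_effect <- function(values, groups, covariates = NULL,
                                adjusted_means = TRUE) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(values))
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.y = values, .group = groups), covariates)
  rhs_cov <- if (ncol(covariates)) paste(colnames(covariates), collapse = " + ")
             else "1"
  full <- stats::lm(stats::as.formula(paste(".y ~", rhs_cov, "+ .group")),
                    data = dat)
  if (anyNA(stats::coef(full))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  }
  reduced <- stats::lm(stats::as.formula(paste(".y ~", rhs_cov)), data = dat)
  cmp <- stats::anova(reduced, full)
  df1 <- cmp$Df[2]
  df2 <- full$df.residual
  sse_full <- cmp$RSS[2]
  sse_red <- cmp$RSS[1]
  mse_full <- sse_full / df2
  F <- ((sse_red - sse_full) / df1) / mse_full
  # guard against negative rounding noise in a saturated null
  if (!is.finite(F) || F < 0) F <- 0
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  emm <- NULL
  adj <- NULL
  if (isTRUE(adjusted_means)) {
    emm <- emmeans::emmeans(full, ".group")
    emm_df <- as.data.frame(emm)
    adj <- stats::setNames(emm_df$emmean, as.character(emm_df$.group))
  }
  out <- .scn_test("One-way ANCOVA (group effect)",
                   statistic = c(F = F), df = c(df1, df2), p.value = p,
                   adjusted_means = adj,
                   fit = full, emmeans = emm, mse = mse_full)
  class(out) <- c("scn_ancova", class(out))
  out
}

#' LSD post hoc pairwise comparisons after ANCOVA
#'
#' Least-significant-difference comparisons of the covariate-adjusted group
#' means: each pairwise t uses the full-model MSE, and no multiplicity
#' correction is applied across pairs (that is the definition of LSD).
#'
#' @param ancova An `"scn_ancova"` object from [ancova_group_effect()].
#' @return Tibble with one row per group pair: `contrast`, `estimate` (adjusted
#'   mean difference), `se`, `df`, `t`, `p`.
#' @export
lsd_posthoc <- function(ancova) {
  stopifnot(inherits(ancova, "scn_ancova"))
  if (is.null(ancova$emmeans)) {
    stop("ANCOVA was fitted with adjusted_means = FALSE; re-fit with ",
         "adjusted_means = TRUE for post hoc contrasts")
  }
  prs <- emmeans::contrast(ancova$emmeans, method = "pairwise", adjust = "none")
  tab <- as.data.frame(prs)
  tibble::tibble(contrast = as.character(tab$contrast),
                 estimate = tab$estimate, se = tab$SE, df = tab$df,
                 t = tab$t.ratio, p = tab$p.value)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates (with intercept).  The p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `k` covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of covariates, or `NULL` for a plain
#'   Pearson correlation.
#' @return `"scn_test"` with the correlation `r`, df and two-tailed p.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates) || NCOL(covariates) == 0 || is.null(dim(covariates)) && length(covariates) == 0) {
    k <- 0L
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    covariates <- as.data.frame(covariates)
    k <- ncol(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)
    k <- ncol(mm) - 1L   # counts dummy-expanded covariate columns
    rx <- stats::resid(stats::lm.fit(mm, x))
    ry <- stats::resid(stats::lm.fit(mm, y))
  }
  if (n <= k + 2) stop("need n > number of covariates + 2")
  tol <- 1e-10
  if (stats::sd(rx) <= tol * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= tol * max(stats::sd(y), 1e-300)) {
    stop("constant residuals; partial correlation is undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  .scn_test("Partial correlation",
            statistic = c(r = r), df = df, p.value = min(p, 1),
            t = tstat, n = n, n_covariates = k)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; adjusted values are monotone,
#' never below the raw p, and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs preserved).
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p, method = "BH") {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}
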