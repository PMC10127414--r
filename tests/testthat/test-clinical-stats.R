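make_test_cohort <- function(n = 20, seed = 1) {
  set.seed(seed)
  spec <- cohort_spec(group_sizes = c(NC = n), seed = seed)
  generate_cohort(spec)
}

test_that("composite z-scores standardize, flip and average correctly", {
  co <- make_test_cohort(24)
  dm <- default_domain_map()

  # hand z-scores with the n-1 denominator
  one <- dm[dm$test == "sdmt", ]
  co4 <- co[1:4, ]
  co4$sdmt <- 1:4
  z <- composite_zscores(co4, one)
  expect_equal(z$executive, c(-1.1618950, -0.3872983, 0.3872983, 1.1618950),
               tolerance = 1e-6)

  # a one-test domain equals that test's z-score
  z_full <- composite_zscores(co, dm[dm$test == "bnt", ])
  expect_equal(z_full$language,
               (co$bnt - mean(co$bnt)) / sd(co$bnt))

  # higher-is-worse tests are sign-flipped before averaging
  tmt <- dm[dm$test == "tmt_a", ]
  z_tmt <- composite_zscores(co, tmt)
  expect_equal(z_tmt$executive,
               -(co$tmt_a - mean(co$tmt_a)) / sd(co$tmt_a))

  # the navigation composite is NOT flipped: higher error -> higher value
  z_all <- composite_zscores(co)
  err <- rowMeans(co[, grep("trial", names(co))])
  expect_gt(cor(z_all$navigation, err), 0.999)

  co$cdt <- 5
  expect_error(composite_zscores(co), "cdt")
})

test_that("median split ranks SCD subjects and respects the tie rule", {
  co <- make_test_cohort(80)
  co$group <- factor(rep("SCD", 80))
  err <- sample(1:80)
  for (cl in grep("trial", names(co), value = TRUE)) co[[cl]] <- err
  split <- split_scd_by_score(co, "navigation")
  expect_equal(as.character(split$group[order(err)]),
               rep(c("G-SCD", "B-SCD"), each = 40))

  # boundary tie: stable input order decides, with a warning
  err2 <- c(1:39, 40, 40, 42:80)
  for (cl in grep("trial", names(co), value = TRUE)) co[[cl]] <- err2
  expect_warning(split2 <- split_scd_by_score(co, "navigation"), "tie")
  expect_equal(as.character(split2$group[40]), "G-SCD")
  expect_equal(as.character(split2$group[41]), "B-SCD")

  # odd SCD count demands a configured rule
  expect_error(split_scd_by_score(co[1:79, ], "navigation"), "odd")
  s79 <- suppressWarnings(split_scd_by_score(co[1:79, ], "navigation",
                                             odd = "good"))
  expect_equal(sum(s79$group == "G-SCD"), 40)

  # cognitive-composite grouping ranks by ability (higher = better)
  co3 <- make_test_cohort(40)
  co3$group <- factor(rep("SCD", 40))
  sp_mem <- split_scd_by_score(co3, "memory")
  comps <- composite_zscores(co3)
  expect_true(min(comps$memory[sp_mem$group == "G-SCD"]) >=
                max(comps$memory[sp_mem$group == "B-SCD"]))
})

test_that("one-way ANOVA matches hand computation and the t-squared identity", {
  ht <- oneway_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                     rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(ht$statistic), 3.0)
  expect_equal(ht$df, c(2, 6))

  set.seed(1)
  x <- rnorm(12); g <- rep(c("a", "b"), 6)
  f2 <- oneway_anova(x, g)
  tt <- two_sample_t(x[g == "a"], x[g == "b"])
  expect_equal(unname(f2$statistic), unname(tt$statistic)^2)
  expect_equal(f2$p.value, tt$p.value)

  expect_equal(unname(oneway_anova(c(1, 2, 1, 2, 1, 2),
                                   rep(c("a", "b", "c"), each = 2))$statistic), 0)
  expect_error(oneway_anova(rep(1, 6), rep(c("a", "b"), 3)), "variance")
})

test_that("chi-square uses Pearson's statistic without continuity correction", {
  # proportional table -> statistic exactly zero
  prop <- matrix(c(10, 20, 20, 40), 2, 2)
  expect_equal(unname(chi_square_test(prop)$statistic), 0)

  # random tables match the direct formula
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 10) + 1, 2, 3)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(unname(chi_square_test(tab)$statistic),
                 sum((tab - e)^2 / e))
  }
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
})

test_that("two-tailed Fisher test matches enumeration and both tail rules", {
  expect_equal(fisher_exact_two_tailed(matrix(c(5, 5, 5, 5), 2, 2))$p.value, 1)

  tab <- matrix(c(1, 9, 9, 1), 2, 2)
  expect_equal(fisher_exact_two_tailed(tab)$p.value, oracle_fisher(tab))

  # the doubling rule is more conservative on this asymmetric table
  tab2 <- matrix(c(1, 11, 9, 3), 2, 2)
  p_sum <- fisher_exact_two_tailed(tab2)$p.value
  p_dbl <- fisher_exact_two_tailed(tab2, rule = "doubling")$p.value
  expect_equal(p_sum, oracle_fisher(tab2))
  expect_gte(p_dbl, p_sum)
})

test_that("pooled two-sample t matches hand computation", {
  ht <- two_sample_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(unname(ht$statistic), -2.190890, tolerance = 1e-6)
  expect_equal(ht$df, 6)
  ht0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
  expect_error(two_sample_t(rep(2, 4), rep(2, 3)), "variance")
})

test_that("ANCOVA group F nests one-way ANOVA and matches normal equations", {
  set.seed(3)
  v <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
  expect_equal(unname(ancova_group_effect(v, g)$statistic),
               unname(oneway_anova(v, g)$statistic))

  # 12-subject fixture, 3 groups, 2 covariates: explicit normal equations
  n <- 12
  g <- rep(c("a", "b", "c"), each = 4)
  x1 <- rnorm(n); x2 <- rnorm(n)
  v <- 2 + 0.5 * x1 - 0.3 * x2 + (g == "b") * 0.8 + rnorm(n)
  anc <- ancova_group_effect(v, g, data.frame(x1 = x1, x2 = x2))
  X_full <- cbind(1, x1, x2, g == "b", g == "c")
  X_red <- cbind(1, x1, x2)
  sse <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% v)
    sum((v - X %*% beta)^2)
  }
  F_hand <- ((sse(X_red) - sse(X_full)) / 2) / (sse(X_full) / (n - 5))
  expect_equal(unname(anc$statistic), F_hand)
  expect_equal(anc$df, c(2, n - 5))

  # no group effect after covariate adjustment -> F = 0, p = 1
  tiv <- rnorm(24)
  g2 <- rep(c("a", "b", "c"), each = 8)
  mm <- model.matrix(~ tiv + g2)
  e <- residuals(lm(rnorm(24) ~ mm))
  v2 <- 3 + 2 * tiv + e
  anc0 <- ancova_group_effect(v2, g2, data.frame(tiv = tiv))
  expect_lt(unname(anc0$statistic), 1e-8)
  expect_gt(anc0$p.value, 0.999)

  # rank deficiency is reported
  expect_error(ancova_group_effect(v, g, data.frame(x1 = x1, x1b = x1)),
               "aliased")
})

test_that("ANCOVA F is invariant to affine rescaling of covariates", {
  set.seed(8)
  co <- generate_cohort(cohort_spec(seed = 8))
  covs <- data.frame(age = co$age, tiv = co$tiv, sex = co$sex)
  f1 <- ancova_group_effect(co$`Basal forebrain`, co$group, covs)
  covs2 <- transform(covs, age = (age - 65) / 10, tiv = 3 * tiv + 2)
  f2 <- ancova_group_effect(co$`Basal forebrain`, co$group, covs2)
  expect_equal(unname(f1$statistic), unname(f2$statistic))
  expect_equal(f1$p.value, f2$p.value)
})

test_that("LSD post hoc equals contrast-vector oracle and ANCOVA for 2 groups", {
  set.seed(9)
  n <- 30
  g <- rep(c("a", "b", "c"), each = 10)
  x <- rnorm(n)
  v <- 1 + x + (g == "c") * 1.2 + rnorm(n)
  anc <- ancova_group_effect(v, g, data.frame(x = x))
  lsd <- lsd_posthoc(anc)
  expect_equal(nrow(lsd), 3)

  # generalized-least-squares contrast oracle at covariate means
  X <- cbind(1, g == "b", g == "c", x)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% v
  s2 <- sum((v - X %*% beta)^2) / (n - 4)
  contr <- list(`a - b` = c(0, -1, 0, 0), `a - c` = c(0, 0, -1, 0),
                `b - c` = c(0, 1, -1, 0))
  for (nm in names(contr)) {
    cv <- contr[[nm]]
    t_hand <- sum(cv * beta) / sqrt(s2 * t(cv) %*% XtXi %*% cv)
    expect_equal(lsd$t[lsd$contrast == nm], as.numeric(t_hand),
                 tolerance = 1e-8)
  }

  # two groups: the single pairwise p equals the omnibus ANCOVA p
  anc2 <- ancova_group_effect(v[g != "c"], g[g != "c"],
                              data.frame(x = x[g != "c"]))
  lsd2 <- lsd_posthoc(anc2)
  expect_equal(lsd2$p, anc2$p.value)

  # identical adjusted means -> t = 0, p = 1
  vv <- rep(c(1, 2), 10)
  gg <- rep(c("a", "b"), each = 10)
  vv <- c(vv[1:10], vv[1:10])  # same values in both groups
  anc3 <- ancova_group_effect(vv + 0.001 * rnorm(20), gg)
  lsd3 <- lsd_posthoc(ancova_group_effect(c(vv[1:10], vv[1:10]) + rep(rnorm(10), 2), gg))
  expect_equal(lsd3$t[1], 0, tolerance = 1e-8)
  expect_equal(lsd3$p[1], 1, tolerance = 1e-8)
})

test_that("partial correlation reduces to Pearson and matches the recursion", {
  set.seed(10)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(unname(partial_correlation(x, y)$statistic), cor(x, y))
  expect_equal(unname(partial_correlation(x, x, data.frame(z = rnorm(30)))$statistic),
               1)

  # 8-point fixture against the closed-form first-order recursion
  x8 <- c(1.2, 0.4, -0.3, 2.2, 1.7, -0.9, 0.1, 0.8)
  y8 <- c(0.6, 1.1, -0.2, 1.9, 2.4, -1.2, 0.3, 0.2)
  z8 <- c(0.1, 0.9, -0.5, 1.2, 1.5, -0.8, 0.2, -0.1)
  r_hand <- (cor(x8, y8) - cor(x8, z8) * cor(y8, z8)) /
    sqrt((1 - cor(x8, z8)^2) * (1 - cor(y8, z8)^2))
  pc <- partial_correlation(x8, y8, data.frame(z = z8))
  expect_equal(unname(pc$statistic), r_hand)
  expect_equal(pc$df, 8 - 2 - 1)

  expect_error(partial_correlation(z8, y8, data.frame(z = z8)), "constant")
})

test_that("Benjamini-Hochberg adjustment follows the step-up definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- runif(20)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})
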