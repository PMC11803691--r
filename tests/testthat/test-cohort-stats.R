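test_that("spearman handles monotone, reversed and tied data", {
  x <- 1:10
  expect_equal(spearman(x, x^2)$estimate, 1)
  expect_equal(spearman(x, rev(x))$estimate, -1)
  expect_error(spearman(1:3, 1:3), "at least 4")
  expect_true(is.na(spearman(rep(1, 6), 1:6)$estimate))
})

test_that("spearman p agrees with the exact permutation null at n = 8", {
  set.seed(17)
  x <- rnorm(8); y <- 0.8 * x + rnorm(8, sd = 0.6)
  res <- spearman(x, y)
  rx <- rank(x); ry <- rank(y)
  expect_equal(res$estimate, cor(rx, ry), tolerance = 1e-12)
  perms <- all_perms(8)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  p_exact <- mean(abs(rhos) >= abs(res$estimate) - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.03)
})

test_that("partial spearman matches the closed-form rank formula", {
  set.seed(23)
  for (i in 1:8) {
    n <- 10
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    res <- partial_spearman(x, y, z)
    expect_equal(res$estimate, oracle_partial_rho(x, y, z),
                 tolerance = 1e-10)
  }
  # x = y with independent z: perfect partial correlation
  x <- rnorm(20)
  expect_equal(partial_spearman(x, x, rnorm(20))$estimate, 1)
})

test_that("partial spearman removes purely covariate-driven association", {
  set.seed(41)
  n <- 500
  z <- rnorm(n)
  x <- 2 * z + rnorm(n)
  y <- -1.5 * z + rnorm(n)
  raw <- spearman(x, y)
  adj <- partial_spearman(x, y, z)
  expect_lt(raw$estimate, -0.5)  # confounded marginal association
  expect_lt(abs(adj$estimate), 0.1)
})

test_that("constant covariate falls back to plain spearman with a warning", {
  set.seed(3)
  x <- rnorm(12); y <- rnorm(12)
  expect_warning(res <- partial_spearman(x, y, rep(2, 12)), "constant")
  expect_equal(res$estimate, spearman(x, y)$estimate)
  expect_equal(res$p_value, spearman(x, y)$p_value)
})

make_groups <- function(n1, n2, ga1, ga2, beta_ga, delta, sd, seed) {
  with_seed <- placentaflow:::with_seed
  with_seed(seed, {
    ga <- c(rnorm(n1, ga1, 2), rnorm(n2, ga2, 2))
    grp <- c(rep("control", n1), rep("CHD", n2))
    y <- 100 + beta_ga * ga + delta * (grp == "CHD") + rnorm(n1 + n2, sd = sd)
    data.frame(id = sprintf("s%03d", seq_along(y)), group = grp,
               ga_weeks = ga, y = y)
  })
}

test_that("ANCOVA is unbiased under the null and recovers confounded effects", {
  # null: identical generative means, shared covariate trend
  tab <- make_groups(100, 100, 34, 34, -3, 0, 5, seed = 55)
  a <- ancova_group(tab, "y")
  expect_lt(abs(a$stat$estimate) / a$emm$diff_se, 3)
  # confounded design: control older, true deficit -10
  tab2 <- make_groups(100, 100, 35, 31, -3, -10, 5, seed = 56)
  a2 <- ancova_group(tab2, "y")
  emm_diff <- a2$emm$group_means["CHD"] - a2$emm$group_means["control"]
  expect_lt(abs(emm_diff - (-10)), 3 * a2$emm$diff_se)
  raw_diff <- mean(tab2$y[tab2$group == "CHD"]) -
    mean(tab2$y[tab2$group == "control"])
  # GA gap of ~4 weeks at slope -3 biases the raw difference by ~ +12
  expect_gt(abs(raw_diff - (-10)), 6)
})

test_that("ANCOVA equals ANOVA when the covariate has no effect", {
  tab <- make_groups(150, 150, 34, 34, 0, -4, 6, seed = 57)
  a <- ancova_group(tab, "y")
  b <- anova_group(tab, "y")
  expect_equal(a$stat$estimate, b$estimate, tolerance = 0.15)
  expect_equal(log10(a$stat$p_value), log10(b$p_value), tolerance = 0.5)
})

test_that("estimated marginal means agree with emmeans", {
  skip_if_not_installed("emmeans")
  tab <- make_groups(40, 60, 35, 32, -2.5, -8, 5, seed = 58)
  a <- ancova_group(tab, "y")
  fit <- lm(y ~ group + ga_weeks,
            data = transform(tab, group = factor(group,
                                                 c("control", "CHD"))))
  em <- as.data.frame(emmeans::emmeans(fit, "group"))
  expect_equal(unname(a$emm$group_means), em$emmean, tolerance = 1e-10)
  expect_equal(unname(a$emm$se), em$SE, tolerance = 1e-10)
})

test_that("EMM difference is invariant to recentering the covariate", {
  tab <- make_groups(40, 60, 35, 32, -2.5, -8, 5, seed = 59)
  a1 <- ancova_group(tab, "y")
  tab2 <- tab; tab2$ga_weeks <- tab2$ga_weeks - 30
  a2 <- ancova_group(tab2, "y")
  d1 <- diff(a1$emm$group_means)
  d2 <- diff(a2$emm$group_means)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-10)
})

test_that("interaction test recovers slope differences", {
  set.seed(61)
  n <- 150
  grp <- rep(c("control", "CHD"), each = n)
  x <- rnorm(2 * n, 100, 15)
  make_y <- function(delta_slope) {
    50 + 0.5 * x + delta_slope * x * (grp == "CHD") + rnorm(2 * n, sd = 8)
  }
  tab0 <- data.frame(id = as.character(1:(2 * n)), group = grp,
                     yv = make_y(0), xv = x)
  r0 <- interaction_test(tab0, "yv", "xv")
  fit0 <- lm(yv ~ xv * factor(group, c("control", "CHD")), data = tab0)
  se0 <- summary(fit0)$coefficients[4, "Std. Error"]
  expect_lt(abs(r0$estimate), 3 * se0)
  tab1 <- tab0; tab1$yv <- make_y(0.3)
  r1 <- interaction_test(tab1, "yv", "xv")
  expect_lt(abs(r1$estimate - 0.3), 0.1)
  expect_lt(r1$p_value, 0.01)
  # constant group is an error
  tab2 <- tab0[tab0$group == "CHD", ]
  expect_error(interaction_test(tab2, "yv", "xv"), "constant")
})

test_that("Mann-Whitney branches agree and match exact references", {
  # completely separated samples of 5 and 5: U = 0, exact p = 2/252
  res <- mann_whitney(1:5, 11:15)
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
  # identical samples: U at its mean, p in the no-evidence region
  res2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res2$estimate, 8)  # n1*n2/2
  expect_gt(res2$p_value, 0.9)
  # exact vs approximate agreement at combined n = 12
  set.seed(71)
  x <- rnorm(6); y <- rnorm(6, 0.5)
  p_exact <- mann_whitney(x, y)$p_value
  p_approx <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.02)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Shapiro-Wilk gate separates Gaussian from heavy-tailed data", {
  set.seed(81)
  expect_equal(shapiro_gate(rnorm(500)), "parametric")
  expect_equal(shapiro_gate(exp(rnorm(500, sd = 1.5))), "nonparametric")
  expect_equal(shapiro_gate(rep(3, 10)), "nonparametric")
  expect_equal(shapiro_gate(c(1, 2)), "nonparametric")
})

test_that("BH adjustment matches the definitional step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(92)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output is monotone along sorted p and order invariant", {
  set.seed(93)
  p <- runif(20)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-14)
})

test_that("the full report covers every analysis family", {
  g <- generate_cohort(cohort_spec(seed = 5))
  rep <- run_statistics(g$table)
  expect_setequal(unique(rep$ga_correlations$metric),
                  c("placenta_t2", "brain_t2", "volume_mm3", "texture",
                    "thickness_mm", "morphology"))
  expect_setequal(unique(rep$ga_correlations$subset),
                  c("all", "control", "CHD"))
  expect_equal(nrow(rep$group_comparisons), 6)
  expect_true(all(rep$group_comparisons$p_fdr >=
                    rep$group_comparisons$p_value - 1e-14))
  expect_setequal(unique(rep$partial_correlations$panel),
                  c("brain_vs_placenta", "texture_vs_placenta_t2"))
  expect_equal(sum(rep$partial_correlations$test == "interaction"), 2)
  expect_equal(rep$meta$n_control + rep$meta$n_chd, 81)
  expect_equal(nrow(rep$demographics), 2)
  expect_error(run_statistics(g$table[, -5]), "missing columns")
})

test_that("a single-group cohort skips group tests with a notice", {
  g <- generate_cohort(cohort_spec(seed = 6))
  solo <- g$table[g$table$group == "CHD", ]
  rep <- run_statistics(solo)
  expect_null(rep$group_comparisons)
  expect_null(rep$demographics)
  expect_match(rep$meta$notes, "skipped")
  expect_false(is.null(rep$ga_correlations))
})
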